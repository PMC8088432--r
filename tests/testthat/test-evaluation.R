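test_that("prediction R^2 matches its proportional-error definition", {
  m <- prediction_r2(c(1, 2, 3), full_pred = c(1.5, 2, 2.5), compact_pred = c(2, 2, 2))
  expect_equal(m$mse_full, 1 / 6)
  expect_equal(m$mse_compact, 2 / 3)
  expect_equal(m$prediction_r2, 0.75)
  obs <- rnorm(10)
  same <- rnorm(10)
  expect_equal(prediction_r2(obs, same, same)$prediction_r2, 0)
  expect_equal(prediction_r2(obs, obs, same)$prediction_r2, 1)
  expect_error(prediction_r2(obs, same, obs), "perfect")
  # invariant to joint relabeling of subjects
  p <- sample(10)
  expect_equal(prediction_r2(obs[p], same[p], (obs + 1)[p])$prediction_r2,
               prediction_r2(obs, same, obs + 1)$prediction_r2)
})

test_that("model-based R^2 is the squared correlation with predictions", {
  m <- model_based_r2(c(0, 1, 2), full_pred = c(0, 2, 4), compact_pred = c(0, 1, 1))
  expect_equal(m$r2_full, 1)
  expect_equal(m$r2_compact, 0.75)
  expect_equal(m$delta_model_r2, 0.25)
  obs <- rnorm(20)
  expect_equal(model_based_r2(obs, 3 * obs + 5, obs + rnorm(20))$r2_full, 1)
  full <- obs + rnorm(20)
  expect_equal(model_based_r2(obs, full + 7, obs)$r2_full,
               model_based_r2(obs, full, obs)$r2_full) # translation invariance
  expect_error(model_based_r2(obs, rep(1, 20), obs), "constant")
})

test_that("both metrics agree with from-definition oracles on random inputs", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    obs <- rnorm(n); full <- rnorm(n); compact <- obs + rnorm(n)
    expect_equal(prediction_r2(obs, full, compact)$prediction_r2,
                 oracle_prediction_r2(obs, full, compact), tolerance = 1e-12)
    expect_equal(model_based_r2(obs, full, compact)$delta_model_r2,
                 oracle_delta_model_r2(obs, full, compact), tolerance = 1e-12)
  }
})

test_that("a perfectly predictive connectivity term earns the minimum p", {
  set.seed(2)
  n <- 10
  spec <- fixed_model_spec()
  baseline <- rnorm(n, 82, 18)
  conn <- zscore_across_subjects(rnorm(n))
  # outcome built so the frozen full model is exact: any shuffle can only hurt
  observed <- spec$beta_baseline * (baseline - mean(baseline)) + spec$beta_conn * conn
  pt <- permutation_test(baseline, conn, observed, spec, n_perms = 999, seed = 5)
  expect_equal(pt$p_value, 1 / 1000)
  expect_equal(pt$observed_stat, 1)
})

test_that("sampled permutation p agrees with the exhaustive oracle at n = 6", {
  set.seed(8)
  n <- 6
  spec <- fixed_model_spec()
  baseline <- rnorm(n, 82, 18)
  conn <- zscore_across_subjects(rnorm(n))
  observed <- 0.5 * (baseline - mean(baseline)) + 4 * conn + rnorm(n, 0, 10)
  for (metric in c("prediction_r2", "delta_model_r2")) {
    exact <- oracle_exhaustive_p(baseline, conn, observed, spec, metric)
    B <- 2000
    pt <- permutation_test(baseline, conn, observed, spec, metric = metric,
                           n_perms = B, seed = 3)
    mc_se <- sqrt(exact * (1 - exact) / B)
    expect_lt(abs(pt$p_value - exact), 3 * mc_se + 2 / B)
  }
})

test_that("permutation tests are deterministic and report sane fields", {
  co <- quick_cohort(seed = 33)
  z <- zscore_across_subjects(fisher_z(co$true_composite_conn))
  a <- permutation_test(co$baseline_lsas, z, co$delta_lsas, n_perms = 499, seed = 4)
  b <- permutation_test(co$baseline_lsas, z, co$delta_lsas, n_perms = 499, seed = 4)
  expect_identical(a$null_stats, b$null_stats)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 500)
  expect_lte(a$p_value, 1)
  expect_length(a$null_stats, 499)
  expect_equal(unname(quantile(a$null_stats, 0.95)), a$crit95)
  expect_error(permutation_test(co$baseline_lsas[1:4], z[1:4], co$delta_lsas[1:4]),
               "at least 5")
  expect_error(permutation_test(co$baseline_lsas, z, co$delta_lsas, n_perms = 10),
               "at least 99")
})

test_that("run_replication pipelines the cohort end to end", {
  co <- quick_cohort(seed = 12, r2_conn = 0.21, dropout_rate = 0.1)
  rep1 <- run_replication(co, n_perms = 199, seed = 6)
  expect_s3_class(rep1, "replication_report")
  expect_equal(rep1$n, sum(co$sessions_completed >= 12))
  expect_named(rep1$permutations, c("prediction_r2", "delta_model_r2"))
  # LOCF outcome recomputed from the series matches the stored column
  eligible <- eligible_subjects(co)
  expect_equal(rep1$predictions$observed,
               eligible$delta_lsas - mean(eligible$delta_lsas))
  # subset restricts before z-scoring
  imm <- run_replication(co, subset = "immediate_only", n_perms = 199, seed = 6)
  expect_equal(imm$n, sum(eligible$group == "immediate"))
  expect_equal(mean(imm$predictions$observed), 0, tolerance = 1e-10)
  # determinism
  rep2 <- run_replication(co, n_perms = 199, seed = 6)
  expect_equal(tidy(rep1), tidy(rep2))
  expect_output(print(rep1), "prediction R")
  gl <- glance(rep1)
  expect_equal(gl$n, rep1$n)
  # normality diagnostics are reported for all three model terms
  expect_named(rep1$normality, c("baseline_lsas", "amyg_conn", "delta_lsas"))
})

test_that("autoplot methods return ggplot objects", {
  co <- quick_cohort(seed = 3)
  rep1 <- run_replication(co, n_perms = 199, seed = 1)
  expect_s3_class(autoplot(rep1), "ggplot")
  expect_s3_class(autoplot(rep1$permutations$prediction_r2), "ggplot")
})

test_that("Anderson-Darling check flags gross non-normality only", {
  set.seed(10)
  ok <- replicate(100, check_normality(rnorm(200))$p.value)
  expect_gte(mean(ok > 0.05), 0.9)
  bimodal <- c(rnorm(250, -5, 0.5), rnorm(250, 5, 0.5))
  expect_lt(check_normality(bimodal)$p.value, 0.001)
  x <- rnorm(100)
  expect_equal(check_normality(3 * x + 7)$statistic, check_normality(x)$statistic,
               tolerance = 1e-10)
  expect_error(check_normality(rnorm(5)), "at least 8")
})

test_that("correlation power matches the Fisher-z closed form", {
  expect_equal(correlation_power(0, 40), 0.05, tolerance = 1e-10)
  # frozen from the closed form: Phi(atanh(.3)*sqrt(37) - 1.96) + Phi(-...)
  expect_equal(correlation_power(0.3, 40), 0.4693, tolerance = 1e-4)
  expect_gt(correlation_power(0.99, 40), 0.999)
  expect_equal(correlation_power(-0.3, 40), correlation_power(0.3, 40))
  expect_error(correlation_power(1, 40), "inside")
  expect_error(correlation_power(0.3, 3), "n >= 4")
})

test_that("variance-explained confidence intervals use the Fisher-z route", {
  ci <- r2_confidence_interval(0.46, 38)
  expect_equal(ci$lower_pct, 2.7, tolerance = 0.05 / 2.7)
  expect_equal(ci$upper_pct, 46.2, tolerance = 0.05 / 46.2)
  # degenerate level: both endpoints collapse to the point estimate
  tiny <- r2_confidence_interval(0.46, 38, level = 1e-12)
  expect_equal(tiny$lower_pct, 100 * 0.46^2, tolerance = 1e-6)
  expect_equal(tiny$upper_pct, 100 * 0.46^2, tolerance = 1e-6)
  # interval straddling zero clamps the lower bound
  low <- r2_confidence_interval(0.1, 38)
  expect_equal(low$lower_pct, 0)
  expect_error(r2_confidence_interval(-0.2, 38), "strictly in")
  expect_error(r2_confidence_interval(0.5, 3), "n >= 4")
})
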