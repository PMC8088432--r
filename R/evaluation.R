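# Scoring the frozen model against the compact model, permutation
# inference, and the closed-form power / confidence-interval calculations.

#' Prediction R-squared (proportional reduction in squared error)
#'
#' Absolute accuracy gain of the full model over the compact model:
#' `NMSE = MSE(observed, full) / MSE(observed, compact)` and
#' `prediction R^2 = 1 - NMSE`. Zero means no improvement; negative values
#' mean the full model predicts worse than the compact model.
#'
#' @param observed Observed change scores.
#' @param full_pred,compact_pred Predictions of the full and compact models.
#' @return A one-row tibble: `mse_full`, `mse_compact`, `nmse`,
#'   `prediction_r2`.
#' @export
prediction_r2 <- function(observed, full_pred, compact_pred) {
  n <- length(observed)
  if (n < 2 || length(full_pred) != n || length(compact_pred) != n) {
    abort("All three vectors must have equal length >= 2.")
  }
  mse_full <- mean((observed - full_pred)^2)
  mse_compact <- mean((observed - compact_pred)^2)
  if (mse_compact == 0) abort("Compact model is perfect: NMSE is undefined.")
  tibble::tibble(
    mse_full = mse_full, mse_compact = mse_compact,
    nmse = mse_full / mse_compact,
    prediction_r2 = 1 - mse_full / mse_compact
  )
}

#' Model-based R-squared (squared correlation with predictions)
#'
#' Scale-free accuracy: squared Pearson correlation between observed
#' outcomes and each model's predictions, and their difference.
#'
#' @inheritParams prediction_r2
#' @return A one-row tibble: `r2_full`, `r2_compact`, `delta_model_r2`.
#' @export
model_based_r2 <- function(observed, full_pred, compact_pred) {
  for (v in list(observed, full_pred, compact_pred)) {
    if (sd(v) == 0) abort("Model-based R^2 is undefined for a constant vector.")
  }
  r2f <- cor(observed, full_pred)^2
  r2c <- cor(observed, compact_pred)^2
  tibble::tibble(r2_full = r2f, r2_compact = r2c, delta_model_r2 = r2f - r2c)
}

# Predictions of the frozen full/compact models on a (centered) cohort.
# In the centered convention baseline and outcome are cohort mean-centered
# and the connectivity term is the (mean-zero) cohort z-score.
frozen_predictions <- function(spec, baseline_lsas, amyg_conn, observed) {
  if (spec$centered) {
    baseline <- baseline_lsas - mean(baseline_lsas)
    obs <- observed - mean(observed)
  } else {
    baseline <- baseline_lsas
    obs <- observed
  }
  list(
    full = predict_fixed(spec, baseline, amyg_conn),
    compact = predict_compact(spec, baseline),
    observed = obs
  )
}

eval_metric <- function(metric, observed, full, compact) {
  if (metric == "prediction_r2") {
    prediction_r2(observed, full, compact)$prediction_r2
  } else {
    model_based_r2(observed, full, compact)$delta_model_r2
  }
}

#' Permutation test for the connectivity term's predictive value
#'
#' Builds a null distribution for a model-comparison statistic by repeatedly
#' shuffling the connectivity term across subjects while keeping the
#' baseline-outcome pairing fixed, recomputing the frozen full-model
#' predictions and the statistic each time (the compact model does not
#' involve the permuted term and is unchanged). The p-value uses the
#' add-one estimator `(1 + #[null >= observed]) / (1 + n_perms)`; the 95th
#' percentile of the null is also reported as a rejection criterion.
#'
#' @param baseline_lsas,amyg_conn,observed Per-subject model inputs and
#'   outcomes (`amyg_conn` standardized, e.g. `cohort_z`).
#' @param spec A [fixed_model_spec()].
#' @param metric `"prediction_r2"` (default) or `"delta_model_r2"`.
#' @param n_perms Number of permutations (default 10000).
#' @param seed RNG seed for the permutation stream.
#' @return An object of class `perm_test`: `observed_stat`, `null_stats`,
#'   `n_perms`, `p_value`, `crit95`, `seed`, `metric`, `n_redrawn`.
#' @export
permutation_test <- function(baseline_lsas, amyg_conn, observed,
                             spec = fixed_model_spec(),
                             metric = c("prediction_r2", "delta_model_r2"),
                             n_perms = 10000L, seed = 1L) {
  metric <- match.arg(metric)
  n <- length(observed)
  if (n < 5) abort("Permutation test needs at least 5 subjects.")
  if (n_perms < 99) abort("Use at least 99 permutations.")
  preds <- frozen_predictions(spec, baseline_lsas, amyg_conn, observed)
  observed_stat <- eval_metric(metric, preds$observed, preds$full, preds$compact)

  set.seed(as.integer(seed))
  compact <- preds$compact
  obs <- preds$observed
  resid_compact <- obs - compact
  mse_compact <- mean(resid_compact^2)
  bc <- spec$beta_conn

  null_stats <- numeric(n_perms)
  n_redrawn <- 0L
  for (b in seq_len(n_perms)) {
    repeat {
      perm_conn <- amyg_conn[sample.int(n)]
      full_b <- compact + bc * perm_conn
      stat <- if (metric == "prediction_r2") {
        1 - mean((obs - full_b)^2) / mse_compact
      } else {
        if (sd(full_b) == 0) NA_real_ else cor(obs, full_b)^2 - cor(obs, compact)^2
      }
      if (is.finite(stat)) break
      n_redrawn <- n_redrawn + 1L
    }
    null_stats[b] <- stat
  }
  structure(
    list(
      observed_stat = observed_stat, null_stats = null_stats,
      n_perms = as.integer(n_perms),
      p_value = (1 + sum(null_stats >= observed_stat)) / (1 + n_perms),
      crit95 = unname(quantile(null_stats, 0.95)),
      seed = as.integer(seed), metric = metric, n_redrawn = n_redrawn
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> %s = %.4f; p = %.4g (%d permutations); 95th null percentile = %.4f\n",
    x$metric, x$observed_stat, x$p_value, x$n_perms, x$crit95
  ))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, estimate = x$observed_stat, p.value = x$p_value,
    crit95 = x$crit95, n.perms = x$n_perms
  )
}

#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(stat = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_stat, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$crit95, linetype = "dashed") +
    ggplot2::labs(
      x = object$metric, y = "permutations",
      title = sprintf("Permutation null (%d shuffles), p = %.3g",
                      object$n_perms, object$p_value),
      subtitle = "solid: observed statistic; dashed: 95th null percentile"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Run the full replication workflow on a cohort
#'
#' End-to-end external validation: filter to treatment completers, derive
#' the outcome by last observation carried forward, restrict to the
#' requested subset, standardize the connectivity term across the analyzed
#' subjects, score the frozen model against the compact model (prediction
#' and model-based R-squared, centered convention by default), and run a
#' permutation test for each metric. Normality of the three model terms is
#' checked with the Anderson-Darling test.
#'
#' @param cohort Subject tibble (see [simulate_clinical_cohort()]); must
#'   contain `baseline_lsas`, `sessions_completed`, `group`, and either
#'   `lsas_series` or `post_lsas`/`delta_lsas`.
#' @param conn Per-subject connectivity on the Fisher-z scale, aligned with
#'   `cohort` rows: a column name (default `"fisher_z"` if present,
#'   otherwise the Fisher transform of `true_composite_conn`) or a numeric
#'   vector. Standardization across analyzed subjects happens inside, after
#'   subsetting.
#' @param spec A [fixed_model_spec()].
#' @param subset `"all"` (default) or `"immediate_only"` (the subset treated
#'   without a waitlist delay).
#' @param n_perms Permutations per metric (default 10000).
#' @param seed RNG seed for the permutation streams.
#' @param min_sessions Eligibility threshold (default 12 of 16 sessions).
#' @return An object of class `replication_report`: metric tibble, one
#'   `perm_test` per metric, normality checks, the analyzed data, and a
#'   configuration echo.
#' @export
run_replication <- function(cohort, conn = NULL, spec = fixed_model_spec(),
                            subset = c("all", "immediate_only"),
                            n_perms = 10000L, seed = 1L,
                            min_sessions = 12L) {
  subset <- match.arg(subset)
  data <- cohort
  data$.conn_fz <- resolve_conn(data, conn)
  data <- eligible_subjects(data, min_sessions)
  if ("lsas_series" %in% names(data)) {
    data$post_lsas <- vapply(data$lsas_series, apply_locf, numeric(1))
    data$delta_lsas <- data$baseline_lsas - data$post_lsas
  }
  if (subset == "immediate_only") {
    data <- dplyr::filter(data, .data$group == "immediate")
  }
  n <- nrow(data)
  if (n < 5) abort("Fewer than 5 analyzable subjects after filtering.")

  amyg_conn <- zscore_across_subjects(data$.conn_fz)
  preds <- frozen_predictions(spec, data$baseline_lsas, amyg_conn, data$delta_lsas)
  metrics <- dplyr::bind_cols(
    prediction_r2(preds$observed, preds$full, preds$compact),
    model_based_r2(preds$observed, preds$full, preds$compact)
  )
  perms <- list(
    prediction_r2 = permutation_test(
      data$baseline_lsas, amyg_conn, data$delta_lsas, spec,
      metric = "prediction_r2", n_perms = n_perms, seed = seed
    ),
    delta_model_r2 = permutation_test(
      data$baseline_lsas, amyg_conn, data$delta_lsas, spec,
      metric = "delta_model_r2", n_perms = n_perms, seed = seed + 1L
    )
  )
  normality <- if (n >= 8) {
    purrr::map(
      list(baseline_lsas = data$baseline_lsas, amyg_conn = amyg_conn,
           delta_lsas = data$delta_lsas),
      check_normality
    )
  } else {
    NULL
  }
  predictions <- tibble::tibble(
    subject_id = data$subject_id %||% sprintf("S%03d", seq_len(n)),
    observed = preds$observed, pred_full = preds$full,
    pred_compact = preds$compact
  )
  structure(
    list(
      metrics = metrics, permutations = perms, normality = normality,
      predictions = predictions, n = n, subset = subset,
      config = list(spec = spec, n_perms = n_perms, seed = seed,
                    min_sessions = min_sessions, centered = spec$centered)
    ),
    class = "replication_report"
  )
}

resolve_conn <- function(data, conn) {
  if (is.numeric(conn)) {
    if (length(conn) != nrow(data)) abort("`conn` vector must align with the cohort rows.")
    return(conn)
  }
  col <- if (is.character(conn)) conn else if ("fisher_z" %in% names(data)) "fisher_z" else NULL
  if (!is.null(col)) {
    if (!col %in% names(data)) abort(sprintf("Connectivity column `%s` not found.", col))
    return(data[[col]])
  }
  if ("true_composite_conn" %in% names(data)) {
    return(fisher_z(data$true_composite_conn))
  }
  abort("No connectivity source: supply `conn` or a fisher_z / true_composite_conn column.")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report> n = %d subjects (%s subset), %s model\n",
              x$n, x$subset,
              if (x$config$centered) "centered intercept-free" else "original"))
  m <- x$metrics
  cat(sprintf("  prediction R^2 = %.4f (p = %.4g)\n",
              m$prediction_r2, x$permutations$prediction_r2$p_value))
  cat(sprintf("  model-based R^2: full %.4f, compact %.4f, delta %.4f (p = %.4g)\n",
              m$r2_full, m$r2_compact, m$delta_model_r2,
              x$permutations$delta_model_r2$p_value))
  if (!is.null(x$normality)) {
    ps <- vapply(x$normality, function(z) z$p.value, numeric(1))
    cat(sprintf("  Anderson-Darling normality p: %s\n",
                paste(sprintf("%s %.2f", names(ps), ps), collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.replication_report <- function(x, ...) {
  tibble::tibble(
    metric = c("prediction_r2", "delta_model_r2"),
    estimate = c(x$metrics$prediction_r2, x$metrics$delta_model_r2),
    p.value = c(x$permutations$prediction_r2$p_value,
                x$permutations$delta_model_r2$p_value),
    crit95 = c(x$permutations$prediction_r2$crit95,
               x$permutations$delta_model_r2$crit95)
  )
}

#' @export
glance.replication_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = x$n, subset = x$subset),
    x$metrics
  )
}

#' @export
autoplot.replication_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$predictions,
                            cols = c("pred_full", "pred_compact"),
                            names_to = "model", values_to = "predicted")
  df$model <- ifelse(df$model == "pred_full", "full (with connectivity)",
                     "compact (baseline only)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "predicted change in LSAS", y = "observed change in LSAS",
                  colour = NULL,
                  title = "Observed vs. predicted treatment response") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Anderson-Darling normality check
#'
#' Composite normality test (mean and variance estimated) used to verify
#' that the model terms are approximately Gaussian.
#'
#' @param values Numeric sample, at least 8 observations.
#' @return An `htest` object with the A statistic and p-value.
#' @export
check_normality <- function(values) {
  if (length(values) < 8) abort("The Anderson-Darling test needs at least 8 observations.")
  nortest::ad.test(values)
}

#' Power of the correlation test
#'
#' Two-tailed power of the Fisher-z test of a Pearson correlation: with
#' `lambda = atanh(rho) * sqrt(n - 3)` and critical value `z[1 - alpha/2]`,
#' `power = Phi(lambda - z) + Phi(-lambda - z)`.
#'
#' @param rho Population correlation, `|rho| < 1`.
#' @param n Sample size (>= 4).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return The power, a probability.
#' @examples
#' correlation_power(0.3, 40) # about 0.47: underpowered for a medium effect
#' @export
correlation_power <- function(rho, n, alpha = 0.05) {
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  if (n < 4) abort("Need n >= 4.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  lambda <- atanh(rho) * sqrt(n - 3)
  zc <- qnorm(1 - alpha / 2)
  pnorm(lambda - zc) + pnorm(-lambda - zc)
}

#' Confidence interval for variance explained by a correlation
#'
#' Fisher-z interval for a Pearson correlation,
#' `atanh(r) +/- z[(1+level)/2] / sqrt(n - 3)`, back-transformed by `tanh`
#' and squared to give percent variance explained. If the correlation
#' interval straddles zero, the lower bound on variance explained is 0.
#'
#' @param r Observed correlation, `0 < r < 1`.
#' @param n Sample size (>= 4).
#' @param level Coverage (default 0.95).
#' @return A one-row tibble: `r`, `n`, `level`, `lower_pct`, `upper_pct`.
#' @examples
#' r2_confidence_interval(0.46, 38) # roughly 2.7% to 46% variance explained
#' @export
r2_confidence_interval <- function(r, n, level = 0.95) {
  if (!is.finite(r) || r <= 0 || r >= 1) abort("`r` must lie strictly in (0, 1).")
  if (n < 4) abort("Need n >= 4.")
  if (level < 0 || level >= 1) abort("`level` must be in [0, 1).")
  se <- 1 / sqrt(n - 3)
  zc <- qnorm((1 + level) / 2)
  r_lo <- tanh(atanh(r) - zc * se)
  r_hi <- tanh(atanh(r) + zc * se)
  lower <- if (r_lo < 0) 0 else 100 * r_lo^2
  tibble::tibble(
    r = r, n = as.integer(n), level = level,
    lower_pct = lower, upper_pct = 100 * r_hi^2
  )
}
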