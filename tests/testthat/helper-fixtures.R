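# Shared fixtures and independent oracles used across the suite.

quick_cohort <- function(n = 42, r2_conn = 0.02, seed = 1, ...) {
  simulate_clinical_cohort(cohort_spec(n_subjects = n,
                                       r2_conn_incremental = r2_conn,
                                       seed = seed, ...))
}

clean_scan_spec <- function(n_volumes = 10000) {
  scan_spec(n_volumes = n_volumes, drift_amplitude = 0, spike_rate = 0,
            voxel_noise_sd = 0)
}

# all permutations of 1..n, one per row (independent of the package's
# sampling-based permutation machinery)
enumerate_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- enumerate_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# from-definition recomputation of the two evaluation metrics
oracle_prediction_r2 <- function(obs, full, compact) {
  1 - mean((obs - full)^2) / mean((obs - compact)^2)
}
oracle_delta_model_r2 <- function(obs, full, compact) {
  cor(obs, full)^2 - cor(obs, compact)^2
}

# exhaustive permutation p-value (add-one convention) for the frozen model
oracle_exhaustive_p <- function(baseline, conn, observed, spec,
                                metric = "prediction_r2") {
  b <- baseline - mean(baseline)
  y <- observed - mean(observed)
  compact <- spec$beta_baseline * b
  obs_stat <- if (metric == "prediction_r2") {
    oracle_prediction_r2(y, compact + spec$beta_conn * conn, compact)
  } else {
    oracle_delta_model_r2(y, compact + spec$beta_conn * conn, compact)
  }
  perms <- enumerate_permutations(length(conn))
  stats <- apply(perms, 1, function(p) {
    full <- compact + spec$beta_conn * conn[p]
    if (metric == "prediction_r2") {
      oracle_prediction_r2(y, full, compact)
    } else {
      oracle_delta_model_r2(y, full, compact)
    }
  })
  mean(stats >= obs_stat) # exhaustive: exact exceedance probability
}

clip_val <- function(x, lo, hi) pmin(pmax(x, lo), hi)
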