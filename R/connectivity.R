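# Composite amygdala-connectivity term: seed-cluster correlations, signed
# average, Fisher transform, cohort z-scoring.

#' Mean time series of a region of interest
#'
#' Unweighted average across voxels at each time point.
#'
#' @param roi_ts Voxel x time numeric matrix.
#' @return Numeric time series of length `ncol(roi_ts)`.
#' @export
roi_mean_timeseries <- function(roi_ts) {
  m <- as.matrix(roi_ts)
  if (nrow(m) < 1) abort("ROI is empty: no voxels to average.")
  colMeans(m)
}

#' Seed-to-cluster correlations
#'
#' Pearson correlation of the amygdala seed's mean time course with each of
#' the four cluster mean time courses of the predictive model (one positive
#' cluster, three negative clusters, in that order).
#'
#' @param amygdala_ts Seed mean time series.
#' @param cluster_ts List of four cluster mean time series, ordered
#'   `(positive, negative1, negative2, negative3)`, or a time x 4 matrix.
#' @return A one-row tibble with columns `r_pos`, `r_neg1`, `r_neg2`,
#'   `r_neg3`.
#' @export
seed_cluster_correlations <- function(amygdala_ts, cluster_ts) {
  if (is.matrix(cluster_ts) || is.data.frame(cluster_ts)) {
    cluster_ts <- as.list(as.data.frame(as.matrix(cluster_ts)))
  }
  if (length(cluster_ts) != 4) abort("Expected exactly 4 cluster time series (1 positive, 3 negative).")
  if (sd(amygdala_ts) == 0) abort("Seed time series has zero variance.")
  r <- vapply(cluster_ts, function(ts) {
    if (length(ts) != length(amygdala_ts)) abort("Seed and cluster time series differ in length.")
    if (length(ts) < 3) abort("Need at least 3 time points for a correlation.")
    if (sd(ts) == 0) abort("A cluster time series has zero variance.")
    cor(amygdala_ts, ts)
  }, numeric(1))
  tibble::tibble(r_pos = r[[1]], r_neg1 = r[[2]], r_neg2 = r[[3]], r_neg3 = r[[4]])
}

#' Composite connectivity from a correlation profile
#'
#' Averages the seed's correlation with the positive cluster and its
#' correlations with the three negative clusters into a single number.
#' Under the default `"flip_negative"` convention the negative-cluster
#' correlations enter with flipped sign, so *reduced* (more negative)
#' connectivity with those clusters raises the composite -- matching the
#' direction in which the biomarker is reported to predict treatment
#' response. `"raw"` averages the four correlations unchanged.
#' `two_group = TRUE` averages the positive correlation with the *mean* of
#' the (signed) negative-cluster correlations instead of pooling all four
#' values equally.
#'
#' @param profile One-row tibble from [seed_cluster_correlations()], or a
#'   numeric vector `(r_pos, r_neg1, r_neg2, r_neg3)`.
#' @param sign_convention `"flip_negative"` (default) or `"raw"`.
#' @param two_group Average-of-two-means variant (default `FALSE`, mean of
#'   four values).
#' @return The composite, a single number in (-1, 1).
#' @export
composite_conn <- function(profile, sign_convention = c("flip_negative", "raw"),
                           two_group = FALSE) {
  sign_convention <- match.arg(sign_convention)
  r <- if (is.data.frame(profile)) {
    c(profile$r_pos, profile$r_neg1, profile$r_neg2, profile$r_neg3)
  } else {
    as.numeric(profile)
  }
  stopifnot(length(r) == 4)
  signed <- if (sign_convention == "flip_negative") c(r[1], -r[2:4]) else r
  if (two_group) {
    mean(c(signed[1], mean(signed[2:4])))
  } else {
    mean(signed)
  }
}

#' Fisher r-to-z transform
#'
#' Variance-stabilizing transform of a Pearson correlation,
#' `atanh(r) = 0.5 * log((1 + r) / (1 - r))`.
#'
#' @param r Correlation value(s), each strictly inside (-1, 1).
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("Fisher transform requires |r| < 1.")
  }
  atanh(r)
}

#' Z-score a per-subject statistic across the cohort
#'
#' Centers and scales by the cohort sample SD (denominator n - 1).
#'
#' @param values One value per subject (at least 2, non-constant).
#' @return Standardized values with mean 0 and sample SD 1.
#' @export
zscore_across_subjects <- function(values) {
  if (length(values) < 2) abort("Cohort z-scoring needs at least 2 subjects.")
  s <- sd(values)
  if (!is.finite(s) || s == 0) abort("Cohort z-scoring is undefined for a constant statistic.")
  (values - mean(values)) / s
}

#' Build per-subject composite connectivity terms
#'
#' Chains the composite construction for a cohort: per subject, the four
#' seed-cluster correlations are averaged under the chosen sign convention
#' (`composite_raw`), Fisher-transformed (`fisher_z`), and finally z-scored
#' across subjects (`cohort_z`, the model's `amyg_conn` input). With
#' `fisher_first = TRUE` each correlation is Fisher-transformed before
#' averaging (a sensitivity variant); the default transforms the average,
#' following how the composite term is defined.
#'
#' @param profiles Tibble with one row per subject: `subject_id` (optional)
#'   and `r_pos`, `r_neg1`, `r_neg2`, `r_neg3`.
#' @param sign_convention Passed to [composite_conn()].
#' @param two_group Passed to [composite_conn()].
#' @param fisher_first Transform each correlation before averaging.
#' @return The input tibble with `composite_raw`, `fisher_z` and `cohort_z`
#'   columns appended; subject order preserved.
#' @export
build_conn_terms <- function(profiles,
                             sign_convention = c("flip_negative", "raw"),
                             two_group = FALSE, fisher_first = FALSE) {
  sign_convention <- match.arg(sign_convention)
  needed <- c("r_pos", "r_neg1", "r_neg2", "r_neg3")
  if (!all(needed %in% names(profiles))) {
    abort("`profiles` must contain columns r_pos, r_neg1, r_neg2, r_neg3.")
  }
  if (nrow(profiles) < 2) abort("Need at least 2 subjects to build cohort terms.")
  rs <- as.matrix(profiles[needed])
  if (fisher_first) rs <- fisher_z(rs)
  composite <- vapply(seq_len(nrow(rs)), function(i) {
    composite_conn(rs[i, ], sign_convention, two_group)
  }, numeric(1))
  fz <- if (fisher_first) composite else fisher_z(composite)
  dplyr::mutate(profiles,
    composite_raw = composite,
    fisher_z = fz,
    cohort_z = zscore_across_subjects(fz)
  )
}

#' Connectivity profile of a cleaned scan
#'
#' Convenience wrapper: computes the seed-cluster correlation profile from a
#' cleaned ROI table (as returned by [denoise_scan()]) or from a `sim_scan`'s
#' raw regional means.
#'
#' @param x A cleaned ROI tibble with columns `amygdala`, `cluster_pos`,
#'   `cluster_neg1..3`, or a `sim_scan`.
#' @return A one-row tibble of correlations (see
#'   [seed_cluster_correlations()]).
#' @export
connectivity_profile <- function(x) {
  if (inherits(x, "sim_scan")) {
    get_ts <- function(nm) roi_mean_timeseries(x$roi_ts[[nm]])
  } else {
    get_ts <- function(nm) x[[nm]]
  }
  seed_cluster_correlations(
    get_ts("amygdala"),
    lapply(c("cluster_pos", "cluster_neg1", "cluster_neg2", "cluster_neg3"), get_ts)
  )
}
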