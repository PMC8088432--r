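# Simulated resting-state ROI data with a planted connectivity composite.

ROI_NAMES <- c("amygdala", "cluster_pos", "cluster_neg1", "cluster_neg2",
               "cluster_neg3", "wm", "csf")
NEURAL_ROIS <- ROI_NAMES[1:5]

#' Specify a simulated resting-state scan
#'
#' Acquisition and artifact parameters for one simulated ROI scan. Defaults
#' follow the replication acquisition: 200 volumes at TR = 1.5 s.
#'
#' @param n_volumes Number of time points (default 200).
#' @param tr Repetition time in seconds (default 1.5).
#' @param voxels_per_roi Voxels simulated per region (default 9).
#' @param drift_amplitude Amplitude of the shared low-frequency drift and
#'   tissue nuisance, in units of the unit-variance neural signal (default 1;
#'   0 disables drift).
#' @param spike_rate Per-volume probability of a motion spike (default 0.02);
#'   an equal-rate independent process produces global-intensity outliers.
#'   Spiked volumes also carry a common broadband deflection in all ROI
#'   series (the scrubbing target).
#' @param motion_spike_mm Minimum size of a simulated motion spike in mm
#'   (default 0.5).
#' @param voxel_noise_sd SD of independent per-voxel measurement noise
#'   relative to the unit-variance regional signal (default 0.5).
#'
#' @return An object of class `scan_spec`.
#' @export
scan_spec <- function(n_volumes = 200L,
                      tr = 1.5,
                      voxels_per_roi = 9L,
                      drift_amplitude = 1,
                      spike_rate = 0.02,
                      motion_spike_mm = 0.5,
                      voxel_noise_sd = 0.5) {
  spec <- list(
    n_volumes = as.integer(n_volumes), tr = tr,
    voxels_per_roi = as.integer(voxels_per_roi),
    drift_amplitude = drift_amplitude, spike_rate = spike_rate,
    motion_spike_mm = motion_spike_mm, voxel_noise_sd = voxel_noise_sd
  )
  class(spec) <- "scan_spec"
  validate_scan_spec(spec)
  spec
}

validate_scan_spec <- function(spec) {
  if (spec$tr <= 0) abort("`tr` must be positive.")
  if (spec$n_volumes < 2 / (spec$tr * 0.01)) {
    abort("`n_volumes` too small: the scan must be long enough to resolve a 0.01 Hz pass-band edge (need n_volumes >= 2 / (tr * 0.01)).")
  }
  if (spec$voxels_per_roi < 1) abort("`voxels_per_roi` must be >= 1.")
  if (spec$spike_rate < 0 || spec$spike_rate > 1) abort("`spike_rate` must be in [0, 1].")
  if (spec$motion_spike_mm <= 0) abort("`motion_spike_mm` must be positive.")
  invisible(spec)
}

# Target 5x5 correlation matrix for the neural ROIs under a planted
# composite c. Seed-cluster correlations are (c, -c, -c, -c) under the
# flip_negative convention (or all c under raw); cluster-cluster entries
# follow the implied single-factor structure rho_i * rho_j, which keeps the
# matrix positive-definite for |c| < 1.
target_corr_matrix <- function(composite, sign_convention = c("flip_negative", "raw")) {
  sign_convention <- match.arg(sign_convention)
  rho <- if (sign_convention == "flip_negative") {
    c(1, composite, -composite, -composite, -composite)
  } else {
    c(1, rep(composite, 4))
  }
  sigma <- outer(rho, rho)
  diag(sigma) <- 1
  dimnames(sigma) <- list(NEURAL_ROIS, NEURAL_ROIS)
  sigma
}

# Symmetric matrix square root with an eigenvalue-clipping nearest-PD repair
# for targets that planting pushed indefinite.
matrix_sqrt_pd <- function(sigma, eps = 1e-10) {
  eig <- eigen(sigma, symmetric = TRUE)
  if (any(eig$values < -1e-8)) {
    warn("Target correlation matrix is indefinite; applying nearest positive-definite repair.")
  }
  vals <- pmax(eig$values, eps)
  eig$vectors %*% (sqrt(vals) * t(eig$vectors))
}

#' Simulate one subject's resting-state ROI scan
#'
#' Generates voxel-level time series for the five neural regions of the
#' predictive model (amygdala seed, one positive cluster, three negative
#' clusters) plus white-matter and CSF compartments, together with a 6-column
#' motion table and a global-signal trace. The neural regions are drawn from
#' a correlation structure whose composite connectivity (under the stated
#' sign convention) equals the subject's `true_composite_conn`; WM/CSF share
#' a low-rank low-frequency drift that also leaks into the neural regions,
#' and motion/intensity spikes add a common broadband deflection.
#'
#' @param record One-row subject tibble with a `true_composite_conn` column,
#'   or a single numeric composite in (-1, 1).
#' @param spec A [scan_spec()].
#' @param sign_convention `"flip_negative"` (default) plants seed-cluster
#'   correlations `(c, -c, -c, -c)`; `"raw"` plants all four at `c`.
#' @param seed Integer seed for this scan.
#'
#' @return An object of class `sim_scan`: a list with `roi_ts` (named list of
#'   voxel x time matrices), `motion` (time x 6: translations mm, rotations
#'   radians), `global_signal`, `spec`, and the planted `true_composite_conn`.
#' @export
simulate_scan <- function(record, spec = scan_spec(),
                          sign_convention = c("flip_negative", "raw"),
                          seed = 1L) {
  sign_convention <- match.arg(sign_convention)
  conn <- if (is.data.frame(record)) record$true_composite_conn[[1]] else as.numeric(record)
  if (!is.finite(conn) || abs(conn) >= 1) {
    abort("`true_composite_conn` must lie strictly inside (-1, 1).")
  }
  validate_scan_spec(spec)
  set.seed(as.integer(seed))

  nt <- spec$n_volumes
  nv <- spec$voxels_per_roi
  t_sec <- (seq_len(nt) - 1) * spec$tr

  # latent unit-variance regional signals with the planted structure
  sqrt_sigma <- matrix_sqrt_pd(target_corr_matrix(conn, sign_convention))
  neural <- sqrt_sigma %*% matrix(rnorm(5 * nt), nrow = 5) # 5 x time
  rownames(neural) <- NEURAL_ROIS

  # shared low-frequency nuisance: two slow sinusoids + linear trend,
  # random phase, random per-ROI loadings (WM/CSF load heavily)
  amp <- spec$drift_amplitude
  drift_basis <- cbind(
    sin(2 * pi * 0.004 * t_sec + runif(1, 0, 2 * pi)),
    sin(2 * pi * 0.007 * t_sec + runif(1, 0, 2 * pi)),
    seq(-1, 1, length.out = nt)
  )
  # drift loads with a consistent positive sign on all regions (scanner
  # drift and slow physiology are shared), jittered per ROI
  neural_load <- matrix(rnorm(5 * 3, mean = 0.8, sd = 0.3), nrow = 5)
  tissue_load <- matrix(rnorm(2 * 3, mean = 1, sd = 0.3), nrow = 2)
  drift_neural <- amp * neural_load %*% t(drift_basis)   # 5 x time
  drift_tissue <- amp * tissue_load %*% t(drift_basis)   # 2 x time

  # motion: small jitter plus spikes; independent intensity outliers
  motion_spikes <- runif(nt) < spec$spike_rate
  motion_spikes[1] <- FALSE
  intensity_spikes <- runif(nt) < spec$spike_rate
  intensity_spikes[1] <- FALSE
  motion <- build_motion(nt, motion_spikes, spec$motion_spike_mm)

  # broadband artifact common to all series at spiked volumes
  artifact <- numeric(nt)
  any_spike <- motion_spikes | intensity_spikes
  artifact[any_spike] <- rnorm(sum(any_spike), mean = 3, sd = 0.5) *
    sample(c(-1, 1), sum(any_spike), replace = TRUE)
  if (spec$spike_rate == 0) artifact[] <- 0

  neural_total <- neural + drift_neural + rep(1, 5) %o% artifact
  wm_ts <- drift_tissue[1, ] + 0.5 * rnorm(nt) + artifact
  csf_ts <- drift_tissue[2, ] + 0.5 * rnorm(nt) + artifact

  expand_voxels <- function(regional) {
    sweep(matrix(rnorm(nv * nt, sd = spec$voxel_noise_sd), nrow = nv),
          2, regional, `+`)
  }
  roi_ts <- c(
    lapply(seq_len(5), function(i) expand_voxels(neural_total[i, ])),
    list(expand_voxels(wm_ts), expand_voxels(csf_ts))
  )
  names(roi_ts) <- ROI_NAMES

  global <- colMeans(do.call(rbind, roi_ts))
  global[intensity_spikes] <- global[intensity_spikes] +
    (3.5 + rexp(sum(intensity_spikes))) * sd(global)

  structure(
    list(roi_ts = roi_ts, motion = motion, global_signal = global,
         spec = spec, true_composite_conn = conn,
         sign_convention = sign_convention),
    class = "sim_scan"
  )
}

build_motion <- function(nt, spikes, spike_mm) {
  jitter_t <- matrix(rnorm(nt * 3, sd = 0.02), ncol = 3)        # mm increments
  jitter_r <- matrix(rnorm(nt * 3, sd = 0.0003), ncol = 3)      # rad increments
  jitter_t[1, ] <- 0
  jitter_r[1, ] <- 0
  for (t in which(spikes)) {
    axis <- sample(1:3, 1)
    jump <- (spike_mm * runif(1, 1.2, 2.5)) * sample(c(-1, 1), 1)
    jitter_t[t, axis] <- jitter_t[t, axis] + jump
  }
  motion <- cbind(apply(jitter_t, 2, cumsum), apply(jitter_r, 2, cumsum))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  motion
}

#' @export
print.sim_scan <- function(x, ...) {
  cat(sprintf(
    "<sim_scan> %d volumes, TR %.2g s, %d voxels/ROI; planted composite %.3f (%s)\n",
    x$spec$n_volumes, x$spec$tr, x$spec$voxels_per_roi,
    x$true_composite_conn, x$sign_convention
  ))
  invisible(x)
}
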