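# Conn-style nuisance removal on ROI time series: motion + derivative
# regressors, tissue principal components, spike censoring, band-pass.

#' Denoising configuration
#'
#' Parameters of the nuisance-removal pipeline. Defaults are the settings
#' the replication analysis used: 3 tissue components per compartment,
#' spike flagging at 0.5 mm frame-to-frame displacement or a global-signal
#' excursion of 3 SD, and a 0.01-0.10 Hz pass band.
#'
#' @param n_tissue_components Principal components retained per tissue
#'   compartment (white matter, CSF).
#' @param spike_translation_threshold Frame-to-frame displacement (mm) at or
#'   above which a volume is flagged as a motion outlier.
#' @param spike_global_z_threshold Global-signal z-score magnitude at or
#'   above which a volume is flagged as an intensity outlier.
#' @param band_low,band_high Pass-band edges in Hz.
#' @param rotation_radius Radius (mm) used to convert rotation differences
#'   to displacements, both for FD and for spike flagging.
#' @param composite_motion If `TRUE`, motion flagging uses the composite
#'   (summed) frame-to-frame displacement rather than the per-parameter
#'   rule. Default `FALSE` (any single parameter exceeding the threshold
#'   flags the volume).
#' @param pooled_tissue If `TRUE`, the WM and CSF compartments are pooled
#'   before component extraction and `n_tissue_components` components are
#'   taken from the pool; default extracts per compartment.
#' @param filter_design If `TRUE` (default) the nuisance regressors are
#'   band-limited to the pass band before regression, so the
#'   regress-then-filter pipeline is an exact projection (applying it twice
#'   changes nothing) and frequencies removed by the filter cannot be
#'   reintroduced by the regression.
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(n_tissue_components = 3L,
                           spike_translation_threshold = 0.5,
                           spike_global_z_threshold = 3,
                           band_low = 0.01,
                           band_high = 0.10,
                           rotation_radius = 50,
                           composite_motion = FALSE,
                           pooled_tissue = FALSE,
                           filter_design = TRUE) {
  cfg <- list(
    n_tissue_components = as.integer(n_tissue_components),
    spike_translation_threshold = spike_translation_threshold,
    spike_global_z_threshold = spike_global_z_threshold,
    band_low = band_low, band_high = band_high,
    rotation_radius = rotation_radius,
    composite_motion = isTRUE(composite_motion),
    pooled_tissue = isTRUE(pooled_tissue),
    filter_design = isTRUE(filter_design)
  )
  if (band_low < 0 || band_low >= band_high) abort("Need 0 <= band_low < band_high.")
  if (spike_translation_threshold <= 0 || spike_global_z_threshold <= 0) {
    abort("Spike thresholds must be positive.")
  }
  class(cfg) <- "denoise_config"
  cfg
}

#' Framewise displacement
#'
#' Per-volume head-motion summary: the sum of absolute backward differences
#' of the three translations plus the three rotations converted to arc
#' length on a sphere of radius `rotation_radius`.
#'
#' @param motion Time x 6 matrix or data frame: translations (mm) then
#'   rotations (radians).
#' @param rotation_radius Conversion radius in mm (default 50).
#' @return A list of class `fd_trace` with `fd` (mm per volume, first volume
#'   0 by convention) and `mean_fd`, `median_fd`, `sd_fd` computed over
#'   volumes 2..T.
#' @export
compute_fd <- function(motion, rotation_radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) abort("FD needs at least 2 volumes.")
  if (ncol(motion) != 6) abort("`motion` must have exactly 6 columns.")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius * rowSums(d[, 4:6, drop = FALSE]))
  structure(
    list(fd = fd, mean_fd = mean(fd[-1]), median_fd = median(fd[-1]),
         sd_fd = sd(fd[-1])),
    class = "fd_trace"
  )
}

#' @export
print.fd_trace <- function(x, ...) {
  cat(sprintf("<fd_trace> %d volumes: mean %.3f mm, median %.3f mm, SD %.3f mm\n",
              length(x$fd), x$mean_fd, x$median_fd, x$sd_fd))
  invisible(x)
}

#' Flag outlier volumes for spike censoring
#'
#' Artifact-detection rule of the replication pipeline: a volume is a motion
#' outlier if its head displacement from the previous frame reaches
#' `spike_translation_threshold` (per parameter by default, rotations
#' converted at `rotation_radius`; composite displacement optionally), and
#' an intensity outlier if its global-signal z-score magnitude reaches
#' `spike_global_z_threshold` (z computed with the sample SD, ddof 1).
#'
#' @param motion Time x 6 motion table (translations mm, rotations radians).
#' @param global_signal Numeric global mean intensity per volume.
#' @param config A [denoise_config()].
#' @return A tibble with `volume`, `flag` (logical) and `reason`
#'   (`"none"`, `"motion"`, `"intensity"`, `"both"`). The first volume is
#'   never motion-flagged (it has no previous frame).
#' @export
flag_outlier_volumes <- function(motion, global_signal, config = denoise_config()) {
  motion <- as.matrix(motion)
  nt <- nrow(motion)
  if (length(global_signal) != nt) {
    abort("`motion` and `global_signal` must cover the same volumes.")
  }
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * config$rotation_radius
  motion_flag <- if (config$composite_motion) {
    c(FALSE, rowSums(d) >= config$spike_translation_threshold)
  } else {
    c(FALSE, apply(d, 1, max) >= config$spike_translation_threshold)
  }
  z <- (global_signal - mean(global_signal)) / sd(global_signal)
  intensity_flag <- abs(z) >= config$spike_global_z_threshold
  reason <- dplyr::case_when(
    motion_flag & intensity_flag ~ "both",
    motion_flag ~ "motion",
    intensity_flag ~ "intensity",
    TRUE ~ "none"
  )
  tibble::tibble(
    volume = seq_len(nt),
    flag = motion_flag | intensity_flag,
    reason = reason
  )
}

#' Extract tissue-compartment principal components
#'
#' aCompCor-style nuisance components: the top-`k` principal-component time
#' courses of a voxel x time compartment matrix, after removing each voxel's
#' mean. Components are ordered by explained variance and are mutually
#' orthogonal.
#'
#' @param compartment_ts Voxel x time numeric matrix.
#' @param k Number of components requested.
#' @return A `k` x time matrix of unit-norm component time courses (fewer
#'   rows, with a warning, if the compartment has rank below `k`).
#' @export
extract_tissue_components <- function(compartment_ts, k) {
  x <- as.matrix(compartment_ts)
  if (nrow(x) < k) abort("Need at least `k` voxels.")
  if (ncol(x) < k + 1) abort("Need at least `k` + 1 time points.")
  xc <- x - rowMeans(x)                  # demean each voxel's series
  sv <- svd(t(xc), nu = min(k, ncol(x)), nv = 0)
  tol <- max(dim(xc)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank < k) {
    warn(sprintf("Compartment rank %d is below the %d requested components; returning %d.",
                 rank, k, rank))
  }
  kk <- min(k, rank)
  comps <- t(sv$u[, seq_len(kk), drop = FALSE])   # k x time, unit norm
  rownames(comps) <- paste0("comp", seq_len(kk))
  comps
}

#' Assemble the nuisance design matrix
#'
#' Columns: the six motion parameters, their first-order backward-difference
#' derivatives (leading zero row), `k` white-matter and `k` CSF component
#' time courses, and one indicator column per flagged volume.
#'
#' @param motion Time x 6 motion table.
#' @param wm_comps,csf_comps Component x time matrices (may have 0 rows).
#' @param flags Logical vector per volume, or the tibble from
#'   [flag_outlier_volumes()].
#' @return A list of class `nuisance_design` with `columns` (time x
#'   regressor matrix) and `labels`.
#' @export
build_nuisance_design <- function(motion, wm_comps = NULL, csf_comps = NULL,
                                  flags = NULL) {
  motion <- as.matrix(motion)
  nt <- nrow(motion)
  if (ncol(motion) != 6) abort("`motion` must have exactly 6 columns.")
  deriv <- rbind(0, diff(motion))
  pieces <- list(motion = motion, motion_derivative = deriv)
  for (nm in c("wm", "csf")) {
    comps <- if (nm == "wm") wm_comps else csf_comps
    if (!is.null(comps) && nrow(comps) > 0) {
      if (ncol(comps) != nt) abort(sprintf("%s components have inconsistent length.", nm))
      pieces[[paste0(nm, "_comp")]] <- t(comps)
    }
  }
  if (!is.null(flags)) {
    if (is.data.frame(flags)) flags <- flags$flag
    if (length(flags) != nt) abort("`flags` length must equal the number of volumes.")
    idx <- which(flags)
    if (length(idx) > 0) {
      spikes <- matrix(0, nt, length(idx))
      spikes[cbind(idx, seq_along(idx))] <- 1
      pieces$spike <- spikes
    }
  }
  columns <- do.call(cbind, pieces)
  labels <- unlist(lapply(names(pieces), function(nm) {
    paste0(nm, seq_len(ncol(pieces[[nm]])))
  }))
  colnames(columns) <- labels
  structure(list(columns = columns, labels = labels), class = "nuisance_design")
}

#' Regress nuisance covariates out of a time series
#'
#' Least-squares projection of a time series onto the orthogonal complement
#' of the nuisance design (an intercept is always included). Constant-zero
#' columns are dropped before fitting; remaining rank deficiency is an
#' error naming the offending columns.
#'
#' @param ts Numeric time series.
#' @param design A [build_nuisance_design()] result or a time x regressor
#'   matrix.
#' @return The residual series, orthogonal to every retained design column.
#' @export
regress_nuisance <- function(ts, design) {
  x <- if (inherits(design, "nuisance_design")) design$columns else as.matrix(design)
  if (length(ts) != nrow(x)) abort("`ts` and the design cover different numbers of volumes.")
  keep <- colSums(abs(x)) > 0
  x <- x[, keep, drop = FALSE]
  xi <- cbind(`(intercept)` = 1, x)
  qr_x <- qr(xi)
  if (qr_x$rank < ncol(xi)) {
    bad <- colnames(xi)[qr_x$pivot[seq.int(qr_x$rank + 1, ncol(xi))]]
    abort(paste0("Nuisance design is rank deficient; offending columns: ",
                 paste(bad, collapse = ", ")))
  }
  qr.resid(qr_x, ts)
}

#' Ideal band-pass filter
#'
#' Discrete-Fourier hard band-pass: frequency bins outside the open interval
#' (`band_low`, `band_high`) are zeroed (including DC, so the output is mean
#' zero) and the series is inverse-transformed. No padding or windowing is
#' applied; the filter is an orthogonal projection, so applying it twice is
#' a no-op.
#'
#' @param ts Numeric time series.
#' @param tr Sampling interval in seconds.
#' @param config A [denoise_config()] supplying `band_low` and `band_high`,
#'   or `NULL` to use `band_low`/`band_high` directly.
#' @param band_low,band_high Pass-band edges in Hz, used when `config` is
#'   `NULL`.
#' @return The filtered series (mean approximately 0).
#' @export
bandpass_filter <- function(ts, tr, config = denoise_config(),
                            band_low = NULL, band_high = NULL) {
  lo <- band_low %||% config$band_low
  hi <- band_high %||% config$band_high
  nyquist <- 1 / (2 * tr)
  if (hi > nyquist + 1e-12) {
    abort(sprintf("band_high = %g Hz exceeds the Nyquist frequency %g Hz for tr = %g s.",
                  hi, nyquist, tr))
  }
  if (lo < 0 || lo >= hi) abort("Need 0 <= band_low < band_high.")
  n <- length(ts)
  freqs <- bin_frequencies(n, tr)
  keep <- freqs > lo & freqs < hi
  co <- fft(ts)
  co[!keep] <- 0
  Re(fft(co, inverse = TRUE)) / n
}

bin_frequencies <- function(n, tr) {
  k <- seq_len(n) - 1
  k <- pmin(k, n - k)            # fold negative frequencies
  k / (n * tr)
}

#' Denoise a simulated or loaded ROI scan
#'
#' Full nuisance-removal pipeline on a scan's regional mean time series:
#' tissue components are extracted from the WM and CSF compartments, outlier
#' volumes are flagged from the motion table and global signal, the combined
#' design (motion, derivatives, tissue components, spike indicators) is
#' regressed out of each neural ROI mean series, and the residuals are
#' band-pass filtered. With `filter_design = TRUE` (default) the design is
#' band-limited first, making the whole pipeline a projection.
#'
#' @param scan A `sim_scan` or a list with `roi_ts`, `motion`,
#'   `global_signal`, `spec`.
#' @param config A [denoise_config()].
#' @return A tibble with one column per neural ROI (cleaned mean series) and
#'   a `volume` column; attributes `flags` (the outlier tibble), `fd` (the
#'   `fd_trace`) and `log` (a list recording the design composition).
#' @export
denoise_scan <- function(scan, config = denoise_config()) {
  tr <- scan$spec$tr
  k <- config$n_tissue_components
  if (config$pooled_tissue) {
    pool <- rbind(scan$roi_ts$wm, scan$roi_ts$csf)
    wm_comps <- extract_tissue_components(pool, k)
    csf_comps <- NULL
  } else {
    wm_comps <- extract_tissue_components(scan$roi_ts$wm, k)
    csf_comps <- extract_tissue_components(scan$roi_ts$csf, k)
  }
  flags <- flag_outlier_volumes(scan$motion, scan$global_signal, config)
  design <- build_nuisance_design(scan$motion, wm_comps, csf_comps, flags)

  x <- design$columns
  if (config$filter_design) {
    x <- apply(x, 2, bandpass_filter, tr = tr, config = config)
    colnames(x) <- design$labels
    x <- x[, colSums(abs(x)) > 1e-12, drop = FALSE]
  }
  cleaned <- lapply(NEURAL_ROIS, function(nm) {
    ts <- roi_mean_timeseries(scan$roi_ts[[nm]])
    bandpass_filter(regress_nuisance(ts, x), tr = tr, config = config)
  })
  out <- tibble::as_tibble(setNames(cleaned, NEURAL_ROIS))
  out <- dplyr::mutate(out, volume = dplyr::row_number(), .before = 1)
  attr(out, "flags") <- flags
  attr(out, "fd") <- compute_fd(scan$motion, config$rotation_radius)
  attr(out, "log") <- list(
    n_regressors = ncol(x), n_flagged = sum(flags$flag),
    band = c(config$band_low, config$band_high),
    filter_design = config$filter_design
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
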