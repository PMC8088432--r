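make_motion <- function(nt = 20) {
  matrix(0, nt, 6, dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
}

test_that("framewise displacement matches hand-computed sums", {
  m <- make_motion()
  expect_equal(compute_fd(m)$fd, rep(0, 20))
  expect_equal(compute_fd(m)$mean_fd, 0)
  # single 0.3 mm step in x between volumes 10 and 11
  m2 <- m; m2[11:20, 1] <- 0.3
  fd <- compute_fd(m2)$fd
  expect_equal(fd[11], 0.3)
  expect_equal(fd[-11], rep(0, 19))
  # 0.01 rad rotation at 50 mm radius contributes 0.5 mm
  m3 <- m; m3[5:20, 4] <- 0.01
  expect_equal(compute_fd(m3)$fd[5], 0.5)
  expect_equal(compute_fd(m3, rotation_radius = 100)$fd[5], 1.0)
  expect_error(compute_fd(m[1, , drop = FALSE]), "at least 2")
})

test_that("outlier flagging applies the 0.5 mm / 3 SD rules", {
  nt <- 50
  m <- make_motion(nt)
  gs <- rep(100, nt) + sin(seq_len(nt)) * 0.5
  expect_true(all(!flag_outlier_volumes(m, gs)$flag))
  # translation jump of 0.55 mm -> motion flag at that volume only
  m2 <- m; m2[20:nt, 2] <- 0.55
  fl <- flag_outlier_volumes(m2, gs)
  expect_true(fl$flag[20])
  expect_equal(fl$reason[20], "motion")
  expect_equal(sum(fl$flag), 1)
  # first volume is never motion-flagged even with a nonzero start
  m3 <- m; m3[1, 1] <- 5
  fl3 <- flag_outlier_volumes(m3, gs)
  expect_false(fl3$reason[1] == "motion")
  expect_true(fl3$flag[2]) # the return to baseline is a jump
  # global-signal excursion at z >= 3 -> intensity flag
  gz <- rnorm(nt)
  gz <- (gz - mean(gz)) / sd(gz)
  gz[30] <- 3.2 * sqrt((nt - 1) / nt) * 1.3 # comfortably past 3 SD after rescale
  fl4 <- flag_outlier_volumes(make_motion(nt), gz)
  expect_true(fl4$flag[30])
  expect_equal(fl4$reason[30], "intensity")
  # rotations are converted via the radius before thresholding
  m5 <- m; m5[10:nt, 5] <- 0.011 # 0.55 mm at 50 mm radius
  expect_equal(flag_outlier_volumes(m5, gs)$reason[10], "motion")
  expect_error(flag_outlier_volumes(m, gs[-1]), "same volumes")
})

test_that("tissue components recover low-rank compartment structure", {
  nt <- 40
  base <- sin(seq_len(nt) / 3)
  rank1 <- outer(c(1, 2, 3, 4), base) # 4 voxels sharing one time course
  expect_warning(c1 <- extract_tissue_components(rank1, 2), "rank 1")
  expect_equal(nrow(c1), 1)
  expect_gt(abs(cor(c1[1, ], base)), 1 - 1e-10)
  # rank-3 compartment: 3 components reconstruct it exactly
  set.seed(1)
  load <- matrix(rnorm(18), 6, 3)
  courses <- matrix(rnorm(3 * nt), 3, nt)
  x <- load %*% courses
  comps <- extract_tissue_components(x, 3)
  xc <- x - rowMeans(x)
  proj <- xc %*% t(comps) %*% comps # components have unit norm rows
  expect_equal(proj, xc, tolerance = 1e-8)
  # components are mutually orthogonal for arbitrary input
  noisy <- x + matrix(rnorm(6 * nt), 6)
  cc <- extract_tissue_components(noisy, 3)
  gram <- cc %*% t(cc)
  expect_equal(gram, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the nuisance design has the documented column structure", {
  nt <- 30
  m <- make_motion(nt)
  m[, 1] <- cumsum(rnorm(nt, sd = 0.01))
  comps <- matrix(rnorm(3 * nt), 3, nt)
  d18 <- build_nuisance_design(m, comps, comps)
  expect_equal(ncol(d18$columns), 18)
  flags <- rep(FALSE, nt); flags[c(7, 19)] <- TRUE
  d20 <- build_nuisance_design(m, comps, comps, flags)
  expect_equal(ncol(d20$columns), 20)
  spikes <- d20$columns[, 19:20]
  expect_equal(colSums(spikes), c(spike1 = 1, spike2 = 1))
  expect_equal(which(spikes[, 1] == 1), 7)
  d12 <- build_nuisance_design(make_motion(nt))
  expect_equal(ncol(d12$columns), 12)
  expect_true(all(d12$columns[, 7:12] == 0)) # derivatives of zero motion
  # derivative convention: backward difference with leading zero
  expect_equal(d18$columns[, 7], c(0, diff(m[, 1])))
})

test_that("nuisance regression is an orthogonal projection", {
  set.seed(3)
  nt <- 60
  x <- matrix(rnorm(nt * 4), nt)
  colnames(x) <- paste0("c", 1:4)
  # exact linear combination -> zero residual
  ts <- x %*% c(1, -2, 0.5, 3) + 7
  expect_equal(max(abs(regress_nuisance(ts, x))), 0, tolerance = 1e-10)
  # arbitrary series -> residual orthogonal to every column
  ts2 <- rnorm(nt)
  r <- regress_nuisance(ts2, x)
  expect_lt(max(abs(crossprod(x, r))), 1e-8 * max(abs(x)) * max(abs(r)) * nt)
  expect_lte(var(r), var(ts2))
  # mean-zero series orthogonal to all columns passes through unchanged
  q <- qr.Q(qr(cbind(1, x)))
  ts3 <- rnorm(nt)
  ts3 <- ts3 - q %*% crossprod(q, ts3)
  expect_equal(as.numeric(regress_nuisance(ts3, x)), as.numeric(ts3),
               tolerance = 1e-10)
  # duplicated column -> named rank-deficiency error
  expect_error(regress_nuisance(ts2, cbind(a = x[, 1], b = x[, 1])),
               "rank deficient.*b")
})

test_that("the ideal band-pass keeps in-band sines and kills the rest", {
  nt <- 200; tr <- 1.5
  t_sec <- (seq_len(nt) - 1) * tr
  expect_equal(bandpass_filter(rep(5, nt), tr), rep(0, nt), tolerance = 1e-12)
  inband <- sin(2 * pi * 0.05 * t_sec)
  out <- bandpass_filter(inband, tr)
  expect_gte(sd(out) / sd(inband), 0.99)
  highband <- sin(2 * pi * 0.20 * t_sec)
  expect_lte(sd(bandpass_filter(highband, tr)) / sd(highband), 0.01)
  # filtering is a projection: applying it twice is a no-op
  y <- rnorm(nt)
  once <- bandpass_filter(y, tr)
  expect_equal(bandpass_filter(once, tr), once, tolerance = 1e-10)
  expect_lt(abs(mean(once)), 1e-12)
  expect_error(bandpass_filter(y, tr = 10), "Nyquist")
})

test_that("the full denoising pipeline is idempotent and variance-reducing", {
  scan <- simulate_scan(0.2, scan_spec(spike_rate = 0.04), seed = 31)
  cfg <- denoise_config()
  clean1 <- denoise_scan(scan, cfg)
  # re-clean the cleaned regional series against the same scan's design
  scan2 <- scan
  for (nm in names(scan$roi_ts)[1:5]) {
    scan2$roi_ts[[nm]] <- matrix(clean1[[nm]], nrow = 1)
  }
  clean2 <- denoise_scan(scan2, cfg)
  rel <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
  for (nm in names(scan$roi_ts)[1:5]) {
    expect_lt(rel(clean2[[nm]], clean1[[nm]]), 1e-6)
    raw <- roi_mean_timeseries(scan$roi_ts[[nm]])
    expect_lte(var(clean1[[nm]]), var(raw))
  }
  lg <- attr(clean1, "log")
  expect_true(lg$n_flagged >= 1)
  expect_equal(lg$band, c(0.01, 0.10))
})

test_that("pooled-tissue and composite-motion variants run and differ", {
  scan <- simulate_scan(0.2, scan_spec(spike_rate = 0.05), seed = 13)
  default_flags <- flag_outlier_volumes(scan$motion, scan$global_signal)
  comp_flags <- flag_outlier_volumes(scan$motion, scan$global_signal,
                                     denoise_config(composite_motion = TRUE))
  expect_gte(sum(comp_flags$flag), sum(default_flags$flag)) # composite sums displacements
  pooled <- denoise_scan(scan, denoise_config(pooled_tissue = TRUE))
  expect_equal(attr(pooled, "log")$n_regressors <
                 attr(denoise_scan(scan), "log")$n_regressors, TRUE)
})
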