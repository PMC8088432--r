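# Reading and writing the pipeline's tabular formats (subject CSV, ROI and
# motion TSV, config YAML/JSON) and optional NIfTI ROI extraction.

#' Write / read a subject table
#'
#' The subject CSV flattens the repeated LSAS measurements into
#' `lsas_t1..lsas_tk` columns; reading restores the `lsas_series`
#' list-column. Round-tripping a simulated cohort reproduces it exactly up
#' to numeric printing precision.
#'
#' @param cohort Subject tibble from [simulate_clinical_cohort()].
#' @param path File path for the CSV.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the subject tibble ordered by `subject_id`.
#' @export
write_cohort_csv <- function(cohort, path) {
  flat <- cohort
  if ("lsas_series" %in% names(flat)) {
    k <- max(lengths(flat$lsas_series))
    series <- t(vapply(flat$lsas_series, function(s) {
      c(s, rep(NA_real_, k - length(s)))
    }, numeric(k)))
    colnames(series) <- paste0("lsas_t", seq_len(k))
    flat <- dplyr::bind_cols(
      dplyr::select(flat, -"lsas_series"),
      tibble::as_tibble(series)
    )
  }
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE)
  if (anyDuplicated(flat$subject_id)) {
    dup <- flat$subject_id[duplicated(flat$subject_id)]
    abort(paste0("Duplicate subject id(s): ", paste(unique(dup), collapse = ", ")))
  }
  series_cols <- grep("^lsas_t[0-9]+$", names(flat), value = TRUE)
  if (length(series_cols) > 0) {
    series_cols <- series_cols[order(as.integer(sub("lsas_t", "", series_cols)))]
    m <- as.matrix(flat[series_cols])
    flat$lsas_series <- lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    flat <- dplyr::select(flat, -dplyr::all_of(series_cols))
  }
  dplyr::arrange(flat, .data$subject_id)
}

#' Write / read per-ROI time-series and motion tables
#'
#' The ROI TSV stores one column per region (regional mean series) plus a
#' `volume` index; voxel-level data are stored as `<roi>_v<j>` columns.
#' The motion TSV stores the 6 motion parameters (translations in mm,
#' rotations in radians).
#'
#' @param scan A `sim_scan`.
#' @param dir Output directory (created if needed).
#' @param subject_id Identifier used in the file names.
#' @return A named list of the written paths, invisibly.
#' @export
write_scan_tsv <- function(scan, dir, subject_id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  voxel_tab <- purrr::imap_dfc(scan$roi_ts, function(m, nm) {
    out <- tibble::as_tibble(t(m), .name_repair = "minimal")
    names(out) <- paste0(nm, "_v", seq_len(nrow(m)))
    out
  })
  voxel_tab <- dplyr::mutate(voxel_tab, volume = dplyr::row_number(), .before = 1)
  roi_path <- file.path(dir, paste0(subject_id, "_roi.tsv"))
  motion_path <- file.path(dir, paste0(subject_id, "_motion.tsv"))
  global_path <- file.path(dir, paste0(subject_id, "_global.tsv"))
  readr::write_tsv(voxel_tab, roi_path)
  readr::write_tsv(tibble::as_tibble(scan$motion), motion_path)
  readr::write_tsv(tibble::tibble(global_signal = scan$global_signal), global_path)
  invisible(list(roi = roi_path, motion = motion_path, global = global_path))
}

#' @rdname write_scan_tsv
#' @param spec A [scan_spec()] describing the stored scan (TR etc.).
#' @export
read_scan_tsv <- function(dir, subject_id, spec = scan_spec()) {
  roi_path <- file.path(dir, paste0(subject_id, "_roi.tsv"))
  motion_path <- file.path(dir, paste0(subject_id, "_motion.tsv"))
  global_path <- file.path(dir, paste0(subject_id, "_global.tsv"))
  for (p in c(roi_path, motion_path, global_path)) {
    if (!file.exists(p)) abort(paste0("Missing scan file: ", p))
  }
  tab <- readr::read_tsv(roi_path, show_col_types = FALSE)
  tab$volume <- NULL
  roi_names <- unique(sub("_v[0-9]+$", "", names(tab)))
  roi_ts <- lapply(roi_names, function(nm) {
    cols <- grep(paste0("^", nm, "_v[0-9]+$"), names(tab), value = TRUE)
    t(as.matrix(tab[cols]))
  })
  names(roi_ts) <- roi_names
  motion <- as.matrix(readr::read_tsv(motion_path, show_col_types = FALSE))
  global <- readr::read_tsv(global_path, show_col_types = FALSE)$global_signal
  structure(
    list(roi_ts = roi_ts, motion = motion, global_signal = global, spec = spec),
    class = "sim_scan"
  )
}

#' Extract ROI voxel time series from a 4D NIfTI volume
#'
#' Applies binary masks to a 4D series by nonzero-voxel indexing. The masks
#' must share the series' spatial grid exactly; no resampling is performed.
#'
#' @param series A 4D array, or a path to a NIfTI file (read with RNifti).
#' @param masks Named list of 3D arrays or NIfTI paths, one per region.
#' @return Named list of voxel x time matrices.
#' @export
roi_ts_from_nifti <- function(series, masks) {
  read_vol <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        abort("Reading NIfTI paths requires the RNifti package.")
      }
      as.array(RNifti::readNifti(x))
    } else {
      as.array(x)
    }
  }
  vol <- read_vol(series)
  if (length(dim(vol)) != 4) abort("`series` must be a 4D volume (x, y, z, time).")
  grid <- dim(vol)[1:3]
  nt <- dim(vol)[4]
  flat <- matrix(vol, ncol = nt)
  purrr::imap(masks, function(mk, nm) {
    m <- read_vol(mk)
    if (!identical(dim(m), as.integer(grid)) && !identical(dim(m), grid)) {
      abort(sprintf("Mask `%s` is on a different grid than the series.", nm))
    }
    idx <- which(m != 0)
    if (length(idx) == 0) abort(sprintf("Mask `%s` selects zero voxels.", nm))
    flat[idx, , drop = FALSE]
  })
}

#' Load a configured analysis bundle
#'
#' Reads the subject table, and when scan paths are configured, each
#' subject's ROI/motion/global tables, validating completeness. Subjects are
#' ordered lexicographically by id so downstream cohort-level operations
#' (z-scoring, permutation seeds) are reproducible.
#'
#' @param config A list (e.g. from [read_run_config()]) with at least
#'   `subject_table`; optional `scan_dir` and `scan` (scan_spec fields).
#' @return A list with `cohort` (subject tibble) and, if configured,
#'   `scans` (named list of scans keyed by subject id).
#' @export
load_inputs <- function(config) {
  if (is.null(config$subject_table) || !file.exists(config$subject_table)) {
    abort("`subject_table` is missing or does not exist.")
  }
  cohort <- read_cohort_csv(config$subject_table)
  needed <- c("subject_id", "baseline_lsas", "sessions_completed", "group")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("Subject table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- list(cohort = cohort)
  if (!is.null(config$scan_dir)) {
    spec <- do.call(scan_spec, config$scan %||% list())
    out$scans <- setNames(
      lapply(cohort$subject_id, function(id) read_scan_tsv(config$scan_dir, id, spec)),
      cohort$subject_id
    )
  }
  out
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration document
#'   mirroring the cohort, scan, denoising and model settings.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

write_provenance <- function(dir, config, seed, stage) {
  rec <- list(
    stage = stage,
    package = "amygconn",
    version = as.character(utils::packageVersion("amygconn")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(dir, paste0(stage, "_provenance.json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(path)
}
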