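#' Construct a subject ROI time-series object
#'
#' Container for one subject's T x N matrix of regional BOLD time series.
#' Columns are named by parcellation node id. The object tracks the
#' repetition time, the current preprocessing stage (`raw`, `trimmed`,
#' `cleaned`) and the sequence of operations already applied, so the
#' preprocessing order contract can be enforced and repeated application of
#' the same step refused.
#'
#' @param data Numeric T x N matrix (time points in rows, ROIs in columns).
#' @param subject_id Subject identifier.
#' @param tr Repetition time in seconds (> 0).
#' @param stage Processing stage; one of `"raw"`, `"trimmed"`, `"cleaned"`.
#' @param applied Character vector of operations already applied.
#' @return An object of class `fc_timeseries`.
#' @export
fc_timeseries <- function(data, subject_id, tr,
                          stage = c("raw", "trimmed", "cleaned"),
                          applied = character()) {
  stage <- match.arg(stage)
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("Time-series data must be numeric.")
  if (nrow(data) < 2) abort("A time series needs at least 2 time points.")
  if (anyNA(data)) abort("Time-series data contains missing values.")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0) {
    abort("tr must be a single positive number of seconds.")
  }
  if (is.null(colnames(data))) colnames(data) <- as.character(seq_len(ncol(data)))
  structure(
    list(data = data, subject_id = as.character(subject_id), tr = tr,
         stage = stage, applied = applied),
    class = "fc_timeseries")
}

#' @export
print.fc_timeseries <- function(x, ...) {
  cat(sprintf("<fc_timeseries> subject %s: %d time points x %d ROIs, TR = %g s, stage = %s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr, x$stage))
  if (length(x$applied) > 0) {
    cat("  applied:", paste(x$applied, collapse = " -> "), "\n")
  }
  zv <- zero_variance_rois(x)
  if (length(zv) > 0) cat("  zero-variance ROIs:", paste(zv, collapse = ", "), "\n")
  invisible(x)
}

#' Identify zero-variance ROI columns
#'
#' ROIs whose series is constant produce undefined correlations downstream;
#' they are flagged (by column name / node id) rather than silently zeroed.
#'
#' @param ts An `fc_timeseries`.
#' @param tol Variance tolerance below which a column counts as constant.
#' @return Character vector of flagged column names (possibly empty).
#' @export
zero_variance_rois <- function(ts, tol = 1e-12) {
  v <- apply(ts$data, 2, stats::var)
  colnames(ts$data)[v < tol]
}

check_not_applied <- function(ts, op) {
  if (op %in% ts$applied) {
    abort(paste0("Operation '", op, "' has already been applied to subject ",
                 ts$subject_id, "; stage repetition is refused."))
  }
}

#' Extract mean ROI time series from a 4D volume and a label volume
#'
#' For each parcellation node, averages the time series of all voxels
#' carrying that node's integer label. Accepts in-memory arrays or NIfTI file
#' paths (read through \pkg{RNifti}). The label volume must be voxel-aligned
#' to the functional grid; spatial preprocessing (realignment, normalisation,
#' smoothing) is assumed done upstream.
#'
#' @param volume4d 4D numeric array (x, y, z, t) or path to a NIfTI file.
#' @param labels 3D integer array or path to a NIfTI label volume; 0 denotes
#'   background, other values must be parcellation node ids.
#' @param parc An `fc_parcellation` tibble.
#' @param subject_id Subject identifier for the returned object.
#' @param tr Repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header `pixdim` when `volume4d` is a file.
#' @return An `fc_timeseries` at stage `"raw"` with one column per node.
#' @export
extract_roi_timeseries <- function(volume4d, labels, parc, subject_id = "subject",
                                   tr = NULL) {
  if (is.character(volume4d)) {
    img <- RNifti::readNifti(volume4d)
    if (is.null(tr)) {
      pd <- attr(img, "pixdim")
      if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) tr <- pd[4]
    }
    volume4d <- as.array(img)
  }
  if (is.character(labels)) labels <- as.array(RNifti::readNifti(labels))
  labels <- round(as.array(labels))
  if (length(dim(volume4d)) != 4) abort("volume4d must be a 4D array.")
  strip1 <- function(d) if (length(d) > 1) d[seq_len(max(which(d > 1), 1))] else d
  dv <- dim(volume4d)[1:3]
  if (!identical(strip1(dv), strip1(dim(labels)))) {
    abort("volume4d and labels do not share the same spatial grid.")
  }
  dim(labels) <- dv   # restore any trailing singleton dimensions
  if (is.null(tr)) abort("tr must be supplied when it cannot be read from the image header.")
  present <- setdiff(unique(as.integer(labels)), 0L)
  bad <- setdiff(present, parc$node_id)
  if (length(bad) > 0) {
    abort(paste0("Label volume contains values outside the parcellation: ",
                 paste(sort(bad), collapse = ", ")))
  }
  absent <- setdiff(parc$node_id, present)
  if (length(absent) > 0) {
    abort(paste0("Parcellation node(s) absent from the label volume: ",
                 paste(sort(absent), collapse = ", ")))
  }
  n_t <- dim(volume4d)[4]
  flat <- matrix(volume4d, ncol = n_t)           # voxels x time
  lab_vec <- as.integer(labels)
  out <- vapply(parc$node_id, function(id) {
    idx <- which(lab_vec == id)
    if (length(idx) == 1) flat[idx, ] else colMeans(flat[idx, , drop = FALSE])
  }, numeric(n_t))
  colnames(out) <- as.character(parc$node_id)
  fc_timeseries(out, subject_id = subject_id, tr = tr, stage = "raw")
}

#' Drop initial volumes
#'
#' Removes the first `k` time points (default 10), discarding the scanner
#' equilibration / subject adaptation period, e.g. 383 acquired volumes
#' become 373 analysed time points.
#'
#' @param ts An `fc_timeseries`.
#' @param k Number of initial volumes to drop (default 10).
#' @return The trimmed `fc_timeseries` (stage `"trimmed"`).
#' @export
drop_initial_volumes <- function(ts, k = 10) {
  check_not_applied(ts, "trim")
  if (k < 0) abort("k must be non-negative.")
  if (nrow(ts$data) <= k) {
    abort(sprintf("Cannot drop %d volumes from a %d-point series.", k, nrow(ts$data)))
  }
  ts$data <- ts$data[seq.int(k + 1, nrow(ts$data)), , drop = FALSE]
  ts$stage <- "trimmed"
  ts$applied <- c(ts$applied, "trim")
  ts
}

#' Remove a linear trend from every ROI column
#'
#' Fits and subtracts an ordinary least-squares line in time per column.
#' Residual columns have zero mean and zero linear trend.
#'
#' @param ts An `fc_timeseries` with at least 3 time points.
#' @return Detrended `fc_timeseries`.
#' @export
detrend_linear <- function(ts) {
  check_not_applied(ts, "detrend")
  n_t <- nrow(ts$data)
  if (n_t < 3) abort("Detrending requires at least 3 time points.")
  x <- cbind(1, seq_len(n_t))
  ts$data <- qr.resid(qr(x), ts$data)
  ts$applied <- c(ts$applied, "detrend")
  ts
}

#' Regress nuisance confounds out of every ROI column
#'
#' Replaces each column by its OLS residual against an intercept plus the
#' supplied confound regressors (e.g. six head-motion parameters, CSF and
#' white-matter signals; optionally the global signal). A rank-deficient
#' design is an error -- collinear confounds must be removed by the caller,
#' no silent pseudo-inverse is taken.
#'
#' @param ts An `fc_timeseries`.
#' @param confounds T x C numeric matrix or data frame of confound
#'   regressors, rows matching the current time-series length.
#' @return Residualised `fc_timeseries`.
#' @export
regress_confounds <- function(ts, confounds) {
  check_not_applied(ts, "confounds")
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts$data)) {
    abort(sprintf("Confounds have %d rows but the series has %d time points.",
                  nrow(confounds), nrow(ts$data)))
  }
  x <- cbind(intercept = 1, confounds)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    abort(paste0("Confound design is rank deficient; remove collinear ",
                 "confound columns before regression."))
  }
  ts$data <- qr.resid(qx, ts$data)
  ts$applied <- c(ts$applied, "confounds")
  ts
}

#' Zero-phase Butterworth band-pass filter
#'
#' Retains fluctuations between `low_hz` and `high_hz` (defaults 0.01 and
#' 0.08 Hz, the conventional resting-state band) using a second-order
#' Butterworth band-pass applied forward and backward
#' (\code{\link[signal]{filtfilt}}), so the filter introduces no phase shift.
#' The DC component lies outside the pass band, so constant columns go to
#' zero. After filtering the series is at stage `"cleaned"`.
#'
#' @param ts An `fc_timeseries` with known `tr`.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)` (the Nyquist frequency).
#' @param order Butterworth order of the underlying filter (default 2).
#' @return Filtered `fc_timeseries` (stage `"cleaned"`).
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08, order = 2) {
  check_not_applied(ts, "bandpass")
  nyquist <- 1 / (2 * ts$tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    abort(sprintf(
      "Band [%g, %g] Hz must satisfy 0 < low < high < Nyquist = %g Hz.",
      low_hz, high_hz, nyquist))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  # remove the column mean first: DC lies outside the pass band anyway, and
  # a nonzero offset induces forward-backward edge transients
  ts$data <- apply(ts$data, 2, function(col) {
    signal::filtfilt(bf, col - mean(col))
  })
  ts$stage <- "cleaned"
  ts$applied <- c(ts$applied, "bandpass")
  ts
}

#' Run the full temporal preprocessing chain
#'
#' Applies, in order: initial-volume trimming, linear detrending, nuisance
#' regression (if confounds are given) and zero-phase band-pass filtering.
#' The order follows the conventional resting-state sequence; each step can
#' be switched off.
#'
#' @param ts An `fc_timeseries` at stage `"raw"` (or `"trimmed"` when
#'   `drop_volumes = 0`).
#' @param drop_volumes Initial volumes to discard (default 10; 0 to skip).
#' @param detrend Apply linear detrending (default `TRUE`).
#' @param confounds Optional T x C confound matrix (rows must match the
#'   post-trimming length).
#' @param bandpass Apply the band-pass filter (default `TRUE`).
#' @param low_hz,high_hz Band edges, see [bandpass_filter()].
#' @return A cleaned `fc_timeseries`.
#' @export
clean_timeseries <- function(ts, drop_volumes = 10, detrend = TRUE,
                             confounds = NULL, bandpass = TRUE,
                             low_hz = 0.01, high_hz = 0.08) {
  if (drop_volumes > 0) ts <- drop_initial_volumes(ts, drop_volumes)
  if (detrend) ts <- detrend_linear(ts)
  if (!is.null(confounds)) ts <- regress_confounds(ts, confounds)
  if (bandpass) ts <- bandpass_filter(ts, low_hz, high_hz)
  if (ts$stage != "cleaned") ts$stage <- "cleaned"
  ts
}

#' Read an ROI time-series table from TSV
#'
#' Reads a table with time points in rows and ROI node ids as column names
#' into an `fc_timeseries`.
#'
#' @param path TSV file path.
#' @param subject_id Subject identifier.
#' @param tr Repetition time in seconds.
#' @param stage Stage of the stored series (default `"raw"`).
#' @return An `fc_timeseries`.
#' @export
read_roi_table <- function(path, subject_id, tr, stage = "raw") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  fc_timeseries(as.matrix(tbl), subject_id = subject_id, tr = tr, stage = stage)
}

#' Write an ROI time-series table to TSV
#'
#' @param ts An `fc_timeseries`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(ts, path) {
  readr::write_tsv(as_tibble(ts$data, .name_repair = "minimal"), path,
                   progress = FALSE)
  invisible(path)
}
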