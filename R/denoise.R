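#' Task regressors for one run
#'
#' One column per condition label: a unit boxcar over each block's stimulus
#' span convolved with the canonical HRF, sampled at the TR and truncated to
#' `n_scans`. Columns are ordered by sorted condition label. A condition in
#' `conditions` that never occurs in the run yields a zero column with a
#' warning.
#'
#' @param design a `block_design`.
#' @param run run index.
#' @param n_scans number of scans (default `design$n_scans_per_run`).
#' @param conditions condition labels to model (default: all labels of the
#'   design, sorted).
#' @return `n_scans` x `length(conditions)` matrix with condition labels as
#'   column names.
#' @export
build_task_regressors <- function(design, run = 1,
                                  n_scans = design$n_scans_per_run,
                                  conditions = condition_labels(design)) {
  stopifnot(inherits(design, "block_design"))
  blocks <- design$runs[[run]]
  tr <- design$tr
  if (nrow(blocks) > 0 &&
      max(blocks$onset_s + .block_span(blocks)) > n_scans * tr)
    stop("`n_scans` x `tr` is shorter than the last block offset", call. = FALSE)
  h <- canonical_hrf(tr)
  t_scan <- (seq_len(n_scans) - 1) * tr
  conditions <- sort(conditions)
  out <- vapply(conditions, function(cond) {
    b <- blocks[blocks$condition_label == cond, , drop = FALSE]
    if (nrow(b) == 0) {
      warning(sprintf("condition '%s' absent from run %d; zero regressor", cond, run))
      return(numeric(n_scans))
    }
    u <- numeric(n_scans)
    for (k in seq_len(nrow(b)))
      u <- u + as.numeric(t_scan >= b$onset_s[k] &
                          t_scan < b$onset_s[k] + .block_span(b)[k])
    ## discrete causal convolution, truncated to the run
    stats::convolve(u, rev(h), type = "open")[seq_len(n_scans)]
  }, numeric(n_scans))
  out[abs(out) < 1e-12] <- 0
  colnames(out) <- conditions
  out
}

#' Assemble the confound matrix for one run
#'
#' Concatenates, in this order: intercept, the supplied confound columns
#' (motion and nuisance components), a centred first-order linear trend, and
#' the HRF-convolved task regressors of every condition (so that residual
#' correlations reflect connectivity rather than shared task co-activation).
#' Column names are preserved; the matrix must be full column rank.
#'
#' @param confounds scans x m matrix with unique named columns (the motion
#'   and nuisance traces of the run).
#' @param design a `block_design`.
#' @param run run index.
#' @param n_scans number of scans.
#' @return scans x (1 + m + 1 + n_conditions) numeric matrix of class
#'   `confound_matrix` with columns `intercept`, the supplied names,
#'   `linear_trend`, then the condition labels.
#' @export
build_confound_matrix <- function(confounds, design, run = 1,
                                  n_scans = design$n_scans_per_run) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != n_scans)
    stop(sprintf("confounds have %d rows but the run has %d scans",
                 nrow(confounds), n_scans), call. = FALSE)
  if (is.null(colnames(confounds)) || anyDuplicated(colnames(confounds)))
    stop("confound columns must have unique names", call. = FALSE)
  trend <- seq_len(n_scans) - 1
  task <- build_task_regressors(design, run = run, n_scans = n_scans)
  x <- cbind(intercept = 1, confounds, linear_trend = trend - mean(trend), task)
  if (anyDuplicated(colnames(x)))
    stop("confound names clash with reserved column names", call. = FALSE)
  if (qr(x)$rank < ncol(x))
    stop("confound matrix is rank-deficient (collinear columns)", call. = FALSE)
  class(x) <- c("confound_matrix", class(x))
  x
}

#' Regress confounds out of ROI time series
#'
#' Ordinary-least-squares residualisation of every ROI column on the full
#' confound matrix; residuals are orthogonal to every confound column.
#'
#' @param ts scans x n_rois matrix.
#' @param x confound matrix with the same number of rows, full column rank.
#' @return residual matrix, same shape and column names as `ts`.
#' @export
regress_confounds <- function(ts, x) {
  ts <- as.matrix(ts)
  x <- unclass(x)
  if (nrow(ts) != nrow(x))
    stop("`ts` and the confound matrix must have the same number of rows",
         call. = FALSE)
  qx <- qr(x)
  if (qx$rank < ncol(x))
    stop("confound matrix is rank-deficient", call. = FALSE)
  res <- qr.resid(qx, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero-phase, squared magnitude response). The default 0.01-0.1 Hz band is
#' the standard window for task/rest functional-connectivity analysis.
#'
#' @param ts scans x n_rois matrix (a plain vector is treated as one column).
#' @param tr repetition time in seconds.
#' @param low_hz,high_hz band edges; `0 <= low_hz < high_hz < 1/(2 tr)`.
#' @param order Butterworth order per band edge and pass direction.
#' @return filtered matrix, same shape and dimnames.
#' @export
bandpass_filter <- function(ts, tr, low_hz = 0.01, high_hz = 0.1, order = 4) {
  .assert_scalar_num(tr, "tr", positive = TRUE)
  nyq <- 1 / (2 * tr)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("band edges must satisfy 0 <= low_hz < high_hz", call. = FALSE)
  if (high_hz >= nyq)
    stop(sprintf("`high_hz` must be below the Nyquist frequency %.4g Hz", nyq),
         call. = FALSE)
  vec <- is.null(dim(ts))
  m <- as.matrix(ts)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  ## demean first: the DC component is outside the pass band by definition,
  ## and removing it up front avoids start-up transients on the mean level
  out <- apply(m, 2, function(col) signal::filtfilt(bf, col - mean(col)))
  out <- matrix(out, nrow(m), ncol(m), dimnames = dimnames(m))
  if (vec) drop(out) else out
}

#' Denoise one subject: regress confounds, then band-pass
#'
#' Per run: assemble the confound matrix (intercept, supplied motion and
#' nuisance traces, centred linear trend, HRF-convolved task regressors),
#' residualise every ROI series on it, then band-pass filter the residuals.
#' Runs are denoised separately to avoid filter artifacts at run boundaries.
#'
#' @param subject a `subject_data`.
#' @param design a `block_design`.
#' @param low_hz,high_hz band edges in Hz.
#' @return the `subject_data` with each run's `bold` replaced by the
#'   denoised series (a `denoised = TRUE` attribute is set).
#' @export
denoise_subject <- function(subject, design, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(subject, "subject_data"))
  subject$runs <- lapply(seq_along(subject$runs), function(r) {
    run <- subject$runs[[r]]
    x <- build_confound_matrix(run$confounds, design, run = r,
                               n_scans = nrow(run$bold))
    run$bold <- bandpass_filter(regress_confounds(run$bold, x), tr = design$tr,
                                low_hz = low_hz, high_hz = high_hz)
    run
  })
  attr(subject, "denoised") <- TRUE
  subject
}

#' Denoise every subject of a cohort
#'
#' @param cohort list of `subject_data`.
#' @inheritParams denoise_subject
#' @return list of denoised `subject_data`.
#' @export
denoise_cohort <- function(cohort, design, low_hz = 0.01, high_hz = 0.1) {
  lapply(cohort, denoise_subject, design = design,
         low_hz = low_hz, high_hz = high_hz)
}
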