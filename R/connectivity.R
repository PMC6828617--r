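#' Scans attributed to a condition
#'
#' Returns, in scan order, the indices of the scans whose HRF-convolved task
#' regressor for `condition` is above `tau` AND maximal across all modelled
#' conditions. The argmax rule keeps the per-condition scan sets disjoint
#' even where the haemodynamic response of neighbouring blocks overlaps.
#'
#' @param task_regressors matrix from [build_task_regressors()].
#' @param condition condition label (a column of `task_regressors`).
#' @param tau positivity threshold (default 1e-6).
#' @return integer vector of scan indices (1-based, ascending).
#' @export
condition_scan_indices <- function(task_regressors, condition, tau = 1e-6) {
  if (!condition %in% colnames(task_regressors))
    stop(sprintf("condition '%s' has no task regressor", condition), call. = FALSE)
  v <- task_regressors[, condition]
  mx <- do.call(pmax, c(lapply(seq_len(ncol(task_regressors)),
                               function(j) task_regressors[, j]), list(0)))
  idx <- which(v > tau & v >= mx)
  if (!length(idx))
    stop(sprintf("no scans attributable to condition '%s'", condition),
         call. = FALSE)
  idx
}

#' Per-condition Fisher-z connectivity map
#'
#' Pools the condition's scans across runs (run order, then scan order) and
#' computes the Pearson correlation between every pair of ROI series over
#' the pooled scans; correlations are clipped to +/-(1 - 1e-7) and Fisher-z
#' transformed (`atanh`). The diagonal is set to 0 by convention. A
#' zero-variance ROI gets r = 0 for all its pairs, with a warning.
#'
#' @param ts_by_run list of denoised scans x n_rois matrices, one per run.
#' @param idx_by_run list of scan-index vectors, one per run (from
#'   [condition_scan_indices()] on each run's regressors).
#' @param condition condition label, stored in the result.
#' @param subject_id optional subject id, stored in the result.
#' @return object of class `fc_map`: list with `subject_id`, `condition`,
#'   `z` (symmetric n_rois x n_rois matrix, zero diagonal) and
#'   `n_scans_used`.
#' @export
fc_map <- function(ts_by_run, idx_by_run, condition, subject_id = NA_character_) {
  stopifnot(length(ts_by_run) == length(idx_by_run))
  x <- do.call(rbind, Map(function(ts, idx) ts[idx, , drop = FALSE],
                          ts_by_run, idx_by_run))
  n <- nrow(x)
  if (n < 3)
    stop(sprintf("condition '%s': only %d scans selected; need at least 3",
                 condition, n), call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  degenerate <- which(sds == 0)
  r <- suppressWarnings(stats::cor(x))
  if (length(degenerate)) {
    warning(sprintf("%d ROI(s) with zero variance; their correlations set to 0",
                    length(degenerate)))
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  structure(list(subject_id = subject_id, condition = condition,
                 z = z, n_scans_used = n), class = "fc_map")
}

#' Connectivity maps for one denoised subject
#'
#' @param subject a denoised `subject_data`.
#' @param design the `block_design` that generated it.
#' @param conditions condition labels to map (default: all).
#' @return named list of `fc_map`, one per condition.
#' @export
subject_fc_maps <- function(subject, design,
                            conditions = condition_labels(design)) {
  regs <- lapply(seq_along(subject$runs), function(r)
    build_task_regressors(design, run = r, n_scans = nrow(subject$runs[[r]]$bold)))
  ts_by_run <- lapply(subject$runs, `[[`, "bold")
  out <- lapply(sort(conditions), function(cond) {
    idx <- lapply(regs, condition_scan_indices, condition = cond)
    fc_map(ts_by_run, idx, cond, subject_id = subject$subject_id)
  })
  names(out) <- sort(conditions)
  out
}

#' Edge index of the strict lower triangle
#'
#' Fixed row-major ordering of the `n (n - 1) / 2` undirected edges of an
#' `n`-node network: i = 2..n, j = 1..(i - 1). All feature vectors, masks
#' and classifier weights in the package refer to edges by position in this
#' table.
#'
#' @param n_rois number of nodes.
#' @return data frame with columns `node_a` (= i) and `node_b` (= j), i > j.
#' @export
edge_index <- function(n_rois) {
  stopifnot(n_rois >= 2)
  ## row-major: for each i, all j < i
  a <- unlist(lapply(2:n_rois, function(k) rep(k, k - 1L)))
  b <- unlist(lapply(2:n_rois, function(k) seq_len(k - 1L)))
  data.frame(node_a = a, node_b = b)
}

#' Vectorize a connectivity map to the edge feature space
#'
#' Extracts the strict lower triangle in row-major order ([edge_index()]
#' gives the node pair of every position). The inverse is
#' [devectorize_edges()].
#'
#' @param cm an `fc_map`, or a bare symmetric matrix.
#' @return numeric vector of length `n (n - 1) / 2`.
#' @export
vectorize_lower_triangle <- function(cm) {
  z <- if (inherits(cm, "fc_map")) cm$z else as.matrix(cm)
  if (max(abs(z - t(z))) > 1e-10)
    stop("matrix is not symmetric", call. = FALSE)
  t(z)[upper.tri(z)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' @param v edge vector in [edge_index()] order.
#' @param n_rois number of nodes.
#' @param diag_value value placed on the diagonal (default 0).
#' @return symmetric `n_rois` x `n_rois` matrix.
#' @export
devectorize_edges <- function(v, n_rois, diag_value = 0) {
  stopifnot(length(v) == n_rois * (n_rois - 1) / 2)
  m <- matrix(diag_value, n_rois, n_rois)
  ei <- edge_index(n_rois)
  m[cbind(ei$node_a, ei$node_b)] <- v
  m[cbind(ei$node_b, ei$node_a)] <- v
  m
}

#' Subject x condition x edge feature array
#'
#' The package's bridge from time series to decoding: optionally denoises
#' every subject, builds the per-condition Fisher-z maps and stacks their
#' lower-triangle vectors into a 3-D array indexed by subject, condition and
#' edge.
#'
#' @param cohort list of `subject_data`.
#' @param design the `block_design`.
#' @param conditions condition labels (default: all labels of the design).
#' @param denoise run [denoise_cohort()] first (default TRUE; set FALSE if
#'   the cohort is already denoised).
#' @param low_hz,high_hz band-pass edges passed to the denoiser.
#' @return numeric array `[subjects, conditions, edges]` with subject ids
#'   and sorted condition labels as dimnames.
#' @export
feature_array <- function(cohort, design,
                          conditions = condition_labels(design),
                          denoise = TRUE, low_hz = 0.01, high_hz = 0.1) {
  if (denoise)
    cohort <- denoise_cohort(cohort, design, low_hz = low_hz, high_hz = high_hz)
  conditions <- sort(conditions)
  n_rois <- ncol(cohort[[1]]$runs[[1]]$bold)
  n_edges <- n_rois * (n_rois - 1) / 2
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  arr <- array(NA_real_, dim = c(length(cohort), length(conditions), n_edges),
               dimnames = list(ids, conditions, NULL))
  for (s in seq_along(cohort)) {
    maps <- subject_fc_maps(cohort[[s]], design, conditions)
    for (cond in conditions)
      arr[s, cond, ] <- vectorize_lower_triangle(maps[[cond]])
  }
  arr
}
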