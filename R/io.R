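#' Write a simulated dataset to a directory
#'
#' One BOLD TSV (scans x ROIs, header = node ids) and one confound TSV
#' (named columns) per subject and run, named
#' `sub-<id>_run-<k>_bold.tsv` / `sub-<id>_run-<k>_confounds.tsv`, plus
#' `design.json` and, when ground truth is supplied, `ground_truth.json`
#' (the injected edges and amplitudes).
#'
#' @param cohort list of `subject_data`.
#' @param design the `block_design`.
#' @param dir output directory (created if needed).
#' @param ground_truth optional list serialised to `ground_truth.json`.
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(cohort, design, dir, ground_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort) {
    for (r in seq_along(subj$runs)) {
      run <- subj$runs[[r]]
      utils::write.table(run$bold,
        file.path(dir, sprintf("%s_run-%d_bold.tsv", subj$subject_id, r)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(run$confounds,
        file.path(dir, sprintf("%s_run-%d_confounds.tsv", subj$subject_id, r)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  dj <- list(
    tr = design$tr,
    fixation_s = design$fixation_s,
    n_scans_per_run = design$n_scans_per_run,
    conditions = design$conditions,
    stimulus_types = design$stimulus_types,
    runs = design$runs
  )
  jsonlite::write_json(dj, file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory
#'
#' Inverse of [write_dataset()]: parses `design.json`, loads every
#' `*_bold.tsv` / `*_confounds.tsv` pair, validates shapes against the
#' design, and returns subjects sorted by id.
#'
#' @param dir dataset directory.
#' @return list with `cohort` (list of `subject_data`) and `design`
#'   (a `block_design`).
#' @export
read_dataset <- function(dir) {
  dpath <- file.path(dir, "design.json")
  if (!file.exists(dpath)) stop("no design.json in ", dir, call. = FALSE)
  dj <- jsonlite::read_json(dpath, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  design <- structure(list(
    tr = dj$tr,
    fixation_s = dj$fixation_s,
    n_scans_per_run = as.integer(dj$n_scans_per_run),
    conditions = dj$conditions,
    stimulus_types = dj$stimulus_types,
    runs = lapply(dj$runs, function(r)
      as.data.frame(r, stringsAsFactors = FALSE))
  ), class = "block_design")

  bold_files <- sort(list.files(dir, pattern = "_bold\\.tsv$"))
  if (!length(bold_files)) stop("no *_bold.tsv files in ", dir, call. = FALSE)
  ids <- sort(unique(sub("_run-\\d+_bold\\.tsv$", "", bold_files)))
  cohort <- lapply(ids, function(id) {
    rfiles <- sort(bold_files[startsWith(bold_files, paste0(id, "_run-"))])
    runs <- lapply(rfiles, function(f) {
      bold <- as.matrix(utils::read.delim(file.path(dir, f)))
      if (nrow(bold) != design$n_scans_per_run)
        stop(sprintf("%s: %d scans but the design specifies %d", f,
                     nrow(bold), design$n_scans_per_run), call. = FALSE)
      cf <- file.path(dir, sub("_bold\\.tsv$", "_confounds.tsv", f))
      if (!file.exists(cf))
        stop("missing confound file: ", basename(cf), call. = FALSE)
      conf <- as.matrix(utils::read.delim(cf))
      if (nrow(conf) != nrow(bold))
        stop(basename(cf), ": confound rows do not match the scan count",
             call. = FALSE)
      if (!all(is.finite(bold)))
        stop(f, ": non-finite values", call. = FALSE)
      list(bold = bold, confounds = conf)
    })
    structure(list(subject_id = id, runs = runs), class = "subject_data")
  })
  names(cohort) <- ids
  list(cohort = cohort, design = design)
}

#' Serialise a decoding result to JSON
#'
#' Accuracy, chance level, selection settings and the per-fold selected-edge
#' lists and weights, for audit.
#'
#' @param result an `fc_decoding`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_decoding_json <- function(result, path) {
  out <- list(
    mode = result$mode,
    classes = result$classes,
    accuracy = result$accuracy,
    chance_level = result$chance_level,
    selection = unclass(result$selection),
    n_subjects = result$n_subjects,
    folds = lapply(result$folds, function(f) list(
      held_out = f$held_out,
      training = f$training,
      selected = f$selected,
      weights = f$weights,
      predictions = as.list(f$predictions),
      correct = as.list(f$correct)
    ))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise a permutation result to JSON
#'
#' Includes every null accuracy, for audit.
#'
#' @param result an `fc_permutation`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_permutation_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write connectivity maps for one subject
#'
#' Square-matrix TSV (node-id header) and long-format edge TSV
#' (`node_a`, `node_b`, `z`) per condition.
#'
#' @param maps named list of `fc_map` from [subject_fc_maps()].
#' @param dir output directory.
#' @param subject_id subject id used in file names.
#' @return invisibly, the files written.
#' @export
write_fc_maps <- function(maps, dir, subject_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- unlist(lapply(maps, function(m) {
    safe <- gsub("[^A-Za-z0-9]+", "-", m$condition)
    f1 <- file.path(dir, sprintf("%s_cond-%s_fcmatrix.tsv", subject_id, safe))
    utils::write.table(m$z, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    n <- nrow(m$z)
    ei <- edge_index(n)
    long <- data.frame(node_a = ei$node_a, node_b = ei$node_b,
                       z = vectorize_lower_triangle(m))
    f2 <- file.path(dir, sprintf("%s_cond-%s_edges.tsv", subject_id, safe))
    utils::write.table(long, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    c(f1, f2)
  }))
  invisible(files)
}
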