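.atlas_modules <- c("frontal", "temporal", "parietal", "insula", "limbic",
                    "occipital", "subcortical")

.atlas_cols <- c("node_id", "label", "mni_x", "mni_y", "mni_z", "module",
                 "hemisphere")

#' Read an atlas node table
#'
#' TSV with columns `node_id` (unique, contiguous 1..N), `label`, `mni_x`,
#' `mni_y`, `mni_z` (mm), `module` and `hemisphere` (L/R). Module strings
#' are normalised to the seven-category vocabulary (frontal, temporal,
#' parietal, insula, limbic, occipital, subcortical); anything else is an
#' error reporting the offending row.
#'
#' @param path path to the TSV file.
#' @return data frame, one row per node, ordered by `node_id`.
#' @export
read_atlas <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.atlas_cols, names(d))
  if (length(missing))
    stop("atlas table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$node_id)) {
    row <- which(duplicated(d$node_id))[1]
    stop(sprintf("duplicate node_id %s at row %d", d$node_id[row], row),
         call. = FALSE)
  }
  d$module <- tolower(trimws(d$module))
  bad <- which(!d$module %in% .atlas_modules)
  if (length(bad))
    stop(sprintf("unknown module '%s' at row %d (must be one of: %s)",
                 d$module[bad[1]], bad[1], paste(.atlas_modules, collapse = ", ")),
         call. = FALSE)
  d <- d[order(d$node_id), , drop = FALSE]
  if (!identical(as.integer(d$node_id), seq_len(nrow(d))))
    stop("node_id values must be contiguous 1..N", call. = FALSE)
  bad_h <- which(!d$hemisphere %in% c("L", "R"))
  if (length(bad_h))
    stop(sprintf("hemisphere must be 'L' or 'R' (row %d)", bad_h[1]), call. = FALSE)
  rownames(d) <- NULL
  d
}

#' Synthetic atlas node table
#'
#' A stand-in node table with plausible module proportions, alternating
#' hemispheres and placeholder MNI coordinates, for running the pipeline on
#' simulated data. It is synthetic: labels, coordinates and module
#' assignments carry no anatomical meaning. Users supply the real atlas
#' table for real data.
#'
#' @param n_nodes number of nodes (default 246, the size of a standard
#'   fine-grained whole-brain parcellation: 210 cortical + 36 subcortical).
#' @param seed integer seed for the placeholder coordinates.
#' @return data frame in the [read_atlas()] schema.
#' @export
synthetic_atlas <- function(n_nodes = 246, seed = 1) {
  ## rough module proportions of a whole-brain parcellation
  props <- c(frontal = 0.28, temporal = 0.16, parietal = 0.14, insula = 0.05,
             limbic = 0.11, occipital = 0.11, subcortical = 0.15)
  counts <- floor(props * n_nodes)
  counts[1] <- counts[1] + n_nodes - sum(counts)
  modules <- rep(names(props), counts)
  withr::with_seed(seed, data.frame(
    node_id = seq_len(n_nodes),
    label = sprintf("SYN_%s_%03d", toupper(substr(modules, 1, 3)), seq_len(n_nodes)),
    mni_x = round(ifelse(seq_len(n_nodes) %% 2 == 1, -1, 1) * stats::runif(n_nodes, 4, 60)),
    mni_y = round(stats::runif(n_nodes, -100, 60)),
    mni_z = round(stats::runif(n_nodes, -40, 70)),
    module = modules,
    hemisphere = ifelse(seq_len(n_nodes) %% 2 == 1, "L", "R"),
    stringsAsFactors = FALSE
  ))
}

#' Write an atlas node table to TSV
#'
#' @param atlas atlas data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
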