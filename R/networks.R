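#' Consensus edge set across cross-validation folds
#'
#' Edges selected by the feature-selection step in every fold. An empty
#' intersection is allowed and produces a warning.
#'
#' @param fold_masks list of integer edge-index vectors (or logical masks),
#'   one per fold; typically `lapply(result$folds, \(f) f$selected)`.
#' @return sorted integer vector of edge indices.
#' @export
consensus_mask <- function(fold_masks) {
  stopifnot(length(fold_masks) >= 1)
  sets <- lapply(fold_masks, function(m) if (is.logical(m)) which(m) else as.integer(m))
  out <- sort(Reduce(intersect, sets))
  if (!length(out)) warning("consensus edge set is empty")
  out
}

#' Discriminative weights of consensus edges
#'
#' The discriminative weight of an edge is the mean of the absolute values
#' of its linear-classifier coefficient across all cross-validation folds.
#'
#' @param fold_weights list (one per fold) of numeric weight vectors named
#'   by edge index — e.g. `lapply(result$folds, \(f) f$weights[["a|b"]])`
#'   for the class pair `a|b` of a [loocv_decode()] result.
#' @param consensus integer edge indices from [consensus_mask()].
#' @return named numeric vector, names = edge indices.
#' @export
discriminative_weights <- function(fold_weights, consensus) {
  stopifnot(length(fold_weights) >= 1)
  key <- as.character(consensus)
  per_fold <- vapply(fold_weights, function(w) {
    if (!all(key %in% names(w)))
      stop("a consensus edge has no weight in some fold (upstream contract violation)",
           call. = FALSE)
    abs(w[key])
  }, numeric(length(key)))
  per_fold <- matrix(per_fold, nrow = length(key))
  stats::setNames(rowMeans(per_fold), key)
}

#' Pairwise discriminative network from a decoding result
#'
#' Convenience wrapper: consensus edges of the folds, mean absolute weights
#' for one class pair, then the top-k network.
#'
#' @param result an `fc_decoding` with fold details.
#' @param pair class-pair key, e.g. `"anger|fear"`; defaults to the only
#'   pair of a pairwise run.
#' @param k number of edges to keep (default 50).
#' @param atlas an atlas table from [read_atlas()] or [synthetic_atlas()].
#' @return a `discriminative_network` (see [top_k_network()]).
#' @export
pairwise_network <- function(result, pair = NULL, k = 50, atlas) {
  stopifnot(inherits(result, "fc_decoding"), !is.null(result$folds))
  pair <- pair %||% names(result$folds[[1]]$weights)[1]
  cons <- consensus_mask(lapply(result$folds, `[[`, "selected"))
  w <- discriminative_weights(lapply(result$folds, function(f) f$weights[[pair]]),
                              cons)
  net <- top_k_network(w, k = k, atlas = atlas)
  net$context <- pair
  net
}

#' Top-k discriminative network
#'
#' The k highest-weight edges (ties broken by ascending edge index; if fewer
#' edges are available, all of them with a warning), annotated with node
#' modules from the atlas. Edges are sorted by weight, descending.
#'
#' @param weights named numeric vector (names = edge indices in the
#'   [edge_index()] ordering implied by the atlas size).
#' @param k number of edges to keep (default 50).
#' @param atlas atlas node table.
#' @param context optional label (class pair or condition) stored with the
#'   network.
#' @return object of class `discriminative_network`: list with `context`,
#'   `k` and `edges`, a data frame with columns `edge`, `node_a`, `node_b`,
#'   `weight`, `module_a`, `module_b`, `intra_module`.
#' @export
top_k_network <- function(weights, k = 50, atlas, context = NA_character_) {
  if (!length(weights)) stop("empty weight map", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  idx <- as.integer(names(weights))
  if (k > length(weights)) {
    warning(sprintf("only %d edges available; keeping all of them", length(weights)))
    k <- length(weights)
  }
  ord <- order(-weights, idx)[seq_len(k)]
  sel_edge <- idx[ord]
  ei <- edge_index(nrow(atlas))
  a <- ei$node_a[sel_edge]
  b <- ei$node_b[sel_edge]
  edges <- data.frame(
    edge = sel_edge,
    node_a = a,
    node_b = b,
    weight = unname(weights[ord]),
    module_a = atlas$module[a],
    module_b = atlas$module[b],
    stringsAsFactors = FALSE
  )
  edges$intra_module <- edges$module_a == edges$module_b
  structure(list(context = context, k = k, edges = edges),
            class = "discriminative_network")
}

#' @export
print.discriminative_network <- function(x, ...) {
  cat(sprintf("<discriminative_network> %s: %d edges (%d intra-module)\n",
              x$context, nrow(x$edges), sum(x$edges$intra_module)))
  invisible(x)
}

#' Condition-preferring network
#'
#' Edges showing reliable discriminative power in both pairwise contrasts
#' involving one condition: the intersection of the two pairwise networks'
#' edge sets, with weights averaged across the two. An empty intersection
#' yields an empty network with a warning.
#'
#' @param pairwise_networks named list of `discriminative_network`, one per
#'   class pair, whose `context` fields are `"a|b"` pair keys.
#' @param condition the condition of interest; exactly two of the networks'
#'   contexts must contain it.
#' @return a `discriminative_network` with `context = condition`.
#' @export
emotion_preferring_network <- function(pairwise_networks, condition) {
  ctx <- vapply(pairwise_networks, `[[`, character(1), "context")
  has <- vapply(strsplit(ctx, "|", fixed = TRUE),
                function(p) condition %in% p, logical(1))
  if (sum(has) != 2)
    stop(sprintf("need exactly two pairwise networks involving '%s'; found %d",
                 condition, sum(has)), call. = FALSE)
  nets <- pairwise_networks[has]
  e1 <- nets[[1]]$edges
  e2 <- nets[[2]]$edges
  common <- intersect(e1$edge, e2$edge)
  if (!length(common)) warning(sprintf("no edges shared by both contrasts of '%s'", condition))
  ea <- e1[match(common, e1$edge), , drop = FALSE]
  eb <- e2[match(common, e2$edge), , drop = FALSE]
  ea$weight <- (ea$weight + eb$weight) / 2
  ea <- ea[order(-ea$weight, ea$edge), , drop = FALSE]
  rownames(ea) <- NULL
  structure(list(context = condition, k = nrow(ea), edges = ea),
            class = "discriminative_network")
}

#' Export a network to disk
#'
#' `fmt = "edge_tsv"` writes a long table (node labels, weight, modules,
#' intra-module flag). `fmt = "viewer"` writes whitespace-delimited `.node`
#' (x y z module-code size label, size = node degree within the network) and
#' `.edge` (square symmetric weight matrix) files suitable for standard
#' surface-viewer import.
#'
#' @param net a `discriminative_network`.
#' @param atlas atlas node table.
#' @param path output path without extension (`.tsv`, or `.node`/`.edge`,
#'   is appended).
#' @param fmt `"edge_tsv"` or `"viewer"`.
#' @return invisibly, the paths written.
#' @export
export_network <- function(net, atlas, path, fmt = c("edge_tsv", "viewer")) {
  fmt <- match.arg(fmt)
  e <- net$edges
  if (fmt == "edge_tsv") {
    out <- data.frame(
      node_a = e$node_a, node_b = e$node_b,
      node_a_label = atlas$label[e$node_a],
      node_b_label = atlas$label[e$node_b],
      weight = e$weight,
      module_a = e$module_a, module_b = e$module_b,
      intra_module = e$intra_module)
    f <- paste0(path, ".tsv")
    utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(f))
  }
  n <- nrow(atlas)
  m <- matrix(0, n, n)
  m[cbind(e$node_a, e$node_b)] <- e$weight
  m[cbind(e$node_b, e$node_a)] <- e$weight
  degree <- tabulate(c(e$node_a, e$node_b), nbins = n)
  node <- data.frame(atlas$mni_x, atlas$mni_y, atlas$mni_z,
                     as.integer(factor(atlas$module, levels = .atlas_modules)),
                     degree, atlas$label)
  fn <- paste0(path, ".node")
  fe <- paste0(path, ".edge")
  utils::write.table(node, fn, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(m, fe, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fn, fe))
}

#' Read a network back from an edge TSV
#'
#' Inverse of [export_network()] with `fmt = "edge_tsv"`.
#'
#' @param path path to the `.tsv` file.
#' @param n_rois atlas size used when the network was exported.
#' @param context optional context label.
#' @return a `discriminative_network`.
#' @export
read_network_tsv <- function(path, n_rois, context = NA_character_) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  ei <- edge_index(n_rois)
  key <- paste(ei$node_a, ei$node_b)
  edge <- match(paste(d$node_a, d$node_b), key)
  edges <- data.frame(edge = edge, node_a = d$node_a, node_b = d$node_b,
                      weight = d$weight, module_a = d$module_a,
                      module_b = d$module_b, intra_module = d$intra_module,
                      stringsAsFactors = FALSE)
  structure(list(context = context, k = nrow(edges), edges = edges),
            class = "discriminative_network")
}
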