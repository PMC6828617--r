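#' Permutation test of decoding accuracy
#'
#' For each permutation, the condition labels are shuffled within every
#' subject (each subject still contributes exactly one map per class, with
#' relabelled identities, preserving exchangeability under
#' leave-one-subject-out cross-validation), and the full decoding pipeline —
#' including per-fold feature selection — is rerun. The default p value uses
#' the add-one rule, `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, which
#' is valid for any number of permutations and can never be zero;
#' `rule = "strict_paper"` instead counts strict exceedances,
#' `#\{null > observed\} / n_perm`.
#'
#' @param features subjects x conditions x edges array.
#' @param classes condition labels to decode.
#' @param selection a [selection_config()].
#' @param n_perm number of permutations (>= 1; 1000 for reported results).
#' @param seed integer seed; the test is deterministic given the seed.
#' @param rule p-value counting rule, `"add_one"` (default) or
#'   `"strict_paper"`.
#' @param cost SVM cost.
#' @return object of class `fc_permutation`: list with `observed_accuracy`,
#'   `null_accuracies`, `p_value`, `n_permutations`, `rule`, `seed` and
#'   `chance_level`.
#' @export
permutation_test <- function(features, classes = dimnames(features)[[2]],
                             selection = selection_config(), n_perm = 1000,
                             seed = 1, rule = c("add_one", "strict_paper"),
                             cost = 1) {
  rule <- match.arg(rule)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  classes <- sort(classes)
  s_n <- dim(features)[1]

  observed <- loocv_decode(features, classes, selection, cost,
                           keep_details = FALSE)$accuracy

  null_acc <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- features
    for (s in seq_len(s_n)) {
      sh <- sample(classes)
      perm[s, classes, ] <- features[s, sh, ]
    }
    loocv_decode(perm, classes, selection, cost, keep_details = FALSE)$accuracy
  }, numeric(1)))

  p <- switch(rule,
    add_one = (1 + sum(null_acc >= observed)) / (n_perm + 1),
    strict_paper = sum(null_acc > observed) / n_perm)

  structure(list(
    observed_accuracy = observed,
    null_accuracies = null_acc,
    p_value = p,
    n_permutations = n_perm,
    rule = rule,
    seed = seed,
    classes = classes,
    chance_level = 1 / length(classes)
  ), class = "fc_permutation")
}

#' @export
print.fc_permutation <- function(x, ...) {
  cat(sprintf(
    "<fc_permutation> observed %.2f%% vs %d label shuffles (mean %.2f%%, chance %.2f%%): p = %.4g [%s]\n",
    100 * x$observed_accuracy, x$n_permutations, 100 * mean(x$null_accuracies),
    100 * x$chance_level, x$p_value, x$rule))
  invisible(x)
}
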