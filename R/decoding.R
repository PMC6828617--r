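#' Vectorised one-sample t test
#'
#' t = mean / (sd / sqrt(n)) with the n-1 sample standard deviation, and the
#' two-sided p from the Student t distribution with n-1 degrees of freedom.
#' Degenerate zero-variance columns get t = 0, p = 1 when the mean is also
#' zero, and a signed infinite t with p = 0 (flagged) otherwise.
#'
#' @param x numeric vector, or subjects x features matrix (the test runs per
#'   column).
#' @return list with `t`, `p`, `df` and logical `degenerate` (zero variance,
#'   nonzero mean).
#' @export
one_sample_t <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  m <- colMeans(x)
  s <- sqrt(.colvars(x))
  tt <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, sign(m) * Inf))
  p <- ifelse(is.finite(tt), 2 * stats::pt(-abs(tt), df = n - 1), 0)
  list(t = unname(tt), p = unname(p), df = n - 1,
       degenerate = unname(s == 0 & m != 0))
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up false-discovery-rate control at level `q`.
#'
#' @param p vector of p values in \[0, 1\].
#' @param q FDR level.
#' @return logical rejection mask (empty input gives an empty mask).
#' @export
bh_fdr <- function(p, q) {
  if (!length(p)) return(logical(0))
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH") <= q
}

#' Selection configuration
#'
#' @param method `"positive_fdr"` (edges significantly positive for at
#'   least one condition, the primary method), `"f_score_topk"` (top-k
#'   edges by Fisher-criterion / ANOVA F score), or `"all"` (no selection).
#' @param q FDR level for `positive_fdr` (default 0.01).
#' @param k feature count for `f_score_topk`; `NULL` (default) means "as
#'   many edges as the positive-FDR union selects on the same fold", which
#'   makes the two methods directly comparable.
#' @param one_sided use halved one-sided p values in the positivity test
#'   instead of the default two-sided p gated by t > 0.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(method = c("positive_fdr", "f_score_topk", "all"),
                             q = 0.01, k = NULL, one_sided = FALSE) {
  method <- match.arg(method)
  if (!(q > 0 && q < 1)) stop("`q` must be in (0, 1)", call. = FALSE)
  if (!is.null(k) && k < 1) stop("`k` must be >= 1", call. = FALSE)
  structure(list(method = method, q = q, k = k, one_sided = one_sided),
            class = "selection_config")
}

#' Positive-connectivity union mask
#'
#' Per condition, an edge passes if its group mean is positive (t > 0) and
#' the BH-FDR correction of its one-sample-t p values rejects at level `q`;
#' the final mask is the union over conditions (edges significantly positive
#' for at least one condition). Negative connections never enter the feature
#' set, however strong.
#'
#' @param train_by_condition named list (>= 2 conditions) of subjects x
#'   edges matrices, training subjects only.
#' @param q FDR level.
#' @param one_sided use halved one-sided p values.
#' @return logical edge mask.
#' @export
positive_union_mask <- function(train_by_condition, q = 0.01, one_sided = FALSE) {
  if (length(train_by_condition) < 2)
    stop("need at least 2 conditions", call. = FALSE)
  masks <- lapply(train_by_condition, function(m) {
    if (nrow(m) < 2) stop("need at least 2 training subjects", call. = FALSE)
    tt <- one_sample_t(m)
    p <- if (one_sided) ifelse(tt$t > 0, tt$p / 2, 1 - tt$p / 2) else tt$p
    tt$t > 0 & bh_fdr(p, q)
  })
  mask <- Reduce(`|`, masks)
  if (!any(mask))
    stop("positive-connectivity selection is empty; increase `q` or provide more training data",
         call. = FALSE)
  mask
}

#' F-score feature ranking
#'
#' With two classes, the Fisher criterion
#' ((m1 - m)^2 + (m2 - m)^2) / (s1^2 + s2^2) per feature (class means m1,
#' m2, overall mean m, within-class sample variances s1^2, s2^2); with three
#' or more classes, the one-way ANOVA F statistic. A feature with zero
#' within-class variance but distinct class means scores +Inf and ranks
#' first; a feature identical across all samples scores 0. The ranking is a
#' stable descending sort with ties broken by feature index.
#'
#' @param x samples x features matrix.
#' @param y class labels, one per row.
#' @return list with `score` (per feature) and `order` (feature indices,
#'   best first).
#' @export
f_score_rank <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(y) < 2)) stop("need at least 2 samples per class", call. = FALSE)
  m <- colMeans(x)
  cm <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  cv <- lapply(classes, function(cl) .colvars(x[y == cl, , drop = FALSE]))
  nc <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  if (length(classes) == 2) {
    num <- (cm[[1]] - m)^2 + (cm[[2]] - m)^2
    den <- cv[[1]] + cv[[2]]
  } else {
    num <- Reduce(`+`, Map(function(mu, n) n * (mu - m)^2, cm, nc)) /
      (length(classes) - 1)
    den <- Reduce(`+`, Map(function(v, n) (n - 1) * v, cv, nc)) /
      (nrow(x) - length(classes))
  }
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  list(score = unname(score),
       order = order(-score, seq_along(score)))
}

#' Train a binary soft-margin linear classifier
#'
#' Linear support vector machine (LIBSVM via e1071), cost-parameterised,
#' without feature scaling. The returned weights are oriented so that the
#' decision value `x . w + b > 0` predicts the alphabetically first of the
#' two classes.
#'
#' @param x samples x features matrix.
#' @param y binary class labels.
#' @param cost soft-margin cost (default 1, the LIBSVM default).
#' @return list of class `linear_svm` with `weights`, `bias`, `classes`
#'   (sorted) and `positive_class`.
#' @export
train_linear_classifier <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training labels contain a single class", call. = FALSE)
  if (length(classes) > 2) stop("binary classifier: got more than 2 classes", call. = FALSE)
  fit <- e1071::svm(x, factor(y, levels = classes), type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE,
                    fitted = FALSE, na.action = stats::na.pass)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## LIBSVM orients the decision value toward its first internal label
  pos <- fit$levels[fit$labels[1]]
  if (pos != classes[1]) { w <- -w; b <- -b }
  structure(list(weights = unname(w), bias = unname(b), classes = classes,
                 positive_class = classes[1]), class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  d <- drop(as.matrix(newdata) %*% object$weights) + object$bias
  ifelse(d > 0, object$classes[1], object$classes[2])
}

## decision value in favour of object$classes[1]
.decision_value <- function(object, x) {
  drop(as.matrix(x) %*% object$weights) + object$bias
}

## fit the selection for one fold; returns list(mask = logical, by = method)
.fold_selection <- function(train_by_cond, selection) {
  if (selection$method == "all") {
    mask <- rep(TRUE, ncol(train_by_cond[[1]]))
  } else if (selection$method == "positive_fdr") {
    mask <- positive_union_mask(train_by_cond, q = selection$q,
                                one_sided = selection$one_sided)
  } else { # f_score_topk
    k <- selection$k %||% sum(positive_union_mask(
      train_by_cond, q = selection$q, one_sided = selection$one_sided))
    x <- do.call(rbind, train_by_cond)
    y <- rep(names(train_by_cond), vapply(train_by_cond, nrow, integer(1)))
    rk <- f_score_rank(x, y)
    k <- min(k, ncol(x))
    mask <- rep(FALSE, ncol(x))
    mask[rk$order[seq_len(k)]] <- TRUE
  }
  mask
}

## core LOOCV engine shared by loocv_decode, accuracy_curve and the
## permutation test; `mask_fun(train_by_cond, fold)` returns the edge mask
.loocv <- function(features, classes, mask_fun, cost, keep_details) {
  subjects <- dimnames(features)[[1]]
  s_n <- length(subjects)
  classes <- sort(classes)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  folds <- if (keep_details) vector("list", s_n) else NULL
  n_correct <- 0L

  for (s in seq_len(s_n)) {
    tr <- setdiff(seq_len(s_n), s)
    train_by_cond <- lapply(classes, function(cl) {
      m <- features[tr, cl, , drop = FALSE]
      dim(m) <- c(length(tr), dim(features)[3])
      m
    })
    names(train_by_cond) <- classes
    mask <- tryCatch(mask_fun(train_by_cond, s), error = function(e)
      stop(sprintf("fold %d (held-out %s): %s", s, subjects[s],
                   conditionMessage(e)), call. = FALSE))
    sel <- which(mask)

    fits <- lapply(pairs, function(pr) {
      xa <- train_by_cond[[pr[1]]][, sel, drop = FALSE]
      xb <- train_by_cond[[pr[2]]][, sel, drop = FALSE]
      train_linear_classifier(rbind(xa, xb),
                              rep(pr, c(nrow(xa), nrow(xb))), cost = cost)
    })

    preds <- vapply(classes, function(true_cl) {
      x <- features[s, true_cl, sel, drop = TRUE]
      votes <- stats::setNames(numeric(length(classes)), classes)
      score <- votes
      for (q in seq_along(pairs)) {
        pr <- pairs[[q]]
        d <- .decision_value(fits[[q]], matrix(x, 1))
        votes[if (d > 0) pr[1] else pr[2]] <- votes[if (d > 0) pr[1] else pr[2]] + 1
        score[pr[1]] <- score[pr[1]] + d
        score[pr[2]] <- score[pr[2]] - d
      }
      top <- names(votes)[votes == max(votes)]
      top[order(-score[top], match(top, classes))][1]
    }, character(1))

    correct <- preds == classes
    n_correct <- n_correct + sum(correct)
    if (keep_details) {
      wts <- lapply(fits, function(f)
        stats::setNames(f$weights, as.character(sel)))
      names(wts) <- vapply(pairs, paste, character(1), collapse = "|")
      folds[[s]] <- list(
        held_out = subjects[s],
        training = subjects[tr],
        selected = sel,
        weights = wts,
        biases = stats::setNames(vapply(fits, `[[`, numeric(1), "bias"), names(wts)),
        predictions = stats::setNames(preds, classes),
        correct = stats::setNames(correct, classes)
      )
    }
  }

  list(accuracy = n_correct / (s_n * length(classes)), folds = folds)
}

#' Leave-one-subject-out decoding of conditions from connectivity features
#'
#' For every fold, one subject is held out, feature selection is fitted on
#' the remaining subjects only (no peeking), one binary linear SVM is
#' trained per class pair on the selected edges, and the held-out subject's
#' per-class connectivity maps are predicted by one-against-one majority
#' vote (a single classifier in the two-class case). Vote ties are broken by
#' the class with the largest summed pairwise decision value, then by class
#' order. Accuracy is the fraction of correct (subject, class) predictions;
#' the number of folds equals the number of subjects.
#'
#' @param features subjects x conditions x edges array from
#'   [feature_array()].
#' @param classes the condition labels to decode (2 for pairwise, 3+ for
#'   multi-category).
#' @param selection a [selection_config()].
#' @param cost SVM soft-margin cost.
#' @param keep_details keep per-fold masks, weights and predictions
#'   (default TRUE; the permutation machinery switches it off).
#' @return object of class `fc_decoding`: list with `mode`, `classes`,
#'   `accuracy`, `chance_level`, `selection`, `n_subjects` and `folds`.
#' @export
loocv_decode <- function(features, classes = dimnames(features)[[2]],
                         selection = selection_config(), cost = 1,
                         keep_details = TRUE) {
  classes <- sort(classes)
  stopifnot(length(dim(features)) == 3,
            all(classes %in% dimnames(features)[[2]]),
            length(classes) >= 2, dim(features)[1] >= 2)
  res <- .loocv(features, classes,
                mask_fun = function(tb, fold) .fold_selection(tb, selection),
                cost = cost, keep_details = keep_details)
  structure(list(
    mode = if (length(classes) == 2) "pairwise" else "multi_category",
    classes = classes,
    accuracy = res$accuracy,
    chance_level = 1 / length(classes),
    selection = selection,
    cost = cost,
    n_subjects = dim(features)[1],
    folds = res$folds
  ), class = "fc_decoding")
}

#' @export
print.fc_decoding <- function(x, ...) {
  cat(sprintf("<fc_decoding> %s [%s]: accuracy %.2f%% (chance %.2f%%), %d folds\n",
              x$mode, paste(x$classes, collapse = " vs "),
              100 * x$accuracy, 100 * x$chance_level, x$n_subjects))
  invisible(x)
}

#' Decoding accuracy as a function of feature count
#'
#' Per fold, edges are ranked by the minimum across-condition one-sample-t
#' p value in ascending order (computed on the training subjects only), the
#' top k are kept, and the rest of the procedure is identical to
#' [loocv_decode()]. No positive-connectivity pre-mask is applied. Values of
#' `k` beyond the feature count are clamped with a warning.
#'
#' @param features subjects x conditions x edges array.
#' @param classes condition labels to decode.
#' @param k_grid feature counts to evaluate.
#' @param cost SVM cost.
#' @return data frame with columns `k` and `accuracy`, one row per grid
#'   point.
#' @export
accuracy_curve <- function(features, classes = dimnames(features)[[2]],
                           k_grid, cost = 1) {
  classes <- sort(classes)
  n_edges <- dim(features)[3]
  if (any(k_grid > n_edges)) {
    warning("values of `k` beyond the number of features were clamped")
    k_grid <- pmin(k_grid, n_edges)
  }
  acc <- vapply(k_grid, function(k) {
    .loocv(features, classes, mask_fun = function(tb, fold) {
      pmat <- vapply(tb, function(m) one_sample_t(m)$p, numeric(n_edges))
      pmin_p <- do.call(pmin, as.data.frame(pmat))
      mask <- rep(FALSE, n_edges)
      mask[order(pmin_p, seq_len(n_edges))[seq_len(k)]] <- TRUE
      mask
    }, cost = cost, keep_details = FALSE)$accuracy
  }, numeric(1))
  data.frame(k = k_grid, accuracy = acc)
}
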