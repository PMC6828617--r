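test_that("one-sample t matches the textbook formula and handles degeneracy", {
  # hand-computed: mean 1.5, sd 0.5774, n 4 -> t = 5.196
  r <- one_sample_t(c(1, 1, 2, 2))
  expect_equal(r$t, 1.5 / (sd(c(1, 1, 2, 2)) / 2), tolerance = 1e-12)
  expect_equal(r$t, 5.196, tolerance = 1e-3)

  # symmetric about zero -> t = 0, p = 1
  r0 <- one_sample_t(c(-1, 1, -2, 2))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # constant nonzero -> flagged infinite-t sentinel
  rc <- one_sample_t(c(3, 3, 3))
  expect_true(is.infinite(rc$t) && rc$t > 0)
  expect_equal(rc$p, 0)
  expect_true(rc$degenerate)
  rz <- one_sample_t(c(0, 0, 0))
  expect_equal(rz$t, 0)
  expect_equal(rz$p, 1)
  expect_false(rz$degenerate)

  # agreement with stats::t.test across random vectors
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    ref <- t.test(x)
    mine <- one_sample_t(x)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }

  expect_error(one_sample_t(1), "at least 2")
  expect_error(one_sample_t(c(1, NA)), "finite")
})

test_that("BH-FDR mask matches a brute-force step-up implementation", {
  brute_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    below <- p[o] <= q * seq_len(m) / m
    k <- if (any(below)) max(which(below)) else 0
    mask <- rep(FALSE, m)
    if (k > 0) mask[o[seq_len(k)]] <- TRUE
    mask
  }
  expect_equal(bh_fdr(c(0.001, 0.02, 0.5), 0.05), c(TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.1), rep(FALSE, 5))
  expect_equal(bh_fdr(0, 0.001), TRUE)
  expect_equal(bh_fdr(numeric(0), 0.05), logical(0))
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")

  set.seed(32)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.005, 0.2)
    expect_identical(bh_fdr(p, q), brute_bh(p, q))
  }
})

test_that("positive union mask pools per-condition positive edges", {
  # condition A significant on edge 1, B on edge 2, both negative on edge 4
  n <- 12
  set.seed(33)
  mk <- function(mu) sapply(mu, function(m) rnorm(n, m, 0.1))
  a <- mk(c(1, 0, 0, -1))
  b <- mk(c(0, 1, 0, -1))
  mask <- positive_union_mask(list(A = a, B = b), q = 0.01)
  expect_true(mask[1] && mask[2])
  expect_false(mask[4])  # strongly negative everywhere: excluded despite |t|

  # decomposition: restricted to one condition = t>0 gate + BH rejection
  tt <- one_sample_t(a)
  ref <- tt$t > 0 & bh_fdr(tt$p, 0.01)
  masks_a <- positive_union_mask(list(A = a, A2 = a), q = 0.01)
  expect_equal(masks_a, ref)

  # pure-noise training data: selected fraction stays small
  noise <- lapply(1:3, function(i) matrix(rnorm(19 * 1000), 19, 1000))
  names(noise) <- c("A", "B", "C")
  sel <- tryCatch(mean(positive_union_mask(noise, q = 0.01)),
                  error = function(e) 0)
  expect_lt(sel, 0.05)

  expect_error(positive_union_mask(list(A = a), q = 0.01), "2 conditions")
})

test_that("F-score ranking follows the Fisher criterion and ANOVA F", {
  # two classes: means 0 vs 2, unit within-variances -> score 1
  set.seed(34)
  x1 <- c(-1, 1, -1, 1)          # mean 0, sample var 4/3
  x2 <- c(1, 3, 1, 3)            # mean 2, sample var 4/3
  x <- cbind(f1 = c(x1, x2), f2 = rep(1, 8), f3 = rnorm(8))
  y <- rep(c("a", "b"), each = 4)
  r <- f_score_rank(x, y)
  expect_equal(r$score[1], (1 + 1) / (4 / 3 + 4 / 3), tolerance = 1e-12)
  expect_equal(r$score[2], 0)   # identical across all samples
  expect_equal(r$order[1], 1)

  # affine rescaling leaves the score unchanged
  xa <- x; xa[, 1] <- -3 * x[, 1] + 7
  expect_equal(f_score_rank(xa, y)$score[1], r$score[1], tolerance = 1e-12)

  # zero within-class variance with distinct means -> +Inf, ranked first
  xz <- cbind(a = rep(c(0, 1), each = 4), b = rnorm(8))
  expect_equal(f_score_rank(xz, y)$score[1], Inf)
  expect_equal(f_score_rank(xz, y)$order[1], 1)

  # >= 3 classes: matches aov's F statistic
  y3 <- rep(c("a", "b", "c"), each = 5)
  x3 <- matrix(rnorm(15 * 4), 15, 4)
  mine <- f_score_rank(x3, y3)$score
  ref <- apply(x3, 2, function(col)
    summary(aov(col ~ factor(y3)))[[1]]$`F value`[1])
  expect_equal(mine, unname(ref), tolerance = 1e-8)

  expect_error(f_score_rank(x, rep("a", 8)), "2 classes")
  expect_error(f_score_rank(x[1:3, ], c("a", "a", "b")), "2 samples per class")
})

test_that("linear SVM separates, is invariant to duplication, and centres its boundary", {
  x <- matrix(c(-1, 1), ncol = 1)
  fit <- train_linear_classifier(x, c("neg", "pos"))
  expect_equal(unname(predict(fit, x)), c("neg", "pos"))

  # duplicating every sample leaves the decision function unchanged
  fit2 <- train_linear_classifier(rbind(x, x), rep(c("neg", "pos"), 2))
  grid <- matrix(seq(-2, 2, 0.5), ncol = 1)
  d1 <- drop(grid %*% fit$weights) + fit$bias
  d2 <- drop(grid %*% fit2$weights) + fit2$bias
  expect_equal(d1, d2, tolerance = 1e-6)

  # {-2,-1} vs {1,2}: boundary strictly inside (-1, 1)
  fit3 <- train_linear_classifier(matrix(c(-2, -1, 1, 2), ncol = 1),
                                  c("a", "a", "b", "b"))
  boundary <- -fit3$bias / fit3$weights
  expect_gt(boundary, -1)
  expect_lt(boundary, 1)

  expect_error(train_linear_classifier(x, c("a", "a")), "single class")
})

test_that("LOOCV holds each subject out exactly once and respects separability", {
  # cleanly separable three-class toy features
  fa <- toy_features(6, c("anger", "fear", "joy"), 30,
                     shift = list(anger = list(edges = 1:5, by = 2),
                                  fear = list(edges = 6:10, by = 2),
                                  joy = list(edges = 11:15, by = 2)))
  dec <- loocv_decode(fa, selection = selection_config(q = 0.05))
  expect_equal(dec$accuracy, 1.0)
  expect_equal(dec$mode, "multi_category")
  expect_equal(dec$chance_level, 1 / 3)
  expect_length(dec$folds, 6)
  expect_setequal(vapply(dec$folds, `[[`, character(1), "held_out"),
                  dimnames(fa)[[1]])
  for (f in dec$folds) {
    expect_false(f$held_out %in% f$training)
    expect_length(f$training, 5)
    expect_length(f$weights, 3)      # one classifier per class pair
    for (w in f$weights) expect_length(w, length(f$selected))
  }

  # pairwise mode: one classifier, chance 1/2
  dp <- loocv_decode(fa, classes = c("anger", "fear"),
                     selection = selection_config(q = 0.05))
  expect_equal(dp$mode, "pairwise")
  expect_equal(dp$accuracy, 1.0)
  expect_length(dp$folds[[1]]$weights, 1)
})

test_that("selection is fitted on training subjects only (no peeking audit)", {
  # class signal present ONLY in each held-out subject's maps: training data
  # are pure noise, so accuracy must stay inside the chance band
  n_sub <- 20
  fa <- toy_features(n_sub, c("a", "b", "c"), 60, base_mean = 0.5, sd = 0.1,
                     seed = 41)
  # inject a strong class-specific signal into EVERY subject; then at test
  # time each fold's training rows are replaced by noise-only versions
  noise_only <- fa
  for (s in seq_len(n_sub)) {
    fa[s, "a", 1:10] <- fa[s, "a", 1:10] + 3
    fa[s, "b", 11:20] <- fa[s, "b", 11:20] + 3
    fa[s, "c", 21:30] <- fa[s, "c", 21:30] + 3
  }
  # manual LOOCV: train on noise_only rows, test on signal rows
  correct <- 0
  for (s in seq_len(n_sub)) {
    tr <- setdiff(seq_len(n_sub), s)
    hybrid <- noise_only
    hybrid[s, , ] <- fa[s, , ]
    dec <- loocv_decode(hybrid, selection = selection_config(q = 0.05),
                        keep_details = TRUE)
    f <- dec$folds[[s]]
    correct <- correct + sum(f$correct)
  }
  acc <- correct / (n_sub * 3)
  band <- qbinom(c(0.025, 0.975), n_sub * 3, 1 / 3) / (n_sub * 3)
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("pairwise accuracy ignores relabelling of the third class", {
  fa <- toy_features(8, c("a", "b", "c"), 40,
                     shift = list(a = list(edges = 1:6, by = 1.5)),
                     seed = 42)
  d1 <- loocv_decode(fa, classes = c("a", "b"),
                     selection = selection_config(q = 0.05))
  fa_swapped <- fa
  fa_swapped[, "c", ] <- fa[, "c", sample(40)]  # scramble the unused class
  d2 <- loocv_decode(fa_swapped, classes = c("a", "b"),
                     selection = selection_config(q = 0.05))
  expect_equal(d1$accuracy, d2$accuracy)

  # an all-negative feature set makes positive selection fail, naming the fold
  neg <- toy_features(5, c("a", "b"), 20, base_mean = -1, sd = 0.1)
  expect_error(loocv_decode(neg, selection = selection_config(q = 0.01)),
               "fold 1")
})

test_that("f_score_topk selection defaults its k to the positive-union size", {
  fa <- toy_features(8, c("a", "b"), 40,
                     shift = list(a = list(edges = 1:4, by = 1.5)), seed = 43)
  dec_f <- loocv_decode(fa, selection = selection_config("f_score_topk", q = 0.05))
  dec_p <- loocv_decode(fa, selection = selection_config(q = 0.05))
  for (s in seq_along(dec_f$folds))
    expect_length(dec_f$folds[[s]]$selected, length(dec_p$folds[[s]]$selected))
  # explicit k is honoured
  dec_k <- loocv_decode(fa, selection = selection_config("f_score_topk", k = 7))
  expect_true(all(lengths(lapply(dec_k$folds, `[[`, "selected")) == 7))
})

test_that("accuracy curve ranks by training-set p values and clamps k", {
  fa <- toy_features(6, c("a", "b"), 25,
                     shift = list(a = list(edges = 1:3, by = 2)), seed = 44)
  curve <- accuracy_curve(fa, k_grid = c(1, 5, 25))
  expect_equal(curve$k, c(1, 5, 25))
  expect_equal(nrow(curve), 3)
  # k = all features equals plain LOOCV with selection disabled
  full <- loocv_decode(fa, selection = selection_config("all"))
  expect_equal(curve$accuracy[3], full$accuracy)
  # separable data: the curve clears chance somewhere
  expect_gte(max(curve$accuracy), 0.5 + 0.3)
  expect_warning(accuracy_curve(fa, k_grid = c(10, 999)), "clamped")
})
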