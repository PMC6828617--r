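test_that("task regressors follow the boxcar-convolution oracle", {
  # single 20 s block at onset 10 s, TR 2, plus a second condition far away
  blocks <- data.frame(
    condition = c("a", "b"), stimulus_type = "face",
    condition_label = c("a", "b"), onset_s = c(10, 200), n_trials = 8,
    trial_dur_s = 2, isi_s = 0.5, post_block_task_s = 2)
  design <- structure(list(tr = 2, fixation_s = 10, n_scans_per_run = 150L,
                           conditions = c("a", "b"), stimulus_types = "face",
                           runs = list(blocks)), class = "block_design")
  reg <- build_task_regressors(design, run = 1)
  expect_equal(colnames(reg), c("a", "b"))

  # independent discrete convolution oracle for condition a
  h <- canonical_hrf(2)
  u <- as.numeric((0:149) * 2 >= 10 & (0:149) * 2 < 30)
  oracle <- sapply(1:150, function(t)
    sum(u[max(1, t - length(h) + 1):t] * rev(h[1:min(t, length(h))])))
  expect_equal(unname(reg[, "a"]), oracle, tolerance = 1e-8)

  # support begins at the first scan inside the block (HRF value at lag 0 is 0,
  # so the first nonzero sample is one scan later) and the peak lags onset
  first_nonzero <- which(reg[, "a"] > 1e-8)[1]
  expect_equal(first_nonzero, 7)      # onset 10 s = scan index 6 (1-based)
  # peak of boxcar * HRF trails the 20 s block: inside (onset + HRF delay,
  # onset + span), i.e. a lag in (4, 20) s
  peak_lag_s <- ((which.max(reg[, "a"]) - 1) * 2) - 10
  expect_gte(peak_lag_s, 4)
  expect_lte(peak_lag_s, 20)
})

test_that("regressor columns match the design's conditions", {
  d <- reduced_design()
  reg <- build_task_regressors(d, run = 1)
  expect_equal(colnames(reg), c("anger", "fear", "joy"))
  # a requested condition absent from the design gives a zero column + warning
  expect_warning(reg2 <- build_task_regressors(d, run = 1,
    conditions = c("anger", "fear", "joy", "zzz")), "zzz")
  expect_equal(unname(reg2[, "zzz"]), numeric(d$n_scans_per_run))
  # a blockless design yields an all-zero matrix
  empty <- d
  empty$runs[[1]] <- d$runs[[1]][0, ]
  suppressWarnings(reg3 <- build_task_regressors(empty, run = 1,
                                                 conditions = c("anger", "fear")))
  expect_true(all(reg3 == 0))
})

test_that("confound matrix assembles intercept, confounds, trend and task columns", {
  d <- reduced_design()
  n <- d$n_scans_per_run
  conf <- matrix(rnorm(n * 11), n, 11,
                 dimnames = list(NULL, c(paste0("mot_", 1:6), paste0("comp", 1:5))))
  x <- build_confound_matrix(conf, d, run = 1)
  # 1 intercept + 6 motion + 5 nuisance + 1 trend + 3 conditions = 16
  expect_equal(ncol(x), 16)
  expect_equal(colnames(x)[1], "intercept")
  expect_equal(colnames(x)[13], "linear_trend")
  tr_col <- x[, "linear_trend"]
  expect_equal(unname(tr_col), (0:(n - 1)) - mean(0:(n - 1)))

  # collinear duplicate column -> rank error
  conf_bad <- cbind(conf, dup = conf[, 1])
  expect_error(build_confound_matrix(conf_bad, d, run = 1), "rank")
  # duplicate names -> error
  conf_dn <- conf
  colnames(conf_dn)[2] <- "mot_1"
  expect_error(build_confound_matrix(conf_dn, d, run = 1), "unique")
  # wrong length -> error
  expect_error(build_confound_matrix(conf[-1, ], d, run = 1), "rows")
})

test_that("confound regression is an exact orthogonal projection", {
  set.seed(42)
  n <- 120
  x <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n), trend = scale(1:n)[, 1])
  # series that is exactly a linear combination of the columns -> ~0 residual
  ts_lin <- x %*% matrix(rnorm(ncol(x) * 3), ncol(x), 3)
  res0 <- regress_confounds(ts_lin, x)
  expect_lt(max(abs(res0)), 1e-8 * max(abs(ts_lin)))

  # residual orthogonal to every column; variance never increases
  ts <- matrix(rnorm(n * 5), n, 5)
  res <- regress_confounds(ts, x)
  dots <- crossprod(x, res)
  norms <- outer(sqrt(colSums(x^2)), sqrt(colSums(res^2)))
  expect_lt(max(abs(dots) / norms), 1e-6)
  expect_true(all(colSums(res^2) <= colSums(scale(ts, scale = FALSE)^2) + 1e-8))

  expect_error(regress_confounds(ts, cbind(x, dup = x[, 2])), "rank")
})

test_that("band-pass filter attenuates out-of-band sinusoids and passes in-band", {
  tr <- 2
  t <- (0:511) * tr
  amp_ratio <- function(f) {
    s <- sin(2 * pi * f * t)
    out <- bandpass_filter(s, tr = tr)
    f_idx <- round(f * length(t) * tr) + 1
    sp_in <- abs(fft(s))[f_idx]
    sp_out <- abs(fft(out))[f_idx]
    sp_out / sp_in
  }
  expect_gt(amp_ratio(0.05), 0.9)   # pass band
  expect_lt(amp_ratio(0.05), 1.1)
  expect_lt(amp_ratio(0.2), 0.1)    # stop band, >= 20 dB down
  expect_lt(amp_ratio(0.005), 0.1)  # below the high-pass edge

  # constant input -> DC removed
  const <- rep(5, 512)
  expect_lt(mean(abs(bandpass_filter(const, tr = tr))), 1e-6 * 5)

  expect_error(bandpass_filter(const, tr = 2, high_hz = 0.3), "Nyquist")
  expect_error(bandpass_filter(const, tr = 2, low_hz = 0.2, high_hz = 0.1), "band edges")
})

test_that("denoised series carry no residual confound structure", {
  d <- reduced_design(n_runs = 1)
  subj <- simulate_subject(d, effect_spec(8), noise_spec(), seed = 13)
  den <- denoise_subject(subj, d)
  run <- den$runs[[1]]
  expect_equal(dim(run$bold), dim(subj$runs[[1]]$bold))
  expect_true(all(is.finite(run$bold)))

  # re-fitting the confound model on the denoised series explains almost no
  # variance, where on the raw series it explains a lot (individual joint-OLS
  # coefficients are not compared: trend, intercept and slow motion walks are
  # nearly collinear, which makes them unstable even at zero correlation)
  x <- unclass(build_confound_matrix(run$confounds, d, run = 1))
  rsq <- function(y) {
    yc <- scale(y, scale = FALSE)
    1 - colSums(qr.resid(qr(x), yc)^2) / colSums(yc^2)
  }
  expect_lt(max(rsq(run$bold)), 0.10)
  expect_gt(min(rsq(subj$runs[[1]]$bold)), 0.30)
})
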