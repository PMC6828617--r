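# Shared desk-scale fixtures, built in code.

# single-stimulus-type reduced design: 3 emotions x 2 repetitions per run
reduced_design <- function(n_runs = 2, seed = 3) {
  make_design(n_runs = n_runs, conditions = c("anger", "fear", "joy"),
              stimulus_types = "face", repetitions = 2, seed = seed)
}

# small null cohort -> feature array (cached per session; several tests share it)
null_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- reduced_design()
      coh <- simulate_cohort(8, d, effect_spec(24), noise_spec(), seed = 5)
      cache <<- feature_array(coh, d)
    }
    cache
  }
})

# null cohort at calibration scale (12 subjects x 60 ROIs), shared by the
# 3-class and 2-class permutation-null checks
calibration_null_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_design(n_runs = 2, conditions = c("anger", "fear", "joy"),
                       stimulus_types = "face", repetitions = 2,
                       seed = derive_seed(101, 1))
      coh <- simulate_cohort(12, d, effect_spec(60, seed = derive_seed(101, 2)),
                             noise_spec(), seed = derive_seed(101, 3))
      cache <<- feature_array(coh, d)
    }
    cache
  }
})

# direct feature-array construction (no simulation): gaussian edges with an
# optional per-class mean shift on chosen edges
toy_features <- function(n_subjects, classes, n_edges, shift = list(),
                         base_mean = 0.4, sd = 0.1, seed = 1) {
  ids <- sprintf("sub-%02d", seq_len(n_subjects))
  arr <- withr::with_seed(seed, array(
    rnorm(n_subjects * length(classes) * n_edges, base_mean, sd),
    dim = c(n_subjects, length(classes), n_edges),
    dimnames = list(ids, classes, NULL)))
  for (cl in names(shift)) {
    sp <- shift[[cl]]
    arr[, cl, sp$edges] <- arr[, cl, sp$edges] + sp$by
  }
  arr
}
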