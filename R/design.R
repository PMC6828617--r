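#' Build a pseudo-randomised block design
#'
#' Constructs a multi-run block design in which every run presents each
#' condition x stimulus-type cell `repetitions` times, in a pseudo-random
#' order such that the same condition never appears in two consecutive
#' blocks, and (when more than one stimulus type is used) neither does the
#' same stimulus type. Each block consists of `n_trials` trials of
#' `trial_dur_s + isi_s` seconds, is preceded by a fixation interval and
#' followed by a short response (button-task) interval.
#'
#' Orders are drawn by rejection sampling with a bounded number of retries;
#' an unsatisfiable constraint set raises an error. With a single stimulus
#' type the type constraint is vacuous (one level cannot alternate) and only
#' the condition constraint is enforced.
#'
#' @param n_runs number of runs.
#' @param conditions character vector of condition labels (>= 2).
#' @param stimulus_types character vector of stimulus-type labels.
#' @param repetitions blocks per condition x type cell per run.
#' @param tr repetition time in seconds.
#' @param n_trials trials per block.
#' @param trial_dur_s,isi_s trial stimulus duration and inter-stimulus
#'   interval, seconds.
#' @param fixation_s fixation interval before every block, seconds.
#' @param post_block_task_s response interval after every block, seconds.
#' @param seed integer seed; the design is deterministic given the seed.
#' @param max_tries retry bound for the ordering constraint.
#' @return an object of class `block_design`: a list with `tr`,
#'   `fixation_s`, `n_scans_per_run`, `conditions`, `stimulus_types` and
#'   `runs` (one data frame of blocks per run with columns `condition`,
#'   `stimulus_type`, `condition_label`, `onset_s`, `n_trials`,
#'   `trial_dur_s`, `isi_s`, `post_block_task_s`). `condition_label` is the
#'   condition name for single-type designs and `"condition:type"`
#'   otherwise; it is the label carried through denoising, connectivity and
#'   decoding.
#' @export
make_design <- function(n_runs = 3,
                        conditions = c("anger", "fear", "joy"),
                        stimulus_types = c("face", "body", "person"),
                        repetitions = 2,
                        tr = 2,
                        n_trials = 8,
                        trial_dur_s = 2,
                        isi_s = 0.5,
                        fixation_s = 10,
                        post_block_task_s = 2,
                        seed = 1,
                        max_tries = 2000) {
  if (length(conditions) < 2)
    stop("at least 2 conditions are required", call. = FALSE)
  if (anyDuplicated(conditions) || anyDuplicated(stimulus_types))
    stop("condition and stimulus-type labels must be unique", call. = FALSE)
  if (repetitions < 1) stop("`repetitions` must be >= 1", call. = FALSE)
  .assert_scalar_num(tr, "tr", positive = TRUE)

  grid <- expand.grid(condition = conditions, stimulus_type = stimulus_types,
                      rep = seq_len(repetitions), stringsAsFactors = FALSE)
  n_blocks <- nrow(grid)
  check_types <- length(stimulus_types) > 1L

  compatible <- function(prev, nxt) {
    if (grid$condition[prev] == grid$condition[nxt]) return(FALSE)
    if (check_types && grid$stimulus_type[prev] == grid$stimulus_type[nxt])
      return(FALSE)
    TRUE
  }

  ## randomised depth-first search with a node budget; exhausting the search
  ## on small instances proves unsatisfiability
  draw_order <- function(budget = 20000L) {
    nodes <- 0L
    recurse <- function(seq_idx, remaining) {
      if (!length(remaining)) return(seq_idx)
      nodes <<- nodes + 1L
      if (nodes > budget) stop("budget")
      cand <- if (length(remaining) > 1) sample(remaining) else remaining
      for (nx in cand) {
        if (length(seq_idx) && !compatible(seq_idx[length(seq_idx)], nx)) next
        res <- recurse(c(seq_idx, nx), setdiff(remaining, nx))
        if (!is.null(res)) return(res)
      }
      NULL
    }
    recurse(integer(0), seq_len(n_blocks))
  }

  block_span <- n_trials * (trial_dur_s + isi_s)
  multi_type <- length(stimulus_types) > 1L

  runs <- withr::with_seed(seed, lapply(seq_len(n_runs), function(r) {
    idx <- tryCatch(draw_order(budget = as.integer(max_tries) * 10L),
                    error = function(e) NULL)
    if (is.null(idx))
      stop("could not find a block order satisfying the ",
           "no-consecutive-repeat constraint; the requested ",
           "condition/type/repetition counts are unsatisfiable ",
           "(or the search budget was exhausted)", call. = FALSE)
    onsets <- fixation_s +
      (seq_len(n_blocks) - 1) * (block_span + post_block_task_s + fixation_s)
    data.frame(
      condition = grid$condition[idx],
      stimulus_type = grid$stimulus_type[idx],
      condition_label = if (multi_type)
        paste(grid$condition[idx], grid$stimulus_type[idx], sep = ":")
      else grid$condition[idx],
      onset_s = onsets,
      n_trials = n_trials,
      trial_dur_s = trial_dur_s,
      isi_s = isi_s,
      post_block_task_s = post_block_task_s,
      stringsAsFactors = FALSE
    )
  }))

  run_end <- fixation_s + n_blocks * (block_span + post_block_task_s + fixation_s)
  design <- structure(list(
    tr = tr,
    fixation_s = fixation_s,
    n_scans_per_run = as.integer(ceiling(run_end / tr)),
    conditions = sort(conditions),
    stimulus_types = stimulus_types,
    runs = runs
  ), class = "block_design")
  stopifnot(all(vapply(runs, function(b)
    all(b$onset_s + block_span <= design$n_scans_per_run * tr), logical(1))))
  design
}

#' Condition labels of a design
#'
#' Distinct `condition_label` values of the blocks, sorted; these are the
#' labels of the task regressors and of the per-condition connectivity maps.
#'
#' @param design a `block_design`.
#' @return sorted character vector.
#' @export
condition_labels <- function(design) {
  sort(unique(unlist(lapply(design$runs, function(b) b$condition_label))))
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf(
    "<block_design> %d run(s), %d blocks/run, TR = %gs, %d scans/run\n",
    length(x$runs), nrow(x$runs[[1]]), x$tr, x$n_scans_per_run))
  cat("  conditions: ", paste(condition_labels(x), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

## stimulus span of a block in seconds
.block_span <- function(blocks) blocks$n_trials * (blocks$trial_dur_s + blocks$isi_s)
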