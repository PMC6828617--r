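#' Random positive-definite base correlation matrix
#'
#' Builds a correlation matrix from a low-rank factor model with positive
#' loadings, `R = cov2cor(W W' + I)`. All off-diagonal correlations are
#' positive (typical of mean ROI BOLD series), moderately heterogeneous, and
#' the matrix is positive-definite by construction.
#'
#' @param n_rois number of ROIs.
#' @param n_factors number of latent factors.
#' @param loading_range range of the uniform positive loadings.
#' @param seed integer seed.
#' @return `n_rois` x `n_rois` correlation matrix.
#' @export
make_base_covariance <- function(n_rois, n_factors = 2,
                                 loading_range = c(0.4, 0.7), seed = 1) {
  stopifnot(n_rois >= 2)
  withr::with_seed(seed, {
    w <- matrix(stats::runif(n_rois * n_factors, loading_range[1], loading_range[2]),
                n_rois, n_factors)
    stats::cov2cor(tcrossprod(w) + diag(n_rois))
  })
}

#' Ground-truth effect specification for the generator
#'
#' Holds the base ROI covariance (a correlation matrix), per-condition
#' correlation increments on named edges, and per-condition activation
#' amplitudes. The perturbed per-condition matrices must remain
#' positive-definite; with `repair = TRUE` (default) a non-PD perturbation
#' is shrunk back toward the base matrix until PD, with a message.
#'
#' @param n_rois number of ROIs.
#' @param base_covariance symmetric positive-definite base matrix; default
#'   [make_base_covariance()].
#' @param condition_deltas named list, one entry per condition, each a data
#'   frame with columns `i`, `j` (ROI indices, `i > j`) and `delta`
#'   (correlation increment).
#' @param activation_amplitudes named list, one numeric scalar or length-
#'   `n_rois` vector per condition: gain of the HRF-convolved boxcar added
#'   to the ROI signal during that condition.
#' @param repair shrink non-PD perturbed matrices toward the base (default)
#'   instead of leaving them for [simulate_subject()] to reject.
#' @param seed seed for the default base covariance.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(n_rois,
                        base_covariance = NULL,
                        condition_deltas = list(),
                        activation_amplitudes = list(),
                        repair = TRUE,
                        seed = 1) {
  base <- base_covariance %||% make_base_covariance(n_rois, seed = seed)
  stopifnot(nrow(base) == n_rois, ncol(base) == n_rois)
  if (max(abs(base - t(base))) > 1e-10)
    stop("`base_covariance` must be symmetric", call. = FALSE)
  if (min(eigen(base, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("`base_covariance` must be positive-definite", call. = FALSE)

  cond_cov <- list()
  for (cond in names(condition_deltas)) {
    d <- condition_deltas[[cond]]
    stopifnot(all(c("i", "j", "delta") %in% names(d)))
    if (any(d$i <= d$j) || any(d$j < 1) || any(d$i > n_rois))
      stop("delta edges must reference valid ROI indices with i > j",
           call. = FALSE)
    r <- base
    for (k in seq_len(nrow(d))) {
      v <- max(min(r[d$i[k], d$j[k]] + d$delta[k], 0.99), -0.99)
      r[d$i[k], d$j[k]] <- v
      r[d$j[k], d$i[k]] <- v
    }
    if (repair) {
      s <- 1
      while (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8 &&
             s > 1e-3) {
        s <- s * 0.8
        r <- base + s * (r - base)
      }
      if (s < 1)
        message(sprintf("condition '%s': delta shrunk by factor %.3f to keep the covariance positive-definite",
                        cond, s))
    }
    cond_cov[[cond]] <- r
  }

  structure(list(
    n_rois = n_rois,
    base_covariance = base,
    condition_deltas = condition_deltas,
    condition_cov = cond_cov,
    activation_amplitudes = activation_amplitudes
  ), class = "effect_spec")
}

#' Noise specification for the generator
#'
#' Scales of the nuisance processes added to the latent condition-dependent
#' signal: thermal (white) noise, six head-motion traces modelled as
#' Gaussian random walks (step scale chosen so that typical per-block
#' excursions are of order 0.1-0.3 mm / degrees), a per-ROI linear drift,
#' and a set of shared smooth physiological-like components with per-ROI
#' loadings (the stand-in for white-matter/CSF principal components).
#'
#' @param thermal_sd white-noise standard deviation.
#' @param motion_walk_sd random-walk step SD of the 6 motion traces.
#' @param motion_coupling_sd SD of the motion-to-ROI coupling coefficients.
#' @param drift_slope_range range (units/s) of the per-ROI linear trend slope.
#' @param n_nuisance_components number of shared nuisance components.
#' @param nuisance_ar AR(1) coefficient of the nuisance components.
#' @param nuisance_loading_sd SD of the per-ROI nuisance loadings.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(thermal_sd = 0.3,
                       motion_walk_sd = 0.02,
                       motion_coupling_sd = 0.2,
                       drift_slope_range = c(-0.01, 0.01),
                       n_nuisance_components = 5,
                       nuisance_ar = 0.9,
                       nuisance_loading_sd = 0.3) {
  sc <- c(thermal_sd, motion_walk_sd, motion_coupling_sd, nuisance_loading_sd)
  if (any(sc < 0)) stop("all noise scales must be >= 0", call. = FALSE)
  stopifnot(n_nuisance_components >= 0, length(drift_slope_range) == 2)
  structure(list(
    thermal_sd = thermal_sd,
    motion_walk_sd = motion_walk_sd,
    motion_coupling_sd = motion_coupling_sd,
    drift_slope_range = drift_slope_range,
    n_nuisance_components = as.integer(n_nuisance_components),
    nuisance_ar = nuisance_ar,
    nuisance_loading_sd = nuisance_loading_sd
  ), class = "noise_spec")
}

.condition_cov <- function(effect, cond) {
  effect$condition_cov[[cond]] %||% effect$base_covariance
}

.activation <- function(effect, cond) {
  a <- effect$activation_amplitudes[[cond]]
  if (is.null(a)) return(rep(0, effect$n_rois))
  if (length(a) == 1L) rep(a, effect$n_rois) else a
}

#' Simulate one subject's block-design ROI BOLD data
#'
#' Per scan, the latent ROI signal is drawn from a multivariate normal whose
#' covariance is the base matrix during rest and the condition-perturbed
#' matrix during scans dominated by that condition (the condition whose
#' HRF-convolved boxcar regressor is maximal and positive at the scan). On
#' top of the latent signal the generator adds HRF-convolved activation,
#' motion-coupled artifact, a linear drift, shared nuisance components and
#' white noise. The exact motion and nuisance traces used are returned as
#' the subject's confound matrix, so confound regression downstream can be
#' exact in expectation.
#'
#' @param design a `block_design`.
#' @param effect an `effect_spec` (ground truth).
#' @param noise a `noise_spec`.
#' @param subject_id subject identifier string.
#' @param seed integer seed; output is deterministic given the seed.
#' @return object of class `subject_data`: list with `subject_id` and
#'   `runs`, each run a list with `bold` (scans x ROIs matrix, columns
#'   `ROI001`, ...) and `confounds` (scans x m matrix with named columns:
#'   `mot_tx`..`mot_rz`, `comp1`..).
#' @export
simulate_subject <- function(design, effect, noise = noise_spec(),
                             subject_id = "sub-01", seed = 1) {
  stopifnot(inherits(design, "block_design"), inherits(effect, "effect_spec"))
  p <- effect$n_rois
  n <- design$n_scans_per_run
  labels <- condition_labels(design)

  ## pre-factor the per-state covariances; a non-PD perturbation is a
  ## ground-truth specification error and is reported with its condition
  chol_of <- list(.rest = chol(effect$base_covariance))
  for (cond in labels) {
    cv <- .condition_cov(effect, cond)
    ch <- tryCatch(chol(cv), error = function(e) NULL)
    if (is.null(ch))
      stop(sprintf("perturbed covariance for condition '%s' is not positive-definite",
                   cond), call. = FALSE)
    chol_of[[cond]] <- ch
  }

  roi_names <- sprintf("ROI%03d", seq_len(p))
  runs <- withr::with_seed(seed, lapply(seq_along(design$runs), function(r) {
    reg <- build_task_regressors(design, run = r)
    mx <- apply(reg, 1, max)
    state <- ifelse(mx > 1e-6, colnames(reg)[max.col(reg, ties.method = "first")],
                    ".rest")

    y <- matrix(0, n, p)
    z <- matrix(stats::rnorm(n * p), n, p)
    for (st in unique(state)) {
      rows <- which(state == st)
      y[rows, ] <- z[rows, , drop = FALSE] %*% chol_of[[st]]
    }
    for (cond in labels)
      y <- y + outer(reg[, cond], .activation(effect, cond))

    ## per-ROI linear drift
    slopes <- stats::runif(p, noise$drift_slope_range[1], noise$drift_slope_range[2])
    y <- y + outer((seq_len(n) - 1) * design$tr, slopes)

    ## motion random walks + coupling into the ROI signal
    mot <- apply(matrix(stats::rnorm(n * 6, sd = noise$motion_walk_sd), n, 6), 2, cumsum)
    colnames(mot) <- c("mot_tx", "mot_ty", "mot_tz", "mot_rx", "mot_ry", "mot_rz")
    coup <- matrix(stats::rnorm(6 * p, sd = noise$motion_coupling_sd), 6, p)
    y <- y + mot %*% coup

    ## shared smooth nuisance components with per-ROI loadings
    k <- noise$n_nuisance_components
    if (k > 0) {
      comp <- vapply(seq_len(k), function(i) {
        g <- as.numeric(stats::filter(stats::rnorm(n), noise$nuisance_ar,
                                      method = "recursive"))
        g / stats::sd(g)
      }, numeric(n))
      colnames(comp) <- paste0("comp", seq_len(k))
      load <- matrix(stats::rnorm(k * p, sd = noise$nuisance_loading_sd), k, p)
      y <- y + comp %*% load
    } else {
      comp <- matrix(numeric(0), n, 0)
    }

    if (noise$thermal_sd > 0)
      y <- y + matrix(stats::rnorm(n * p, sd = noise$thermal_sd), n, p)

    colnames(y) <- roi_names
    list(bold = y, confounds = cbind(mot, comp))
  }))

  structure(list(subject_id = subject_id, runs = runs), class = "subject_data")
}

#' Simulate a cohort of subjects
#'
#' Independent subjects generated from per-subject seeds derived from the
#' master seed; the whole cohort is reproducible bit-for-bit given
#' (`design`, `effect`, `noise`, `seed`).
#'
#' @param n_subjects number of subjects (>= 2; the downstream
#'   cross-validation needs at least two).
#' @param design,effect,noise as in [simulate_subject()].
#' @param seed master integer seed.
#' @param subject_effect_sd between-subject SD of a multiplicative factor on
#'   the condition deltas (default 0: every subject carries the identical
#'   effect).
#' @return list of `subject_data`, names = subject ids.
#' @export
simulate_cohort <- function(n_subjects = 20, design, effect,
                            noise = noise_spec(), seed = 1,
                            subject_effect_sd = 0) {
  if (n_subjects < 2)
    stop("`n_subjects` must be >= 2 (leave-one-subject-out cross-validation is impossible otherwise)",
         call. = FALSE)
  ids <- sprintf("sub-%02d", seq_len(n_subjects))
  cohort <- lapply(seq_len(n_subjects), function(i) {
    eff_i <- effect
    if (subject_effect_sd > 0 && length(effect$condition_deltas)) {
      fac <- withr::with_seed(derive_seed(seed, 10000 + i),
                              max(0, 1 + stats::rnorm(1, sd = subject_effect_sd)))
      deltas <- lapply(effect$condition_deltas, function(d) {
        d$delta <- d$delta * fac
        d
      })
      eff_i <- effect_spec(effect$n_rois, effect$base_covariance, deltas,
                           effect$activation_amplitudes, repair = TRUE)
    }
    simulate_subject(design, eff_i, noise, subject_id = ids[i],
                     seed = derive_seed(seed, i))
  })
  names(cohort) <- ids
  cohort
}
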