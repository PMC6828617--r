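`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic stream-splitting used wherever one master seed has to drive
#' several independent stochastic units (subjects of a cohort, replicate
#' datasets). Kept below 2^31 - 1 so the result is always a valid R integer
#' seed.
#'
#' @param master master integer seed.
#' @param i positive integer index of the child stream.
#' @return an integer seed.
#' @export
derive_seed <- function(master, i) {
  s <- (as.numeric(master) %% 2147483647) * 7919 + as.numeric(i) * 104729
  as.integer(s %% 2147483647) + 1L
}

## column variances with explicit centering (stable for the t statistics)
.colvars <- function(x) {
  n <- nrow(x)
  xc <- x - rep(colMeans(x), each = n)
  colSums(xc * xc) / (n - 1)
}

.assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}
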