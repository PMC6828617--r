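#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical HRF (difference of two gamma densities: response
#' peak around 5 s, delayed undershoot) at the scan repetition time. The
#' kernel is normalised to unit peak; its value at t = 0 is exactly zero.
#'
#' @param tr repetition time in seconds (> 0).
#' @param duration kernel support in seconds (>= `tr`); 32 s covers the
#'   response and undershoot at the default parameters.
#' @param peak_delay,undershoot_delay gamma delays in seconds (defaults 6, 16).
#' @param peak_disp,undershoot_disp gamma dispersions (defaults 1, 1).
#' @param ratio undershoot-to-peak amplitude ratio (default 1/6).
#' @return numeric kernel of length `ceiling(duration / tr)`, sampled at
#'   t = 0, tr, 2 tr, ...
#' @export
canonical_hrf <- function(tr, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, ratio = 1 / 6) {
  .assert_scalar_num(tr, "tr", positive = TRUE)
  .assert_scalar_num(duration, "duration")
  if (duration < tr) stop("`duration` must be at least one `tr`", call. = FALSE)
  t <- seq(0, by = tr, length.out = ceiling(duration / tr))
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                          scale = undershoot_disp)
  h / max(h)
}
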