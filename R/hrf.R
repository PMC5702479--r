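#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive lobe peaking at `peak`
#' seconds and an undershoot peaking at `undershoot` seconds, scaled by
#' `ratio`. Gamma shapes are chosen so the mode of each lobe falls exactly at
#' the requested latency (shape = latency + 1, rate = 1). The returned values
#' are normalized so the response maximum is 1.
#'
#' @param t numeric vector of times (seconds, >= 0).
#' @param peak latency of the response peak (seconds). Default 6.
#' @param undershoot latency of the undershoot peak (seconds). Default 16.
#' @param ratio relative amplitude of the undershoot. Default 1/6.
#' @return numeric vector of HRF values, max 1.
#' @examples
#' h <- hrf_double_gamma(seq(0, 32, 0.5))
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  stopifnot(is.numeric(t), all(is.finite(t)), peak > 0, undershoot > peak)
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h[t < 0] <- 0
  h / max(stats::dgamma(peak, shape = peak + 1, rate = 1))
}

#' Sampled HRF kernel on the TR grid
#'
#' @param tr sampling interval (seconds).
#' @param length_s kernel support (seconds). Default 32.
#' @inheritParams hrf_double_gamma
#' @return numeric vector, the HRF sampled at `seq(0, length_s, by = tr)`.
#' @export
hrf_kernel <- function(tr, length_s = 32, peak = 6, undershoot = 16,
                       ratio = 1 / 6) {
  stopifnot(tr > 0, length_s > tr)
  hrf_double_gamma(seq(0, length_s, by = tr), peak, undershoot, ratio)
}

# causal convolution of a regressor with a kernel, truncated to input length
.convolve_causal <- function(x, kernel) {
  n <- length(x)
  y <- stats::convolve(x, rev(kernel), type = "open")
  y[seq_len(n)]
}
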