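# Zero-phase Butterworth low-pass filtering.
#
# Coefficients come from signal::butter; the zero-phase application (odd
# reflection padding, forward pass, backward pass) is done here so that the
# padding scheme is explicit and stable for near-Nyquist cutoffs such as
# 20 Hz video data sampled at 50 Hz. Dual-pass filtering squares the
# magnitude response, so the effective attenuation of an order-2 design is
# that of an order-4 filter with no phase lag.

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a second-order (by default) Butterworth low-pass filter twice,
#' forward and backward, so the output has zero phase lag: peaks of the
#' filtered signal are not shifted in time. The signal is extended at both
#' ends by odd reflection before filtering to suppress edge transients.
#'
#' @param x numeric signal.
#' @param rate_hz sampling rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz; must be below the Nyquist rate.
#'   Cutoffs at or above 80% of Nyquist are allowed but trigger a warning.
#' @param order filter order of each pass (default 2).
#' @return filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1/500)
#' x <- sin(2 * pi * 5 * t) + 0.2 * sin(2 * pi * 150 * t)
#' y <- butter_lowpass(x, 500, 100)
#' @export
butter_lowpass <- function(x, rate_hz, cutoff_hz, order = 2L) {
  check_numeric_vector(x, "x", min_len = 2L)
  nyq <- rate_hz / 2
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0)
    stop_config("cutoff_hz must be positive (got %s)", format(cutoff_hz))
  if (cutoff_hz >= nyq)
    stop_config("cutoff %.3g Hz is at or above the Nyquist frequency %.3g Hz (rate %.3g Hz)",
                cutoff_hz, nyq, rate_hz)
  if (cutoff_hz / nyq >= 0.8)
    warning(sprintf("cutoff %.3g Hz is %.0f%% of Nyquist (%.3g Hz); attenuation in the passband edge will be mild",
                    cutoff_hz, 100 * cutoff_hz / nyq, nyq), call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  filtfilt_oddpad(bf$b, bf$a, as.numeric(x))
}

# Forward-backward IIR filtering with odd-reflection end padding (pad
# length 3 * filter length) and steady-state initial conditions, so a
# constant signal passes through exactly and step transients at the ends
# are suppressed.
filtfilt_oddpad <- function(b, a, x) {
  n <- length(x)
  padlen <- 3L * max(length(a), length(b))
  if (n <= padlen)
    stop_data("signal too short to filter: %d samples, need more than %d", n, padlen)
  head_ext <- 2 * x[1] - x[seq(padlen + 1, 2)]
  tail_ext <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  ext <- c(head_ext, x, tail_ext)
  one_pass <- function(z) {
    # initialize the filter at steady state for the first sample's level
    k <- max(length(a), length(b)) - 1L
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], k), init.y = rep(z[1], k)))
  }
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  y[(padlen + 1):(padlen + n)]
}
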