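#' Denoising filter configuration
#'
#' @param smooth_window Moving-average window in samples; odd, >= 1.
#' @param notch_freq Powerline notch centre frequency, Hz.
#' @param notch_q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @param highpass_cutoff Baseline-removal high-pass cutoff, Hz.
#' @param highpass_order Butterworth order of the high-pass.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(smooth_window = 5, notch_freq = 50, notch_q = 30,
                          highpass_cutoff = 0.5, highpass_order = 4) {
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be odd and >= 1")
  if (highpass_cutoff <= 0 || highpass_cutoff >= notch_freq)
    stop("need 0 < highpass_cutoff < notch_freq")
  structure(list(smooth_window = as.integer(smooth_window),
                 notch_freq = notch_freq, notch_q = notch_q,
                 highpass_cutoff = highpass_cutoff,
                 highpass_order = as.integer(highpass_order)),
            class = "filter_config")
}

# reflect-pad a signal by npad samples on each side
reflect_pad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  c(x[(npad + 1L):2L], x, x[(n - 1L):(n - npad)])
}

#' Moving-average smoothing
#'
#' Centred moving average of odd width; edges handled by reflection so the
#' output has the input's length.
#'
#' @param x Numeric signal.
#' @param window Odd window width in samples, <= `length(x)`.
#' @return Smoothed signal, same length as `x`.
#' @export
#' @examples
#' smooth_signal(c(0, 3, 0), 3)
smooth_signal <- function(x, window = 5) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  if (window > length(x)) stop("window larger than signal length")
  if (window == 1) return(x)
  k <- (window - 1L) %/% 2L
  xp <- reflect_pad(x, k)
  out <- stats::filter(xp, rep(1 / window, window), sides = 2)
  as.numeric(out[(k + 1L):(k + length(x))])
}

# RBJ biquad notch coefficients
notch_coeffs <- function(fs, freq, q) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# zero-phase filtering with reflect padding to suppress edge transients
zerophase <- function(b, a, x, npad) {
  xp <- reflect_pad(x, npad)
  y <- signal::filtfilt(b, a, xp)
  k <- min(npad, length(x) - 1L)
  y[(k + 1L):(k + length(x))]
}

#' Powerline notch filter
#'
#' Second-order IIR notch applied forward-backward (zero phase). Attenuation
#' at the notch frequency exceeds 20 dB; the passband is essentially flat.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param freq Notch centre frequency, Hz; must be below `fs / 2`.
#' @param q Quality factor.
#' @return Filtered signal, same length.
#' @export
notch_filter <- function(x, fs, freq = 50, q = 30) {
  if (freq >= fs / 2) stop("notch frequency must be below the Nyquist frequency")
  co <- notch_coeffs(fs, freq, q)
  zerophase(co$b, co$a, x, round(fs))
}

#' Baseline-removing high-pass filter
#'
#' Butterworth high-pass applied forward-backward (zero phase), so peak
#' positions do not shift and the DC component is removed.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz; `0 < cutoff < fs / 2`.
#' @param order Butterworth order.
#' @return Filtered signal, same length.
#' @export
highpass_filter <- function(x, fs, cutoff = 0.5, order = 4) {
  if (cutoff <= 0 || cutoff >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  bt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  zerophase(bt$b, bt$a, x, round(2 * fs))
}

#' Denoise every lead of an ECG record
#'
#' Applies, in order: moving-average smoothing, powerline notch, high-pass.
#'
#' @param record An `ecg_record`.
#' @param config A [filter_config()].
#' @return The record with filtered signals.
#' @export
preprocess_record <- function(record, config = filter_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "filter_config"))
  sig <- record$signals
  for (ld in seq_len(ncol(sig))) {
    x <- smooth_signal(sig[, ld], config$smooth_window)
    x <- notch_filter(x, record$fs, config$notch_freq, config$notch_q)
    x <- highpass_filter(x, record$fs, config$highpass_cutoff, config$highpass_order)
    sig[, ld] <- x
  }
  record$signals <- sig
  record
}
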