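#' STFT configuration for HRV band decomposition
#'
#' Defaults: the unevenly sampled RR series is interpolated onto a 4 Hz grid
#' and analysed with 5-s Hann windows sliding in 0.5-s steps (20-sample
#' windows, hop 2 at the default rate, i.e. overlap 0.9). The 5-s window
#' fixes the 0.2 Hz bin spacing that places a bin inside each analysis band;
#' the short stride gives roughly nine frames on a 10-s record, so symbol
#' sequences are long enough for sliding windows of length 2-4.
#'
#' @param resample_hz Uniform resampling rate of the RR series, Hz.
#' @param window_seconds STFT window length, seconds.
#' @param overlap_fraction Window overlap in `[0, 1)`.
#' @param window_shape Taper; `"hann"` or `"rect"`.
#' @return Object of class `stft_config`.
#' @export
stft_config <- function(resample_hz = 4, window_seconds = 5,
                        overlap_fraction = 0.9, window_shape = "hann") {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (window_seconds * resample_hz < 4)
    stop("window must span at least 4 samples")
  window_shape <- match.arg(window_shape, c("hann", "rect"))
  structure(list(resample_hz = resample_hz, window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction,
                 window_shape = window_shape),
            class = "stft_config")
}

#' Resample an RR series onto a uniform time grid
#'
#' The RR tachogram is an unevenly sampled series (interval `rr[i]` observed
#' at cumulative time `sum(rr[1:i])`); cubic interpolation onto a uniform
#' grid makes it amenable to the STFT. Output length is
#' `floor(total time span * resample_hz)`.
#'
#' @param rr Numeric RR intervals in seconds, length >= 4.
#' @param resample_hz Grid rate, Hz.
#' @return Numeric uniform series with attribute `fs = resample_hz`.
#' @export
resample_hrv <- function(rr, resample_hz = 4) {
  if (length(rr) < 4) stop("series too short for interpolation: need >= 4 intervals")
  t <- cumsum(rr)
  span <- t[length(t)] - t[1]
  m <- floor(span * resample_hz)
  if (m < 2) stop("series too short for interpolation: time span too small")
  grid <- t[1] + (seq_len(m) - 1) / resample_hz
  y <- spline(t, rr, xout = grid)$y
  structure(y, fs = resample_hz)
}

# short-time Fourier transform magnitudes: frames x bins, bin centres in Hz
stft_magnitudes <- function(x, fs, config) {
  nw <- round(config$window_seconds * fs)
  hop <- max(1L, round(nw * (1 - config$overlap_fraction)))
  if (length(x) < nw) stop("series shorter than one STFT window")
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  win <- if (config$window_shape == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  } else rep(1, nw)
  nb <- nw %/% 2L + 1L
  mags <- matrix(0, length(starts), nb)
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nw - 1L)] * win
    mags[k, ] <- Mod(fft(seg))[seq_len(nb)]
  }
  list(mag = mags, freqs = (0:(nb - 1)) * fs / nw,
       times = (starts - 1 + nw / 2) / fs)
}

# TRUE for bin centres belonging to band [low, high); 0.4 Hz closes HF2
band_mask <- function(freqs, band) {
  lo <- HHDR_BANDS[[band]][1]; hi <- HHDR_BANDS[[band]][2]
  if (band == "HF2") freqs >= lo & freqs <= hi + 1e-9 else freqs >= lo & freqs < hi
}

#' Decompose a uniform HRV series into LF/HF1/HF2 band magnitudes
#'
#' The series mean is removed first: band magnitudes describe heart-rate
#' *variability*, and without mean removal the (large) DC heart-rate level
#' leaks through the window taper into the low-frequency bins and swamps the
#' modulation structure. Per STFT frame and band, the magnitude is then the
#' sum of spectral magnitudes over frequency bins whose centre lies in the
#' band's range (LF 0-0.15, HF1 0.15-0.25, HF2 0.25-0.4 Hz; half-open
#' `[low, high)`, 0.4 Hz closing HF2). All three bands share the same frame
#' grid.
#'
#' @param x Uniform series from [resample_hrv()].
#' @param config An [stft_config()].
#' @param fs Sampling rate of `x`; defaults to its `fs` attribute.
#' @return Object of class `band_decomposition`: list with `bands` (named
#'   list of per-frame magnitude vectors), `times` (frame centres, s).
#' @export
band_decompose <- function(x, config = stft_config(), fs = attr(x, "fs")) {
  if (is.null(fs)) fs <- config$resample_hz
  x <- as.numeric(x)
  st <- stft_magnitudes(x - mean(x), fs, config)
  bands <- lapply(names(HHDR_BANDS), function(b) {
    m <- band_mask(st$freqs, b)
    if (!any(m)) rep(0, nrow(st$mag)) else rowSums(st$mag[, m, drop = FALSE])
  })
  names(bands) <- names(HHDR_BANDS)
  structure(list(bands = bands, times = st$times), class = "band_decomposition")
}

#' Quantize band magnitudes to the A-D alphabet
#'
#' Levels are quartiles of the series' own maximum `Amax`: A `[0, 0.25)`,
#' B `[0.25, 0.5)`, C `[0.5, 0.75)`, D `[0.75, 1]` in units of `Amax` (top
#' bin closed, so the maximum always maps to D). A flat zero series maps to
#' all A with a warning. Scaling the series by any positive constant leaves
#' the symbols unchanged.
#'
#' @param v Non-negative magnitude series.
#' @return Character string over `{A, B, C, D}`, one symbol per frame.
#' @export
#' @examples
#' quantize_magnitudes(c(0.3, 1, 0.6))  # "BDC"
quantize_magnitudes <- function(v) {
  if (length(v) == 0) stop("empty band series")
  amax <- max(abs(v))
  if (amax == 0) {
    warning("flat zero band series: quantized to all 'A'")
    return(paste(rep("A", length(v)), collapse = ""))
  }
  r <- abs(v) / amax
  sym <- ifelse(r >= 0.75, "D", ifelse(r >= 0.5, "C", ifelse(r >= 0.25, "B", "A")))
  paste(sym, collapse = "")
}

#' Sliding-window subsequences of a symbol sequence
#'
#' All contiguous substrings of each requested window length, stride 1, in
#' order; a sequence shorter than a window contributes none for that length.
#'
#' @param symbols Character string over `{A, B, C, D}`.
#' @param window_lengths Integer vector of window lengths (default 2:4).
#' @return Character vector (a multiset) of subsequences, window-2 items
#'   first, then window-3, etc.
#' @export
#' @examples
#' windowed_subsequences("ADC", 2)  # "AD" "DC"
windowed_subsequences <- function(symbols, window_lengths = 2:4) {
  n <- nchar(symbols)
  out <- character(0)
  for (w in window_lengths) {
    if (n < w) next
    out <- c(out, substring(symbols, 1:(n - w + 1), w:n))
  }
  out
}

#' Quantize every (lead, band) of an ECG record
#'
#' Full per-record chain: denoise, detect R-peaks per lead, extract the RR
#' series, resample, band-decompose, quantize. Leads whose RR series is too
#' short to analyse are skipped with a warning.
#'
#' @param record An `ecg_record` (raw; set `preprocessed = TRUE` if already
#'   filtered).
#' @param filter_cfg,rpeak_cfg,stft_cfg Stage configurations.
#' @param preprocessed Skip the denoising stage.
#' @return Data frame with columns `record_id`, `lead`, `band`, `symbols`.
#' @export
quantize_record <- function(record, filter_cfg = filter_config(),
                            rpeak_cfg = rpeak_config(),
                            stft_cfg = stft_config(), preprocessed = FALSE) {
  if (!preprocessed) record <- preprocess_record(record, filter_cfg)
  rows <- list()
  for (ld in seq_len(ncol(record$signals))) {
    peaks <- suppressWarnings(detect_rpeaks(record$signals[, ld], record$fs, rpeak_cfg))
    if (length(peaks) < 2) { warning(sprintf("lead %d: too few peaks, skipped", ld)); next }
    rr <- extract_hrv(peaks, record$fs, rpeak_cfg)
    ok <- try({
      u <- resample_hrv(rr, stft_cfg$resample_hz)
      bd <- band_decompose(u, stft_cfg)
    }, silent = TRUE)
    if (inherits(ok, "try-error")) {
      warning(sprintf("lead %d: RR series too short for spectral analysis, skipped", ld))
      next
    }
    for (b in names(bd$bands)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = record$record_id, lead = ld, band = b,
        symbols = suppressWarnings(quantize_magnitudes(bd$bands[[b]])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(record_id = character(0), lead = integer(0),
                      band = character(0), symbols = character(0)))
  do.call(rbind, rows)
}

#' Band power fractions of a uniform series (periodogram)
#'
#' Fraction of non-DC periodogram power falling into each of LF/HF1/HF2 (the
#' denominator includes all non-DC bins up to Nyquist). Used to verify band
#' placement of planted RR modulations.
#'
#' @param x Uniform series.
#' @param fs Sampling rate, Hz; defaults to the `fs` attribute.
#' @return Named numeric vector (LF, HF1, HF2) summing to at most 1.
#' @export
band_power_fractions <- function(x, fs = attr(x, "fs")) {
  if (is.null(fs)) stop("fs missing")
  x <- as.numeric(x)
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  nb <- n %/% 2L + 1L
  p <- p[seq_len(nb)]
  freqs <- (0:(nb - 1)) * fs / n
  tot <- sum(p[-1])
  if (tot == 0) return(c(LF = 0, HF1 = 0, HF2 = 0))
  out <- vapply(names(HHDR_BANDS), function(b) {
    m <- band_mask(freqs, b)
    m[1] <- FALSE  # exclude DC
    sum(p[m]) / tot
  }, numeric(1))
  out
}
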