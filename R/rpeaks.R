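#' R-peak detector configuration
#'
#' @param threshold_fraction Fraction of the signal range above the minimum
#'   used as the peak-gating threshold (default 0.6).
#' @param localmax_window Window in samples for the optional post-hoc snap of
#'   each accepted peak to the local argmax; `NULL` means `0.2 s * fs`,
#'   resolved at detection time.
#' @param merge_distance Refractory merge distance DMAX in samples: a
#'   candidate closer than this to the last accepted peak is discarded;
#'   `NULL` means `0.2 s * fs`.
#' @param rr_min,rr_max Physiological RR-interval bounds in seconds; intervals
#'   outside are dropped from the HRV series.
#' @param refine Apply the local-argmax snap after merging (default `TRUE`).
#' @return Object of class `rpeak_config`.
#' @export
rpeak_config <- function(threshold_fraction = 0.6, localmax_window = NULL,
                         merge_distance = NULL, rr_min = 0.3, rr_max = 2.0,
                         refine = TRUE) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  if (rr_min <= 0 || rr_min >= rr_max) stop("need 0 < rr_min < rr_max")
  structure(list(threshold_fraction = threshold_fraction,
                 localmax_window = localmax_window,
                 merge_distance = merge_distance,
                 rr_min = rr_min, rr_max = rr_max, refine = refine),
            class = "rpeak_config")
}

#' Adjacent-sample difference signal
#'
#' First difference `y[i] = x[i+1] - x[i]`. Exposed as a helper; the default
#' detector operates on the signal itself, not its difference.
#'
#' @param x Numeric signal.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
diff_signal <- function(x) diff(x)

#' Peak-gating threshold from the signal range
#'
#' `T = fraction * (VMAX - VMIN) + VMIN` where VMAX/VMIN are the signal's
#' extremes. A constant signal gives `T = VMAX` with attribute
#' `degenerate = TRUE`, so detection yields no peaks rather than all samples.
#'
#' @param x Numeric signal (non-empty).
#' @param fraction Range fraction, default 0.6.
#' @return Threshold value; attribute `degenerate` flags a zero-range signal.
#' @export
#' @examples
#' compute_threshold(c(0, 1))        # 0.6
#' compute_threshold(c(-1, 1))       # 0.2
compute_threshold <- function(x, fraction = 0.6) {
  if (length(x) == 0) stop("signal is empty")
  vmax <- max(x); vmin <- min(x)
  t <- fraction * (vmax - vmin) + vmin
  if (vmax == vmin) attr(t, "degenerate") <- TRUE
  t
}

#' Detect R-peaks by threshold, local maxima and refractory merge
#'
#' Candidates are strict local maxima (`x[i-1] < x[i] > x[i+1]`) above the
#' range-fraction threshold. Scanning candidates in order, a candidate is
#' accepted only when its distance to the last accepted peak exceeds the
#' merge distance DMAX (near-duplicate suppression). Accepted peaks are then
#' optionally snapped to the argmax of the signal within the local-max
#' window; plateau argmax ties resolve to the first index.
#'
#' @param x Numeric signal, length >= 3.
#' @param fs Sampling rate, Hz.
#' @param config An [rpeak_config()].
#' @return Strictly increasing integer vector of 1-based peak sample indices
#'   with attribute `fs`. Empty (with a warning) when no candidate clears the
#'   threshold.
#' @export
detect_rpeaks <- function(x, fs, config = rpeak_config()) {
  stopifnot(inherits(config, "rpeak_config"), length(x) >= 3)
  dmax <- config$merge_distance
  if (is.null(dmax)) dmax <- round(0.2 * fs)
  dmax <- as.integer(dmax)
  w <- config$localmax_window
  if (is.null(w)) w <- round(0.2 * fs)
  w <- as.integer(w)

  thr <- compute_threshold(x, config$threshold_fraction)
  if (isTRUE(attr(thr, "degenerate"))) {
    warning("constant signal: no R-peaks detected")
    return(structure(integer(0), fs = fs))
  }
  n <- length(x)
  i <- 2:(n - 1)
  cand <- i[x[i - 1] < x[i] & x[i] > x[i + 1] & x[i] > thr]
  if (length(cand) == 0) {
    warning("no R-peak candidates above threshold")
    return(structure(integer(0), fs = fs))
  }
  merged <- merge_peaks(cand, dmax)
  if (config$refine && length(merged) > 0) {
    half <- w %/% 2L
    merged <- vapply(merged, function(p) {
      lo <- max(1L, p - half); hi <- min(n, p + half)
      lo + which.max(x[lo:hi]) - 1L
    }, integer(1))
    merged <- merge_peaks(sort(unique(merged)), dmax)
  }
  structure(as.integer(merged), fs = fs)
}

# keep first candidate, then append only when gap to last kept exceeds dmax
merge_peaks <- function(cand, dmax) {
  if (length(cand) == 0) return(integer(0))
  kept <- cand[1]
  for (p in cand[-1]) if (p - kept[length(kept)] > dmax) kept <- c(kept, p)
  kept
}

#' RR-interval (HRV) series from detected peaks
#'
#' `rr[i] = (peaks[i+1] - peaks[i]) / fs`; intervals outside
#' `[rr_min, rr_max]` are removed as physiologically implausible.
#'
#' @param peaks Integer peak indices (>= 2), e.g. from [detect_rpeaks()].
#' @param fs Sampling rate, Hz; defaults to the `fs` attribute of `peaks`.
#' @param config An [rpeak_config()] providing the interval bounds.
#' @return Numeric vector of RR intervals in seconds.
#' @export
#' @examples
#' extract_hrv(c(100L, 600L, 1100L), fs = 500)
extract_hrv <- function(peaks, fs = attr(peaks, "fs"), config = rpeak_config()) {
  if (length(peaks) < 2) stop("insufficient peaks: need at least 2 to form an interval")
  if (is.null(fs)) stop("fs missing")
  rr <- diff(as.numeric(peaks)) / fs
  rr[rr >= config$rr_min & rr <= config$rr_max]
}

#' Standard deviation of RR intervals (SDNN)
#'
#' Classical time-domain HRV summary: sample standard deviation (n-1
#' denominator) of the RR series. Provided alongside, not instead of, the
#' interval list.
#'
#' @param rr Numeric RR intervals, length >= 2.
#' @return SDNN in seconds.
#' @export
sdnn <- function(rr) {
  if (length(rr) < 2) stop("need at least 2 intervals")
  sd(rr)
}
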