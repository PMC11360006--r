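#' Per-class RR-interval dynamics profiles
#'
#' Default generator profiles: one per diagnostic superclass, each a distinct
#' (mean RR, band modulation amplitude, band modulation frequency) tuple so
#' that classes occupy different regions of LF/HF1/HF2 band-power space.
#' These encode the autonomic signatures the pipeline is meant to pick up —
#' e.g. a sympathetically dominated class modulates LF strongly while its
#' high-frequency (vagal) bands carry little beyond measurement noise, and
#' the globally depressed-variability class modulates no band — but they are
#' a test harness, not a clinical claim.
#'
#' @return Named list (one entry per class in [HHDR_CLASSES]) of lists with
#'   fields `mean_rr` (s), `amp` (length-3 numeric, modulation amplitude in s
#'   for LF/HF1/HF2) and `freq` (length-3 numeric, modulation frequency in Hz,
#'   each inside its band's range).
#' @export
#' @examples
#' hhdr_rr_profiles()$NORM
hhdr_rr_profiles <- function() {
  list(
    NORM = list(mean_rr = 0.85, amp = c(0.030, 0.050, 0.040), freq = c(0.10, 0.20, 0.30)),
    MI   = list(mean_rr = 0.70, amp = c(0.080, 0.002, 0.002), freq = c(0.12, 0.20, 0.30)),
    STTC = list(mean_rr = 0.80, amp = c(0.002, 0.080, 0.002), freq = c(0.10, 0.22, 0.30)),
    CD   = list(mean_rr = 1.00, amp = c(0.002, 0.002, 0.080), freq = c(0.10, 0.20, 0.33)),
    HYP  = list(mean_rr = 0.60, amp = c(0.002, 0.002, 0.002), freq = c(0.10, 0.20, 0.30))
  )
}

#' Synthetic record configuration
#'
#' Bundles every knob of the synthetic 12-lead ECG generator. Defaults follow
#' the PTB-XL record layout (10-s, 500 Hz, 12 leads, European 50 Hz mains).
#'
#' @param class_label One of [HHDR_CLASSES]; selects the RR profile.
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz; `duration * fs` must be an integer >= 2.
#' @param n_leads Number of leads.
#' @param noise_sd Broadband white-noise standard deviation, mV.
#' @param baseline_amp,baseline_freq Baseline-wander sinusoid amplitude (mV)
#'   and frequency (Hz, must be < 0.5).
#' @param powerline_amp,powerline_freq Mains-interference sinusoid amplitude
#'   (mV) and frequency (Hz).
#' @param rr_profile RR dynamics profile (see [hhdr_rr_profiles()]); defaults
#'   to the profile of `class_label`.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(class_label = "NORM", duration = 10, fs = 500,
                             n_leads = 12, noise_sd = 0.02,
                             baseline_amp = 0.1, baseline_freq = 0.3,
                             powerline_amp = 0.05, powerline_freq = 50,
                             rr_profile = NULL, seed = 1L) {
  class_label <- match.arg(class_label, HHDR_CLASSES)
  if (is.null(rr_profile)) rr_profile <- hhdr_rr_profiles()[[class_label]]
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9 || round(n) < 2)
    stop("duration * fs must be an integer sample count >= 2")
  if (baseline_freq >= 0.5) stop("baseline_freq must be below 0.5 Hz")
  # worst-case RR with the per-lead amplitude jitter (<= 1.2x) must stay positive
  if (rr_profile$mean_rr - 1.2 * sum(abs(rr_profile$amp)) <= 0)
    stop(sprintf(
      "rr_profile yields non-positive RR intervals: mean_rr=%.3f, sum(|amp|)=%.3f",
      rr_profile$mean_rr, sum(abs(rr_profile$amp))))
  structure(list(
    class_label = class_label, duration = duration, fs = fs,
    n_leads = n_leads, noise_sd = noise_sd,
    baseline_amp = baseline_amp, baseline_freq = baseline_freq,
    powerline_amp = powerline_amp, powerline_freq = powerline_freq,
    rr_profile = rr_profile, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Gaussian bump added in place over a +/- 4 sd support
add_bump <- function(sig, center_s, amp, sd_s, fs) {
  n <- length(sig)
  i0 <- max(1L, floor((center_s - 4 * sd_s) * fs) + 1L)
  i1 <- min(n, ceiling((center_s + 4 * sd_s) * fs) + 1L)
  if (i0 > i1) return(sig)
  idx <- i0:i1
  t <- (idx - 1) / fs
  sig[idx] <- sig[idx] + amp * exp(-0.5 * ((t - center_s) / sd_s)^2)
  sig
}

#' Generate one synthetic 12-lead ECG record with ground truth
#'
#' Beat times per lead follow `RR(t) = mean_rr + sum_b amp_b sin(2 pi f_b t
#' + phi_b)` with a band-specific frequency inside each of LF/HF1/HF2 and a
#' uniform random phase per (lead, band), so the 12 leads are distinct
#' realisations of the same class dynamics. Each beat is a 1 mV Gaussian QRS
#' bump (sd 10 ms) flanked by smaller P (0.12 mV) and T (0.25 mV) bumps; the
#' per-lead QRS amplitude scale varies in \[0.6, 1.4\]. Baseline wander,
#' powerline interference and white noise are added on top. Output is
#' bit-identical for identical configs.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `record` (an `ecg_record`: `record_id`,
#'   `signals` sample-by-lead matrix in mV, `fs`, `label`) and `truth` (a
#'   `ground_truth`: per-lead `true_peak_samples` 1-based indices, per-lead
#'   `true_rr` in seconds, `class_label`). A beat whose QRS apex falls
#'   within 50 ms of the record end is rendered (truncated) but excluded
#'   from the truth lists, since the boundary clips its maximum.
#' @export
#' @examples
#' rec <- generate_record(synthetic_config("NORM", seed = 7))
#' dim(rec$record$signals)
generate_record <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- round(config$duration * config$fs)
  fs <- config$fs
  prof <- config$rr_profile
  set.seed(config$seed)
  qrs_scale <- runif(config$n_leads, 0.6, 1.4)
  amp_scale <- runif(config$n_leads, 0.8, 1.2)
  phases <- matrix(runif(config$n_leads * 3, 0, 2 * pi), ncol = 3)
  base_phase <- runif(1, 0, 2 * pi)
  pl_phase <- runif(1, 0, 2 * pi)
  tt <- (seq_len(n) - 1) / fs

  signals <- matrix(0, n, config$n_leads)
  true_peaks <- vector("list", config$n_leads)
  true_rr <- vector("list", config$n_leads)

  for (ld in seq_len(config$n_leads)) {
    beats <- numeric(0)
    t <- prof$mean_rr / 2
    while (t < config$duration) {
      beats <- c(beats, t)
      rr <- prof$mean_rr + sum(amp_scale[ld] * prof$amp *
                                 sin(2 * pi * prof$freq * t + phases[ld, ]))
      if (rr <= 0)
        stop(sprintf(
          "non-positive RR realisation (%.4f s) at t=%.2f s: mean_rr=%.3f, amp=[%s]",
          rr, t, prof$mean_rr, paste(format(prof$amp), collapse = ", ")))
      t <- t + rr
    }
    sig <- numeric(n)
    for (b in beats) {
      sig <- add_bump(sig, b, 1.00 * qrs_scale[ld], 0.010, fs)          # QRS
      sig <- add_bump(sig, b - 0.20, 0.12 * qrs_scale[ld], 0.025, fs)   # P
      sig <- add_bump(sig, b + 0.28, 0.25 * qrs_scale[ld], 0.045, fs)   # T
    }
    sig <- sig +
      config$baseline_amp * sin(2 * pi * config$baseline_freq * tt + base_phase) +
      config$powerline_amp * sin(2 * pi * config$powerline_freq * tt + pl_phase)
    if (config$noise_sd > 0) sig <- sig + rnorm(n, 0, config$noise_sd)
    signals[, ld] <- sig
    # a final beat whose QRS apex falls within 50 ms of the record end is
    # truncated by the boundary (and smeared into it by any edge-padded
    # filter); it stays in the waveform but is not listed as planted truth
    kept <- beats[round(beats * fs) + 1L <= n - ceiling(0.05 * fs)]
    true_peaks[[ld]] <- as.integer(round(kept * fs) + 1L)
    true_rr[[ld]] <- diff(kept)
  }

  record <- structure(list(
    record_id = sprintf("sim_%s_%d", config$class_label, config$seed),
    signals = signals, fs = fs, label = config$class_label
  ), class = "ecg_record")
  truth <- structure(list(
    true_peak_samples = true_peaks, true_rr = true_rr,
    class_label = config$class_label
  ), class = "ground_truth")
  list(record = record, truth = truth)
}

#' Generate a balanced labelled synthetic dataset
#'
#' `n_per_class` records per superclass; per-record seeds are drawn
#' reproducibly from the master seed, so equal seeds give identical datasets.
#'
#' @param n_per_class Records per class (>= 1).
#' @param seed Master integer seed.
#' @param ... Further arguments passed to [synthetic_config()] (all but
#'   `class_label` and `seed`).
#' @return List with `records` (list of `ecg_record`), `labels` (character),
#'   `truths` (list of `ground_truth`).
#' @export
generate_dataset <- function(n_per_class, seed = 1L, ...) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  n_total <- 5L * n_per_class
  seeds <- sample.int(.Machine$integer.max, n_total)
  labels <- rep(HHDR_CLASSES, each = n_per_class)
  records <- vector("list", n_total)
  truths <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cfg <- synthetic_config(class_label = labels[i], seed = seeds[i], ...)
    out <- generate_record(cfg)
    out$record$record_id <- sprintf("sim_%s_%03d", labels[i], i)
    records[[i]] <- out$record
    truths[[i]] <- out$truth
  }
  list(records = records, labels = labels, truths = truths)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d leads x %d samples @ %g Hz, label=%s>\n",
              x$record_id, ncol(x$signals), nrow(x$signals), x$fs,
              if (is.null(x$label)) "<none>" else x$label))
  invisible(x)
}
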