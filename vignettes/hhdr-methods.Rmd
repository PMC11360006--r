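---
title: "Recognising heart disease from HRV rule features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising heart disease from HRV rule features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Heart rate variability (HRV) — the beat-to-beat variation of RR intervals —
reflects autonomic regulation of the heart and differs systematically across
cardiac disease classes. `hhdr` implements a full recognition pipeline from
raw 12-lead ECG waveforms to a five-way diagnostic superclass decision
(NORM, MI, STTC, CD, HYP), or a binary normal/disease decision:

1. **Denoising.** Each lead is smoothed with a centred moving average
   (high-frequency noise), passed through a powerline notch (mains
   interference), then a zero-phase Butterworth high-pass (baseline wander).
   The order is fixed: smooth, notch, high-pass.
2. **R-peak detection.** A gating threshold `T = 0.6 (VMAX - VMIN) + VMIN`
   is computed from the lead's range; strict local maxima above `T` are
   candidates; candidates within a refractory distance DMAX of the last
   accepted peak are discarded; accepted peaks are snapped to the local
   argmax within a short window. The RR (HRV) series is the sequence of
   peak-to-peak gaps in seconds, with intervals outside `[rr_min, rr_max]`
   removed as artefactual.
3. **Band decomposition and quantization.** The unevenly sampled RR series
   is cubic-interpolated onto a uniform 4 Hz grid, mean-removed, and
   analysed by short-time Fourier transform. Per frame, spectral magnitude
   is summed over the bins of three bands — LF 0–0.15 Hz, HF1 0.15–0.25 Hz,
   HF2 0.25–0.4 Hz — and each band's frame series is quantized against its
   own maximum into the four-letter alphabet A (< 25% of the maximum), B, C,
   D (>= 75%, the maximum itself always D).
4. **Rule mining.** Each lead's per-band symbol string is a *sequence
   segment*; its sliding-window substrings of length 2–4 are the items of
   one transaction. Per (class, band), FP-growth mines exact frequent
   itemsets; association rules `X -> Z` keep
   `confidence = support(X u Z) / support(X) >= 0.6`; *potential rules*
   link adjacent leads: when an itemset's conditional co-occurrence between
   lead k and lead k+1 reaches 0.5, a prefix–suffix rule is added with
   support = prefix support x correlation. Rules whose item content appears
   in two or more classes are deleted from all of them, leaving per-class
   libraries pairwise disjoint.
5. **SMQ features.** Per band, a record's pooled subsequence occurrences are
   matched against the combined deduplicated library; a rule is *active*
   when its full item content is contained in the record's subsequence set,
   and every occurrence of an item of an active rule counts one match. Seven
   statistics per band — match count MR, total support TS, total confidence
   TC, match frequency FR = MR/LE, support median SQ, support skewness SS,
   support kurtosis SK — give 21 base features. A one-vs-rest random forest
   per class ranks the 21 features by impurity importance; the top three,
   importance-weighted, form one combined feature per class (5 more).
6. **Classification.** A 100-tree random forest on the 26 features, trained
   on a stratified 4:1 split and evaluated on the held-out fifth.

## The synthetic generator

Real clinical 12-lead corpora cannot ship with a package, so `hhdr`
includes a generator that plants the ground truth every stage needs:
beat times follow

    RR(t) = mean_rr + sum_b amp_b * sin(2 pi f_b t + phi_(lead,b))

with one modulation per band, each lead drawing its own phases and a mild
amplitude jitter so the 12 sequence segments are distinct realisations of
the same dynamics. Each beat is a 1 mV Gaussian QRS bump (sd 10 ms) with
smaller P and T bumps; baseline wander (0.1 mV at 0.3 Hz), powerline
interference (0.05 mV at 50 Hz) and white noise (0.02 mV) are added. The
defaults follow the PTB-XL record layout: 10 s, 500 Hz, 12 leads, European
50 Hz mains.

The five class profiles are distinct (mean RR, band amplitude, band
frequency) tuples — e.g. the MI profile modulates LF strongly (0.08 s at
0.12 Hz) with only noise-level amplitude (2 ms) in the high-frequency
bands, the STTC profile concentrates in HF1, CD in HF2, NORM modulates all
three moderately, and HYP modulates none (globally depressed variability)
with the shortest mean RR. They are caricatures of autonomic signatures
chosen to exercise the pipeline, not clinical claims: passing tests show
the pipeline recovers planted band structure, not that it diagnoses real
patients. Real ECGs differ in ways the generator does not emulate:
morphology pathology (ST shifts, bundle-branch QRS widening), ectopic
beats, non-stationary modulation, electrode artefacts, multi-label
diagnoses.

## Numerical and design choices

* **Filter parameters.** Smoothing window 5 samples; notch 50 Hz with Q = 30
  (RBJ biquad, applied forward–backward); Butterworth order 4, cutoff
  0.5 Hz, zero phase so peak positions do not shift. Edges are
  reflect-padded, so lengths are preserved. These are conventional ECG
  choices; all are exposed in `filter_config()`.
* **Detector.** Threshold fraction 0.6 of the range; DMAX and the argmax
  snap window both default to 0.2 s (a refractory period); `rr_min` 0.3 s
  and `rr_max` 2.0 s bound plausible human RR intervals. The merge rule
  *appends a candidate only when its gap to the last accepted peak exceeds
  DMAX*; plateau argmax ties resolve to the first index. A constant lead
  yields a degenerate threshold and an empty peak list rather than
  all-samples. The adjacent-sample difference signal is exposed as
  `diff_signal()` but unused by the default detector.
* **STFT.** 4 Hz resampling; 5-s Hann window — the shortest window whose
  0.2 Hz bin spacing places a bin inside each band — sliding in 0.5-s
  steps. On a 10-s record that gives roughly nine frames per segment, so
  sliding windows of length 2–4 all produce subsequences; with a coarser
  stride (e.g. half-window hops) segments shrink to two symbols and
  window lengths 3–4 can never match anything, which degenerates the whole
  mining stage. The series mean is removed before the transform: band
  magnitudes describe variability, and the large DC heart-rate level would
  otherwise leak through the taper into the LF/HF1 bins and saturate the
  quantizer. Note the 5-s window cannot sharply isolate tones near band
  edges (the edges are closer together than the resolution); this does not
  matter downstream because quantization is normalized per band, but tests
  of band selection use a longer window.
* **Quantization boundaries.** Half-open level bins with the top bin
  closed: 0 maps to A, the band maximum to D. Scaling a band series by any
  positive constant leaves its symbols unchanged. A flat zero band
  quantizes to all A with a warning.
* **Mining thresholds.** min_support 0.2, min_confidence 0.6,
  corr_threshold 0.5 — unreported in the method's source, exposed in
  `mining_config()`. Itemsets are capped at 3 items: dense segments (long
  single-symbol runs) make most subsets of their items frequent, so
  unbounded mining grows exponentially while adding only redundant large
  itemsets; matching consumes small item sets.
* **Potential rules.** The adjacent-segment correlation of itemset X is
  `#records with X in leads k and k+1 / #records with X in lead k`; leads
  are taken in the record's fixed order, and one rule per itemset is kept
  at the maximum correlation over the eleven adjacent pairs. The
  correlation notion is defined only narratively in the method's source;
  this conditional co-occurrence reading is an interpretation.
* **Dedup identity.** Rules are compared by (band, antecedent, consequent)
  item content only; supports and confidences differ across classes and
  must not prevent the removal of common rules. Deduplication runs after
  potential-rule generation.
* **Matching.** Features are matched against the combined all-class library
  (the 21 features are band-indexed, not class-indexed; class information
  enters through the classifier). Degenerate statistics (fewer than 3–4
  matches, or zero spread) return 0 rather than propagating NaN into the
  forest. An empty library yields an all-zero accumulator with a warning.
* **Split and leakage.** The rule library and the impact factors are fitted
  on the training fold only; mining them on all records would leak test
  labels into the features. The binary task collapses {MI, STTC, CD, HYP}
  to "disease" at the classifier only — mining and combined features always
  use the five superclasses.
* **Final feature set.** The forest consumes all 21 base features plus the
  5 combined ones by default; `forest_config(feature_set = "top")` selects
  the narrative variant (union of per-class top-3 plus the 5 combined).
* **Indexing.** Sample indices are 1-based (R convention); times and
  intervals are in seconds.

## Problem sizes and what the tests show

The test suite validates each stage against independent oracles
(brute-force local-maximum scans, exhaustive itemset enumeration,
naive-loop moment formulas) at small sizes, and the end-to-end property on
simulated cohorts of 40 records per class: across three seeds the held-out
five-class accuracy exceeds 0.60 (chance 0.20) and binary accuracy exceeds
0.85, while label permutation collapses both to their chance bands. For the
binary task the 1:4 NORM:disease prior puts a feature-blind classifier
between 0.68 (proportional guessing) and 0.80 (majority vote); the
permutation control is judged against that band, not 0.5. Band-placement
checks use 60-s single-band records, where the periodogram can resolve the
0.1-Hz-wide bands.

These numbers quantify recovery of planted structure under the generator's
assumptions. They say nothing about accuracy on clinical data, which
depends on morphology, artefacts and label noise the generator does not
model.

## Known limitations

* 10-s records carry few beats; HRV spectral estimates at this length are
  noisy, and the LF band in particular is barely resolved. The method
  compensates by pooling 12 leads, as short-record HRV work typically does.
* The detector is a threshold/local-maximum scheme; it is validated on the
  generator's morphology and moderate noise, not on pathological QRS
  shapes.
* Deduplication can empty a class's library when class dynamics are too
  similar; the features of such a class degrade to zeros (a warning is
  raised).
* Multi-label records are out of scope: one superclass per record.
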