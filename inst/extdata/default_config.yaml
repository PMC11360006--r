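# Default pipeline configuration: runs the full synthetic pipeline unedited.
filters:
  smooth_window: 5
  notch_freq: 50
  notch_q: 30
  highpass_cutoff: 0.5
  highpass_order: 4
rpeak:
  threshold_fraction: 0.6
  rr_min: 0.3
  rr_max: 2.0
stft:
  resample_hz: 4
  window_seconds: 5
  overlap_fraction: 0.9
  window_shape: hann
mining:
  min_support: 0.2
  min_confidence: 0.6
  corr_threshold: 0.5
  max_itemset_size: 3
forest:
  ntree: 100
  feature_set: full
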