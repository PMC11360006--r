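Package: hhdr
Title: Heart Disease Recognition from Heart Rate Variability Rule Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for recognising cardiac disease classes from
    12-lead electrocardiogram (ECG) records via heart rate variability (HRV).
    Raw ECG leads are denoised (moving-average smoothing, powerline notch,
    baseline high-pass), R-peaks are detected with a range-fraction threshold
    plus local-maximum and refractory-merge rules, and the RR-interval series
    is decomposed into LF/HF1/HF2 spectral bands by short-time Fourier
    transform. Band magnitudes are quantized to a four-letter alphabet,
    sliding-window subsequences are mined per disease class with FP-growth
    (frequent itemsets, association rules, adjacent-lead potential rules,
    cross-class deduplication), and rule-matching statistics form a
    26-dimensional feature vector classified by a random forest. A synthetic
    ECG generator with planted R-peaks and class-dependent RR band structure
    makes the whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
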