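# hhdr — heart disease recognition from HRV rule features

`hhdr` recognises cardiac disease superclasses (NORM, MI, STTC, CD, HYP)
from 12-lead ECG records by mining symbolic rules from the spectral
structure of heart rate variability (HRV). It is aimed at biomedical
signal-processing researchers who want a fully inspectable, stage-by-stage
reference pipeline — every intermediate (peaks, RR series, band
magnitudes, symbol sequences, rule libraries, features) is a first-class
object — plus a synthetic ECG generator that makes the whole chain testable
without clinical data.

## The method

From each denoised lead, R-peaks are detected by gating at

    T = 0.6 (V_max − V_min) + V_min

keeping strict local maxima above `T` and suppressing candidates within a
refractory distance of the last accepted peak. The RR series
`L = [R_{i+1} − R_i]` (seconds) is resampled to 4 Hz and decomposed by STFT
into the classical HRV bands LF (0–0.15 Hz), HF1 (0.15–0.25 Hz) and HF2
(0.25–0.4 Hz). Each band's frame-magnitude series is quantized against its
own maximum into the alphabet A–D (quartiles of the band maximum), turning
every (lead, band) into a short symbol string. Sliding windows of length
2–4 over those strings give transactions; per class and band, FP-growth
mines frequent itemsets (support = fraction of transactions containing the
itemset), association rules are kept at confidence
`supp(X∪Z)/supp(X) ≥ 0.6`, adjacent-lead *potential rules* are added with
support = prefix support × co-occurrence correlation, and rules appearing
in more than one class are deleted everywhere. Matching a record against
the combined library yields seven statistics per band (match count, total
support, total confidence, match frequency, support median, skewness,
kurtosis); 21 base features plus 5 impact-weighted combined features (one
per class, built from each class's top-3 features under one-vs-rest random
forest importances) feed a 100-tree random forest, evaluated on a
stratified 4:1 train/test split.

## Worked example

```r
library(hhdr)

res <- run_hhdr_pipeline(n_per_class = 20, seed = 1)
res
#> <hhdr_eval multi task: accuracy 0.850 on 20 test records>
#>       predicted
#> truth  NORM MI STTC CD HYP
#>   NORM    3  0    0  0   1
#>   MI      0  4    0  0   0
#>   STTC    0  0    4  0   0
#>   CD      0  0    0  4   0
#>   HYP     2  0    0  0   2
```

This simulates 100 labelled 10-s records (20 per class), mines the rule
library on the 80-record training fold, extracts the 26 features and
reports held-out accuracy with the confusion table (rows = truth). The
residual confusion sits where the planted dynamics overlap most (NORM vs
HYP). Individual stages are plain functions:

```r
rec <- generate_record(synthetic_config("MI", seed = 7))
pp  <- preprocess_record(rec$record)
pk  <- detect_rpeaks(pp$signals[, 1], pp$fs)
head(extract_hrv(pk))
#> [1] 0.716 0.760 0.784 0.782 0.756 0.710
quantize_record(rec$record)[1:3, ]
#>   record_id lead band symbols
#> 1  sim_MI_7    1   LF DDBABCD
#> 2  sim_MI_7    1  HF1 DDDCDDD
#> 3  sim_MI_7    1  HF2 CDDDDDD
```

A thin CLI wraps the same functions:

```sh
Rscript exec/hhdr run --simulate --n-per-class 20 --seed 1 --out eval.json
Rscript exec/hhdr simulate --n-per-class 2 --seed 1 --out records/
Rscript exec/hhdr quantize --in records/sim_NORM_001.csv
```

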