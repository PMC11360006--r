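tiny_library <- function(rules_df) {
  defaults <- data.frame(class_label = "NORM", band = "LF", kind = "frequent",
                         consequent = "", confidence = 1,
                         stringsAsFactors = FALSE)
  for (col in names(defaults)) {
    if (is.null(rules_df[[col]])) rules_df[[col]] <- defaults[[col]]
  }
  class(rules_df) <- c("rule_library", "data.frame")
  rules_df
}

test_that("matching accumulates counts, supports and confidences per occurrence", {
  lib <- tiny_library(data.frame(antecedent = "AD", support = 0.4,
                                 confidence = 0.8, stringsAsFactors = FALSE))
  acc <- match_record(c("AD", "DC"), lib)
  expect_equal(acc$MR, 1L)
  expect_equal(acc$TS, 0.4)
  expect_equal(acc$TC, 0.8)
  expect_equal(acc$LE, 2L)
  expect_equal(acc$SA, 0.4)
  none <- match_record(c("BB", "CC"), lib)
  expect_equal(none$MR, 0L)
  expect_equal(none$TS + none$TC, 0)
  expect_warning(zero <- match_record("AD", lib[0, ]), "empty rule set")
  expect_equal(zero$MR, 0L)
})

test_that("a rule fires only when its whole item content is present", {
  lib <- tiny_library(data.frame(antecedent = "AD", consequent = "DC",
                                 support = 0.4, confidence = 0.8,
                                 stringsAsFactors = FALSE))
  both <- match_record(c("AD", "DC", "AD"), lib)
  expect_equal(both$MR, 3L)        # every occurrence of either item counts
  half <- match_record(c("AD", "AD"), lib)
  expect_equal(half$MR, 0L)        # consequent absent: rule inactive
})

test_that("doubling a record's subsequences doubles MR, TS, TC and LE but not FR", {
  lib <- tiny_library(data.frame(antecedent = c("AD", "DC"),
                                 support = c(0.4, 0.2),
                                 confidence = c(0.8, 0.7),
                                 stringsAsFactors = FALSE))
  s <- c("AD", "DC", "CC")
  a <- match_record(s, lib)
  b <- match_record(rep(s, 2), lib)
  expect_equal(b$MR, 2L * a$MR)
  expect_equal(b$TS, 2 * a$TS)
  expect_equal(b$TC, 2 * a$TC)
  expect_equal(b$LE, 2L * a$LE)
  expect_equal(match_frequency(b$MR, b$LE), match_frequency(a$MR, a$LE))
})

test_that("matching frequency is the match rate over examined subsequences", {
  expect_equal(match_frequency(5, 20), 0.25)
  expect_equal(match_frequency(0, 20), 0)
  expect_equal(match_frequency(20, 20), 1.0)
  expect_equal(match_frequency(0, 0), 0)
})

test_that("support score is the median of matched supports", {
  expect_equal(support_score(c(0.1, 0.2, 0.9)), 0.2)
  expect_equal(support_score(c(0.1, 0.3)), 0.2)
  expect_equal(support_score(numeric(0)), 0)
  set.seed(6)
  sa <- sort(runif(31))
  expect_equal(support_score(sa), sa[16])
})

test_that("support skewness and kurtosis match naive textbook loops to 1e-12", {
  expect_equal(support_skewness(c(0.1, 0.2, 0.3)), 0)
  expect_gt(support_skewness(c(0.1, 0.1, 0.1, 0.9)), 0)
  expect_lt(support_kurtosis(rep(c(-1, 1), 10)), 0)
  expect_equal(support_skewness(c(0.5, 0.5)), 0)  # degenerate: n < 3
  expect_equal(support_kurtosis(c(1, 2, 3)), 0)   # degenerate: n < 4
  expect_equal(support_skewness(rep(0.4, 10)), 0) # degenerate: zero spread
  for (seed in 1:20) {
    set.seed(seed)
    x <- runif(50)
    expect_equal(support_skewness(x), oracle_skewness(x), tolerance = 1e-12)
    expect_equal(support_kurtosis(x), oracle_kurtosis(x), tolerance = 1e-12)
  }
})

test_that("excess kurtosis of a large normal sample is near zero", {
  set.seed(7)
  x <- rnorm(1e5)
  expect_lt(abs(support_kurtosis(x)), 0.05)
})

test_that("skewness and kurtosis are location and scale invariant", {
  set.seed(8)
  x <- runif(40)
  expect_equal(support_skewness(x + 3.2), support_skewness(x), tolerance = 1e-9)
  expect_equal(support_skewness(2.5 * x), support_skewness(x), tolerance = 1e-9)
  expect_equal(support_kurtosis(x + 3.2), support_kurtosis(x), tolerance = 1e-9)
  expect_equal(support_kurtosis(2.5 * x), support_kurtosis(x), tolerance = 1e-9)
})

test_that("feature extraction yields the 21 named base features", {
  out <- generate_record(synthetic_config("NORM", seed = 13))
  q <- quantize_record(out$record)
  lib <- tiny_library(data.frame(
    band = c("LF", "HF1", "HF2"), antecedent = "DD",
    support = 0.5, confidence = 1, stringsAsFactors = FALSE))
  f <- extract_features(q, lib)
  expect_length(f, 21)
  expect_named(f, hhdr_feature_names())
  expect_true(all(is.finite(f)))
  # per band: TS and TC cannot exceed MR when supports/confidences are <= 1
  for (b in c("LF", "HF1", "HF2")) {
    expect_lte(f[[paste0(b, "_TS")]], f[[paste0(b, "_MR")]])
    expect_lte(f[[paste0(b, "_TC")]], f[[paste0(b, "_MR")]])
    expect_gte(f[[paste0(b, "_FR")]], 0)
    expect_lte(f[[paste0(b, "_FR")]], 1)
  }
  empty <- suppressWarnings(extract_features(q, lib[0, ]))
  expect_true(all(empty == 0))
})

test_that("lead order does not affect the feature vector", {
  out <- generate_record(synthetic_config("MI", seed = 14))
  q <- quantize_record(out$record)
  lib <- tiny_library(data.frame(
    band = rep(c("LF", "HF1", "HF2"), each = 2),
    antecedent = rep(c("DD", "DC"), 3),
    support = 0.5, confidence = 0.9, stringsAsFactors = FALSE))
  f1 <- extract_features(q, lib)
  set.seed(9)
  f2 <- extract_features(q[sample(nrow(q)), ], lib)
  expect_equal(f2, f1)
})

test_that("combined features are impact-weighted means of the top three", {
  ft <- data.frame(record_id = "r1", label = "NORM",
                   a = 1, b = 2, c = 3, d = 7)
  imp <- list(NORM = list(features = c("a", "b", "c"), weights = c(1, 1, 1)),
              MI = list(features = c("d", "b", "c"), weights = c(1, 0, 0)))
  out <- combined_features(ft, imp)
  expect_equal(out$FN_NORM, 2.0)
  expect_equal(out$FN_MI, 7.0)
  set.seed(10)
  for (i in 1:10) {
    w <- runif(3)
    v <- runif(3) * 10
    ft2 <- data.frame(record_id = "x", label = "NORM",
                      a = v[1], b = v[2], c = v[3])
    fn <- combined_features(ft2, list(Z = list(features = c("a", "b", "c"),
                                               weights = w)))$FN_Z
    expect_gte(fn, min(v))
    expect_lte(fn, max(v))
  }
  expect_error(combined_features(ft, list(N = list(features = c("a", "b", "c"),
                                                   weights = c(0, 0, 0)))),
               "positive sum")
})
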