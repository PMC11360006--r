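make_tx <- function(sets, band = "LF") {
  out <- list()
  for (i in seq_along(sets)) {
    out[[i]] <- list(record_id = sprintf("r%02d", i), lead = 1L, band = band,
                     items = sets[[i]])
  }
  out
}

test_that("transactions mirror the record's lead-band segments", {
  out <- generate_record(synthetic_config("NORM", seed = 8))
  q <- quantize_record(out$record)
  tx <- build_transactions(q)
  expect_length(tx, 36)
  df <- data.frame(record_id = "r", lead = 1L, band = "LF", symbols = "ADC")
  tx2 <- build_transactions(df, 2)
  expect_setequal(tx2[[1]]$items, c("AD", "DC"))
  # a segment too short for every window contributes no transaction
  df$symbols <- "A"
  expect_length(build_transactions(df, 2:4), 0)
})

test_that("support counts transactions containing the itemset", {
  tx <- c(replicate(3, c("a", "b"), simplify = FALSE),
          replicate(7, "c", simplify = FALSE))
  fq <- mine_frequent(tx, 0.2)
  expect_equal(fq$support[fq$items == "a"], 0.3)
  expect_equal(fq$support[fq$items == "a,b"], 0.3)
  expect_equal(fq$support[fq$items == "c"], 0.7)
  fq1 <- mine_frequent(tx, 1.0)
  expect_equal(nrow(fq1), 0)
  tx2 <- replicate(4, c("x", "y"), simplify = FALSE)
  expect_setequal(mine_frequent(tx2, 1.0)$items, c("x", "y", "x,y"))
  expect_equal(nrow(mine_frequent(list(), 0.5)), 0)
})

test_that("FP-growth equals exhaustive enumeration on random instances", {
  for (seed in 1:50) {
    tx <- random_instance(seed)
    ms <- sample(c(0.1, 0.2, 0.3, 0.5), 1)
    got <- mine_frequent(tx, ms)
    want <- oracle_frequent(tx, ms)
    expect_setequal(got$items, want$items)
    expect_equal(got$count[match(want$items, got$items)], want$count)
  }
})

test_that("itemset size caps bound the mined output", {
  tx <- replicate(10, c("a", "b", "c", "d"), simplify = FALSE)
  fq <- mine_frequent(tx, 0.5, max_size = 2)
  expect_equal(max(fq$size), 2)
  expect_setequal(fq$items, oracle_frequent(tx, 0.5, max_size = 2)$items)
})

test_that("association rules satisfy the confidence identity and match enumeration", {
  # item a in 6 of 10 transactions, {a, z} in 3: confidence(a -> z) = 0.5
  tx <- c(replicate(3, c("a", "z"), simplify = FALSE),
          replicate(3, "a", simplify = FALSE),
          replicate(4, "q", simplify = FALSE))
  fq <- mine_frequent(tx, 0.2)
  ar <- association_rules(fq, 0.4)
  r <- ar[ar$antecedent == "a" & ar$consequent == "z", ]
  expect_equal(r$confidence, 0.5)
  expect_equal(r$support, 0.3)
  # a consequent present in every transaction has confidence 1
  tx2 <- lapply(list(c("a", "u"), c("b", "u"), c("a", "u")), identity)
  ar2 <- association_rules(mine_frequent(tx2, 0.3), 0.9)
  expect_true(all(ar2[ar2$consequent == "u", "confidence"] == 1))
  for (seed in 51:70) {
    tx <- random_instance(seed)
    got <- association_rules(mine_frequent(tx, 0.2), 0.6)
    want <- oracle_assoc(tx, 0.2, 0.6)
    key <- function(d) paste(d$antecedent, d$consequent, sep = "|")
    expect_setequal(key(got), key(want))
    m <- match(key(want), key(got))
    expect_equal(got$confidence[m], want$confidence, tolerance = 1e-12)
    expect_equal(got$support[m], want$support, tolerance = 1e-12)
  }
})

test_that("support is anti-monotone over mined itemsets", {
  for (seed in 71:75) {
    tx <- random_instance(seed)
    fq <- mine_frequent(tx, 0.1)
    supp <- stats::setNames(fq$support, fq$items)
    for (i in which(fq$size >= 2)) {
      items <- strsplit(fq$items[i], ",", fixed = TRUE)[[1]]
      for (it in items) {
        expect_gte(supp[[it]], fq$support[i])
      }
    }
  }
})

test_that("adjacent-segment correlation is the conditional co-occurrence rate", {
  tx <- list(
    list(record_id = "r1", lead = 1L, band = "LF", items = "AD"),
    list(record_id = "r1", lead = 2L, band = "LF", items = "AD"),
    list(record_id = "r2", lead = 1L, band = "LF", items = "AD"),
    list(record_id = "r2", lead = 2L, band = "LF", items = "DC"),
    list(record_id = "r3", lead = 1L, band = "LF", items = "AD"),
    list(record_id = "r3", lead = 2L, band = "LF", items = "AD"),
    list(record_id = "r4", lead = 1L, band = "LF", items = "AD"),
    list(record_id = "r4", lead = 2L, band = "LF", items = "DC"))
  expect_equal(adjacent_correlation(tx, "LF", 1, 2, "AD"), 0.5)
  expect_equal(adjacent_correlation(tx, "LF", 1, 2, "ZZ"), 0)
  # AD appears in lead 2 of r1 and r3 only, and in lead 1 of both: 1.0
  expect_equal(adjacent_correlation(tx, "LF", 2, 1, "AD"), 1.0)
})

test_that("potential rules multiply prefix support by adjacent correlation", {
  sets <- list(c("AD"), c("AD"), c("AD"), c("AD"), c("DC"))
  tx <- c(make_tx(sets), lapply(seq_along(sets), function(i)
    list(record_id = sprintf("r%02d", i), lead = 2L, band = "LF",
         items = if (i <= 2) "AD" else "DC")))
  fq <- mine_frequent(tx, 0.2)
  pr <- mine_potential_rules(tx, fq, "LF", corr_threshold = 0.5, n_leads = 2)
  r <- pr[pr$antecedent == "AD", ]
  # AD occurs in lead 1 of 4 records, in both leads for 2: correlation 0.5
  expect_equal(r$confidence, 0.5)
  expect_equal(r$support, fq$support[fq$items == "AD"] * 0.5)
  expect_equal(r$consequent, "AD")
  # below the correlation threshold nothing is emitted
  pr2 <- mine_potential_rules(tx, fq, "LF", corr_threshold = 0.6, n_leads = 2)
  expect_false("AD" %in% pr2$antecedent)
  # correlation 1 passes the prefix support through unchanged
  tx3 <- c(make_tx(list("AD", "AD")), lapply(1:2, function(i)
    list(record_id = sprintf("r%02d", i), lead = 2L, band = "LF", items = "AD")))
  fq3 <- mine_frequent(tx3, 0.2)
  pr3 <- mine_potential_rules(tx3, fq3, "LF", 0.5, n_leads = 2)
  expect_equal(pr3$support[pr3$antecedent == "AD"],
               fq3$support[fq3$items == "AD"])
  # confidences agree with the reference correlation computation
  expect_equal(pr$confidence[pr$antecedent == "AD"],
               adjacent_correlation(tx, "LF", 1, 2, "AD"))
})

test_that("rules shared between classes are removed from every class", {
  rules <- data.frame(
    class_label = c("NORM", "MI", "NORM", "MI"),
    band = "LF", kind = "frequent",
    antecedent = c("AD", "AD", "DC", "CB"),
    consequent = "", support = c(0.5, 0.4, 0.3, 0.6), confidence = 1,
    stringsAsFactors = FALSE)
  out <- deduplicate_rules(rules)
  expect_setequal(out$antecedent, c("DC", "CB"))
  disjoint <- data.frame(class_label = c("NORM", "MI"), band = "LF",
                         kind = "frequent", antecedent = c("AA", "BB"),
                         consequent = "", support = 0.5, confidence = 1,
                         stringsAsFactors = FALSE)
  expect_equal(deduplicate_rules(disjoint), disjoint)
  same <- transform(rules, antecedent = "AD")
  expect_warning(none <- deduplicate_rules(same), "lost all rules")
  expect_equal(nrow(none), 0)
})

test_that("built libraries have pairwise disjoint per-class rule keys", {
  sim <- generate_dataset(4, seed = 12)
  q <- quantize_dataset(sim$records)
  labels <- stats::setNames(sim$labels,
                            vapply(sim$records, `[[`, character(1), "record_id"))
  lib <- suppressWarnings(
    build_rule_library(build_transactions(q), labels))
  expect_s3_class(lib, "rule_library")
  expect_gt(nrow(lib), 0)
  key <- paste(lib$band, lib$antecedent, lib$consequent, sep = "|")
  expect_true(all(tapply(lib$class_label, key,
                         function(cl) length(unique(cl))) == 1))
  expect_true(all(lib$support > 0 & lib$support <= 1))
  expect_true(all(lib$confidence >= 0 & lib$confidence <= 1))
})
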