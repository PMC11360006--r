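HHDR_BASE_STATS <- c("MR", "TS", "TC", "FR", "SQ", "SS", "SK")

#' Names of the 21 base rule-matching features
#'
#' @return Character vector `LF_MR`, ..., `HF2_SK` (7 statistics x 3 bands).
#' @export
hhdr_feature_names <- function() {
  as.vector(t(outer(names(HHDR_BANDS), HHDR_BASE_STATS, paste, sep = "_")))
}

rule_item_content <- function(rules) {
  lapply(seq_len(nrow(rules)), function(i)
    unique(c(split_items(rules$antecedent[i]), split_items(rules$consequent[i]))))
}

#' Match a record's subsequences against a band's rule set
#'
#' Every windowed subsequence occurrence of the record in that band (all
#' leads, all window lengths) is tested against every rule of the band in the
#' combined, deduplicated library. A rule is active when its full item
#' content (antecedent plus consequent) is contained in the record's
#' subsequence set for the band; each occurrence of an item of an active rule
#' counts as one match, adding the rule's support to TS, its confidence to
#' TC, and its support to the SA list. LE is the total number of subsequence
#' occurrences examined.
#'
#' @param subseqs Character vector (multiset) of the record's windowed
#'   subsequences for one band, all leads pooled.
#' @param rules Data frame of that band's rules (any classes).
#' @param contents Optional precomputed `rule_item_content(rules)` (reused
#'   across records when matching a whole table).
#' @return List with `MR`, `TS`, `TC`, `SA` (sorted ascending), `LE`.
#' @export
match_record <- function(subseqs, rules, contents = NULL) {
  acc <- list(MR = 0L, TS = 0, TC = 0, SA = numeric(0), LE = length(subseqs))
  if (nrow(rules) == 0) {
    warning("empty rule set: all-zero match accumulator")
    return(acc)
  }
  if (is.null(contents)) contents <- rule_item_content(rules)
  occ <- table(subseqs)
  present <- names(occ)
  sa_parts <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    items <- contents[[i]]
    m <- match(items, present)
    if (anyNA(m)) next            # rule inactive: not all items present
    n_occ <- sum(occ[m])
    acc$MR <- acc$MR + n_occ
    acc$TS <- acc$TS + n_occ * rules$support[i]
    acc$TC <- acc$TC + n_occ * rules$confidence[i]
    sa_parts[[i]] <- rep(rules$support[i], n_occ)
  }
  acc$SA <- as.numeric(sort(unlist(sa_parts)))
  acc$MR <- as.integer(acc$MR)
  acc
}

#' Matching frequency
#'
#' `FR = MR / LE`; 0 when no subsequences were examined.
#'
#' @param mr Number of matches.
#' @param le Number of subsequences examined.
#' @return Fraction (>= 0).
#' @export
match_frequency <- function(mr, le) if (le > 0) mr / le else 0

#' Support score: median of matched-rule supports
#'
#' Middle element of the sorted support list when its length is odd, mean of
#' the two middle elements when even, 0 when empty.
#'
#' @param sa Numeric vector of matched-rule supports.
#' @return The support score.
#' @export
support_score <- function(sa) {
  if (length(sa) == 0) return(0)
  median(sa)
}

#' Support skewness
#'
#' Adjusted Fisher-Pearson sample skewness
#' `n / ((n-1)(n-2)) * sum(((x - mean) / s)^3)` with `s` the sample standard
#' deviation. Returns 0 (degenerate) when `n < 3` or `s = 0`.
#'
#' @param sa Numeric vector of matched-rule supports.
#' @return Skewness value.
#' @export
support_skewness <- function(sa) {
  n <- length(sa)
  if (n < 3) return(0)
  s <- sd(sa)
  if (s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((sa - mean(sa)) / s)^3)
}

#' Support kurtosis
#'
#' Sample excess kurtosis
#' `n(n+1) / ((n-1)(n-2)(n-3)) * sum(((x - mean) / s)^4) -
#' 3 (n-1)^2 / ((n-2)(n-3))`. Returns 0 when `n < 4` or `s = 0`.
#'
#' @param sa Numeric vector of matched-rule supports.
#' @return Excess kurtosis value.
#' @export
support_kurtosis <- function(sa) {
  n <- length(sa)
  if (n < 4) return(0)
  s <- sd(sa)
  if (s == 0) return(0)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((sa - mean(sa)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Extract the 21 base rule-matching features for one record
#'
#' Seven statistics (MR, TS, TC, FR, SQ, SS, SK) per band: match counts,
#' summed supports/confidences, matching frequency, support median, support
#' skewness and kurtosis, against the combined deduplicated library.
#'
#' @param symbol_df One record's rows from [quantize_record()].
#' @param library A `rule_library` from [build_rule_library()].
#' @param window_lengths Window lengths used when matching.
#' @return Named numeric vector of length 21 (see [hhdr_feature_names()]).
#' @export
extract_features <- function(symbol_df, library, window_lengths = 2:4) {
  contents <- lapply(names(HHDR_BANDS), function(b)
    rule_item_content(library[library$band == b, , drop = FALSE]))
  names(contents) <- names(HHDR_BANDS)
  extract_features_impl(symbol_df, library, contents, window_lengths)
}

extract_features_impl <- function(symbol_df, library, contents, window_lengths) {
  out <- stats::setNames(numeric(21), hhdr_feature_names())
  for (b in names(HHDR_BANDS)) {
    rows <- symbol_df[symbol_df$band == b, , drop = FALSE]
    subseqs <- unlist(lapply(rows$symbols, windowed_subsequences,
                             window_lengths = window_lengths), use.names = FALSE)
    rules_b <- library[library$band == b, , drop = FALSE]
    acc <- suppressWarnings(match_record(subseqs, rules_b, contents[[b]]))
    out[paste0(b, "_MR")] <- acc$MR
    out[paste0(b, "_TS")] <- acc$TS
    out[paste0(b, "_TC")] <- acc$TC
    out[paste0(b, "_FR")] <- match_frequency(acc$MR, acc$LE)
    out[paste0(b, "_SQ")] <- support_score(acc$SA)
    out[paste0(b, "_SS")] <- support_skewness(acc$SA)
    out[paste0(b, "_SK")] <- support_kurtosis(acc$SA)
  }
  out
}

#' Base feature table for a set of records
#'
#' @param symbol_df Row-bound [quantize_record()] output over records.
#' @param library A `rule_library`.
#' @param labels Optional named character vector `record_id -> class`.
#' @param window_lengths Window lengths used when matching.
#' @return Data frame: `record_id`, `label` (NA when unknown), 21 feature
#'   columns.
#' @export
extract_feature_table <- function(symbol_df, library, labels = NULL,
                                  window_lengths = 2:4) {
  recs <- unique(symbol_df$record_id)
  contents <- lapply(names(HHDR_BANDS), function(b)
    rule_item_content(library[library$band == b, , drop = FALSE]))
  names(contents) <- names(HHDR_BANDS)
  feats <- t(vapply(recs, function(r)
    extract_features_impl(symbol_df[symbol_df$record_id == r, , drop = FALSE],
                          library, contents, window_lengths),
    numeric(21)))
  out <- data.frame(record_id = recs,
                    label = if (is.null(labels)) NA_character_ else unname(labels[recs]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(feats))
}

#' Impact-weighted combined features
#'
#' For each class, the weighted mean of the record's three most influential
#' base features, the weights being the class's feature-importance values:
#' `FN_c = sum(W_i x_i) / sum(W_i)`. One combined feature per class.
#'
#' @param feature_table Data frame containing the 21 base feature columns.
#' @param impact An `impact_report` from [impact_factors()] (or a named list
#'   of lists with `features` (3 names) and `weights` (3 non-negative, not
#'   all zero)).
#' @return The feature table with columns `FN_<class>` appended.
#' @export
combined_features <- function(feature_table, impact) {
  for (cl in names(impact)) {
    sel <- impact[[cl]]
    w <- sel$weights
    if (any(w < 0) || sum(w) == 0) stop("weights must be non-negative with positive sum")
    x <- as.matrix(feature_table[, sel$features, drop = FALSE])
    feature_table[[paste0("FN_", cl)]] <- as.numeric(x %*% w) / sum(w)
  }
  feature_table
}
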