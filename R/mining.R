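#' Rule-mining configuration
#'
#' @param min_support Minimum itemset support (fraction of transactions).
#' @param min_confidence Minimum association-rule confidence.
#' @param corr_threshold Minimum adjacent-lead correlation for a potential
#'   rule.
#' @param window_lengths Sliding-window lengths used to build transactions.
#' @param max_itemset_size Largest itemset mined. Dense segments (long runs
#'   of one symbol) make most subsets of their items frequent, so unbounded
#'   mining grows exponentially; small itemsets carry the discriminative
#'   content and are what rule matching consumes.
#' @return Object of class `mining_config`.
#' @export
mining_config <- function(min_support = 0.2, min_confidence = 0.6,
                          corr_threshold = 0.5, window_lengths = 2:4,
                          max_itemset_size = 3) {
  if (min_support <= 0 || min_support > 1) stop("min_support must lie in (0, 1]")
  if (min_confidence < 0 || min_confidence > 1) stop("min_confidence must lie in [0, 1]")
  if (corr_threshold <= 0 || corr_threshold > 1) stop("corr_threshold must lie in (0, 1]")
  if (max_itemset_size < 1) stop("max_itemset_size must be >= 1")
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 corr_threshold = corr_threshold,
                 window_lengths = as.integer(window_lengths),
                 max_itemset_size = as.integer(max_itemset_size)),
            class = "mining_config")
}

#' Build transactions from quantized symbol sequences
#'
#' One transaction per (record, lead, band): its items are the distinct
#' sliding-window subsequences of that lead-band symbol string ("sequence
#' segment"). Segments too short for every window length are omitted.
#'
#' @param symbol_df Data frame from [quantize_record()] (possibly row-bound
#'   over records): columns `record_id`, `lead`, `band`, `symbols`.
#' @param window_lengths Integer window lengths.
#' @return List of transactions, each a list with `record_id`, `lead`,
#'   `band`, `items` (character vector of distinct subsequences).
#' @export
build_transactions <- function(symbol_df, window_lengths = 2:4) {
  out <- list()
  for (i in seq_len(nrow(symbol_df))) {
    items <- unique(windowed_subsequences(symbol_df$symbols[i], window_lengths))
    if (length(items) == 0) next
    out[[length(out) + 1L]] <- list(record_id = symbol_df$record_id[i],
                                    lead = symbol_df$lead[i],
                                    band = symbol_df$band[i],
                                    items = items)
  }
  out
}

canon_items <- function(items) paste(sort(items), collapse = ",")
split_items <- function(key) if (identical(key, "")) character(0) else strsplit(key, ",", fixed = TRUE)[[1]]

# ---- FP-growth ------------------------------------------------------------

fp_node <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item; e$count <- 0L; e$parent <- parent
  e$children <- list()
  e
}

# txc: list of list(items = chr, count = int); emits itemsets into acc env
fp_mine <- function(txc, min_count, suffix, acc, max_size = Inf) {
  if (length(txc) == 0 || length(suffix) >= max_size) return(invisible())
  all_items <- unlist(lapply(txc, `[[`, "items"), use.names = FALSE)
  wts <- rep(vapply(txc, `[[`, integer(1), "count"),
             vapply(txc, function(t) length(t$items), integer(1)))
  tot <- tapply(wts, all_items, sum)
  tot <- tot[tot >= min_count]
  if (length(tot) == 0) return(invisible())
  ord <- names(tot)[order(-tot, names(tot))]  # desc freq, ties lexicographic

  # build the FP-tree over filtered, order-sorted transactions
  root <- fp_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())
  for (t in txc) {
    its <- ord[ord %in% t$items]
    node <- root
    for (it in its) {
      ch <- node$children[[it]]
      if (is.null(ch)) {
        ch <- fp_node(it, node)
        node$children[[it]] <- ch
        header[[it]] <- c(if (is.null(header[[it]])) list() else header[[it]], list(ch))
      }
      ch$count <- ch$count + t$count
      node <- ch
    }
  }

  # grow patterns from the least frequent item upward
  for (it in rev(ord)) {
    cnt <- as.integer(tot[[it]])
    key <- canon_items(c(it, suffix))
    assign(key, cnt, envir = acc)
    base <- list()
    for (node in header[[it]]) {
      path <- character(0)
      p <- node$parent
      while (!is.null(p) && !is.na(p$item)) { path <- c(p$item, path); p <- p$parent }
      if (length(path) > 0)
        base[[length(base) + 1L]] <- list(items = path, count = node$count)
    }
    fp_mine(base, min_count, c(it, suffix), acc, max_size)
  }
  invisible()
}

#' Mine frequent itemsets with FP-growth
#'
#' Exact frequent-itemset mining: every itemset of at most `max_size` items
#' whose support (fraction of transactions containing it) is at least
#' `min_support` is returned, with its exact support.
#'
#' @param transactions Either the output of [build_transactions()] or a bare
#'   list of character item vectors.
#' @param min_support Minimum support in (0, 1].
#' @param max_size Largest itemset size mined (`Inf` for unbounded).
#' @return Data frame with columns `items` (canonical comma-joined sorted
#'   item key), `size`, `count`, `support`, ordered by decreasing support.
#' @export
mine_frequent <- function(transactions, min_support = 0.2, max_size = Inf) {
  if (min_support <= 0 || min_support > 1) stop("min_support must lie in (0, 1]")
  tx <- transaction_items(transactions)
  n <- length(tx)
  empty <- data.frame(items = character(0), size = integer(0),
                      count = integer(0), support = numeric(0))
  if (n == 0) return(empty)
  min_count <- max(1L, ceiling(min_support * n - 1e-9))
  txc <- lapply(tx, function(it) list(items = unique(it), count = 1L))
  acc <- new.env(parent = emptyenv())
  fp_mine(txc, min_count, character(0), acc, max_size)
  keys <- ls(acc)
  if (length(keys) == 0) return(empty)
  counts <- vapply(keys, function(k) get(k, envir = acc), integer(1))
  out <- data.frame(items = keys,
                    size = lengths(strsplit(keys, ",", fixed = TRUE)),
                    count = as.integer(counts),
                    support = counts / n,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$items), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_transactions") <- n
  out
}

transaction_items <- function(transactions) {
  if (length(transactions) == 0) return(list())
  if (is.list(transactions[[1]]) && !is.null(transactions[[1]]$items))
    lapply(transactions, `[[`, "items")
  else
    transactions
}

#' Derive association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2 and every non-empty proper subset
#' X (consequent Z its complement), the rule X -> Z is kept when its
#' confidence `support(X u Z) / support(X)` reaches `min_confidence`. The
#' rule's support is `support(X u Z)`.
#'
#' @param frequent Data frame from [mine_frequent()] (closed under subsets).
#' @param min_confidence Minimum confidence in \[0, 1\].
#' @return Data frame with columns `antecedent`, `consequent` (canonical
#'   keys), `support`, `confidence`.
#' @export
association_rules <- function(frequent, min_confidence = 0.6) {
  supp <- stats::setNames(frequent$support, frequent$items)
  rows <- list()
  for (i in seq_len(nrow(frequent))) {
    if (frequent$size[i] < 2) next
    items <- split_items(frequent$items[i])
    k <- length(items)
    s_full <- frequent$support[i]
    for (mask in seq_len(2^k - 2)) {
      ant <- items[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
      cons <- setdiff(items, ant)
      s_ant <- supp[[canon_items(ant)]]
      conf <- s_full / s_ant
      if (conf >= min_confidence - 1e-12)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = canon_items(ant), consequent = canon_items(cons),
          support = s_full, confidence = conf, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, out$antecedent, out$consequent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-record, per-lead item sets for one band
lead_itemsets <- function(transactions, band) {
  tx <- Filter(function(t) t$band == band, transactions)
  recs <- unique(vapply(tx, `[[`, character(1), "record_id"))
  out <- lapply(recs, function(r) {
    sel <- Filter(function(t) t$record_id == r, tx)
    stats::setNames(lapply(sel, `[[`, "items"),
                    vapply(sel, function(t) as.character(t$lead), character(1)))
  })
  stats::setNames(out, recs)
}

#' Correlation of an itemset between two adjacent sequence segments
#'
#' Fraction of records in which the itemset occurs in lead `lead_b` among
#' those where it occurs in lead `lead_a` (conditional co-occurrence across
#' adjacent leads); 0 when the itemset never occurs in `lead_a`.
#'
#' @param transactions Output of [build_transactions()].
#' @param band Band name.
#' @param lead_a,lead_b Adjacent lead indices.
#' @param itemset Character vector of items.
#' @return Fraction in \[0, 1\].
#' @export
adjacent_correlation <- function(transactions, band, lead_a, lead_b, itemset) {
  per_rec <- lead_itemsets(transactions, band)
  in_lead <- function(rec, lead) {
    its <- rec[[as.character(lead)]]
    !is.null(its) && all(itemset %in% its)
  }
  n_a <- sum(vapply(per_rec, in_lead, logical(1), lead = lead_a))
  if (n_a == 0) return(0)
  n_ab <- sum(vapply(per_rec, function(r) in_lead(r, lead_a) && in_lead(r, lead_b),
                     logical(1)))
  n_ab / n_a
}

#' Mine prefix-suffix potential rules across adjacent leads
#'
#' For each frequent itemset, the correlation with the next lead is computed
#' for every adjacent lead pair (1-2, 2-3, ...); when the maximum correlation
#' reaches `corr_threshold`, a potential rule is emitted whose antecedent and
#' consequent are the itemset (prefix in lead k, suffix in lead k+1), with
#' support = prefix support x correlation and confidence = correlation.
#'
#' @param transactions Output of [build_transactions()] (one band's worth is
#'   selected internally via `band`).
#' @param frequent Data frame from [mine_frequent()] for that band.
#' @param band Band name.
#' @param corr_threshold Minimum correlation in (0, 1].
#' @param n_leads Number of leads in the record layout.
#' @return Data frame `antecedent`, `consequent`, `support`, `confidence`.
#' @export
mine_potential_rules <- function(transactions, frequent, band,
                                 corr_threshold = 0.5, n_leads = 12) {
  empty <- data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0))
  if (nrow(frequent) == 0) return(empty)
  tx <- Filter(function(t) t$band == band, transactions)
  if (length(tx) == 0) return(empty)
  recs <- unique(vapply(tx, `[[`, character(1), "record_id"))
  # item incidence over (lead, record) cells, restricted to mined items
  vocab <- unique(unlist(strsplit(frequent$items, ",", fixed = TRUE)))
  M <- matrix(FALSE, length(vocab), n_leads * length(recs))
  for (t in tx) {
    cell <- (match(t$record_id, recs) - 1L) * n_leads + as.integer(t$lead)
    M[match(intersect(t$items, vocab), vocab), cell] <- TRUE
  }
  rows <- list()
  for (i in seq_len(nrow(frequent))) {
    ii <- match(split_items(frequent$items[i]), vocab)
    pres <- matrix(colSums(M[ii, , drop = FALSE]) == length(ii), nrow = n_leads)
    cmax <- 0
    for (k in seq_len(n_leads - 1)) {
      denom <- sum(pres[k, ])
      if (denom == 0) next
      cmax <- max(cmax, sum(pres[k, ] & pres[k + 1, ]) / denom)
    }
    if (cmax >= corr_threshold - 1e-12)
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = frequent$items[i], consequent = frequent$items[i],
        support = frequent$support[i] * cmax, confidence = cmax,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove rules shared between classes
#'
#' Any rule whose (band, antecedent, consequent) key occurs in two or more
#' classes is removed from all of them, leaving per-class rule sets pairwise
#' disjoint. Supports and confidences play no role in rule identity.
#'
#' @param rules Data frame with columns `class_label`, `band`, `antecedent`,
#'   `consequent` (plus any others, preserved).
#' @return The filtered data frame; warns when a class loses all its rules.
#' @export
deduplicate_rules <- function(rules) {
  if (nrow(rules) == 0) return(rules)
  key <- paste(rules$band, rules$antecedent, rules$consequent, sep = "|")
  n_classes <- tapply(rules$class_label, key, function(cl) length(unique(cl)))
  shared <- names(n_classes)[n_classes >= 2]
  before <- unique(rules$class_label)
  out <- rules[!(key %in% shared), , drop = FALSE]
  lost <- setdiff(before, unique(out$class_label))
  if (length(lost) > 0)
    warning(sprintf("class(es) %s lost all rules in deduplication",
                    paste(lost, collapse = ", ")))
  rownames(out) <- NULL
  out
}

#' Build the per-class, per-band rule library
#'
#' Mines each (class, band) separately: FP-growth frequent itemsets,
#' association rules, adjacent-lead potential rules; then removes rules
#' shared between classes. Within a class and band, rules carrying the same
#' (antecedent, consequent) key are collapsed to one row (frequent-itemset
#' rows win over derived kinds, keeping supports consistent).
#'
#' @param transactions Output of [build_transactions()] over all training
#'   records.
#' @param record_labels Named character vector mapping `record_id` to class.
#' @param config A [mining_config()].
#' @param n_leads Lead count of the record layout.
#' @return Data frame of class `rule_library`: columns `class_label`, `band`,
#'   `kind` (frequent/association/potential), `antecedent`, `consequent`,
#'   `support`, `confidence`.
#' @export
build_rule_library <- function(transactions, record_labels,
                               config = mining_config(), n_leads = 12) {
  classes <- unique(record_labels)
  all_rules <- list()
  for (cl in classes) {
    recs <- names(record_labels)[record_labels == cl]
    tx_cl <- Filter(function(t) t$record_id %in% recs, transactions)
    for (b in names(HHDR_BANDS)) {
      tx_cb <- Filter(function(t) t$band == b, tx_cl)
      if (length(tx_cb) == 0) next
      fq <- mine_frequent(tx_cb, config$min_support, config$max_itemset_size)
      if (nrow(fq) == 0) next
      rules <- data.frame(class_label = cl, band = b, kind = "frequent",
                          antecedent = fq$items, consequent = "",
                          support = fq$support, confidence = 1,
                          stringsAsFactors = FALSE)
      ar <- association_rules(fq, config$min_confidence)
      if (nrow(ar) > 0)
        rules <- rbind(rules, data.frame(class_label = cl, band = b,
                                         kind = "association",
                                         antecedent = ar$antecedent,
                                         consequent = ar$consequent,
                                         support = ar$support,
                                         confidence = ar$confidence,
                                         stringsAsFactors = FALSE))
      pr <- mine_potential_rules(tx_cb, fq, b, config$corr_threshold, n_leads)
      if (nrow(pr) > 0)
        rules <- rbind(rules, data.frame(class_label = cl, band = b,
                                         kind = "potential",
                                         antecedent = pr$antecedent,
                                         consequent = pr$consequent,
                                         support = pr$support,
                                         confidence = pr$confidence,
                                         stringsAsFactors = FALSE))
      key <- paste(rules$antecedent, rules$consequent, sep = "|")
      rules <- rules[!duplicated(key), , drop = FALSE]
      all_rules[[length(all_rules) + 1L]] <- rules
    }
  }
  if (length(all_rules) == 0)
    return(structure(data.frame(class_label = character(0), band = character(0),
                                kind = character(0), antecedent = character(0),
                                consequent = character(0), support = numeric(0),
                                confidence = numeric(0)),
                     class = c("rule_library", "data.frame")))
  lib <- deduplicate_rules(do.call(rbind, all_rules))
  rownames(lib) <- NULL
  class(lib) <- c("rule_library", "data.frame")
  lib
}
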