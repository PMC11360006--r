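# Independent oracles used across test files. These deliberately use naive
# loops / exhaustive enumeration, never the package's own code paths.

# strict local maxima above a threshold, by direct scan
oracle_local_maxima <- function(x, thr) {
  out <- integer(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i - 1] < x[i] && x[i] > x[i + 1] && x[i] > thr) out <- c(out, i)
  }
  out
}

# exhaustive frequent-itemset enumeration over all subsets of the vocabulary
oracle_frequent <- function(tx, min_support, max_size = Inf) {
  vocab <- sort(unique(unlist(tx)))
  n <- length(tx)
  rows <- list()
  for (k in seq_len(min(length(vocab), max_size))) {
    for (comb in utils::combn(vocab, k, simplify = FALSE)) {
      cnt <- sum(vapply(tx, function(t) all(comb %in% t), logical(1)))
      if (cnt / n >= min_support - 1e-9) {
        rows[[length(rows) + 1L]] <- data.frame(
          items = paste(comb, collapse = ","), count = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(items = character(0), count = integer(0)))
  do.call(rbind, rows)
}

# exhaustive association rules from exact supports
oracle_assoc <- function(tx, min_support, min_confidence) {
  fr <- oracle_frequent(tx, min_support)
  n <- length(tx)
  supp <- stats::setNames(fr$count / n, fr$items)
  rows <- list()
  for (key in fr$items) {
    items <- strsplit(key, ",", fixed = TRUE)[[1]]
    k <- length(items)
    if (k < 2) next
    for (m in seq_len(2^k - 2)) {
      ant <- items[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
      cons <- setdiff(items, ant)
      conf <- supp[[key]] / supp[[paste(sort(ant), collapse = ",")]]
      if (conf >= min_confidence - 1e-9)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(sort(ant), collapse = ","),
          consequent = paste(sort(cons), collapse = ","),
          support = supp[[key]], confidence = conf, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0)))
  do.call(rbind, rows)
}

# textbook adjusted Fisher-Pearson skewness / excess kurtosis, naive loops
oracle_skewness <- function(x) {
  n <- length(x)
  m <- mean(x); s <- sd(x)
  acc <- 0
  for (xi in x) acc <- acc + ((xi - m) / s)^3
  n / ((n - 1) * (n - 2)) * acc
}
oracle_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x); s <- sd(x)
  acc <- 0
  for (xi in x) acc <- acc + ((xi - m) / s)^4
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * acc -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

# quiet config for noise-free generator runs
clean_config <- function(class_label = "NORM", seed = 1L, ...) {
  synthetic_config(class_label, noise_sd = 0, baseline_amp = 0,
                   powerline_amp = 0, seed = seed, ...)
}

# profile with a single modulated band
single_band_profile <- function(band, amp = 0.05) {
  freq <- c(LF = 0.1, HF1 = 0.2, HF2 = 0.3)
  amps <- c(LF = 0, HF1 = 0, HF2 = 0)
  amps[band] <- amp
  list(mean_rr = 0.85, amp = unname(amps), freq = unname(freq))
}

# fraction of planted peaks recovered within +/- tol samples, one lead
recovery_fraction <- function(detected, truth, tol = 2) {
  if (length(truth) == 0) return(NA_real_)
  hits <- vapply(truth, function(p) any(abs(detected - p) <= tol), logical(1))
  mean(hits)
}

# small deterministic random transaction instance
random_instance <- function(seed, n_tx_max = 20, n_items_max = 8) {
  set.seed(seed)
  n_tx <- sample(5:n_tx_max, 1)
  vocab <- paste0("i", seq_len(sample(3:n_items_max, 1)))
  lapply(seq_len(n_tx), function(i)
    sample(vocab, sample(seq_along(vocab), 1)))
}
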