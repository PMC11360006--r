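#' Full pipeline configuration
#'
#' One document resolving every stage's parameters. Unknown fields are
#' rejected by [read_hhdr_config()].
#'
#' @param filters A [filter_config()].
#' @param rpeak An [rpeak_config()].
#' @param stft An [stft_config()].
#' @param mining A [mining_config()].
#' @param forest A [forest_config()].
#' @return Object of class `hhdr_config`.
#' @export
hhdr_config <- function(filters = filter_config(), rpeak = rpeak_config(),
                        stft = stft_config(), mining = mining_config(),
                        forest = forest_config()) {
  structure(list(filters = filters, rpeak = rpeak, stft = stft,
                 mining = mining, forest = forest),
            class = "hhdr_config")
}

#' Quantize a list of records
#'
#' Label-free (hence leakage-free) stage: denoise, detect peaks, extract RR,
#' decompose and quantize every record. The result can be passed to
#' [run_hhdr_pipeline()] via `quantized` to reuse across tasks.
#'
#' @param records List of `ecg_record`.
#' @param config An [hhdr_config()].
#' @return Row-bound data frame as from [quantize_record()].
#' @export
quantize_dataset <- function(records, config = hhdr_config()) {
  do.call(rbind, lapply(records, quantize_record,
                        filter_cfg = config$filters, rpeak_cfg = config$rpeak,
                        stft_cfg = config$stft))
}

#' Run the full recognition pipeline
#'
#' Stratified 4:1 split; rule library and impact factors are computed from
#' training records only (the alternative would leak test labels into the
#' features); features are extracted for all records against the training
#' library; a random forest is trained and evaluated on the held-out fifth.
#'
#' @param records List of `ecg_record`, or `NULL` to simulate.
#' @param labels Character class labels, one per record (taken from the
#'   records' own labels when missing).
#' @param n_per_class When `records` is `NULL`, simulate this many records
#'   per class with [generate_dataset()].
#' @param config An [hhdr_config()].
#' @param seed Integer seed driving simulation, split and forests.
#' @param task `"multi"` or `"binary"`.
#' @param quantized Optional precomputed [quantize_dataset()] output.
#' @param permute_labels Shuffle the labels before any label-dependent stage
#'   (negative control: accuracy should collapse to chance).
#' @return `hhdr_eval` result, extended with `seed`, `train_ids`, `test_ids`,
#'   `library`, `impact`, `model`, `features`.
#' @export
#' @examples
#' \donttest{
#' res <- run_hhdr_pipeline(n_per_class = 8, seed = 1)
#' res$accuracy
#' }
run_hhdr_pipeline <- function(records = NULL, labels = NULL, n_per_class = NULL,
                              config = hhdr_config(), seed = 1L,
                              task = c("multi", "binary"), quantized = NULL,
                              permute_labels = FALSE) {
  task <- match.arg(task)
  if (is.null(records)) {
    if (is.null(n_per_class)) stop("provide records or n_per_class")
    sim <- generate_dataset(n_per_class, seed = seed)
    records <- sim$records
    labels <- sim$labels
  }
  if (is.null(labels))
    labels <- vapply(records, function(r) r$label %||% NA_character_, character(1))
  if (anyNA(labels)) stop("missing labels")
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) stop("duplicate record_ids")
  if (permute_labels) {
    set.seed(seed + 424243L)
    labels <- sample(labels)
  }
  names(labels) <- ids

  if (is.null(quantized)) quantized <- quantize_dataset(records, config)

  sp <- split_dataset(unname(labels), seed = seed)
  train_ids <- ids[sp$train]
  test_ids <- ids[sp$test]

  wl <- config$mining$window_lengths
  tx_train <- build_transactions(
    quantized[quantized$record_id %in% train_ids, , drop = FALSE], wl)
  library <- suppressWarnings(
    build_rule_library(tx_train, labels[train_ids], config$mining))

  feats <- extract_feature_table(quantized, library, labels, wl)
  train_ft <- feats[feats$record_id %in% train_ids, , drop = FALSE]
  impact <- impact_factors(train_ft, seed = seed, ntree = config$forest$ntree)
  feats <- combined_features(feats, impact)
  train_ft <- feats[feats$record_id %in% train_ids, , drop = FALSE]
  test_ft <- feats[feats$record_id %in% test_ids, , drop = FALSE]

  model <- train_hhdr(train_ft, task = task, seed = seed,
                      config = config$forest, impact = impact)
  res <- evaluate_model(model, test_ft, test_ft$label)
  res$seed <- as.integer(seed)
  res$train_ids <- train_ids
  res$test_ids <- test_ids
  res$library <- library
  res$impact <- impact
  res$model <- model
  res$features <- feats
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
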