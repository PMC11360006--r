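#' Random-forest configuration
#'
#' @param ntree Number of trees.
#' @param feature_set `"full"`: all 21 base features plus the 5 combined
#'   features enter the final forest; `"top"`: only the union of per-class
#'   top-3 features plus the 5 combined.
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(ntree = 100, feature_set = c("full", "top")) {
  structure(list(ntree = as.integer(ntree),
                 feature_set = match.arg(feature_set)),
            class = "forest_config")
}

#' Per-class feature importances and top-3 selection
#'
#' For each class a one-vs-rest random forest is fitted on the 21 base
#' features; mean-decrease-in-impurity importances are ranked (ties broken
#' by feature name) and the top three recorded. Deterministic given the seed.
#'
#' @param feature_table Data frame with the 21 base feature columns and a
#'   `label` column.
#' @param seed Integer seed.
#' @param ntree Trees per one-vs-rest forest.
#' @return Object of class `impact_report`: named list per class with
#'   `ranking` (data frame `feature`, `importance`), `features` (top-3
#'   names), `weights` (their importances).
#' @export
impact_factors <- function(feature_table, seed = 1L, ntree = 100) {
  base_cols <- hhdr_feature_names()
  labels <- feature_table$label
  counts <- table(labels)
  if (any(counts < 2)) stop("every class needs at least 2 records")
  x <- feature_table[, base_cols, drop = FALSE]
  out <- list()
  for (k in seq_along(sort(unique(labels)))) {
    cl <- sort(unique(labels))[k]
    y <- factor(ifelse(labels == cl, cl, "REST"), levels = c(cl, "REST"))
    set.seed(seed + k)
    rf <- randomForest::randomForest(x, y, ntree = ntree)
    imp <- rf$importance[, "MeanDecreaseGini"]
    ranking <- data.frame(feature = names(imp), importance = as.numeric(imp),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$importance, ranking$feature), , drop = FALSE]
    rownames(ranking) <- NULL
    out[[cl]] <- list(ranking = ranking,
                      features = ranking$feature[1:3],
                      weights = ranking$importance[1:3])
  }
  structure(out, class = "impact_report")
}

#' Stratified train/test split
#'
#' Deterministic stratified split at the given test fraction (default 1:4
#' test:train); every class contributes `round(n_class * test_fraction)`
#' test records (at least one), and no record appears in both parts.
#'
#' @param labels Character vector of class labels, one per record.
#' @param seed Integer seed.
#' @param test_fraction Fraction held out (default 0.2).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, seed = 1L, test_fraction = 0.2) {
  counts <- table(labels)
  if (any(counts < 5)) stop("every class needs at least 5 records for a 4:1 split")
  set.seed(seed)
  test <- integer(0)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

collapse_binary <- function(labels) {
  factor(ifelse(labels == "NORM", "NORM", "DISEASE"),
         levels = c("NORM", "DISEASE"))
}

task_labels <- function(labels, task) {
  if (task == "binary") collapse_binary(labels)
  else factor(labels, levels = intersect(HHDR_CLASSES, unique(labels)))
}

#' Train the final random forest
#'
#' Fits on the 21 base features plus the 5 combined features (or the reduced
#' top-feature set, see [forest_config()]). The binary task collapses all
#' disease classes against NORM.
#'
#' @param feature_table Data frame with base + `FN_*` columns and `label`.
#' @param task `"multi"` (5-class) or `"binary"` (normal vs disease).
#' @param seed Integer seed.
#' @param config A [forest_config()].
#' @param impact Needed when `config$feature_set == "top"`.
#' @return Fitted `randomForest` model with attribute `feature_cols`.
#' @export
train_hhdr <- function(feature_table, task = c("multi", "binary"), seed = 1L,
                       config = forest_config(), impact = NULL) {
  task <- match.arg(task)
  y <- task_labels(feature_table$label, task)
  if (nlevels(droplevels(y)) < 2) stop("training data contain a single class")
  fn_cols <- grep("^FN_", names(feature_table), value = TRUE)
  base_cols <- if (config$feature_set == "full") {
    hhdr_feature_names()
  } else {
    if (is.null(impact)) stop("feature_set='top' requires an impact report")
    unique(unlist(lapply(impact, `[[`, "features")))
  }
  cols <- c(base_cols, fn_cols)
  set.seed(seed)
  model <- randomForest::randomForest(feature_table[, cols, drop = FALSE], y,
                                      ntree = config$ntree)
  attr(model, "feature_cols") <- cols
  attr(model, "task") <- task
  model
}

#' Evaluate a trained model on a test set
#'
#' @param model Fitted model from [train_hhdr()].
#' @param feature_table Test-set feature table (same columns).
#' @param labels True labels of the test records (superclass names; collapsed
#'   automatically for a binary model).
#' @return Object of class `hhdr_eval`: `task`, `accuracy`, `confusion`
#'   (rows = truth), `precision`, `recall` (per class), `n_test`.
#' @export
evaluate_model <- function(model, feature_table, labels) {
  if (nrow(feature_table) == 0) stop("empty test set")
  task <- attr(model, "task")
  y <- task_labels(labels, task)
  pred <- predict(model, feature_table[, attr(model, "feature_cols"), drop = FALSE])
  conf <- table(truth = y, predicted = factor(pred, levels = levels(y)))
  acc <- sum(diag(conf)) / sum(conf)
  precision <- diag(conf) / pmax(1, colSums(conf))
  recall <- diag(conf) / pmax(1, rowSums(conf))
  structure(list(task = task, accuracy = acc, confusion = conf,
                 precision = precision, recall = recall, n_test = length(y)),
            class = "hhdr_eval")
}

#' @export
print.hhdr_eval <- function(x, ...) {
  cat(sprintf("<hhdr_eval %s task: accuracy %.3f on %d test records>\n",
              x$task, x$accuracy, x$n_test))
  print(x$confusion)
  invisible(x)
}
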