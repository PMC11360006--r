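#' Write an ECG record to CSV
#'
#' One column per lead (`lead1` ... `leadN`), preceded by `#`-comment header
#' lines carrying `record_id`, `fs` and `label`, so a record round-trips
#' through [read_ecg_csv()].
#'
#' @param record An `ecg_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# record_id=%s", record$record_id),
               sprintf("# fs=%.10g", record$fs),
               sprintf("# label=%s", record$label %||% "")), con)
  df <- as.data.frame(record$signals)
  names(df) <- paste0("lead", seq_len(ncol(df)))
  write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Counterpart of [write_ecg_csv()]. A 12-lead layout is enforced by default.
#'
#' @param path CSV path.
#' @param n_leads Expected lead count (`NA` to accept any).
#' @return An `ecg_record`.
#' @export
read_ecg_csv <- function(path, n_leads = 12) {
  lines <- readLines(path, n = 10)
  hdr <- grep("^# *[A-Za-z_]+=", lines, value = TRUE)
  meta <- list(record_id = basename(path), fs = NA_real_, label = NULL)
  for (h in hdr) {
    kv <- strsplit(sub("^# *", "", h), "=", fixed = TRUE)[[1]]
    if (kv[1] == "record_id") meta$record_id <- kv[2]
    if (kv[1] == "fs") meta$fs <- as.numeric(kv[2])
    if (kv[1] == "label" && length(kv) > 1 && nzchar(kv[2])) meta$label <- kv[2]
  }
  if (is.na(meta$fs)) stop("unreadable header: missing 'fs' comment line")
  df <- read.csv(path, comment.char = "#")
  if (!is.na(n_leads) && ncol(df) != n_leads)
    stop(sprintf("expected %d leads, found %d columns", n_leads, ncol(df)))
  if (!is.null(meta$label) && !(meta$label %in% HHDR_CLASSES))
    stop(sprintf("unknown label '%s'", meta$label))
  structure(list(record_id = meta$record_id,
                 signals = as.matrix(sapply(df, as.numeric)),
                 fs = meta$fs, label = meta$label),
            class = "ecg_record")
}

#' Serialize a rule library to JSON
#'
#' One object per rule: class, band, kind, antecedent/consequent item arrays,
#' support, confidence.
#'
#' @param library A `rule_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_library_json <- function(library, path) {
  objs <- lapply(seq_len(nrow(library)), function(i) list(
    class = library$class_label[i], band = library$band[i],
    kind = library$kind[i],
    antecedent = as.list(split_items(library$antecedent[i])),
    consequent = as.list(split_items(library$consequent[i])),
    support = library$support[i], confidence = library$confidence[i]))
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rule library from JSON
#'
#' @param path JSON path written by [write_rule_library_json()].
#' @return A `rule_library` data frame.
#' @export
read_rule_library_json <- function(path) {
  objs <- jsonlite::read_json(path)
  lib <- do.call(rbind, lapply(objs, function(o) data.frame(
    class_label = o$class, band = o$band, kind = o$kind,
    antecedent = canon_items(unlist(o$antecedent)),
    consequent = canon_items(unlist(o$consequent)),
    support = o$support, confidence = o$confidence,
    stringsAsFactors = FALSE)))
  class(lib) <- c("rule_library", "data.frame")
  lib
}

#' Write an evaluation result to JSON
#'
#' @param result An `hhdr_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(result, path) {
  out <- list(task = result$task, accuracy = result$accuracy,
              n_test = result$n_test, seed = result$seed,
              confusion = as.data.frame(result$confusion),
              precision = as.list(result$precision),
              recall = as.list(result$recall))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Every stage block (`filters`, `rpeak`, `stft`, `mining`, `forest`) is
#' optional and falls back to its defaults; unknown blocks or keys are
#' rejected.
#'
#' @param path YAML path.
#' @return An [hhdr_config()].
#' @export
read_hhdr_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  builders <- list(filters = filter_config, rpeak = rpeak_config,
                   stft = stft_config, mining = mining_config,
                   forest = forest_config)
  extra <- setdiff(names(doc), names(builders))
  if (length(extra) > 0)
    stop(sprintf("unknown config block(s): %s", paste(extra, collapse = ", ")))
  args <- list()
  for (blk in names(builders)) {
    given <- doc[[blk]] %||% list()
    allowed <- names(formals(builders[[blk]]))
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0)
      stop(sprintf("unknown key(s) in '%s': %s", blk, paste(bad, collapse = ", ")))
    args[[blk]] <- do.call(builders[[blk]], given)
  }
  do.call(hhdr_config, args)
}
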