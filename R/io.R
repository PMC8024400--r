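#' Write / read a similarity matrix as CSV with a task-id header
#'
#' @param sim a `similarity_matrix` (or plain matrix).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(sim, path) {
  v <- if (inherits(sim, "similarity_matrix")) sim$values else as.matrix(sim)
  if (is.null(rownames(v))) dimnames(v) <- list(paste0("task", seq_len(nrow(v))),
                                                paste0("task", seq_len(nrow(v))))
  utils::write.csv(v, path)
  invisible(path)
}

#' @param path CSV path written by [write_similarity_csv()].
#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}

#' Write a feature table as CSV plus a JSON manifest
#'
#' One row per event with `subject`, `task`, `block` label columns before
#' the features; the manifest records the metadata.
#'
#' @param ft a `feature_table`.
#' @param stem path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return The CSV path, invisibly.
#' @export
write_feature_table <- function(ft, stem) {
  df <- data.frame(subject = ft$subject, task = ft$y, block = ft$block)
  df <- cbind(df, as.data.frame(ft$X))
  csv <- paste0(stem, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- ft$meta
  meta$edge_index <- NULL
  meta$n_events <- nrow(ft$X)
  meta$n_features <- ncol(ft$X)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csv)
}

#' @param stem path stem used by [write_feature_table()].
#' @rdname write_feature_table
#' @export
read_feature_table <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  feature_table(as.matrix(df[, -(1:3)]), df$task, df$subject, df$block,
                meta = as.list(meta))
}

#' Read BIDS-style events from TSV
#'
#' Expects at least `onset` and `duration` columns; `trial_type` of the
#' form `task<k>` is parsed into a task index when present.
#'
#' @param path TSV path.
#' @return Data frame with `onset`, `duration` and, when parseable,
#'   `task`.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path)
  if (!all(c("onset", "duration") %in% names(ev)))
    stop("events TSV must have onset and duration columns")
  if ("trial_type" %in% names(ev)) {
    task <- suppressWarnings(as.integer(sub("^task", "", ev$trial_type)))
    if (!anyNA(task)) ev$task <- task
  }
  ev
}
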