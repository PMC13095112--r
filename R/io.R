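#' Read and write embedding matrices and label files
#'
#' The on-disk embedding format is a TSV whose first column (`user_id` or
#' `tweet_id`) holds row identifiers and whose remaining columns are the
#' embedding dimensions. Labels travel as a two-column CSV
#' (`user_id`, `party`).
#'
#' @param file path.
#' @return `readEmbeddingsTSV()` returns a numeric matrix with row ids as
#'   rownames.
#' @export
readEmbeddingsTSV <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname readEmbeddingsTSV
#' @param m numeric matrix with ids as rownames.
#' @param idColumn name of the identifier column.
#' @export
writeEmbeddingsTSV <- function(m, file, idColumn = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(idColumn, colnames(m) %||% paste0("d", seq_len(ncol(m))))
  utils::write.table(df, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' @rdname readEmbeddingsTSV
#' @return `readLabelsCSV()` returns a named character vector (id ->
#'   label).
#' @export
readLabelsCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname readEmbeddingsTSV
#' @param embeddingsFile,labelsFile paths to the matrix TSV and label
#'   CSV; ids are matched (users present in both are kept).
#' @return `readEmbeddedPopulation()` returns an
#'   [EmbeddedPopulation-class].
#' @export
readEmbeddedPopulation <- function(embeddingsFile, labelsFile) {
  m <- readEmbeddingsTSV(embeddingsFile)
  lab <- readLabelsCSV(labelsFile)
  ids <- intersect(rownames(m), names(lab))
  if (!length(ids)) stop("no user ids shared between embeddings and labels")
  EmbeddedPopulation(m[ids, , drop = FALSE], lab[ids], ids)
}

#' Read and write tweet records as JSONL
#'
#' One JSON object per line with fields `tweet_id`, `user_id`,
#' `timestamp` (ISO date), `text`, `hashtags` (array) and, when present,
#' `topics` (array).
#'
#' @param file path.
#' @return data.frame with a `hashtags` (and possibly `topics`)
#'   list-column.
#' @export
readTweetsJSONL <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(
    tweet_id = vapply(recs, function(r) as.character(r$tweet_id), ""),
    user_id = vapply(recs, function(r) as.character(r$user_id), ""),
    timestamp = as.Date(vapply(recs, function(r) as.character(r$timestamp), "")),
    text = vapply(recs, function(r) as.character(r$text %||% ""), ""),
    stringsAsFactors = FALSE)
  df$hashtags <- lapply(recs, function(r) as.character(unlist(r$hashtags)))
  if (any(vapply(recs, function(r) !is.null(r$topics), logical(1))))
    df$topics <- lapply(recs, function(r) as.character(unlist(r$topics)))
  df
}

#' @rdname readTweetsJSONL
#' @param tweets tweet data.frame.
#' @export
writeTweetsJSONL <- function(tweets, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(tweets))) {
    rec <- list(tweet_id = tweets$tweet_id[i],
                user_id = tweets$user_id[i],
                timestamp = as.character(tweets$timestamp[i]),
                text = tweets$text[i],
                hashtags = I(tweets$hashtags[[i]]))
    if (!is.null(tweets$topics)) rec$topics <- I(tweets$topics[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
               con)
  }
  invisible(file)
}

#' Lexicons as YAML
#'
#' Party lexicons serialize as `keywords:` (party -> list) plus
#' `families:` (party -> family); topic lexicons as `topics:` plus
#' `min_count:`.
#'
#' @param file path.
#' @return the lexicon object.
#' @export
readPartyLexiconYAML <- function(file) {
  y <- yaml::read_yaml(file)
  partyLexicon(y$keywords, unlist(y$families))
}

#' @rdname readPartyLexiconYAML
#' @param lexicon the lexicon to write.
#' @export
writePartyLexiconYAML <- function(lexicon, file) {
  yaml::write_yaml(list(keywords = lexicon$keywords,
                        families = as.list(lexicon$familyMap)), file)
  invisible(file)
}

#' @rdname readPartyLexiconYAML
#' @export
readTopicLexiconYAML <- function(file) {
  y <- yaml::read_yaml(file)
  topicLexicon(y$topics, y$min_count %||% 100L)
}

#' @rdname readPartyLexiconYAML
#' @export
writeTopicLexiconYAML <- function(lexicon, file) {
  yaml::write_yaml(list(topics = lexicon$topics,
                        min_count = lexicon$minCount), file)
  invisible(file)
}

#' Write a polarization series as tidy CSV
#'
#' Columns: `period`, `region`, `topic`, `poli`, `defined`, `method`,
#' `nUsers`, `volume`, plus the per-family count columns.
#'
#' @param series a series from [computeSeries()].
#' @param file path.
#' @export
writeSeriesCSV <- function(series, file) {
  utils::write.csv(as.data.frame(series), file, row.names = FALSE)
  invisible(file)
}
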