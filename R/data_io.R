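#' Normalize item labels
#'
#' Lower-cases, trims leading/trailing whitespace and collapses internal
#' whitespace runs to single spaces. No stemming or synonym mapping is
#' applied; transcripts are assumed pre-cleaned. The normalization is
#' idempotent.
#'
#' @param x character vector of raw item labels.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Construct a fluency list
#'
#' One ordered response sequence from one participant visit. Repeats
#' (perseverations) are kept verbatim; the model consumes them.
#'
#' @param participant_id,list_id identifier strings.
#' @param items character vector of responses in production order
#'   (length >= 1); labels are normalized with [normalize_label()].
#' @return an object of class `fluency_list`.
#' @export
fluency_list <- function(participant_id, list_id, items) {
  items <- normalize_label(items)
  if (length(items) < 1L) stop("a fluency list needs at least one item")
  if (any(!nzchar(items))) stop("empty item label after normalization")
  structure(list(participant_id = as.character(participant_id),
                 list_id = as.character(list_id),
                 items = items),
            class = "fluency_list")
}

#' @export
print.fluency_list <- function(x, ...) {
  cat(sprintf("<fluency_list %s/%s: %d items>\n  %s\n",
              x$participant_id, x$list_id, length(x$items),
              paste(x$items, collapse = ", ")))
  invisible(x)
}

#' Construct a fluency corpus
#'
#' All fluency lists of one participant (under one diagnosis). The
#' vocabulary is the set of unique labels across lists, in first-occurrence
#' order; its size is the `M` of the estimation model.
#'
#' @param participant_id identifier string.
#' @param lists list of [fluency_list()] objects.
#' @return an object of class `fluency_corpus` with elements
#'   `participant_id`, `lists`, `vocabulary`.
#' @export
fluency_corpus <- function(participant_id, lists) {
  if (length(lists) < 1L) stop("a corpus needs at least one list")
  ok <- vapply(lists, inherits, logical(1), "fluency_list")
  if (!all(ok)) stop("all elements must be fluency_list objects")
  vocab <- unique(unlist(lapply(lists, `[[`, "items")))
  structure(list(participant_id = as.character(participant_id),
                 lists = lists, vocabulary = vocab),
            class = "fluency_corpus")
}

#' @export
print.fluency_corpus <- function(x, ...) {
  cat(sprintf("<fluency_corpus %s: %d lists, %d unique items>\n",
              x$participant_id, length(x$lists), length(x$vocabulary)))
  invisible(x)
}

#' Read a fluency corpus file
#'
#' Delimited text (comma or tab, auto-detected from the header line) with
#' header columns `participant_id`, `list_id`, `position`, `item`. Items are
#' normalized; within each list rows are ordered by position.
#'
#' @param path file path.
#' @return named list of [fluency_corpus()] objects, one per participant.
#' @export
read_fluency_file <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   stringsAsFactors = FALSE, comment.char = "",
                   colClasses = "character")
  required <- c("participant_id", "list_id", "position", "item")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("fluency file is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$position <- as.integer(df$position)
  key <- paste(df$participant_id, df$list_id, df$position, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf(
      "duplicate (participant, list, position) at row %d: (%s, %s, %d)",
      bad, df$participant_id[bad], df$list_id[bad], df$position[bad]))
  }
  out <- list()
  for (pid in unique(df$participant_id)) {
    dp <- df[df$participant_id == pid, , drop = FALSE]
    lists <- lapply(unique(dp$list_id), function(lid) {
      dl <- dp[dp$list_id == lid, , drop = FALSE]
      dl <- dl[order(dl$position), , drop = FALSE]
      fluency_list(pid, lid, dl$item)
    })
    out[[pid]] <- fluency_corpus(pid, lists)
  }
  out
}

#' Write fluency corpora to a delimited file
#'
#' @param corpora a `fluency_corpus` or list of them.
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_fluency_file <- function(corpora, path, sep = ",") {
  if (inherits(corpora, "fluency_corpus")) corpora <- list(corpora)
  rows <- do.call(rbind, lapply(corpora, function(cp) {
    do.call(rbind, lapply(cp$lists, function(fl) {
      data.frame(participant_id = fl$participant_id, list_id = fl$list_id,
                 position = seq_along(fl$items), item = fl$items,
                 stringsAsFactors = FALSE)
    }))
  }))
  write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Corpus summaries used by the cohort pipeline
#'
#' @param corpus a [fluency_corpus()].
#' @return `mean_list_length()`: mean number of responses per list.
#' @export
mean_list_length <- function(corpus) {
  mean(vapply(corpus$lists, function(l) length(l$items), numeric(1)))
}
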