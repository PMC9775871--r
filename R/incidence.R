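#' Fluency datasets: participants-by-words incidence
#'
#' A `fluency_dataset` holds the binary incidence matrix of a semantic
#' fluency task — one row per participant, one column per distinct word the
#' whole sample produced, cell = 1 iff that participant produced the word —
#' together with language and semantic-category labels.
#'
#' @param incidence Binary matrix, participants x words, with dimnames.
#' @param language,category Optional labels (e.g. `"D1"`, `"animal"`).
#' @return An object of class `fluency_dataset`: a list with fields
#'   `incidence`, `word_labels`, `participants`, `language`, `category`.
#' @keywords internal
#' @export
new_fluency_dataset <- function(incidence, language = NA_character_,
                                category = NA_character_) {
  if (!is.matrix(incidence) || is.null(colnames(incidence))) {
    stop_bilexnet("`incidence` must be a matrix with column (word) names.", "validation")
  }
  if (!all(incidence %in% c(0L, 1L))) {
    stop_bilexnet("Incidence entries must all be 0 or 1.", "validation")
  }
  if (anyDuplicated(colnames(incidence))) {
    stop_bilexnet("Word labels must be unique.", "validation")
  }
  if (nrow(incidence) < 2L || ncol(incidence) < 2L) {
    stop_bilexnet("A fluency dataset needs at least 2 participants and 2 words.",
                  "validation")
  }
  if (is.null(rownames(incidence))) {
    rownames(incidence) <- sprintf("p%02d", seq_len(nrow(incidence)))
  }
  storage.mode(incidence) <- "integer"
  structure(
    list(
      incidence = incidence,
      word_labels = colnames(incidence),
      participants = rownames(incidence),
      language = language,
      category = category
    ),
    class = "fluency_dataset"
  )
}

#' @export
print.fluency_dataset <- function(x, ...) {
  cat(sprintf("<fluency_dataset> %d participants x %d words (%s / %s)\n",
              nrow(x$incidence), ncol(x$incidence),
              x$language %||% NA, x$category %||% NA))
  cat(sprintf("  words produced per participant: median %g, range %d-%d\n",
              stats::median(rowSums(x$incidence)),
              min(rowSums(x$incidence)), max(rowSums(x$incidence))))
  invisible(x)
}

#' @describeIn new_fluency_dataset Wide tibble view: `participant` column
#'   followed by one 0/1 column per word.
#' @param x A `fluency_dataset`.
#' @param ... Unused.
#' @export
as_tibble.fluency_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(participant = x$participants),
    tibble::as_tibble(as.data.frame(x$incidence))
  )
}

#' Coerce a wide data frame to a fluency dataset
#'
#' Accepts the wide CSV layout (a `participant` id column — or any single
#' non-numeric first column — followed by one 0/1 column per word).
#'
#' @param data A `fluency_dataset` or a wide data frame.
#' @param language,category Labels, used when `data` is a plain data frame.
#' @return A `fluency_dataset`.
#' @export
as_fluency_dataset <- function(data, language = NA_character_,
                               category = NA_character_) {
  if (inherits(data, "fluency_dataset")) {
    return(data)
  }
  if (!is.data.frame(data)) {
    stop_bilexnet("`data` must be a fluency_dataset or a data frame.", "validation")
  }
  id_col <- if (!is.numeric(data[[1L]])) 1L else integer(0)
  words <- if (length(id_col)) data[-id_col] else data
  inc <- as.matrix(words)
  rownames(inc) <- if (length(id_col)) as.character(data[[1L]]) else NULL
  new_fluency_dataset(inc, language = language, category = category)
}

#' Build an incidence matrix from raw fluency responses
#'
#' Converts long-format fluency responses (one row per produced word) into a
#' participants-by-words binary incidence matrix.  Columns are the union of
#' distinct words over all participants in order of first appearance;
#' within-participant repetitions collapse to a single 1.  Word strings are
#' assumed already normalised (whitespace-trimmed, transcription variants
#' resolved upstream).
#'
#' @param responses Data frame with columns `participant` and `word` (other
#'   columns, e.g. `position`, are ignored).  A row with `NA` or empty `word`
#'   records a participant who produced nothing: they are retained as an
#'   all-zero row, with a warning.
#' @param language,category Labels stored on the result.
#' @return A `fluency_dataset`.
#' @export
#' @examples
#' build_incidence(data.frame(participant = c("a", "a", "b"),
#'                            word = c("cat", "dog", "dog")))
build_incidence <- function(responses, language = NA_character_,
                            category = NA_character_) {
  if (!is.data.frame(responses) || nrow(responses) == 0L) {
    stop_bilexnet("`responses` must be a non-empty data frame.", "validation")
  }
  check_columns(responses, c("participant", "word"), "`responses`")
  participant <- as.character(responses$participant)
  word <- as.character(responses$word)
  blank <- is.na(word) | word == ""

  participants <- unique(participant)
  words <- unique(word[!blank])
  if (length(words) == 0L) {
    stop_bilexnet("No non-empty words in `responses`.", "validation")
  }
  inc <- matrix(0L, nrow = length(participants), ncol = length(words),
                dimnames = list(participants, words))
  inc[cbind(match(participant[!blank], participants), match(word[!blank], words))] <- 1L
  empty <- rowSums(inc) == 0L
  if (any(empty)) {
    rlang::warn(sprintf("Participant(s) with zero words retained as all-zero rows: %s",
                        paste(participants[empty], collapse = ", ")))
  }
  new_fluency_dataset(inc, language = language, category = category)
}

#' Long view of a fluency dataset
#'
#' Inverse of [build_incidence()]: one row per (participant, produced word),
#' words in incidence-column order within participant.
#'
#' @param dataset A `fluency_dataset`.
#' @return A tibble with columns `participant`, `word`.
#' @export
fluency_responses <- function(dataset) {
  dataset <- as_fluency_dataset(dataset)
  idx <- which(dataset$incidence == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(
    participant = dataset$participants[idx[, 1L]],
    word = dataset$word_labels[idx[, 2L]]
  )
}

#' Read and write fluency datasets as CSV
#'
#' The on-disk format is the wide layout of [as_tibble.fluency_dataset()]; a
#' JSON sidecar (`<path>.json`) records labels and, for simulated data, the
#' generating spec and seed.
#'
#' @param dataset A `fluency_dataset`.
#' @param path CSV file path.
#' @return `write_fluency_csv()` returns `path` invisibly;
#'   `read_fluency_csv()` returns a `fluency_dataset`.
#' @export
write_fluency_csv <- function(dataset, path) {
  dataset <- as_fluency_dataset(dataset)
  readr::write_csv(as_tibble(dataset), path)
  meta <- list(language = dataset$language, category = dataset$category)
  spec <- attr(dataset, "sim_spec")
  if (!is.null(spec)) {
    meta$sim_spec <- unclass(spec)
    meta$sim_spec$clusters <- as.list(spec$clusters)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fluency_csv
#' @export
read_fluency_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".json")
  language <- NA_character_
  category <- NA_character_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    language <- meta$language %||% NA_character_
    category <- meta$category %||% NA_character_
  }
  as_fluency_dataset(as.data.frame(data), language = language, category = category)
}
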