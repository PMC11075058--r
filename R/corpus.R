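#' Construct a chord corpus
#'
#' A chord corpus is an ordered collection of songs, each song a character
#' vector of chord labels. Transitions are only ever counted within a song;
#' songs are treated as independent sequences.
#'
#' @param songs list of character vectors, one per song. Labels must be
#'   non-empty strings; equality is exact string match.
#' @return An object of class `chord_corpus` with elements `songs` (the list)
#'   and `vocabulary` (sorted unique labels).
#' @examples
#' cp <- chord_corpus(list(c("C", "G", "Am", "F"), c("C", "F", "G")))
#' cp$vocabulary
#' @export
chord_corpus <- function(songs) {
  if (!is.list(songs) || length(songs) == 0L)
    stop("'songs' must be a non-empty list of character vectors")
  songs <- lapply(songs, as.character)
  if (any(vapply(songs, function(s) any(is.na(s) | !nzchar(s)), logical(1))))
    stop("chord labels must be non-empty strings")
  structure(
    list(songs = songs, vocabulary = sort(unique(unlist(songs)))),
    class = "chord_corpus"
  )
}

#' @export
print.chord_corpus <- function(x, ...) {
  ntok <- sum(lengths(x$songs))
  cat("chord_corpus:", length(x$songs), "songs,", ntok, "tokens,",
      length(x$vocabulary), "distinct chords\n")
  invisible(x)
}

#' Read a chord corpus from disk
#'
#' Two plain-text layouts are supported: one song per line with
#' whitespace-separated chord tokens (`format = "lines"`), or a delimited
#' table with columns `song_id`, `position`, `chord_label`
#' (`format = "table"`).
#'
#' @param path file path.
#' @param format `"lines"` or `"table"`.
#' @param sep field separator for `format = "table"`.
#' @return A [chord_corpus()].
#' @export
read_chord_corpus <- function(path, format = c("lines", "table"), sep = "\t") {
  format <- match.arg(format)
  if (format == "lines") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    songs <- strsplit(trimws(lines), "[[:space:]]+")
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    need <- c("song_id", "position", "chord_label")
    if (!all(need %in% names(tab)))
      stop("corpus table must have columns: ", paste(need, collapse = ", "))
    tab <- tab[order(tab$song_id, tab$position), ]
    songs <- split(tab$chord_label, tab$song_id)
    songs <- unname(songs)
  }
  chord_corpus(songs)
}

#' Write a chord corpus as plain text, one song per line
#'
#' @param corpus a [chord_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chord_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "chord_corpus"))
  writeLines(vapply(corpus$songs, paste, character(1), collapse = " "), path)
  invisible(path)
}
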