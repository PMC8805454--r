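#' Read a raw valence/arousal/dominance lexicon
#'
#' Reads a delimited word table of crowdsourced affect norms rated on the
#' 1-9 scale, one row per lemma. Both comma- and tab-separated files are
#' accepted (the delimiter is sniffed from the header line), and column
#' names are remapped through `col_map` so published norm files with
#' nonstandard headers load without editing.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param col_map Named character vector mapping the canonical names
#'   `word`, `valence`, `arousal`, `dominance` to the columns in the file.
#' @return A tibble with columns `word`, `valence_raw`, `arousal_raw`,
#'   `dominance_raw`; words lowercase, alphabetic and unique, ratings
#'   within \[1, 9\].
#' @seealso [standardize_lexicon()] for the z-transform applied before any
#'   scoring.
#' @export
load_lexicon <- function(path,
                         col_map = c(word = "word", valence = "valence",
                                     arousal = "arousal",
                                     dominance = "dominance")) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    stop("lexicon format error: empty file: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(raw) == 0L) {
    stop("lexicon format error: no data rows in ", path, call. = FALSE)
  }
  needed <- c("word", "valence", "arousal", "dominance")
  if (!all(needed %in% names(col_map))) {
    stop("col_map must name word, valence, arousal and dominance columns",
         call. = FALSE)
  }
  missing_cols <- setdiff(unname(col_map[needed]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("lexicon format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  entries <- tibble::tibble(
    word = tolower(as.character(raw[[col_map[["word"]]]])),
    valence_raw = as.numeric(raw[[col_map[["valence"]]]]),
    arousal_raw = as.numeric(raw[[col_map[["arousal"]]]]),
    dominance_raw = as.numeric(raw[[col_map[["dominance"]]]])
  )
  validate_lexicon_entries(entries)
  entries
}

#' Validate raw lexicon entries
#'
#' Enforces the raw-entry contract: nonempty, purely alphabetic, unique
#' words; all three ratings numeric and within the 1-9 rating scale.
#'
#' @param entries A data frame with columns `word`, `valence_raw`,
#'   `arousal_raw`, `dominance_raw`.
#' @return `entries`, invisibly, if valid; otherwise an error.
#' @export
validate_lexicon_entries <- function(entries) {
  bad_word <- !grepl("^[a-z]+$", entries$word)
  if (any(bad_word)) {
    stop("lexicon validation error: non-alphabetic or empty word(s): ",
         paste(head(entries$word[bad_word], 5L), collapse = ", "),
         call. = FALSE)
  }
  dup <- entries$word[duplicated(entries$word)]
  if (length(dup) > 0L) {
    stop("lexicon validation error: duplicate word(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  ratings <- as.matrix(entries[, c("valence_raw", "arousal_raw",
                                   "dominance_raw")])
  if (anyNA(ratings)) {
    stop("lexicon validation error: missing rating(s)", call. = FALSE)
  }
  out_of_range <- ratings < 1 | ratings > 9
  if (any(out_of_range)) {
    i <- which(rowSums(out_of_range) > 0L)
    stop("lexicon validation error: rating outside [1, 9] for word(s): ",
         paste(head(entries$word[i], 5L), collapse = ", "), call. = FALSE)
  }
  invisible(entries)
}

#' Z-standardize a raw lexicon
#'
#' Converts the raw 1-9 ratings into z-scores relative to the loaded
#' lexicon itself, per dimension, so downstream scores read as SDs above or
#' below the average rated word. The raw mean and sample SD used for each
#' dimension are retained so the transform is auditable and invertible.
#'
#' @param entries Raw entries as returned by [load_lexicon()].
#' @return An object of class `affect_lexicon`: a list with
#'   `scores` (tibble `word`, `V`, `A`, `D`) and `standardization`
#'   (tibble `dimension`, `mean_raw`, `sd_raw`).
#' @export
standardize_lexicon <- function(entries) {
  validate_lexicon_entries(entries)
  if (nrow(entries) < 2L) {
    stop("degenerate lexicon: need at least 2 entries to standardize",
         call. = FALSE)
  }
  dims <- c(V = "valence_raw", A = "arousal_raw", D = "dominance_raw")
  mu <- vapply(dims, function(col) mean(entries[[col]]), numeric(1))
  sigma <- vapply(dims, function(col) .sd_fun(entries[[col]]), numeric(1))
  if (any(sigma == 0)) {
    stop("degenerate lexicon: constant ratings in dimension(s): ",
         paste(names(sigma)[sigma == 0], collapse = ", "), call. = FALSE)
  }
  scores <- tibble::tibble(
    word = entries$word,
    V = (entries$valence_raw - mu[["V"]]) / sigma[["V"]],
    A = (entries$arousal_raw - mu[["A"]]) / sigma[["A"]],
    D = (entries$dominance_raw - mu[["D"]]) / sigma[["D"]]
  )
  structure(
    list(
      scores = scores,
      standardization = tibble::tibble(
        dimension = names(dims),
        mean_raw = unname(mu),
        sd_raw = unname(sigma)
      )
    ),
    class = "affect_lexicon"
  )
}

#' @export
print.affect_lexicon <- function(x, ...) {
  cat("<affect_lexicon> ", nrow(x$scores), " words\n", sep = "")
  s <- x$standardization
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: raw mean %.3f, raw SD %.3f\n",
                s$dimension[i], s$mean_raw[i], s$sd_raw[i]))
  }
  invisible(x)
}

#' Write a standardized lexicon to TSV
#'
#' @param lexicon An `affect_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "affect_lexicon"))
  write.table(lexicon$scores, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
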