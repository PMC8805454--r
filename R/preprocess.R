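#' Clean a headline title into analysis tokens
#'
#' Lowercases the title, splits on (and thereby removes) every
#' non-alphabetic character, and drops stop words. Token order is
#' preserved; tokens emptied by character stripping (e.g. "19", "3") are
#' dropped. So "covid-19" tokenizes to "covid".
#'
#' @param title A single character string (may be empty).
#' @param stopwords Character vector of words to remove; defaults to
#'   [default_stopwords()].
#' @return Character vector of lowercase alphabetic tokens (possibly
#'   empty).
#' @export
preprocess_title <- function(title, stopwords = default_stopwords()) {
  stopifnot(is.character(title), length(title) == 1L)
  tokens <- strsplit(tolower(title), "[^a-z]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens[!tokens %in% stopwords]
}

#' Map cleaned tokens to lexicon affect scores
#'
#' Out-of-vocabulary tokens are silently dropped; repeated words are kept
#' as separate rows so daily statistics are token-weighted.
#'
#' @param tokens Character vector of cleaned tokens.
#' @param lexicon An `affect_lexicon` from [standardize_lexicon()].
#' @return Tibble with one row per mapped token occurrence: `word`, `V`,
#'   `A`, `D`.
#' @export
map_tokens <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "affect_lexicon"))
  idx <- match(tokens, lexicon$scores$word)
  lexicon$scores[idx[!is.na(idx)], , drop = FALSE]
}

#' Read a headline table
#'
#' @param path CSV with columns `state`, `date` (ISO-8601), `title`.
#' @return Tibble with `state` (character), `date` (Date), `title`.
#' @export
read_headlines <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("state", "date", "title")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("headline format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    state = as.character(raw$state),
    date = as.Date(raw$date),
    title = as.character(raw$title)
  )
  if (anyNA(out$date)) {
    stop("headline format error: unparseable date(s)", call. = FALSE)
  }
  keep <- nzchar(trimws(out$title))
  out[keep, , drop = FALSE]
}

#' Pool headline tokens by state and publication date
#'
#' Cleans every title, maps surviving tokens to the lexicon, and
#' concatenates all of a day's tokens (repeats kept) into one pool per
#' (state, date) that has at least one headline. Days whose headlines map
#' zero words still yield a pool (with an empty token table) so downstream
#' features can be marked missing rather than the day silently vanishing.
#'
#' The corpus-level mapping rate n_mapped / n_raw — the fraction of
#' non-stop-word tokens found in the lexicon — is attached as attribute
#' `mapping_rate` and is typically well below 1 on real corpora.
#'
#' @param headlines Tibble with `state`, `date`, `title` (see
#'   [read_headlines()]).
#' @param lexicon An `affect_lexicon`.
#' @param stopwords Stop-word vector; defaults to [default_stopwords()].
#' @return Tibble with one row per (state, date): `state`, `date`,
#'   `n_raw_tokens`, `n_mapped`, and a list-column `tokens` of per-token
#'   affect tibbles. Attribute `mapping_rate` holds the corpus rate.
#' @export
pool_daily <- function(headlines, lexicon, stopwords = default_stopwords()) {
  stopifnot(all(c("state", "date", "title") %in% names(headlines)))
  token_lists <- lapply(headlines$title, preprocess_title,
                        stopwords = stopwords)
  keys <- paste(headlines$state, headlines$date, sep = "\r")
  split_tokens <- split(token_lists, keys)
  first <- !duplicated(keys)
  pools <- tibble::tibble(
    state = headlines$state[first],
    date = headlines$date[first],
    key = keys[first]
  )
  pools <- pools[order(pools$state, pools$date), , drop = FALSE]
  pooled <- lapply(split_tokens[pools$key],
                   function(lst) unlist(lst, use.names = FALSE))
  pools$n_raw_tokens <- unname(vapply(pooled, length, integer(1)))
  pools$tokens <- unname(lapply(pooled, map_tokens, lexicon = lexicon))
  pools$n_mapped <- vapply(pools$tokens, nrow, integer(1))
  pools$key <- NULL
  n_raw <- sum(pools$n_raw_tokens)
  attr(pools, "mapping_rate") <-
    if (n_raw > 0L) sum(pools$n_mapped) / n_raw else NA_real_
  pools
}
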