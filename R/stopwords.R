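#' Default English stop-word list
#'
#' A standard list of English function words (articles, pronouns,
#' prepositions, auxiliaries and common contraction stems) removed from
#' headline text before lexicon mapping. Analyses of real corpora usually
#' extend it with corpus-specific additions — location names, media
#' boilerplate ("video", "subscribe"), and proper nouns that collide with
#' lexicon lemmas — via the `extra` argument or a plain-text additions file
#' (one word per line) passed to [read_stopword_additions()].
#'
#' @param extra Character vector of additional words to include.
#' @return A lowercase character vector of stop words.
#' @export
default_stopwords <- function(extra = character()) {
  base <- c(
    "a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "aren", "as", "at", "be", "because", "been",
    "before", "being", "below", "between", "both", "but", "by", "can",
    "cannot", "could", "couldn", "did", "didn", "do", "does", "doesn",
    "doing", "don", "down", "during", "each", "few", "for", "from",
    "further", "had", "hadn", "has", "hasn", "have", "haven", "having",
    "he", "her", "here", "hers", "herself", "him", "himself", "his", "how",
    "i", "if", "in", "into", "is", "isn", "it", "its", "itself", "just",
    "ll", "me", "mightn", "more", "most", "mustn", "my", "myself", "needn",
    "no", "nor", "not", "now", "o", "of", "off", "on", "once", "only",
    "or", "other", "our", "ours", "ourselves", "out", "over", "own", "re",
    "s", "same", "shan", "she", "should", "shouldn", "so", "some", "such",
    "t", "than", "that", "the", "their", "theirs", "them", "themselves",
    "then", "there", "these", "they", "this", "those", "through", "to",
    "too", "under", "until", "up", "ve", "very", "was", "wasn", "we",
    "were", "weren", "what", "when", "where", "which", "while", "who",
    "whom", "why", "will", "with", "won", "would", "wouldn", "y", "you",
    "your", "yours", "yourself", "yourselves"
  )
  unique(c(base, tolower(extra)))
}

#' Read stop-word additions from a plain-text file
#'
#' @param path File with one word per line; blank lines and lines starting
#'   with `#` are ignored.
#' @return Character vector of lowercase words.
#' @export
read_stopword_additions <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
}
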