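# In-code fixtures shared across test files.

tiny_lexicon_entries <- function() {
  tibble::tibble(
    word = c("calm", "panic", "hope", "dread", "covid", "surge", "deaths",
             "peak"),
    valence_raw = c(7.5, 2.0, 8.0, 1.5, 3.0, 4.0, 1.8, 6.0),
    arousal_raw = c(2.0, 7.5, 4.5, 6.5, 5.5, 6.8, 6.0, 5.0),
    dominance_raw = c(6.5, 3.0, 6.0, 2.5, 4.0, 4.5, 3.2, 5.5)
  )
}

tiny_lexicon <- function() standardize_lexicon(tiny_lexicon_entries())

write_lexicon_fixture <- function(entries, sep = ",",
                                  header = c("word", "valence", "arousal",
                                             "dominance")) {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  lines <- c(paste(header, collapse = sep),
             apply(entries, 1, paste, collapse = sep))
  writeLines(lines, path)
  path
}

# a pool table shaped like pool_daily() output, built from explicit
# per-token (V, A, D) rows
make_pool <- function(state, date, vad) {
  tok <- tibble::tibble(word = sprintf("w%d", seq_len(nrow(vad))),
                        V = vad[, 1], A = vad[, 2], D = vad[, 3])
  tibble::tibble(state = state, date = as.Date(date),
                 n_raw_tokens = nrow(tok) + 2L,
                 tokens = list(tok), n_mapped = nrow(tok))
}
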