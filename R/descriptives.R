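#' The study's five pandemic-phase windows
#'
#' The collection period (2020-01-23 to 2020-10-22) splits into three
#' phases: Pre-pandemic (50 days, up to the national-emergency
#' proclamation), Early Response (26 days, ending with the last statewide
#' stay-at-home announcement on 2020-04-07), and Mid-pandemic (198 days),
#' the last subdivided into three equal 66-day partitions for temporal
#' parity. Windows are inclusive on both ends, non-overlapping, and tile
#' the 274-day period.
#'
#' @return Tibble with `name`, `start_date`, `end_date`, `length_days`.
#' @export
default_phase_windows <- function() {
  w <- tibble::tibble(
    name = c("Pre-pandemic", "Early Response",
             "Mid-pandemic 1", "Mid-pandemic 2", "Mid-pandemic 3"),
    start_date = as.Date(c("2020-01-23", "2020-03-13", "2020-04-08",
                           "2020-06-13", "2020-08-18")),
    end_date = as.Date(c("2020-03-12", "2020-04-07", "2020-06-12",
                         "2020-08-17", "2020-10-22"))
  )
  w$length_days <- as.integer(w$end_date - w$start_date) + 1L
  w
}

#' Root mean square of successive differences
#'
#' Day-to-day volatility of an ordered daily series: the square root of the
#' mean squared difference over successive pairs. Only pairs where both
#' adjacent positions are non-missing contribute; a gap contributes no
#' pair, so multi-day change is never conflated with daily change. The
#' series must be supplied on a complete (calendar-spaced) grid for
#' adjacency to mean adjacent days.
#'
#' @param series Numeric vector in time order; may contain `NA`.
#' @return RMSSD, or `NA_real_` when no valid successive pair exists.
#' @export
rmssd <- function(series) {
  if (length(series) < 2L) return(NA_real_)
  d <- diff(series)
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NA_real_)
  sqrt(mean(d^2))
}

#' Per-state, per-phase descriptives of daily mean affect
#'
#' For each state, phase window and affect dimension (V, A, D), computes
#' the mean, sample variance and RMSSD of the daily mean-affect series.
#' RMSSD is computed on the calendar grid of the window (missing days
#' enter as `NA`, so only truly adjacent days pair up).
#'
#' @param daily Output of [compute_daily_features()].
#' @param windows Phase windows; defaults to [default_phase_windows()].
#' @return Tibble: `state`, `window`, `dimension`, `n_days`, `mean`,
#'   `variance`, `rmssd` — one row per (state, window, dimension).
#' @export
phase_stats <- function(daily, windows = default_phase_windows()) {
  dims <- c(V = "mean_V", A = "mean_A", D = "mean_D")
  states <- sort(unique(daily$state))
  rows <- list()
  for (s in states) {
    ds <- daily[daily$state == s, , drop = FALSE]
    for (i in seq_len(nrow(windows))) {
      grid <- seq(windows$start_date[i], windows$end_date[i], by = "day")
      idx <- match(grid, ds$date)
      for (dim in names(dims)) {
        x <- ds[[dims[[dim]]]][idx]
        obs <- x[!is.na(x)]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          state = s,
          window = windows$name[i],
          dimension = dim,
          n_days = length(obs),
          mean = if (length(obs) >= 1L) mean(obs) else NA_real_,
          variance = if (length(obs) >= 2L) .var_fun(obs) else NA_real_,
          rmssd = rmssd(x)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Cross-state percentile ranks
#'
#' Rank-based percentiles with midrank tie handling, mapped linearly so the
#' minimum is 0 and the maximum 100 when n >= 2. A single value (or an
#' all-tied set) maps to 50. `NA` values get `NA` percentiles and do not
#' affect the ranks of the rest.
#'
#' @param values Named numeric vector (names are typically states).
#' @return Named numeric vector of percentiles in \[0, 100\].
#' @export
percentile_rank <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("percentile_rank: all values missing", call. = FALSE)
  out <- rep(NA_real_, length(values))
  names(out) <- names(values)
  x <- values[ok]
  n <- length(x)
  # midrank ties: an all-tied set gets rank (n+1)/2 everywhere, hence 50
  out[ok] <- if (n == 1L) 50 else (rank(x, ties.method = "average") - 1) /
    (n - 1) * 100
  out
}

#' Percentile-ranked phase RMSSD table across states
#'
#' The tabular backbone of a choropleth: for each window and dimension,
#' the cross-state percentile rank of phase RMSSD.
#'
#' @param stats Output of [phase_stats()].
#' @return Tibble: `window`, `dimension`, `state`, `percentile`.
#' @export
percentile_rank_table <- function(stats) {
  groups <- unique(stats[, c("window", "dimension")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- stats[stats$window == groups$window[i] &
                 stats$dimension == groups$dimension[i], , drop = FALSE]
    # a window with no usable series in any state (short collections)
    # yields NA percentiles rather than an error
    pct <- if (all(is.na(g$rmssd))) rep(NA_real_, nrow(g)) else
      unname(percentile_rank(setNames(g$rmssd, g$state)))
    tibble::tibble(
      window = groups$window[i],
      dimension = groups$dimension[i],
      state = g$state,
      percentile = pct
    )
  })
  dplyr::bind_rows(rows)
}

#' High-frequency words for a state's pooled headlines
#'
#' Selects word types whose total occurrence count across all of the
#' state's daily pools is at least 2 sample SDs above the mean type count,
#' returning counts with (V, A) coordinates for circumplex plotting tables.
#' With few or evenly used types nothing may exceed the threshold.
#'
#' @param pools [pool_daily()] rows for one state.
#' @param lexicon The `affect_lexicon` used for mapping.
#' @return Tibble: `word`, `count`, `V`, `A`, sorted by decreasing count.
#' @export
frequent_words <- function(pools, lexicon) {
  words <- unlist(lapply(pools$tokens, function(t) t$word),
                  use.names = FALSE)
  counts <- table(words)
  if (length(counts) < 2L) {
    stop("frequent_words: need at least 2 distinct word types",
         call. = FALSE)
  }
  type_sd <- .sd_fun(as.numeric(counts))
  threshold <- mean(counts) + 2 * type_sd
  # evenly used vocabularies (SD 0) have no standout words; without this
  # guard the >= comparison would select every type at the mean
  keep <- if (type_sd == 0) counts[0] else counts[counts >= threshold]
  keep <- keep[order(-as.numeric(keep), names(keep))]
  idx <- match(names(keep), lexicon$scores$word)
  tibble::tibble(
    word = names(keep),
    count = as.integer(keep),
    V = lexicon$scores$V[idx],
    A = lexicon$scores$A[idx]
  )
}
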