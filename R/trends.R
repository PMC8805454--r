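#' Mental-health search-term clusters
#'
#' The 17 tracked search terms partition into three construct-specific
#' clusters — Depression (7 terms), Anxiety (6) and Nonspecific (4) — whose
#' union is the All cluster.
#'
#' @return Named list of character vectors: `All`, `Depression`, `Anxiety`,
#'   `Nonspecific`.
#' @export
mh_term_clusters <- function() {
  depression <- c("apathy", "depression", "hopeless", "suicidal",
                  "suicide", "tired", "worthless")
  anxiety <- c("afraid", "anxiety", "avoiding", "restless", "tense",
               "worried")
  nonspecific <- c("angry", "insomnia", "irritable", "scattered")
  list(
    All = c(depression, anxiety, nonspecific),
    Depression = depression,
    Anxiety = anxiety,
    Nonspecific = nonspecific
  )
}

#' Published comparator volume tiers
#'
#' Trending-term search volumes are published in tiers ("50,000+",
#' "100,000+", ...). The usable absolute number is the tier floor — the
#' lowest volume consistent with the published tier — which makes the
#' resulting count estimates conservative.
#'
#' @param volume Numeric vector of (estimated or true) volumes.
#' @param tiers Ascending vector of published tier floors.
#' @return For each volume, the largest tier floor not exceeding it.
#' @export
comparator_tier_floor <- function(volume,
                                  tiers = c(20000, 50000, 100000, 200000,
                                            500000, 1e6, 2e6, 5e6, 1e7)) {
  stopifnot(all(diff(tiers) > 0))
  idx <- findInterval(volume, tiers)
  if (any(idx == 0)) {
    stop("comparator volume below the lowest published tier", call. = FALSE)
  }
  tiers[idx]
}

#' Rescale a normalized national total to an estimated absolute count
#'
#' The platform reports 0-100 normalized search interest; a same-query
#' comparator term with published absolute volume tier anchors the scale:
#' `MH_AdjTot = MH_NormTot * COMP_SV / COMP_NormTot`. The result is
#' summative across all states.
#'
#' @param mh_norm_total Normalized national value for the target term.
#' @param comp_search_volume Comparator tier floor (absolute searches).
#' @param comp_norm_total Normalized national value for the comparator;
#'   must be positive for the day to be usable.
#' @return Estimated national count (real; not yet floored).
#' @export
adjust_total <- function(mh_norm_total, comp_search_volume,
                         comp_norm_total) {
  if (any(comp_norm_total <= 0)) {
    stop("unusable comparator: normalized comparator total must be > 0",
         call. = FALSE)
  }
  mh_norm_total * comp_search_volume / comp_norm_total
}

#' Apportion a national count estimate to one state
#'
#' `MH_AdjState = floor(MH_AdjTot * (MH_NormState / MH_NormTot) *
#' (POP_State / POP_Tot))`: the national estimate scaled by the state's
#' share of normalized interest and its population share, rounded down to
#' a whole count.
#'
#' @param mh_adj_tot National estimate from [adjust_total()].
#' @param mh_norm_state Normalized state-level value for the target term.
#' @param mh_norm_total Normalized national value for the target term.
#' @param pop_state,pop_tot State and total populations.
#' @return Non-negative integer count (vectorized).
#' @export
apportion_state <- function(mh_adj_tot, mh_norm_state, mh_norm_total,
                            pop_state, pop_tot) {
  stopifnot(all(pop_tot > 0), all(pop_state > 0))
  zero_tot <- mh_norm_total == 0
  if (any(zero_tot & mh_norm_state != 0)) {
    stop("inconsistent record: state interest nonzero while national ",
         "total is zero", call. = FALSE)
  }
  share <- ifelse(zero_tot, 0, mh_norm_state / mh_norm_total)
  # guard against products that are mathematically integral landing a few
  # ulps below the integer before the floor
  as.integer(floor(mh_adj_tot * share * pop_state / pop_tot + 1e-9))
}

#' Estimate absolute state-level counts from normalized trends records
#'
#' Applies the comparator rescaling and state apportionment to a long
#' table of normalized records. Days with an unusable comparator
#' (`comp_norm_total` = 0) are dropped with a message rather than imputed;
#' the number dropped is attached as attribute `n_dropped_days`.
#'
#' @param trends Long tibble with columns `date`, `term`, `state`,
#'   `mh_norm_state`, `mh_norm_total`, `comp_norm_total`,
#'   `comp_search_volume`.
#' @param populations Tibble with `state`, `population` (unique states,
#'   positive populations).
#' @return Tibble `state`, `date`, `term`, `count` (integer, >= 0).
#' @export
estimate_state_counts <- function(trends, populations) {
  needed <- c("date", "term", "state", "mh_norm_state", "mh_norm_total",
              "comp_norm_total", "comp_search_volume")
  missing_cols <- setdiff(needed, names(trends))
  if (length(missing_cols) > 0L) {
    stop("trends format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(populations$state)) {
    stop("population table: duplicate state(s)", call. = FALSE)
  }
  stopifnot(all(populations$population > 0))
  pop_tot <- sum(populations$population)

  unusable <- trends$comp_norm_total <= 0
  if (any(unusable)) {
    dropped <- unique(trends$date[unusable])
    message("dropping ", length(dropped),
            " day(s) with unusable comparator (normalized total = 0)")
    trends <- trends[!unusable, , drop = FALSE]
  } else {
    dropped <- as.Date(character())
  }
  pop <- populations$population[match(trends$state, populations$state)]
  if (anyNA(pop)) {
    stop("population table: missing state(s): ",
         paste(unique(trends$state[is.na(pop)]), collapse = ", "),
         call. = FALSE)
  }
  adj_tot <- adjust_total(trends$mh_norm_total, trends$comp_search_volume,
                          trends$comp_norm_total)
  out <- tibble::tibble(
    state = trends$state,
    date = trends$date,
    term = trends$term,
    count = apportion_state(adj_tot, trends$mh_norm_state,
                            trends$mh_norm_total, pop, pop_tot)
  )
  attr(out, "n_dropped_days") <- length(dropped)
  out
}

#' Pool per-term counts into cluster sums
#'
#' Sums estimated counts over each cluster's term set per (state, date).
#' A (state, date) missing some but not all of a cluster's terms signals
#' upstream corruption and errors; a day absent entirely is simply absent
#' from the output.
#'
#' @param counts Output of [estimate_state_counts()].
#' @param clusters Named list of term sets; defaults to
#'   [mh_term_clusters()].
#' @return Tibble `state`, `date`, `cluster`, `count`.
#' @export
cluster_sums <- function(counts, clusters = mh_term_clusters()) {
  out <- list()
  for (cl in names(clusters)) {
    terms <- clusters[[cl]]
    sub <- counts[counts$term %in% terms, , drop = FALSE]
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$state, .data$date),
      count = sum(.data$count), n_terms = dplyr::n(), .groups = "drop"
    )
    partial <- agg$n_terms != length(terms)
    if (any(partial)) {
      bad <- agg[partial, , drop = FALSE]
      stop("cluster_sums: partial day for cluster ", cl, " at ",
           bad$state[1], " ", bad$date[1], " (", bad$n_terms[1], "/",
           length(terms), " terms present)", call. = FALSE)
    }
    agg$n_terms <- NULL
    agg$cluster <- cl
    out[[cl]] <- agg
  }
  dplyr::bind_rows(out)[, c("state", "date", "cluster", "count")]
}

#' Read a long-format normalized trends table
#'
#' Accepts the long dialect directly (columns as in
#' [estimate_state_counts()]) or a wide per-state dialect with one column
#' per state named `norm_<state>`, which is pivoted to long.
#'
#' @param path CSV file path.
#' @return Long tibble suitable for [estimate_state_counts()].
#' @export
read_trends <- function(path) {
  raw <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
  raw$date <- as.Date(raw$date)
  if ("mh_norm_state" %in% names(raw)) return(raw)
  state_cols <- grep("^norm_", names(raw), value = TRUE)
  if (length(state_cols) == 0L) {
    stop("trends format error: neither long ('mh_norm_state') nor wide ",
         "('norm_<state>') columns found", call. = FALSE)
  }
  long <- tidyr::pivot_longer(raw, dplyr::all_of(state_cols),
                              names_to = "state", names_prefix = "norm_",
                              values_to = "mh_norm_state")
  long
}

#' Read a state population table
#'
#' @param path CSV with columns `state`, `population`.
#' @return Tibble with unique states and positive integer populations.
#' @export
read_populations <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("state", "population") %in% names(raw)))
  out <- tibble::tibble(state = as.character(raw$state),
                        population = as.numeric(raw$population))
  if (anyDuplicated(out$state)) {
    stop("population table: duplicate state(s)", call. = FALSE)
  }
  if (any(out$population <= 0)) {
    stop("population table: nonpositive population(s)", call. = FALSE)
  }
  out
}
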