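#' Generate a synthetic affect lexicon
#'
#' Draws raw 1-9 valence/arousal/dominance ratings for invented lowercase
#' lemmas. Default per-dimension means and SDs match the scale properties
#' of the large crowdsourced English norms (valence 5.064/1.275, arousal
#' 4.211/0.986, dominance 5.185/0.938); draws are clipped to the rating
#' scale.
#'
#' @param n Number of words (>= 10).
#' @param means,sds Named numeric vectors (`V`, `A`, `D`) of raw-scale
#'   means and SDs; SDs must be positive.
#' @param seed Integer seed; the same seed reproduces the same lexicon.
#' @return Tibble of raw entries (`word`, `valence_raw`, `arousal_raw`,
#'   `dominance_raw`) accepted by [standardize_lexicon()].
#' @export
generate_lexicon <- function(n = 1000,
                             means = c(V = 5.064, A = 4.211, D = 5.185),
                             sds = c(V = 1.275, A = 0.986, D = 0.938),
                             seed = 1L) {
  stopifnot(n >= 10L)
  if (any(sds <= 0)) {
    stop("degenerate lexicon: rating SDs must be positive", call. = FALSE)
  }
  set.seed(seed)
  words <- unique(random_words(3L * n, min_len = 4L, max_len = 8L))
  words <- setdiff(words, default_stopwords())
  if (length(words) < n) {
    stop("could not generate ", n, " unique words", call. = FALSE)
  }
  words <- words[seq_len(n)]
  clip <- function(x) pmin(9, pmax(1, x))
  tibble::tibble(
    word = words,
    valence_raw = clip(rnorm(n, means[["V"]], sds[["V"]])),
    arousal_raw = clip(rnorm(n, means[["A"]], sds[["A"]])),
    dominance_raw = clip(rnorm(n, means[["D"]], sds[["D"]]))
  )
}

random_words <- function(n, min_len = 4L, max_len = 8L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(letters, l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Default per-day affect regime for the headline generator
#'
#' One row per (state, date) of generation targets: mean V/A/D drifting
#' around mildly positive values (daily means of real pandemic-era
#' headlines hovered between 0 and 0.5 z-units) with day-to-day wobble,
#' and per-dimension spreads near 1 (word z-scores have unit SD
#' lexicon-wide) so daily flux lands near 1 with realistic variation.
#'
#' @param states Character vector of state labels.
#' @param dates Date vector of publication days.
#' @param seed Integer seed.
#' @param base_mean,mean_sd Center and day-to-day SD of the target means.
#' @param base_spread,spread_sd Center and SD of the target spreads.
#' @return Tibble: `state`, `date`, `mu_V`, `mu_A`, `mu_D`, `spread_V`,
#'   `spread_A`, `spread_D`.
#' @export
default_affect_regime <- function(states, dates, seed = 1L,
                                  base_mean = 0.25, mean_sd = 0.15,
                                  base_spread = 1, spread_sd = 0.08) {
  set.seed(seed)
  grid <- tidyr::expand_grid(state = states, date = dates)
  n <- nrow(grid)
  draw_mu <- function() rnorm(n, base_mean, mean_sd)
  draw_s <- function() pmax(0.3, rnorm(n, base_spread, spread_sd))
  dplyr::bind_cols(grid, tibble::tibble(
    mu_V = draw_mu(), mu_A = draw_mu(), mu_D = draw_mu(),
    spread_V = draw_s(), spread_A = draw_s(), spread_D = draw_s()
  ))
}

#' Generate a synthetic headline corpus with controllable affect dynamics
#'
#' For each (state, date) in `regime`, samples target token affect vectors
#' from a Gaussian centered on the day's regime (its means set the daily
#' mean affect; its spreads set flux, and through the 2D geometry pulse
#' and spin), matches each target to the nearest lexicon word in VAD
#' z-space, and accepts the day's word set once its realized mean and flux
#' sit within `tolerance` (relative, against the regime) or retries up to
#' `max_tries` times, keeping the best attempt. Tokens are then assembled
#' into headline titles with out-of-vocabulary filler words, stop words,
#' numerals and punctuation mixed in, so the corpus exercises the cleaning
#' rules and maps at a rate well below 1.
#'
#' A regime with zero spread is feasible (every token collapses onto one
#' word; flux and spin are 0). A spread target is infeasible when the
#' lexicon is degenerate in the relevant plane (fewer than 2 distinct
#' angles); this raises an error.
#'
#' @param lexicon An `affect_lexicon` (the generator matches against its
#'   z-scores).
#' @param regime Tibble from [default_affect_regime()] (or same shape).
#' @param seed Integer seed.
#' @param tokens_per_day Mapped tokens drawn per (state, date).
#' @param words_per_headline Approximate title length in content words.
#' @param oov_rate Fraction of additional out-of-vocabulary filler tokens
#'   relative to mapped tokens.
#' @param tolerance Relative acceptance tolerance on realized mean and
#'   flux (recorded as an attribute on the output).
#' @param max_tries Rejection-sampling retries per day.
#' @return Tibble `state`, `date`, `title`; attribute `tolerance`.
#' @export
generate_headlines <- function(lexicon, regime, seed = 1L,
                               tokens_per_day = 40L,
                               words_per_headline = 6L,
                               oov_rate = 0.6, tolerance = 0.1,
                               max_tries = 20L) {
  stopifnot(inherits(lexicon, "affect_lexicon"))
  set.seed(seed)
  lex <- lexicon$scores
  Z <- as.matrix(lex[, c("V", "A", "D")])
  ang <- word_angle(Z[, 1], Z[, 2])
  if (length(unique(round(ang[!is.na(ang)], 6))) < 2L) {
    stop("infeasible regime: lexicon is angularly degenerate in the VA ",
         "plane", call. = FALSE)
  }
  stop_pool <- default_stopwords()
  oov_pool <- make_oov_pool(500L, lex$word)

  titles <- vector("list", nrow(regime))
  for (i in seq_len(nrow(regime))) {
    r <- regime[i, ]
    mu <- c(r$mu_V, r$mu_A, r$mu_D)
    s <- c(r$spread_V, r$spread_A, r$spread_D)
    idx <- sample_day_tokens(Z, mu, s, tokens_per_day, tolerance,
                             max_tries)
    titles[[i]] <- compose_titles(lex$word[idx], stop_pool, oov_pool,
                                  words_per_headline, oov_rate)
  }
  out <- tidyr::unnest(
    dplyr::mutate(regime[, c("state", "date")], title = titles),
    "title"
  )
  attr(out, "tolerance") <- tolerance
  out
}

# Rejection-sample one day's token set: draw Gaussian targets, snap to the
# nearest lexicon word, accept when realized mean and flux are within the
# relative tolerance of the regime (absolute tolerance 0.1 when a target
# is 0), else keep the best of max_tries attempts.
sample_day_tokens <- function(Z, mu, s, n_tokens, tolerance, max_tries) {
  best_idx <- NULL
  best_err <- Inf
  for (try in seq_len(max_tries)) {
    targets <- cbind(rnorm(n_tokens, mu[1], s[1]),
                     rnorm(n_tokens, mu[2], s[2]),
                     rnorm(n_tokens, mu[3], s[3]))
    idx <- nearest_word(Z, targets)
    realized_mu <- colMeans(Z[idx, , drop = FALSE])
    realized_s <- apply(Z[idx, , drop = FALSE], 2, .sd_fun)
    rel_err <- function(got, want) {
      abs(got - want) / pmax(abs(want), 0.1)
    }
    err <- max(rel_err(realized_mu, mu), rel_err(realized_s, s))
    if (err < best_err) {
      best_err <- err
      best_idx <- idx
    }
    if (err <= tolerance) break
  }
  best_idx
}

nearest_word <- function(Z, targets) {
  # squared-distance argmin via the expansion |z - t|^2 = |z|^2 - 2 z.t + c
  cross <- Z %*% t(targets)                      # n_lex x n_targets
  d2 <- rowSums(Z^2) - 2 * cross                 # column-wise argmin below
  apply(d2, 2, which.min)
}

make_oov_pool <- function(n, lexicon_words) {
  pool <- unique(random_words(2L * n, min_len = 5L, max_len = 9L))
  pool <- setdiff(pool, c(lexicon_words, default_stopwords()))
  pool[seq_len(min(n, length(pool)))]
}

# Weave mapped tokens, OOV filler and stop words into headline strings,
# with numerals/punctuation noise that the cleaning step must strip.
compose_titles <- function(tokens, stop_pool, oov_pool,
                           words_per_headline, oov_rate) {
  n_oov <- rbinom(1L, length(tokens), oov_rate / (1 + oov_rate)) +
    round(length(tokens) * oov_rate * 0.5)
  content <- c(tokens, sample(oov_pool, min(n_oov, length(oov_pool))))
  content <- sample(content)
  n_titles <- max(1L, ceiling(length(content) / words_per_headline))
  groups <- sort(rep_len(seq_len(n_titles), length(content)))
  vapply(split(content, groups), function(ws) {
    ws <- c(ws, sample(stop_pool, max(1L, rbinom(1L, 3L, 0.5))))
    ws <- sample(ws)
    ws[1] <- toupper_first(ws[1])
    title <- paste(ws, collapse = " ")
    if (runif(1) < 0.3) title <- paste0(title, ": ", sample(3:99, 1))
    if (runif(1) < 0.2) title <- sub(" ", " - ", title, fixed = TRUE)
    title
  }, character(1), USE.NAMES = FALSE)
}

toupper_first <- function(w) {
  paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
}

#' Generate a synthetic state population table
#'
#' Log-uniform populations between about 0.5 and 40 million, the span of
#' real US state populations.
#'
#' @param states Character vector of state labels.
#' @param seed Integer seed.
#' @return Tibble `state`, `population`.
#' @export
generate_populations <- function(states, seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    state = states,
    population = round(exp(runif(length(states), log(5e5), log(4e7))))
  )
}

#' Directly simulate daily circumplex features
#'
#' Draws a plausible daily feature table without generating a corpus, for
#' model-level studies (parameter recovery, power) where the text pipeline
#' is not under test. Scales mirror what the full pipeline produces from
#' the default regime: daily means around 0.25 z-units, flux near 1, pulse
#' near the Rayleigh SD of an isotropic unit cloud (~0.65), and
#' literal-mode spin near 26 degrees.
#'
#' @param n_states Number of states.
#' @param n_days Number of consecutive days starting at `origin`.
#' @param seed Integer seed.
#' @param origin First date; default 2020-03-24 (t = 0).
#' @return Tibble shaped like [compute_daily_features()] output.
#' @export
simulate_features <- function(n_states = 50L, n_days = 200L, seed = 1L,
                              origin = as.Date("2020-03-24")) {
  set.seed(seed)
  states <- sprintf("S%02d", seq_len(n_states))
  grid <- tidyr::expand_grid(state = states,
                             date = origin + seq_len(n_days) - 1L)
  n <- nrow(grid)
  tpos <- function(m, s, lo) pmax(lo, rnorm(n, m, s))
  dplyr::bind_cols(grid, tibble::tibble(
    n_mapped = 30L + rbinom(n, 40L, 0.5),
    mean_V = rnorm(n, 0.25, 0.15),
    mean_A = rnorm(n, 0.25, 0.15),
    mean_D = rnorm(n, 0.25, 0.15),
    Flux_V = tpos(1, 0.15, 0.2),
    Flux_A = tpos(1, 0.15, 0.2),
    Flux_D = tpos(1, 0.15, 0.2),
    Pulse_VA = tpos(0.65, 0.1, 0.1),
    Pulse_VD = tpos(0.65, 0.1, 0.1),
    Pulse_AD = tpos(0.65, 0.1, 0.1),
    Spin_VA = tpos(26, 4, 1),
    Spin_VD = tpos(26, 4, 1),
    Spin_AD = tpos(26, 4, 1)
  ))
}

#' Default ground-truth coefficients for the trends generator
#'
#' Log-scale effects for the VA model terms, signed as in the fitted
#' study models (negative Spin_VA, positive Flux_A and Pulse_VA) and
#' scaled to the units the features are produced in (Spin in degrees, so
#' its per-degree coefficient is small).
#'
#' @return Named numeric vector over `t`, `V`, `A`, `Spin_VA`, `Pulse_VA`,
#'   `Flux_V`, `Flux_A`.
#' @export
default_trends_beta <- function() {
  c(t = -0.001, V = -0.06, A = -0.01, Spin_VA = -0.02, Pulse_VA = 0.13,
    Flux_V = 0.02, Flux_A = 0.22)
}

#' Generate normalized search-interest records from a known count model
#'
#' Draws ground-truth per-state daily counts for each disjoint term
#' cluster from a negative binomial mixed model — mean
#' exp(intercept + X beta + state intercept), nbinom2 dispersion `theta` —
#' where X holds the VA-model features for that (state, date), then
#' splits cluster counts over their member terms (multinomial, equal
#' rates) and converts the true counts into 0-100 normalized records with
#' a daily comparator term.
#'
#' Normalization emulates the platform: within each (date, term) query,
#' state values are per-capita search propensities and the national
#' values per-capita totals, all scaled by a common factor so the maximum
#' is 100. With `lossless = TRUE` the normalized values keep full
#' precision and the comparator tier floor equals its true volume, so the
#' estimator inverts the construction exactly (up to the final floor);
#' with `lossless = FALSE` normalized values are rounded to integers and
#' tier floors are taken from [comparator_tier_floor()], emulating the
#' real platform's information loss.
#'
#' @param features Daily feature table ([simulate_features()] or
#'   [compute_daily_features()] output).
#' @param populations Tibble `state`, `population`.
#' @param beta Named truth vector over the VA model terms.
#' @param intercepts Named log-scale baselines per disjoint cluster.
#' @param theta nbinom2 dispersion (> 0).
#' @param re_sd SD of the Gaussian state intercepts.
#' @param seed Integer seed.
#' @param lossless Logical; see above.
#' @param origin Date giving t = 0 in the mean structure.
#' @return List with `trends` (long tibble for
#'   [estimate_state_counts()]) and `truth` (list: `beta`, `intercepts`,
#'   `theta`, `re_sd`, `random_modes`, `counts` — true per-term counts,
#'   and `cluster_counts`).
#' @export
generate_trends <- function(features, populations,
                            beta = default_trends_beta(),
                            intercepts = c(Depression = log(30),
                                           Anxiety = log(25),
                                           Nonspecific = log(15)),
                            theta = 5, re_sd = 0.3, seed = 1L,
                            lossless = TRUE,
                            origin = as.Date("2020-03-24")) {
  stopifnot(theta > 0, re_sd >= 0)
  set.seed(seed)
  clusters <- mh_term_clusters()
  stopifnot(all(names(intercepts) %in% names(clusters)))

  terms_va <- model_terms("VA")
  feats <- dplyr::rename(features, V = "mean_V", A = "mean_A",
                         D = "mean_D")
  feats$t <- as.numeric(feats$date - origin)
  feats <- feats[feats$t >= 0, , drop = FALSE]
  keep <- stats::complete.cases(feats[, terms_va, drop = FALSE])
  feats <- feats[keep, , drop = FALSE]
  stopifnot(all(names(beta) == terms_va))

  states <- sort(unique(feats$state))
  stopifnot(all(states %in% populations$state))
  b_state <- setNames(rnorm(length(states), 0, re_sd), states)
  eta_x <- drop(as.matrix(feats[, terms_va]) %*% beta) +
    b_state[feats$state]

  # ground-truth counts: cluster level, then a multinomial per-term split
  count_rows <- list()
  for (cl in names(intercepts)) {
    mu <- exp(intercepts[[cl]] + eta_x)
    y <- rnbinom(length(mu), mu = mu, size = theta)
    cl_terms <- clusters[[cl]]
    split_mat <- vapply(seq_along(y), function(j) {
      rmultinom(1, y[j], rep(1, length(cl_terms)))[, 1]
    }, integer(length(cl_terms)))
    count_rows[[cl]] <- tibble::tibble(
      state = rep(feats$state, each = length(cl_terms)),
      date = rep(feats$date, each = length(cl_terms)),
      cluster = cl,
      term = rep_len(cl_terms, length(y) * length(cl_terms)),
      count = as.integer(split_mat)
    )
  }
  truth_counts <- dplyr::bind_rows(count_rows)

  trends <- normalize_counts(truth_counts, populations, lossless, seed)
  cluster_counts <- dplyr::summarise(
    dplyr::group_by(truth_counts, .data$state, .data$date, .data$cluster),
    count = sum(.data$count), .groups = "drop"
  )
  all_counts <- dplyr::summarise(
    dplyr::group_by(truth_counts, .data$state, .data$date),
    count = sum(.data$count), .groups = "drop"
  )
  all_counts$cluster <- "All"
  cluster_counts <- dplyr::bind_rows(cluster_counts, all_counts)

  list(
    trends = trends,
    truth = list(beta = beta, intercepts = intercepts, theta = theta,
                 re_sd = re_sd, random_modes = b_state,
                 counts = truth_counts[, c("state", "date", "term",
                                           "count")],
                 cluster_counts = cluster_counts)
  )
}

# Emulate per-query 0-100 normalization with a shared per-capita basis for
# the target term and the day's comparator.
normalize_counts <- function(truth_counts, populations, lossless, seed) {
  set.seed(seed + 7L)
  pop <- setNames(populations$population, populations$state)
  pop_tot <- sum(pop)
  dates <- sort(unique(truth_counts$date))
  comp_true <- setNames(round(exp(runif(length(dates), log(6e4),
                                        log(5e6)))),
                        as.character(dates))
  comp_terms <- setNames(random_words(length(dates), 5L, 8L),
                         as.character(dates))

  per_term <- dplyr::group_by(truth_counts, .data$date, .data$term)
  out <- dplyr::group_modify(per_term, function(df, key) {
    d <- as.character(key$date)
    tot <- sum(df$count)
    state_pc <- df$count / pop[df$state]
    tot_pc <- tot / pop_tot
    comp_pc <- comp_true[[d]] / pop_tot
    scale <- 100 / max(c(state_pc, tot_pc, comp_pc, 1e-12))
    norm <- function(x) if (lossless) x * scale else round(x * scale)
    tibble::tibble(
      state = df$state,
      mh_norm_state = norm(state_pc),
      mh_norm_total = norm(tot_pc),
      comparator_term = comp_terms[[d]],
      comp_norm_total = norm(comp_pc),
      comp_search_volume = if (lossless) comp_true[[d]] else
        comparator_tier_floor(comp_true[[d]])
    )
  })
  dplyr::ungroup(out)
}

#' Generate every pipeline input from one seed
#'
#' One-call study generator: synthetic lexicon, per-day affect regimes,
#' headline corpus, populations, and normalized search records whose
#' ground-truth counts are driven by the circumplex features realized
#' from that same corpus. A single global seed derives independent
#' per-module substreams, so each artifact is reproducible on its own.
#'
#' @param seed Integer master seed.
#' @param states Character vector of state labels; default 50 synthetic
#'   states.
#' @param dates Date vector; default the 2020-01-23 to 2020-10-22
#'   collection period.
#' @param lexicon_size Number of lexicon words.
#' @param ... Passed to [generate_trends()] (truth overrides).
#' @return List: `lexicon_raw`, `lexicon`, `regime`, `headlines`,
#'   `populations`, `features`, `trends`, `truth`.
#' @export
simulate_study <- function(seed = 1L,
                           states = sprintf("S%02d", 1:50),
                           dates = seq(as.Date("2020-01-23"),
                                       as.Date("2020-10-22"), by = "day"),
                           lexicon_size = 1000L, ...) {
  lexicon_raw <- generate_lexicon(lexicon_size, seed = seed)
  lexicon <- standardize_lexicon(lexicon_raw)
  regime <- default_affect_regime(states, dates, seed = seed + 1L)
  headlines <- generate_headlines(lexicon, regime, seed = seed + 2L)
  populations <- generate_populations(states, seed = seed + 3L)
  pools <- pool_daily(headlines, lexicon)
  features <- compute_daily_features(pools)
  tr <- generate_trends(features, populations, seed = seed + 4L, ...)
  list(
    lexicon_raw = lexicon_raw, lexicon = lexicon, regime = regime,
    headlines = headlines, populations = populations,
    features = features, trends = tr$trends, truth = tr$truth
  )
}
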