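test_that("the synthetic lexicon matches the target scale properties", {
  lex <- generate_lexicon(1000, seed = 61)
  expect_equal(nrow(lex), 1000)
  expect_false(any(duplicated(lex$word)))
  expect_true(all(grepl("^[a-z]+$", lex$word)))
  expect_true(all(lex$valence_raw >= 1 & lex$valence_raw <= 9))
  expect_lt(abs(mean(lex$valence_raw) - 5.064), 0.1)
  expect_lt(abs(mean(lex$arousal_raw) - 4.211), 0.1)
  expect_lt(abs(mean(lex$dominance_raw) - 5.185), 0.1)
  expect_identical(lex, generate_lexicon(1000, seed = 61))
  expect_error(generate_lexicon(100, sds = c(V = 0, A = 1, D = 1)),
               "degenerate")
})

test_that("headline generation is deterministic and regime-responsive", {
  lex <- standardize_lexicon(generate_lexicon(400, seed = 62))
  dates <- as.Date("2020-03-24") + 0:4
  reg <- default_affect_regime("S1", dates, seed = 62)
  h1 <- generate_headlines(lex, reg, seed = 63)
  h2 <- generate_headlines(lex, reg, seed = 63)
  expect_identical(h1, h2)

  wide <- reg; wide$spread_V <- 1.3; wide$spread_A <- 1.3
  tight <- reg; tight$spread_V <- 0.35; tight$spread_A <- 0.35
  fw <- compute_daily_features(pool_daily(
    generate_headlines(lex, wide, seed = 64), lex))
  ft <- compute_daily_features(pool_daily(
    generate_headlines(lex, tight, seed = 64), lex))
  expect_true(all(fw$Flux_V > ft$Flux_V))
  expect_true(all(fw$Flux_A > ft$Flux_A))
})

test_that("a zero-spread regime collapses flux and spin to ~0", {
  lex <- standardize_lexicon(generate_lexicon(400, seed = 65))
  reg <- default_affect_regime("S1", as.Date("2020-03-24") + 0:2,
                               seed = 65)
  reg$spread_V <- 0; reg$spread_A <- 0; reg$spread_D <- 0
  h <- generate_headlines(lex, reg, seed = 66)
  f <- compute_daily_features(pool_daily(h, lex))
  expect_true(all(f$Flux_V < 1e-8))
  expect_true(all(is.na(f$Spin_VA) | f$Spin_VA < 1e-8))
})

test_that("the corpus maps at a rate below 1 and round-trips its schema", {
  lex <- standardize_lexicon(generate_lexicon(300, seed = 67))
  reg <- default_affect_regime(c("S1", "S2"),
                               as.Date("2020-03-24") + 0:3, seed = 67)
  h <- generate_headlines(lex, reg, seed = 68)
  pools <- pool_daily(h, lex)
  rate <- attr(pools, "mapping_rate")
  expect_lt(rate, 1)
  expect_gt(rate, 0.2)

  path <- tempfile(fileext = ".csv")
  write.csv(h, path, row.names = FALSE)
  again <- read_headlines(path)
  expect_equal(nrow(again), nrow(h))
  pools2 <- pool_daily(again, lex)
  expect_equal(attr(pools2, "mapping_rate"), rate)
})

test_that("near-Poisson truth with zero effects yields the right mean", {
  feats <- simulate_features(10, 100, seed = 69)
  pops <- generate_populations(unique(feats$state), seed = 69)
  beta0 <- setNames(rep(0, 7), model_terms("VA"))
  tr <- generate_trends(feats, pops, beta = beta0,
                        intercepts = c(Depression = log(10)),
                        theta = 1e8, re_sd = 0, seed = 70)
  y <- tr$truth$cluster_counts
  y <- y$count[y$cluster == "Depression"]
  expect_lt(abs(mean(y) - 10), 3 * sqrt(10 / length(y)))
  expect_lt(abs(var(y) / mean(y) - 1), 0.15)  # Poisson-like dispersion
})

test_that("lossless normalization round-trips the true counts exactly", {
  feats <- simulate_features(4, 25, seed = 71)
  pops <- generate_populations(unique(feats$state), seed = 71)
  tr <- generate_trends(feats, pops, seed = 71, lossless = TRUE)
  counts <- estimate_state_counts(tr$trends, pops)
  m <- dplyr::inner_join(counts, tr$truth$counts,
                         by = c("state", "date", "term"),
                         suffix = c("_est", "_true"))
  expect_equal(nrow(m), nrow(tr$truth$counts))
  expect_equal(m$count_est, m$count_true)
})

test_that("lossy normalization stays close but not exact", {
  feats <- simulate_features(4, 25, seed = 72)
  pops <- generate_populations(unique(feats$state), seed = 72)
  tr <- generate_trends(feats, pops, seed = 72, lossless = FALSE)
  expect_true(all(tr$trends$comp_search_volume %in%
                    c(2e4, 5e4, 1e5, 2e5, 5e5, 1e6, 2e6, 5e6, 1e7)))
  counts <- estimate_state_counts(tr$trends, pops)
  m <- dplyr::inner_join(counts, tr$truth$counts,
                         by = c("state", "date", "term"),
                         suffix = c("_est", "_true"))
  # tier flooring makes estimates conservative on average
  expect_lte(median(m$count_est - m$count_true), 0)
})

test_that("trends generation is reproducible and persists ground truth", {
  feats <- simulate_features(3, 10, seed = 73)
  pops <- generate_populations(unique(feats$state), seed = 73)
  a <- generate_trends(feats, pops, seed = 74)
  b <- generate_trends(feats, pops, seed = 74)
  expect_identical(a$trends, b$trends)
  expect_identical(a$truth$counts, b$truth$counts)
  expect_equal(names(a$truth$beta), model_terms("VA"))
  expect_equal(sort(unique(a$truth$counts$term)),
               sort(mh_term_clusters()$All))
  # per-term split conserves the cluster totals
  dep <- a$truth$counts[a$truth$counts$term %in%
                          mh_term_clusters()$Depression, ]
  per_term <- dplyr::summarise(dplyr::group_by(dep, state, date),
                               count = sum(count), .groups = "drop")
  truth_cl <- a$truth$cluster_counts
  truth_cl <- truth_cl[truth_cl$cluster == "Depression", ]
  m <- dplyr::inner_join(per_term, truth_cl, by = c("state", "date"),
                         suffix = c("_split", "_cl"))
  expect_equal(m$count_split, m$count_cl)
})

test_that("one master seed reproduces a full study byte-for-byte", {
  dates <- as.Date("2020-03-20") + 0:9
  s1 <- simulate_study(seed = 75, states = c("S1", "S2"), dates = dates,
                       lexicon_size = 200)
  s2 <- simulate_study(seed = 75, states = c("S1", "S2"), dates = dates,
                       lexicon_size = 200)
  expect_identical(s1$headlines, s2$headlines)
  expect_identical(s1$trends, s2$trends)
  expect_identical(s1$features, s2$features)
})
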