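make_design_inputs <- function(n_states = 4, n_days = 30, seed = 51) {
  feats <- simulate_features(n_states, n_days, seed = seed)
  pops <- generate_populations(unique(feats$state), seed = seed)
  tr <- generate_trends(feats, pops, seed = seed, lossless = TRUE)
  counts <- estimate_state_counts(tr$trends, pops)
  list(features = feats, clusters = cluster_sums(counts), truth = tr$truth)
}

test_that("design rows are the complete inner join with correct t", {
  inp <- make_design_inputs(2, 3)
  d <- build_design(inp$features, inp$clusters, cluster = "All")
  expect_equal(nrow(d), 6)
  expect_equal(d$t[d$date == as.Date("2020-03-24")], c(0, 0))
  expect_equal(sort(unique(d$t)), c(0, 1, 2))

  f2 <- inp$features
  f2$Spin_VA[3] <- NA
  d2 <- build_design(f2, inp$clusters, cluster = "All")
  expect_equal(nrow(d2), 5)

  # the study window spans 213 daily time points
  expect_equal(as.numeric(as.Date("2020-10-22") - as.Date("2020-03-24")),
               212)

  dl <- build_design(inp$features, inp$clusters, cluster = "All",
                     time_transform = "log")
  expect_equal(sort(unique(dl$t)), log(c(0, 1, 2) + 1))
  expect_equal(model_terms("VA"),
               c("t", "V", "A", "Spin_VA", "Pulse_VA", "Flux_V", "Flux_A"))
  expect_equal(length(model_terms("VAD")), 13)
})

test_that("Efron pseudo-r2 matches its definition", {
  y <- c(1, 2, 3)
  expect_equal(efron_pseudo_r2(y, y), 1)
  expect_equal(efron_pseudo_r2(y, rep(mean(y), 3)), 0)
  expect_equal(efron_pseudo_r2(y, c(1, 2, 2)), 0.5)
  expect_error(efron_pseudo_r2(c(2, 2), c(1, 2)), "zero-variance")
  set.seed(52)
  yy <- rpois(50, 10); fit <- yy + rnorm(50)
  expect_lte(efron_pseudo_r2(yy, fit), 1)
})

test_that("percent change is the exponentiated-coefficient reading", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  expect_equal(percent_change(c(0.221, -0.207)),
               c(exp(0.221) - 1, exp(-0.207) - 1) * 100)
})

test_that("the NB mixed fit recovers known parameters on one replicate", {
  inp <- make_design_inputs(10, 80, seed = 53)
  d <- build_design(inp$features, inp$clusters, cluster = "Depression")
  fit <- fit_nb_glmm(d)
  truth <- inp$truth$beta
  est <- setNames(fit$coef$beta, fit$coef$term)
  for (term in names(truth)) {
    se <- fit$coef$se[fit$coef$term == term]
    expect_lt(abs(est[[term]] - truth[[term]]), 3 * se + 1e-8)
  }
  expect_lt(abs(est[["(Intercept)"]] - inp$truth$intercepts[["Depression"]]),
            3 * fit$coef$se[1])
  expect_gt(fit$theta, 0)
  expect_true(all(fit$coef$ci_low < fit$coef$beta))
  expect_true(all(fit$coef$beta < fit$coef$ci_high))
  expect_equal(sort(names(fit$random_modes)), sort(unique(d$state)))
  expect_lte(fit$pseudo_r2, 1)
})

test_that("the fit agrees with an independent NB mixed implementation", {
  skip_if_not_installed("lme4")
  inp <- make_design_inputs(6, 60, seed = 54)
  d <- build_design(inp$features, inp$clusters, cluster = "All")
  fit <- fit_nb_glmm(d)
  ref <- suppressWarnings(lme4::glmer.nb(
    count ~ t + V + A + Spin_VA + Pulse_VA + Flux_V + Flux_A + (1 | state),
    data = d))
  ours <- setNames(fit$coef$beta, fit$coef$term)
  theirs <- lme4::fixef(ref)
  expect_equal(ours[names(theirs)], theirs, tolerance = 0.02)
})

test_that("huge dispersion reduces to an independent Poisson mixed fit", {
  skip_if_not_installed("lme4")
  feats <- simulate_features(6, 60, seed = 55)
  pops <- generate_populations(unique(feats$state), seed = 55)
  tr <- generate_trends(feats, pops, seed = 55, theta = 1e8,
                        lossless = TRUE)
  d <- build_design(feats, tr$truth$cluster_counts, cluster = "All")
  fit <- suppressWarnings(fit_nb_glmm(d))
  ref <- suppressWarnings(lme4::glmer(
    count ~ t + V + A + Spin_VA + Pulse_VA + Flux_V + Flux_A + (1 | state),
    data = d, family = poisson()))
  ours <- setNames(fit$coef$beta, fit$coef$term)
  expect_equal(ours[names(lme4::fixef(ref))], lme4::fixef(ref),
               tolerance = 1e-2)
})

test_that("fit inputs are validated", {
  inp <- make_design_inputs(2, 10, seed = 56)
  d <- build_design(inp$features, inp$clusters, cluster = "All")
  one_state <- d[d$state == d$state[1], ]
  expect_error(fit_nb_glmm(one_state), ">= 2 states")
  frac <- d; frac$count <- frac$count + 0.5
  expect_error(fit_nb_glmm(frac), "non-negative integers")
})

test_that("marginal predictions follow the link and the coefficients", {
  inp <- make_design_inputs(6, 60, seed = 57)
  d <- build_design(inp$features, inp$clusters, cluster = "All")
  fit <- fit_nb_glmm(d)
  beta <- setNames(fit$coef$beta, fit$coef$term)
  mu <- fit$feature_means
  at_means <- predict_marginal(fit, "Flux_A", mu[["Flux_A"]])
  expect_equal(at_means$predicted,
               exp(beta[["(Intercept)"]] +
                     sum(beta[names(mu)] * mu)), tolerance = 1e-10)
  grid <- seq(0, 3, length.out = 7)
  up <- predict_marginal(fit, "Flux_A", grid)
  expect_true(all(diff(up$predicted) > 0) == (beta[["Flux_A"]] > 0))
  surface <- predict_marginal(fit, "Spin_VA", c(10, 30), "Flux_A",
                              c(0.5, 1.5))
  expect_equal(nrow(surface), 4)
  expect_error(predict_marginal(fit, "nope", 1), "unknown variable")
})

test_that("linear and log time fits are reported side by side", {
  inp <- make_design_inputs(6, 60, seed = 58)
  rep <- compare_time_transforms(inp$features, inp$clusters,
                                 cluster = "All")
  expect_equal(rep$time_transform, c("linear", "log"))
  expect_equal(rep$pseudo_r2_2dp, round(rep$pseudo_r2, 2))
  # data generated with linear time: the linear fit should not be worse
  # beyond simulation noise
  expect_gte(rep$pseudo_r2[1], rep$pseudo_r2[2] - 0.02)
})
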