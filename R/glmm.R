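#' Fixed-effect term sets for the circumplex models
#'
#' The VA (2D) model regresses a cluster count on time plus the
#' valence-arousal plane's affect and dynamics features; the VAD (3D)
#' model adds dominance and the VD/AD planes.
#'
#' @param feature_set `"VA"` or `"VAD"`.
#' @return Ordered character vector of fixed-effect names.
#' @export
model_terms <- function(feature_set = c("VA", "VAD")) {
  feature_set <- match.arg(feature_set)
  va <- c("t", "V", "A", "Spin_VA", "Pulse_VA", "Flux_V", "Flux_A")
  if (feature_set == "VA") return(va)
  c("t", "V", "A", "D", "Spin_VA", "Spin_VD", "Spin_AD",
    "Pulse_VA", "Pulse_VD", "Pulse_AD", "Flux_V", "Flux_A", "Flux_D")
}

#' Build the stacked model design
#'
#' Inner-joins daily circumplex features with cluster count sums on
#' (state, date), computes the day count `t` since the configured origin
#' (optionally log-transformed as log(t + 1) so t = 0 is admissible),
#' renames daily mean affect to `V`/`A`/`D`, and drops rows falling before
#' the origin or missing any required feature.
#'
#' @param features Output of [compute_daily_features()].
#' @param clusters Output of [cluster_sums()].
#' @param cluster Which outcome cluster to model.
#' @param feature_set `"VA"` or `"VAD"`.
#' @param time_transform `"linear"` or `"log"`.
#' @param origin Date giving t = 0; default 2020-03-24, the first day of
#'   outcome collection (so the default study window spans 213 daily time
#'   points, t = 0..212, through 2020-10-22).
#' @return Tibble with `state`, `date`, `count`, and one column per model
#'   term; attributes record the spec used.
#' @export
build_design <- function(features, clusters,
                         cluster = c("All", "Depression", "Anxiety",
                                     "Nonspecific"),
                         feature_set = c("VA", "VAD"),
                         time_transform = c("linear", "log"),
                         origin = as.Date("2020-03-24")) {
  cluster <- match.arg(cluster)
  feature_set <- match.arg(feature_set)
  time_transform <- match.arg(time_transform)

  cl <- clusters[clusters$cluster == cluster, , drop = FALSE]
  feats <- dplyr::rename(features, V = "mean_V", A = "mean_A", D = "mean_D")
  joined <- dplyr::inner_join(feats, cl[, c("state", "date", "count")],
                              by = c("state", "date"))
  if (nrow(joined) == 0L) {
    stop("build_design: features and counts share no (state, date) rows",
         call. = FALSE)
  }
  joined <- joined[joined$date >= origin, , drop = FALSE]
  t_days <- as.numeric(joined$date - origin)
  joined$t <- if (time_transform == "log") log(t_days + 1) else t_days

  terms <- model_terms(feature_set)
  cols <- c("state", "date", "count", terms)
  design <- joined[, cols, drop = FALSE]
  complete <- stats::complete.cases(design[, terms, drop = FALSE])
  design <- design[complete, , drop = FALSE]
  if (nrow(design) == 0L) {
    stop("build_design: no complete rows after the missing-feature filter",
         call. = FALSE)
  }
  attr(design, "cluster") <- cluster
  attr(design, "feature_set") <- feature_set
  attr(design, "time_transform") <- time_transform
  attr(design, "origin") <- origin
  design
}

#' Fit a negative binomial mixed model of cluster counts
#'
#' Fits `count ~ <fixed terms> + (1 | state)` by maximum likelihood with a
#' log link, Gaussian random intercepts integrated by Laplace
#' approximation, and the nbinom2 variance form (variance = mu + mu^2 /
#' theta), via glmmTMB. Wald 95% intervals are beta +/- 1.96 se. The fit
#' is deterministic given the data.
#'
#' @param design Output of [build_design()] (or any tibble with `count`,
#'   `state` and the model-term columns).
#' @param feature_set `"VA"` or `"VAD"`; defaults to the design attribute.
#' @return An object of class `nb_glmm_fit`: list with `coef` (tibble
#'   `term`, `beta`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `percent_change`), `theta`, `random_modes` (named vector),
#'   `pseudo_r2` (Efron, from conditional fitted means), `n_rows`,
#'   `feature_means`, `feature_set`, `time_transform`, and `model` (the
#'   underlying glmmTMB fit).
#' @export
fit_nb_glmm <- function(design, feature_set = attr(design, "feature_set")) {
  if (is.null(feature_set)) feature_set <- "VA"
  terms <- model_terms(feature_set)
  stopifnot(all(c("count", "state", terms) %in% names(design)))
  if (length(unique(design$state)) < 2L) {
    stop("fit_nb_glmm: need >= 2 states for a random intercept",
         call. = FALSE)
  }
  if (any(design$count < 0) || any(design$count != round(design$count))) {
    stop("fit_nb_glmm: counts must be non-negative integers", call. = FALSE)
  }
  dat <- as.data.frame(design)
  dat$state <- factor(dat$state)
  form <- stats::as.formula(
    paste("count ~", paste(terms, collapse = " + "), "+ (1 | state)"))
  fit <- glmmTMB::glmmTMB(form, data = dat, family = glmmTMB::nbinom2())
  conv <- fit$fit$convergence
  if (!isTRUE(conv == 0) || !isTRUE(fit$sdr$pdHess)) {
    stop("fit_nb_glmm: optimizer did not converge (code ", conv,
         ", pdHess = ", isTRUE(fit$sdr$pdHess), "); message: ",
         fit$fit$message, call. = FALSE)
  }
  theta <- glmmTMB::sigma(fit)
  if (theta > 1e4) {
    warning("dispersion at the Poisson limit (theta = ",
            format(theta, digits = 3), ")", call. = FALSE)
  }
  ctab <- summary(fit)$coefficients$cond
  coef_tbl <- tibble::tibble(
    term = rownames(ctab),
    beta = ctab[, "Estimate"],
    se = ctab[, "Std. Error"],
    ci_low = ctab[, "Estimate"] - 1.96 * ctab[, "Std. Error"],
    ci_high = ctab[, "Estimate"] + 1.96 * ctab[, "Std. Error"],
    p_value = ctab[, "Pr(>|z|)"]
  )
  coef_tbl$percent_change <- percent_change(coef_tbl$beta)
  re <- glmmTMB::ranef(fit)$cond$state
  y_hat <- stats::predict(fit, type = "response")
  structure(
    list(
      coef = coef_tbl,
      theta = theta,
      random_modes = setNames(re[[1]], rownames(re)),
      pseudo_r2 = efron_pseudo_r2(dat$count, y_hat),
      n_rows = nrow(dat),
      feature_means = colMeans(dat[, terms, drop = FALSE]),
      feature_set = feature_set,
      time_transform = attr(design, "time_transform") %||% "linear",
      cluster = attr(design, "cluster") %||% NA_character_,
      model = fit
    ),
    class = "nb_glmm_fit"
  )
}

#' @export
print.nb_glmm_fit <- function(x, ...) {
  cat("<nb_glmm_fit> ", x$feature_set, " model",
      if (!is.na(x$cluster)) paste0(", ", x$cluster, " cluster"),
      ": ", x$n_rows, " rows, ", length(x$random_modes), " states\n",
      sep = "")
  cat(sprintf("  dispersion theta = %.3f, Efron pseudo-r2 = %.3f\n",
              x$theta, x$pseudo_r2))
  tbl <- x$coef
  cat(sprintf("  %-10s %8s %8s %18s %8s\n",
              "term", "beta", "se", "95% CI", "p"))
  for (i in seq_len(nrow(tbl))) {
    cat(sprintf("  %-10s %8.3f %8.3f [%7.3f, %7.3f] %8.3g\n",
                tbl$term[i], tbl$beta[i], tbl$se[i], tbl$ci_low[i],
                tbl$ci_high[i], tbl$p_value[i]))
  }
  invisible(x)
}

#' Efron pseudo-r-squared
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`: the proportional
#' reduction in squared error of the fitted means over the outcome mean.
#' Can be negative for a fit worse than the mean; never exceeds 1.
#'
#' @param y Observed counts.
#' @param y_hat Fitted means (same length).
#' @return A real number <= 1.
#' @export
efron_pseudo_r2 <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("efron_pseudo_r2: zero-variance outcome", call. = FALSE)
  }
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Percent-change interpretation of a log-scale coefficient
#'
#' Under the log link, a unit increase in a feature multiplies the
#' expected count by exp(beta); `(exp(beta) - 1) * 100` is the signed
#' percent change per unit increase.
#'
#' @param beta Log-scale coefficient(s).
#' @return Signed percent change(s), unrounded (narrative reporting rounds
#'   to 1 decimal).
#' @export
percent_change <- function(beta) {
  (exp(beta) - 1) * 100
}

#' Marginal (and interaction) predictions from a fitted model
#'
#' Expected counts along a grid of one feature — or a crossed grid of two —
#' with every other fixed effect held at its sample mean and the random
#' intercept at 0 (the population level).
#'
#' @param fit An `nb_glmm_fit`.
#' @param variable Fixed-effect name to vary.
#' @param grid Numeric vector of values for `variable`.
#' @param variable2,grid2 Optional second feature and grid; when supplied
#'   the two grids are fully crossed (an interaction-style surface).
#' @return Tibble with the grid column(s) and `predicted` (expected count,
#'   > 0).
#' @export
predict_marginal <- function(fit, variable, grid, variable2 = NULL,
                             grid2 = NULL) {
  stopifnot(inherits(fit, "nb_glmm_fit"))
  terms <- model_terms(fit$feature_set)
  if (!variable %in% terms) {
    stop("predict_marginal: unknown variable '", variable, "'",
         call. = FALSE)
  }
  if (!is.null(variable2) && !variable2 %in% terms) {
    stop("predict_marginal: unknown variable '", variable2, "'",
         call. = FALSE)
  }
  newdata <- if (is.null(variable2)) {
    tibble::tibble(!!variable := grid)
  } else {
    tidyr::expand_grid(!!variable := grid, !!variable2 := grid2)
  }
  X <- matrix(rep(fit$feature_means, each = nrow(newdata)),
              nrow = nrow(newdata),
              dimnames = list(NULL, terms))
  X[, variable] <- newdata[[variable]]
  if (!is.null(variable2)) X[, variable2] <- newdata[[variable2]]
  beta <- setNames(fit$coef$beta, fit$coef$term)
  eta <- beta[["(Intercept)"]] + drop(X %*% beta[terms])
  newdata$predicted <- exp(eta)
  newdata
}

#' Compare linear and log time transforms
#'
#' Refits the same model with `t` entered linearly and as log(t + 1) and
#' reports Efron pseudo-r-squared side by side, rounded to 2 decimals as
#' in narrative reporting (fit differences smaller than that are treated
#' as not appreciable).
#'
#' @param features,clusters,cluster,feature_set As in [build_design()].
#' @param origin Time origin passed through to [build_design()].
#' @return Tibble: `time_transform`, `pseudo_r2`, `pseudo_r2_2dp`.
#' @export
compare_time_transforms <- function(features, clusters, cluster = "All",
                                    feature_set = "VA",
                                    origin = as.Date("2020-03-24")) {
  rows <- lapply(c("linear", "log"), function(tt) {
    design <- build_design(features, clusters, cluster = cluster,
                           feature_set = feature_set, time_transform = tt,
                           origin = origin)
    fit <- fit_nb_glmm(design)
    tibble::tibble(time_transform = tt, pseudo_r2 = fit$pseudo_r2,
                   pseudo_r2_2dp = round(fit$pseudo_r2, 2))
  })
  dplyr::bind_rows(rows)
}

#' Write a coefficient table to CSV
#'
#' Mirrors the published table layout: feature, beta, CI bounds, p-value,
#' plus the percent-change reading of beta.
#'
#' @param fit An `nb_glmm_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coef_table <- function(fit, path) {
  write.csv(fit$coef, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
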