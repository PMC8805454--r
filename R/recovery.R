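#' Parameter-recovery simulation for the NB mixed model
#'
#' Repeatedly simulates daily features and cluster counts from known
#' coefficients (negative Spin_VA effect, positive Flux_A effect, as in
#' the fitted study models), refits the VA model, and summarizes per-term
#' mean estimates, mean absolute bias, and 95% Wald interval coverage
#' across replicates.
#'
#' @param n_states,n_days Size of each replicate.
#' @param n_reps Number of replicates.
#' @param seed Master seed; replicate r uses seed + r substreams.
#' @param beta,intercept,theta,re_sd Ground truth passed to
#'   [generate_trends()] (the Depression cluster is modeled).
#' @return List: `summary` (tibble `term`, `truth`, `mean_estimate`,
#'   `abs_bias` — absolute bias of the mean estimate — `mean_abs_error`
#'   (per-replicate), and `coverage`), `n_rows` (rows per replicate fit),
#'   and `fit` (the last replicate's `nb_glmm_fit`, for downstream
#'   marginal checks). Bias and coverage are usually assessed on the
#'   slope coefficients; the intercept row's per-replicate error also
#'   absorbs the realized mean of the random intercepts.
#' @export
recovery_study <- function(n_states = 50L, n_days = 200L, n_reps = 20L,
                           seed = 1L, beta = default_trends_beta(),
                           intercept = log(30), theta = 5, re_sd = 0.3) {
  truth <- c("(Intercept)" = unname(intercept), beta)
  est <- matrix(NA_real_, n_reps, length(truth),
                dimnames = list(NULL, names(truth)))
  cover <- matrix(NA, n_reps, length(truth),
                  dimnames = list(NULL, names(truth)))
  last_fit <- NULL
  n_rows <- NA_integer_
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + 1000L * r
    feats <- simulate_features(n_states, n_days, seed = rep_seed)
    pops <- generate_populations(unique(feats$state), seed = rep_seed)
    tr <- generate_trends(feats, pops, beta = beta,
                          intercepts = c(Depression = unname(intercept)),
                          theta = theta, re_sd = re_sd,
                          seed = rep_seed + 1L)
    design <- build_design(feats, tr$truth$cluster_counts,
                           cluster = "Depression")
    fit <- fit_nb_glmm(design)
    b <- setNames(fit$coef$beta, fit$coef$term)
    lo <- setNames(fit$coef$ci_low, fit$coef$term)
    hi <- setNames(fit$coef$ci_high, fit$coef$term)
    est[r, ] <- b[colnames(est)]
    cover[r, ] <- truth >= lo[colnames(est)] & truth <= hi[colnames(est)]
    last_fit <- fit
    n_rows <- fit$n_rows
  }
  list(
    summary = tibble::tibble(
      term = names(truth),
      truth = unname(truth),
      mean_estimate = colMeans(est),
      abs_bias = abs(colMeans(est) - truth),
      mean_abs_error = colMeans(abs(est - rep(truth, each = n_reps))),
      coverage = colMeans(cover)
    ),
    n_rows = n_rows,
    fit = last_fit
  )
}
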