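# Single-trait BayesC-pi whole-genome regression. The model is
#   y_i = mu + sum_j m_ij alpha_j + e_i
# with a flat prior on mu, i.i.d. N(0, sigma2_e) residuals, and a point-mass /
# normal mixture prior on each marker effect: alpha_j = 0 with probability pi
# and N(0, sigma2_alpha) otherwise. pi has a Uniform(0,1) prior; both
# variances have scaled inverse chi-square priors. Sampling is a single-site
# Gibbs sweep (compiled) with a joint (delta_j, alpha_j) update.

#' Prior specification for BayesC-pi
#'
#' Scales left `NULL` are resolved from the data when the chain starts:
#' `scale_e` so the prior mean of the residual variance equals
#' `var(y) * (1 - genetic_variance_guess)`, and `scale_alpha` so the prior
#' mean of the marker-effect variance equals
#' `genetic_variance_guess * var(y) / ((1 - pi0) * sum(2 f_j (1 - f_j)))`
#' with `pi0 = 0.5` — the convention used by whole-genome regression
#' software such as GenSel and JWAS.
#'
#' @param nu_alpha,nu_e Degrees of freedom of the scaled inverse chi-square
#'   priors on the marker-effect and residual variances.
#' @param scale_alpha,scale_e Prior scales; `NULL` = resolve from data.
#' @param genetic_variance_guess Assumed fraction of phenotypic variance that
#'   is genetic, used only to resolve the scales.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(nu_alpha = 4, scale_alpha = NULL,
                       nu_e = 4, scale_e = NULL,
                       genetic_variance_guess = 0.5) {
  stopifnot(nu_alpha > 2, nu_e > 2,
            genetic_variance_guess > 0, genetic_variance_guess < 1)
  structure(list(nu_alpha = nu_alpha, scale_alpha = scale_alpha,
                 nu_e = nu_e, scale_e = scale_e,
                 genetic_variance_guess = genetic_variance_guess),
            class = "prior_spec")
}

#' MCMC chain settings
#'
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Discarded initial sweeps (`< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param seed Integer seed; required, all runs are reproducible.
#' @return An object of class `chain_config`. The stored draw count is
#'   `floor((n_iter - burn_in) / thin)`; at least ~100 stored draws are
#'   recommended for WPPA resolution.
#' @export
chain_config <- function(n_iter = 5000, burn_in = 1000, thin = 4, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

resolve_prior <- function(prior, y, freqs) {
  vy <- stats::var(y)
  g <- prior$genetic_variance_guess
  if (is.null(prior$scale_e))
    prior$scale_e <- vy * (1 - g) * (prior$nu_e - 2) / prior$nu_e
  if (is.null(prior$scale_alpha)) {
    denom <- 0.5 * sum(2 * freqs * (1 - freqs))
    mean_s2a <- if (denom > 0) g * vy / denom else g * vy
    prior$scale_alpha <- mean_s2a * (prior$nu_alpha - 2) / prior$nu_alpha
  }
  prior
}

#' Run the BayesC-pi Gibbs sampler
#'
#' @param G A [genotype_matrix()] (no missing dosages; markers should already
#'   be MAF-filtered). Columns are centered internally; the intercept absorbs
#'   the shift, and all window-variance summaries downstream are
#'   shift-invariant.
#' @param y Phenotype vector aligned with the rows of `G`.
#' @param prior A [prior_spec()].
#' @param chain A [chain_config()]; `chain$seed` drives all randomness.
#' @param pin Optional named list fixing parameters for validation runs: any
#'   of `pi`, `sigma2_alpha`, `sigma2_e`. A pinned parameter keeps its value
#'   for the whole chain.
#' @return An object of class `bayescpi_draws`: thinned post-burn-in draws of
#'   `alpha` (draws x p), `delta`, and vectors `mu`, `pi`, `sigma2_alpha`,
#'   `sigma2_e`, plus the resolved prior, chain settings and dimensions.
#' @export
run_bayescpi <- function(G, y, prior = prior_spec(),
                         chain = chain_config(seed = 1), pin = list()) {
  stopifnot(inherits(G, "geno_matrix"))
  n <- nrow(G$dosages); p <- ncol(G$dosages)
  if (length(y) != n) stop("phenotype length does not match genotypes")
  if (n < 2) stop("at least 2 individuals are required")
  if (!all(is.finite(y))) stop("phenotypes must be finite")
  if (anyNA(G$dosages)) stop("genotypes contain missing values")
  if (p > 0) {
    sds <- col_sds(G$dosages)
    if (any(sds == 0))
      stop("zero-variance genotype column present; run filter_maf first")
  }
  bad_pin <- setdiff(names(pin), c("pi", "sigma2_alpha", "sigma2_e"))
  if (length(bad_pin)) stop("unknown pin: ", paste(bad_pin, collapse = ", "))

  freqs <- if (p > 0) colMeans(G$dosages) / 2 else numeric(0)
  prior <- resolve_prior(prior, y, freqs)
  centers <- if (p > 0) colMeans(G$dosages) else numeric(0)
  M <- if (p > 0) sweep(G$dosages, 2, centers) else
    matrix(0, nrow = n, ncol = 0)

  init_pi <- if (!is.null(pin$pi)) pin$pi else 0.5
  init_s2e <- if (!is.null(pin$sigma2_e)) pin$sigma2_e else stats::var(y) / 2
  default_s2a <- prior$scale_alpha * prior$nu_alpha / (prior$nu_alpha - 2)
  init_s2a <- if (!is.null(pin$sigma2_alpha)) pin$sigma2_alpha else default_s2a

  set.seed(chain$seed)
  res <- .bayescpi_mcmc(M, as.numeric(y),
                        prior$nu_alpha, prior$scale_alpha,
                        prior$nu_e, prior$scale_e,
                        chain$n_iter, chain$burn_in, chain$thin,
                        mean(y), numeric(p), integer(p),
                        init_pi, init_s2a, init_s2e,
                        !is.null(pin$pi), !is.null(pin$sigma2_alpha),
                        !is.null(pin$sigma2_e))
  colnames(res$alpha) <- colnames(res$delta) <- G$map$marker_id
  structure(list(alpha = res$alpha, delta = res$delta, mu = res$mu,
                 pi = res$pi, sigma2_alpha = res$sigma2_alpha,
                 sigma2_e = res$sigma2_e, chain = chain, prior = prior,
                 n = n, p = p, marker_ids = G$map$marker_id),
            class = "bayescpi_draws")
}

#' @export
print.bayescpi_draws <- function(x, ...) {
  cat("BayesC-pi draws:", nrow(x$alpha), "stored states,",
      x$p, "markers,", x$n, "individuals\n")
  cat(sprintf("posterior means: pi = %.3f, sigma2_alpha = %.4g, sigma2_e = %.4g\n",
              mean(x$pi), mean(x$sigma2_alpha), mean(x$sigma2_e)))
  invisible(x)
}

#' One Gibbs sweep from a given model state
#'
#' Runs a single full-conditional sweep (intercept, each locus in index
#' order, pi, both variances) and returns the updated state. Uses the current
#' R random stream; call `set.seed()` beforehand for reproducibility.
#' Intended for sweep-level validation; normal use goes through
#' [run_bayescpi()].
#'
#' @param state List with `mu`, `alpha`, `delta`, `pi`, `sigma2_alpha`,
#'   `sigma2_e`.
#' @param G A [genotype_matrix()]; columns are centered internally.
#' @param y Phenotype vector.
#' @param prior A [prior_spec()] (scales resolved from data if `NULL`).
#' @param pin Same as in [run_bayescpi()].
#' @return The updated state list.
#' @export
gibbs_sweep <- function(state, G, y, prior = prior_spec(), pin = list()) {
  stopifnot(inherits(G, "geno_matrix"))
  p <- ncol(G$dosages)
  stopifnot(length(state$alpha) == p, length(state$delta) == p)
  freqs <- if (p > 0) colMeans(G$dosages) / 2 else numeric(0)
  prior <- resolve_prior(prior, y, freqs)
  centers <- if (p > 0) colMeans(G$dosages) else numeric(0)
  M <- if (p > 0) sweep(G$dosages, 2, centers) else
    matrix(0, nrow = length(y), ncol = 0)
  res <- .bayescpi_mcmc(M, as.numeric(y),
                        prior$nu_alpha, prior$scale_alpha,
                        prior$nu_e, prior$scale_e,
                        1L, 0L, 1L,
                        state$mu, as.numeric(state$alpha),
                        as.integer(state$delta),
                        state$pi, state$sigma2_alpha, state$sigma2_e,
                        !is.null(pin$pi), !is.null(pin$sigma2_alpha),
                        !is.null(pin$sigma2_e))
  res$final_state
}

#' Posterior summaries of a BayesC-pi run
#'
#' @param draws A `bayescpi_draws` object with at least one stored state.
#' @return List of class `bayescpi_summary`: `markers` (data frame with
#'   `marker_id`, `effect_mean`, `inclusion_prob`) and posterior means
#'   `pi_mean`, `sigma2_alpha_mean`, `sigma2_e_mean`, `mu_mean`.
#' @export
posterior_summaries <- function(draws) {
  stopifnot(inherits(draws, "bayescpi_draws"))
  if (nrow(draws$alpha) < 1) stop("no stored draws")
  structure(list(
    markers = data.frame(marker_id = draws$marker_ids,
                         effect_mean = colMeans(draws$alpha),
                         inclusion_prob = colMeans(draws$delta),
                         row.names = NULL, stringsAsFactors = FALSE),
    pi_mean = mean(draws$pi),
    sigma2_alpha_mean = mean(draws$sigma2_alpha),
    sigma2_e_mean = mean(draws$sigma2_e),
    mu_mean = mean(draws$mu)), class = "bayescpi_summary")
}

# column standard deviations without an extra dependency
col_sds <- function(m) {
  mu <- colMeans(m)
  sqrt(pmax(colMeans(m * m) - mu * mu, 0))
}
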