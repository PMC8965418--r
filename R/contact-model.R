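# Holling Type II functional response for snail-snail contact rates.
#
# Expected contacts per focal individual during an observation window of T
# minutes at partner density N:
#
#   contacts = (e * T * N) / (1 + e * H * (N - 1))
#
# where e is the encounter rate (min^-1 per unit density) and H the contact
# handling time (min). Handling caps the rate at T/H as N grows.

#' Holling-model parameters
#'
#' @param e Encounter rate, min^-1; prior support \[0, 1\].
#' @param H Contact handling time, minutes; prior support \[0, 44\].
#' @param sigma Residual SD of container-mean contacts; `> 0`.
#' @return A named list of class `holling_params`.
#' @export
holling_params <- function(e, H, sigma = 1) {
  stopifnot(e >= 0, e <= 1, H >= 0, H <= 44, sigma > 0)
  structure(list(e = e, H = H, sigma = sigma), class = "holling_params")
}

#' Expected contacts per focal snail (Holling Type II)
#'
#' With `N = 1` the handling term vanishes and the expectation is `e * T`;
#' with `H = 0` the response is the linear encounter process `e * T * N`.
#' The `(N - 1)` form counts handling only against the additional partners
#' beyond the first; `variant = "N"` uses the plain `N` denominator for
#' sensitivity analysis.
#'
#' @param params [holling_params()] (or compatible list).
#' @param density Partner (alternative-host) count in the arena, `>= 1`.
#' @param obs_minutes Observation window T in minutes, `> 0` (default 45).
#' @param variant `"N_minus_1"` (default) or `"N"` denominator form.
#' @return Expected contacts per focal individual; vectorized over
#'   `density`.
#' @export
#' @examples
#' holling_mean_contacts(holling_params(0.012, 3.25), density = 18)
holling_mean_contacts <- function(params, density, obs_minutes = 45,
                                  variant = c("N_minus_1", "N")) {
  variant <- match.arg(variant)
  if (any(density < 1)) stop("density must be >= 1", call. = FALSE)
  if (any(obs_minutes <= 0)) stop("obs_minutes must be > 0", call. = FALSE)
  nn <- if (variant == "N_minus_1") density - 1 else density
  (params$e * obs_minutes * density) / (1 + params$e * params$H * nn)
}

#' Normal log-likelihood of container-mean contact counts
#'
#' The container means are modelled as normal around the Holling Type II
#' expectation with constant SD `sigma`; containers (not individual snails)
#' are the independent units.
#'
#' @param params [holling_params()] with `sigma > 0`.
#' @param trials Contact-trial records (see [table_schemas]).
#' @param variant Denominator form passed to [holling_mean_contacts()].
#' @return Scalar log-likelihood.
#' @export
contacts_loglik <- function(params, trials, variant = "N_minus_1") {
  trials <- validate_table(trials, "contact")
  if (nrow(trials) == 0) stop("no contact trials", call. = FALSE)
  if (params$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  mu <- holling_mean_contacts(params, trials$alt_density,
                              trials$obs_minutes, variant)
  sum(stats::dnorm(trials$mean_contacts, mu, params$sigma, log = TRUE))
}

#' Build a fast contact log-likelihood closure for MCMC
#'
#' @param trials Contact-trial records.
#' @param variant Denominator form.
#' @return Function: named vector `(e, H, sigma)` -> log-likelihood.
#' @export
make_contacts_loglik <- function(trials, variant = "N_minus_1") {
  trials <- validate_table(trials, "contact")
  N <- trials$alt_density
  T_ <- trials$obs_minutes
  y <- trials$mean_contacts
  nn <- if (variant == "N_minus_1") N - 1 else N
  function(theta) {
    mu <- (theta[["e"]] * T_ * N) / (1 + theta[["e"]] * theta[["H"]] * nn)
    sum(stats::dnorm(y, mu, theta[["sigma"]], log = TRUE))
  }
}

#' Fit the Holling Type II contact model by MCMC
#'
#' Bounded-uniform priors: encounter rate in \[0, 1\], handling time in
#' \[0, 44\] min, residual SD in (0, 20\].
#'
#' @param trials Contact-trial records.
#' @param n_chains,n_iter,burn_in MCMC settings (defaults 3 x 30000 /
#'   15000).
#' @param seed Integer seed.
#' @param variant Denominator form (see [holling_mean_contacts()]).
#' @return A `posterior_chains` object over `(e, H, sigma)`.
#' @export
fit_contacts <- function(trials, n_chains = 3, n_iter = 30000,
                         burn_in = 15000, seed, variant = "N_minus_1") {
  ll <- make_contacts_loglik(trials, variant)
  prior <- prior_spec(c("e", "H", "sigma"), lower = c(0, 0, 1e-6),
                      upper = c(1, 44, 20))
  run_mcmc(ll, prior, n_chains = n_chains, n_iter = n_iter,
           burn_in = burn_in, seed = seed)
}

#' Fitted contact-rate curve with a posterior band
#'
#' @param chains A `posterior_chains` from [fit_contacts()].
#' @param densities Densities at which to evaluate the curve.
#' @param obs_minutes Observation window (default 45).
#' @param level Band level (default 0.95).
#' @return Data.frame: `density`, `predicted` (posterior median of the mean
#'   curve), `lower`, `upper`.
#' @export
contact_curve_table <- function(chains, densities = 1:18, obs_minutes = 45,
                                level = 0.95) {
  pooled <- as.matrix(chains)
  alpha <- 1 - level
  out <- lapply(densities, function(N) {
    mu <- (pooled[, "e"] * obs_minutes * N) /
      (1 + pooled[, "e"] * pooled[, "H"] * (N - 1))
    qs <- stats::quantile(mu, c(alpha / 2, 0.5, 1 - alpha / 2),
                          names = FALSE)
    data.frame(density = N, predicted = qs[2], lower = qs[1], upper = qs[3])
  })
  do.call(rbind, out)
}

#' Compare two fitted functional responses
#'
#' Reports per-parameter 95% credible intervals for two posterior fits over
#' the same parameterization, whether the intervals overlap, and the
#' posterior probability that each parameter is larger in the first fit
#' (draws paired by pooled index).
#'
#' @param fit_a,fit_b `posterior_chains` objects with identical parameter
#'   names (e.g. intraspecific vs interspecific contact fits).
#' @param level Interval level (default 0.95).
#' @return Data.frame: `parameter`, interval columns for both fits,
#'   `overlap`, `prob_a_gt_b`.
#' @export
compare_functional_responses <- function(fit_a, fit_b, level = 0.95) {
  if (!identical(fit_a$parameters, fit_b$parameters)) {
    stop("posteriors have different parameterizations", call. = FALSE)
  }
  ci_a <- credible_interval(fit_a, level)
  ci_b <- credible_interval(fit_b, level)
  a <- as.matrix(fit_a)
  b <- as.matrix(fit_b)
  n <- min(nrow(a), nrow(b))
  prob <- vapply(fit_a$parameters, function(p) {
    av <- a[seq_len(n), p]; bv <- b[seq_len(n), p]
    mean(av > bv) + 0.5 * mean(av == bv)  # ties split evenly
  }, 0)
  data.frame(parameter = fit_a$parameters,
             point_a = ci_a$point, lower_a = ci_a$lower,
             upper_a = ci_a$upper,
             point_b = ci_b$point, lower_b = ci_b$lower,
             upper_b = ci_b$upper,
             overlap = ci_a$lower <= ci_b$upper & ci_b$lower <= ci_a$upper,
             prob_a_gt_b = prob, row.names = NULL,
             stringsAsFactors = FALSE)
}
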