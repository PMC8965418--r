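# Multi-host force-of-infection model for sentinel-host infestation data.
#
# FOI_F = beta_FF * N_F^k_FF * (I_F/N_F) + beta_FA * N_A^k_FA * (I_A/N_A)
#
# The unitless exponents k interpolate between frequency-dependent (k = 0)
# and density-dependent (k = 1) transmission. Densities are snails per
# 0.1 m^2; a species' term is defined as 0 when its density is 0 (I = 0
# whenever N = 0, so the 0/0 never carries information).

#' FOI model parameters
#'
#' @param beta_ff,beta_fa Intra- and interspecific transmission rates
#'   (day^-1 on the density^k scale); prior support \[0, 2\].
#' @param k_ff,k_fa Unitless density-dependence exponents; prior support
#'   \[0, 1\].
#' @return A named list of class `foi_params`.
#' @export
foi_params <- function(beta_ff, k_ff, beta_fa = 0, k_fa = 0.5) {
  stopifnot(beta_ff >= 0, beta_ff <= 2, beta_fa >= 0, beta_fa <= 2,
            k_ff >= 0, k_ff <= 1, k_fa >= 0, k_fa <= 1)
  structure(list(beta_ff = beta_ff, k_ff = k_ff, beta_fa = beta_fa,
                 k_fa = k_fa), class = "foi_params")
}

.foi_term <- function(beta, k, n, i) {
  ifelse(n > 0, beta * n^k * (i / n), 0)
}

#' Multi-host force of infection on the focal host
#'
#' Per-capita infestation rate experienced by a susceptible focal host,
#' summed over the intraspecific (focal-focal) and interspecific
#' (alternative-focal) contributions. With `k = 1` a species' term reduces
#' to `beta * I` (density-dependent transmission); with `k = 0` it reduces
#' to `beta * I/N` (frequency-dependent).
#'
#' @param params A [foi_params()] object (or list with the same names).
#' @param n_f,i_f Focal-host density and infested density (per 0.1 m^2).
#' @param n_a,i_a Alternative-host density and infested density.
#' @return FOI in day^-1; vectorized over the density arguments.
#' @export
#' @examples
#' foi_multi_host(foi_params(0.2, 1, 0.02, 0.5), n_f = 10, i_f = 5,
#'                n_a = 4, i_a = 2)
foi_multi_host <- function(params, n_f, i_f, n_a = 0, i_a = 0) {
  if (any(n_f < 0 | i_f < 0 | n_a < 0 | i_a < 0)) {
    stop("densities must be >= 0", call. = FALSE)
  }
  if (any(i_f > n_f) || any(i_a > n_a)) {
    stop("infested density cannot exceed total density", call. = FALSE)
  }
  .foi_term(params$beta_ff, params$k_ff, n_f, i_f) +
    .foi_term(params$beta_fa, params$k_fa, n_a, i_a)
}

#' Probability a sentinel host is infested by trial end
#'
#' Constant-hazard conversion of an FOI into the expected proportion of
#' sentinels infested after `t` days: `1 - exp(-foi * t)`.
#'
#' @param foi Force of infection, day^-1, `>= 0`.
#' @param t Trial duration in days, `>= 0`.
#' @return Probability in \[0, 1\]; vectorized.
#' @export
prob_infested <- function(foi, t) {
  if (any(foi < 0) || any(t < 0)) {
    stop("prob_infested requires foi >= 0 and t >= 0", call. = FALSE)
  }
  -expm1(-foi * t)
}

# Weekly covariates for the likelihood: field observations aggregated
# (mean across sites) per week x species. FOI is held constant within a
# trial at that week's aggregated state.
.weekly_field_state <- function(fields) {
  fields <- validate_table(fields, "field")
  agg <- stats::aggregate(cbind(density, infested_density) ~
                            week_index + species, data = fields, FUN = mean)
  foc <- agg[agg$species == "focal", ]
  alt <- agg[agg$species == "alternative", ]
  weeks <- sort(unique(agg$week_index))
  state <- data.frame(week_index = weeks,
                      n_f = 0, i_f = 0, n_a = 0, i_a = 0)
  state$n_f <- foc$density[match(weeks, foc$week_index)]
  state$i_f <- foc$infested_density[match(weeks, foc$week_index)]
  state$n_a <- alt$density[match(weeks, alt$week_index)]
  state$i_a <- alt$infested_density[match(weeks, alt$week_index)]
  state[is.na(state)] <- 0
  state
}

# p is clamped away from {0, 1} so that impossible configurations give a
# very negative, finite log-likelihood (keeps Metropolis numerically sane).
.P_EPS <- 1e-12

#' Binomial log-likelihood of sentinel trials under the FOI model
#'
#' Each trial contributes a binomial log-probability of `n_infested` out of
#' `n_exposed` with success probability
#' `1 - exp(-FOI(week covariates) * duration_days)`. Trial covariates are
#' the same-week field densities, averaged across survey sites.
#'
#' @param params [foi_params()] (or compatible list).
#' @param trials Sentinel-trial records (see [table_schemas]).
#' @param fields Field-survey records supplying the week-matched densities.
#' @return Scalar log-likelihood.
#' @export
sentinel_loglik <- function(params, trials, fields) {
  ll_fun <- make_sentinel_loglik(trials, fields)
  ll_fun(c(beta_ff = params$beta_ff, k_ff = params$k_ff,
           beta_fa = params$beta_fa, k_fa = params$k_fa))
}

#' Build a fast sentinel log-likelihood closure
#'
#' Pre-pairs trials with their week-matched (site-averaged) field
#' covariates and returns a function of the parameter vector, suitable for
#' [run_mcmc()]. The parameter vector is `(beta_ff, k_ff)` for the
#' single-host model or `(beta_ff, k_ff, beta_fa, k_fa)` for the
#' multi-host model.
#'
#' @param trials Sentinel-trial records.
#' @param fields Field-survey records.
#' @param model `"multi"` (default) or `"single"`; the single-host model
#'   fixes `beta_fa = 0`.
#' @return Function: named parameter vector -> log-likelihood.
#' @export
make_sentinel_loglik <- function(trials, fields,
                                 model = c("multi", "single")) {
  model <- match.arg(model)
  trials <- validate_table(trials, "sentinel")
  state <- .weekly_field_state(fields)
  idx <- match(trials$week_index, state$week_index)
  if (anyNA(idx)) {
    stop("no field observations for trial week(s) ",
         paste(unique(trials$week_index[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  n_f <- state$n_f[idx]; i_f <- state$i_f[idx]
  n_a <- state$n_a[idx]; i_a <- state$i_a[idx]
  x <- trials$n_infested; n <- trials$n_exposed; t <- trials$duration_days
  function(theta) {
    bfa <- if (model == "multi") theta[["beta_fa"]] else 0
    kfa <- if (model == "multi") theta[["k_fa"]] else 0
    foi <- .foi_term(theta[["beta_ff"]], theta[["k_ff"]], n_f, i_f) +
      .foi_term(bfa, kfa, n_a, i_a)
    p <- pmin(pmax(-expm1(-foi * t), .P_EPS), 1 - .P_EPS)
    sum(stats::dbinom(x, n, p, log = TRUE))
  }
}

#' Force of infection from contact, success and prevalence components
#'
#' Multiplies each host species' contribution out of its three amplifying
#' components — contact rate `c(N)`, per-contact transmission success `v`,
#' and infestation prevalence `I/N` — and sums across species. Optionally
#' scales by the susceptible focal population size to give a population
#' incidence rate rather than a per-capita rate.
#'
#' @param components Data.frame (or list of lists) with columns/fields
#'   `contact_rate` (contacts per susceptible per day, >= 0),
#'   `success_prob` (in \[0,1\]) and `prevalence` (in \[0,1\]), one row per
#'   host species.
#' @param susceptibles Optional susceptible count `S_focal`.
#' @return Rate in day^-1 (times hosts when `susceptibles` is given).
#' @export
#' @examples
#' foi_from_components(data.frame(contact_rate = 0.5, success_prob = 0.1,
#'                                prevalence = 0.5))
foi_from_components <- function(components, susceptibles = NULL) {
  if (!is.data.frame(components)) {
    components <- do.call(rbind, lapply(components, as.data.frame))
  }
  with(components, {
    if (any(contact_rate < 0)) stop("contact_rate must be >= 0",
                                    call. = FALSE)
    if (any(success_prob < 0 | success_prob > 1)) {
      stop("success_prob must be in [0, 1]", call. = FALSE)
    }
    if (any(prevalence < 0 | prevalence > 1)) {
      stop("prevalence must be in [0, 1]", call. = FALSE)
    }
  })
  total <- sum(components$contact_rate * components$success_prob *
                 components$prevalence)
  if (!is.null(susceptibles)) total <- total * susceptibles
  total
}

#' Fit the FOI model to sentinel and field data by MCMC
#'
#' Runs the adaptive Metropolis sampler on the binomial sentinel likelihood
#' with the study's bounded-uniform priors: transmission rates in \[0, 2\],
#' density-dependence exponents in \[0, 1\]. The single-host model omits the
#' interspecific term (`beta_fa = 0`), giving the nested comparison used to
#' judge whether interspecific transmission adds explanatory power.
#'
#' @param trials Sentinel-trial records.
#' @param fields Field-survey records.
#' @param model `"multi"` or `"single"`.
#' @param n_chains,n_iter,burn_in MCMC settings (defaults 3 chains x 30000
#'   iterations, 15000 burn-in).
#' @param seed Integer seed.
#' @param compute_dic Compute pD/DIC on the fitted chains (default TRUE).
#' @return A `posterior_chains` object (with `pd`/`dic` when requested) and
#'   attribute `model`.
#' @export
fit_foi <- function(trials, fields, model = c("multi", "single"),
                    n_chains = 3, n_iter = 30000, burn_in = 15000, seed,
                    compute_dic = TRUE) {
  model <- match.arg(model)
  ll <- make_sentinel_loglik(trials, fields, model)
  prior <- if (model == "multi") {
    prior_spec(c("beta_ff", "k_ff", "beta_fa", "k_fa"),
               lower = c(0, 0, 0, 0), upper = c(2, 1, 2, 1))
  } else {
    prior_spec(c("beta_ff", "k_ff"), lower = c(0, 0), upper = c(2, 1))
  }
  chains <- run_mcmc(ll, prior, n_chains = n_chains, n_iter = n_iter,
                     burn_in = burn_in, seed = seed)
  if (compute_dic) chains <- dic(chains, ll)
  attr(chains, "model") <- model
  chains
}
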