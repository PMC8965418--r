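# Bayesian machinery: bounded-uniform priors, adaptive component-wise
# random-walk Metropolis, split-Rhat, equal-tailed credible intervals, DIC.

#' Bounded-uniform prior specification
#'
#' @param names Ordered parameter names.
#' @param lower,upper Elementwise bounds, `lower < upper`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(names, lower, upper) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper))
  if (any(lower >= upper)) stop("prior bounds must satisfy lower < upper",
                                call. = FALSE)
  structure(list(names = names, lower = as.numeric(lower),
                 upper = as.numeric(upper)), class = "prior_spec")
}

#' Adaptive random-walk Metropolis sampler
#'
#' Samples from the posterior implied by `log_likelihood` and a
#' bounded-uniform prior, using component-wise Gaussian random-walk
#' Metropolis. Per-parameter step sizes are tuned toward a 20-45% acceptance
#' rate during burn-in only and frozen afterwards, so retained draws come
#' from a valid Markov chain. Starting values are drawn uniformly within the
#' prior bounds, separately per chain; chain `c` is seeded with `seed + c`,
#' making runs reproducible.
#'
#' @param log_likelihood Function of a named numeric parameter vector,
#'   returning a finite log-likelihood (or `-Inf` for impossible data).
#' @param prior A [prior_spec()].
#' @param n_chains Number of chains (default 3).
#' @param n_iter Iterations per chain (default 30000).
#' @param burn_in Burn-in iterations discarded per chain (default 15000).
#' @param seed Integer seed; required.
#' @return An object of class `posterior_chains`: post-burn-in `draws`
#'   (iterations x parameters x chains array), per-parameter split-Rhat
#'   (`rhat`), per-chain post-burn-in `acceptance_rates`, and the `seed`.
#' @export
run_mcmc <- function(log_likelihood, prior, n_chains = 3, n_iter = 30000,
                     burn_in = 15000, seed) {
  stopifnot(inherits(prior, "prior_spec"), burn_in < n_iter, n_chains >= 1)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  p <- length(prior$names)
  lo <- prior$lower
  hi <- prior$upper
  n_keep <- n_iter - burn_in

  log_post <- function(theta) {
    if (any(theta < lo | theta > hi)) return(-Inf)
    names(theta) <- prior$names
    ll <- log_likelihood(theta)
    if (is.nan(ll) || is.na(ll)) {
      stop("log_likelihood returned NaN at theta = (",
           paste(signif(theta, 6), collapse = ", "), ")", call. = FALSE)
    }
    ll
  }

  draws <- array(NA_real_, dim = c(n_keep, p, n_chains),
                 dimnames = list(NULL, prior$names, NULL))
  acc_rates <- numeric(n_chains)
  stagnated <- FALSE

  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch)
    # starting point with finite posterior density
    theta <- NULL
    for (try in 1:100) {
      cand <- lo + stats::runif(p) * (hi - lo)
      if (is.finite(log_post(cand))) { theta <- cand; break }
    }
    if (is.null(theta)) {
      stop("could not find a starting point with finite log-likelihood",
           call. = FALSE)
    }
    lp <- log_post(theta)
    step <- 0.1 * (hi - lo)
    win_acc <- integer(p)
    win_n <- integer(p)
    acc_post <- 0L
    n_post <- 0L
    consec_rej <- 0L

    for (it in seq_len(n_iter)) {
      it_accepted <- FALSE
      for (j in seq_len(p)) {
        prop <- theta
        prop[j] <- theta[j] + stats::rnorm(1, 0, step[j])
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) &&
            log(stats::runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          it_accepted <- TRUE
          if (it <= burn_in) win_acc[j] <- win_acc[j] + 1L
          if (it > burn_in) acc_post <- acc_post + 1L
        }
        if (it <= burn_in) win_n[j] <- win_n[j] + 1L
        if (it > burn_in) n_post <- n_post + 1L
      }
      if (it_accepted) consec_rej <- 0L else consec_rej <- consec_rej + 1L
      if (consec_rej == 1000L && !stagnated) {
        warning("MCMC stagnation: 1000 consecutive iterations rejected",
                call. = FALSE)
        stagnated <- TRUE
      }
      # adapt step sizes during burn-in only
      if (it <= burn_in && it %% 50 == 0) {
        rate <- ifelse(win_n > 0, win_acc / win_n, 0.3)
        step <- ifelse(rate < 0.20, step * 0.8,
                       ifelse(rate > 0.45, step * 1.25, step))
        step <- pmin(pmax(step, 1e-8 * (hi - lo)), hi - lo)
        win_acc[] <- 0L
        win_n[] <- 0L
      }
      if (it > burn_in) draws[it - burn_in, , ch] <- theta
    }
    acc_rates[ch] <- acc_post / max(n_post, 1L)
  }

  out <- structure(list(draws = draws, parameters = prior$names,
                        rhat = NULL, acceptance_rates = acc_rates,
                        seed = seed, prior = prior, n_iter = n_iter,
                        burn_in = burn_in, pd = NULL, dic = NULL),
                   class = "posterior_chains")
  out$rhat <- gelman_rubin(out)
  out
}

#' Pool posterior draws across chains
#'
#' @param x A `posterior_chains` object.
#' @param ... Unused.
#' @return A (chains x iterations) by parameters matrix.
#' @export
as.matrix.posterior_chains <- function(x, ...) {
  d <- x$draws
  out <- matrix(aperm(d, c(1, 3, 2)), ncol = dim(d)[2])
  colnames(out) <- x$parameters
  out
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf("posterior_chains: %d chains x %d kept draws, %d parameter%s\n",
              dim(x$draws)[3], dim(x$draws)[1], length(x$parameters),
              if (length(x$parameters) > 1) "s" else ""))
  ci <- credible_interval(x)
  print(ci, row.names = FALSE)
  cat(sprintf("Rhat: %s; acceptance: %s\n",
              paste(sprintf("%s=%.3f", x$parameters, x$rhat),
                    collapse = ", "),
              paste(sprintf("%.2f", x$acceptance_rates), collapse = ", ")))
  if (!is.null(x$dic)) cat(sprintf("pD = %.2f, DIC = %.2f\n", x$pd, x$dic))
  invisible(x)
}

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half, and the potential scale reduction factor is
#' computed per parameter from the between- and within-half-chain variances.
#' Values near 1 indicate convergence. If the within-chain variance is zero
#' everywhere (degenerate chains), 1 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param draws A `posterior_chains` object or an iterations x parameters x
#'   chains array with at least 2 chains and 10 draws per chain.
#' @return Named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "posterior_chains")) draws <- draws$draws
  stopifnot(length(dim(draws)) == 3)
  n <- dim(draws)[1]
  p <- dim(draws)[2]
  m <- dim(draws)[3]
  if (m < 2 && n < 20) stop("need >= 2 chains or enough draws to split",
                            call. = FALSE)
  half <- floor(n / 2)
  if (half < 5) stop("need >= 10 post-burn-in draws per chain",
                     call. = FALSE)
  out <- numeric(p)
  degenerate <- FALSE
  for (j in seq_len(p)) {
    halves <- list()
    for (ch in seq_len(m)) {
      halves[[2 * ch - 1]] <- draws[1:half, j, ch]
      halves[[2 * ch]] <- draws[(n - half + 1):n, j, ch]
    }
    mns <- vapply(halves, mean, 0)
    vars <- vapply(halves, stats::var, 0)
    W <- mean(vars)
    B <- half * stats::var(mns)
    if (W <= 0) {
      out[j] <- 1
      degenerate <- TRUE
    } else {
      var_plus <- (half - 1) / half * W + B / half
      out[j] <- sqrt(var_plus / W)
    }
  }
  names(out) <- dimnames(draws)[[2]]
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Equal-tailed posterior credible intervals
#'
#' @param draws A `posterior_chains` object or a draws matrix (columns are
#'   parameters); at least 100 draws.
#' @param level Coverage level (default 0.95).
#' @return A data.frame with one row per parameter: `parameter`, `point`
#'   (posterior median), `lower`, `upper`, `level`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (inherits(draws, "posterior_chains")) draws <- as.matrix(draws)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "theta"))
  if (nrow(draws) < 100) stop("need >= 100 draws", call. = FALSE)
  alpha <- 1 - level
  qs <- apply(draws, 2, stats::quantile,
              probs = c(alpha / 2, 0.5, 1 - alpha / 2), names = FALSE)
  data.frame(parameter = colnames(draws), point = qs[2, ], lower = qs[1, ],
             upper = qs[3, ], level = level, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Deviance information criterion
#'
#' Classic plug-in form: with deviance `D(theta) = -2 log L(theta)`,
#' `pD = mean(D) - D(posterior mean)` and `DIC = mean(D) + pD`. If the
#' log-likelihood is not finite at the posterior mean (e.g. the mean falls
#' outside the support), the posterior median is used instead, with a
#' warning.
#'
#' @param chains A `posterior_chains` object.
#' @param log_likelihood The same log-likelihood the chains were run with.
#' @param max_evals Draws are thinned to at most this many deviance
#'   evaluations (default 3000).
#' @return The `chains` object with `pd` and `dic` filled in; retrieve them
#'   as `$pd` and `$dic`.
#' @export
dic <- function(chains, log_likelihood, max_evals = 3000) {
  stopifnot(inherits(chains, "posterior_chains"))
  pooled <- as.matrix(chains)
  idx <- if (nrow(pooled) > max_evals) {
    round(seq(1, nrow(pooled), length.out = max_evals))
  } else seq_len(nrow(pooled))
  dev <- vapply(idx, function(i) {
    th <- pooled[i, ]
    names(th) <- chains$parameters
    -2 * log_likelihood(th)
  }, 0)
  d_bar <- mean(dev)
  theta_hat <- colMeans(pooled)
  names(theta_hat) <- chains$parameters
  d_hat <- -2 * log_likelihood(theta_hat)
  if (!is.finite(d_hat)) {
    warning("deviance undefined at the posterior mean; using the median",
            call. = FALSE)
    theta_hat <- apply(pooled, 2, stats::median)
    names(theta_hat) <- chains$parameters
    d_hat <- -2 * log_likelihood(theta_hat)
  }
  chains$pd <- d_bar - d_hat
  chains$dic <- d_bar + chains$pd
  chains
}

#' Export posterior draws as a long table
#'
#' @param chains A `posterior_chains` object.
#' @return A data.frame with columns `chain`, `iteration`, one column per
#'   parameter.
#' @export
posterior_draws_table <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  d <- chains$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) {
    cbind(data.frame(chain = ch, iteration = seq_len(dim(d)[1])),
          as.data.frame(matrix(d[, , ch], ncol = dim(d)[2])))
  }))
  names(out)[-(1:2)] <- chains$parameters
  out
}
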