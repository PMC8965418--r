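# Adaptive Metropolis engine, convergence diagnostics, intervals, DIC.

test_that("a flat likelihood returns the uniform prior", {
  ch <- run_mcmc(function(theta) 0, prior_spec("u", 0, 1),
                 n_chains = 3, n_iter = 8000, burn_in = 3000, seed = 4)
  pooled <- as.matrix(ch)
  expect_equal(mean(pooled), 0.5, tolerance = 0.02)
  ci <- credible_interval(ch)
  expect_lt(abs(ci$lower - 0.025), 0.015)
  expect_lt(abs(ci$upper - 0.975), 0.015)
  expect_true(all(pooled >= 0 & pooled <= 1))
})

test_that("binomial likelihood reproduces the conjugate Beta posterior", {
  ll <- function(theta) dbinom(12, 20, theta[["p"]], log = TRUE)
  ch <- run_mcmc(ll, prior_spec("p", 0, 1), n_chains = 3, n_iter = 8000,
                 burn_in = 4000, seed = 2)
  pooled <- as.matrix(ch)
  expect_equal(mean(pooled), 13 / 22, tolerance = 0.01)
  beta_sd <- sqrt(13 * 9 / ((22^2) * 23))
  expect_equal(sd(pooled), beta_sd, tolerance = 0.15 * beta_sd)
  expect_true(all(ch$rhat < 1.01))
})

test_that("beta-binomial agreement holds across random instances", {
  set.seed(99)
  errs <- vapply(1:10, function(i) {
    n <- sample(10:60, 1)
    x <- rbinom(1, n, runif(1, 0.1, 0.9))
    ll <- function(theta) dbinom(x, n, theta[["p"]], log = TRUE)
    ch <- run_mcmc(ll, prior_spec("p", 0, 1), n_chains = 2,
                   n_iter = 5000, burn_in = 2500, seed = 500 + i)
    abs(mean(as.matrix(ch)) - (x + 1) / (n + 2))
  }, 0)
  expect_lt(max(errs), 0.01)
})

test_that("the sampler is bitwise reproducible given a seed", {
  ll <- function(theta) dnorm(theta[["m"]], 0, 1, log = TRUE)
  ch1 <- run_mcmc(ll, prior_spec("m", -5, 5), n_chains = 2,
                  n_iter = 1000, burn_in = 400, seed = 7)
  ch2 <- run_mcmc(ll, prior_spec("m", -5, 5), n_chains = 2,
                  n_iter = 1000, burn_in = 400, seed = 7)
  expect_identical(ch1$draws, ch2$draws)
  ch3 <- run_mcmc(ll, prior_spec("m", -5, 5), n_chains = 2,
                  n_iter = 1000, burn_in = 400, seed = 8)
  expect_false(identical(ch1$draws, ch3$draws))
})

test_that("sampling a standard normal target is calibrated", {
  ll <- function(theta) dnorm(theta[["z"]], 0, 1, log = TRUE)
  ch <- run_mcmc(ll, prior_spec("z", -8, 8), n_chains = 3,
                 n_iter = 10000, burn_in = 5000, seed = 12)
  pooled <- as.matrix(ch)
  n_eff_bound <- 3 * sqrt(1 / nrow(pooled)) * 5  # generous SE for RW draws
  expect_lt(abs(mean(pooled)), n_eff_bound)
  expect_equal(var(as.vector(pooled)), 1, tolerance = 0.1)
  expect_true(all(ch$acceptance_rates > 0.1 & ch$acceptance_rates < 0.6))
})

test_that("NaN log-likelihoods are reported with the parameter vector", {
  ll <- function(theta) if (theta[["x"]] > 0.5) NaN else 0
  expect_error(run_mcmc(ll, prior_spec("x", 0, 1), n_chains = 1,
                        n_iter = 200, burn_in = 100, seed = 1),
               "NaN at theta")
})

test_that("split-Rhat detects gross non-convergence and passes the null", {
  set.seed(6)
  good <- array(rnorm(3 * 1000), dim = c(1000, 1, 3))
  expect_lt(gelman_rubin(good), 1.01)
  bad <- array(c(rnorm(1000, 0), rnorm(1000, 10)), dim = c(1000, 1, 2))
  expect_gt(gelman_rubin(bad), 1.1)
  # a duplicated chain split in two is self-consistent
  one <- rnorm(1000)
  dup <- array(c(one, one), dim = c(1000, 1, 2))
  expect_equal(as.numeric(gelman_rubin(dup)), 1, tolerance = 0.05)
  # degenerate chains return 1 with a flag
  const <- array(1, dim = c(100, 1, 2))
  r <- gelman_rubin(const)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "degenerate"))
})

test_that("credible intervals are equal-tailed empirical quantiles", {
  draws <- matrix(seq_len(1000) / 1000, ncol = 1,
                  dimnames = list(NULL, "q"))
  ci <- credible_interval(chains_from_draws(draws, "q"))
  oracle <- quantile(draws[, 1], c(0.025, 0.5, 0.975), names = FALSE)
  expect_equal(c(ci$lower, ci$point, ci$upper), oracle)
  # narrower level gives a narrower interval
  ci50 <- credible_interval(chains_from_draws(draws, "q"), level = 0.5)
  expect_lt(ci50$upper - ci50$lower, ci$upper - ci$lower)
  # constant draws give a zero-width interval
  const <- chains_from_draws(matrix(2, 500, 1, dimnames =
                                      list(NULL, "c")), "c")
  cic <- credible_interval(const)
  expect_equal(c(cic$lower, cic$point, cic$upper), c(2, 2, 2))
})

test_that("DIC: point-mass posterior has pD = 0; a fitted mean has pD ~ 1", {
  ll <- function(theta) dnorm(theta[["m"]], 1, 2, log = TRUE)
  const <- chains_from_draws(matrix(0.7, 600, 1,
                                    dimnames = list(NULL, "m")), "m")
  d0 <- dic(const, ll)
  expect_equal(d0$pd, 0, tolerance = 1e-10)
  expect_equal(d0$dic, -2 * ll(c(m = 0.7)), tolerance = 1e-10)

  set.seed(8)
  y <- rnorm(25, 3, 1)
  ll_mean <- function(theta) sum(dnorm(y, theta[["mu"]], 1, log = TRUE))
  ch <- run_mcmc(ll_mean, prior_spec("mu", -10, 10), n_chains = 3,
                 n_iter = 8000, burn_in = 4000, seed = 9)
  ch <- dic(ch, ll_mean)
  expect_equal(ch$pd, 1, tolerance = 0.15)
})

test_that("a flat extra parameter barely changes DIC", {
  set.seed(15)
  y <- rnorm(25, 3, 1)
  ll1 <- function(theta) sum(dnorm(y, theta[["mu"]], 1, log = TRUE))
  ll2 <- function(theta) sum(dnorm(y, theta[["mu"]], 1, log = TRUE)) + 0 *
    theta[["junk"]]
  ch1 <- dic(run_mcmc(ll1, prior_spec("mu", -10, 10), 3, 8000, 4000,
                      seed = 10), ll1)
  ch2 <- dic(run_mcmc(ll2, prior_spec(c("mu", "junk"), c(-10, 0),
                                      c(10, 1)), 3, 8000, 4000,
                      seed = 11), ll2)
  expect_lt(abs(ch2$dic - ch1$dic), 1)
  expect_lt(ch2$pd - ch1$pd, 0.3)
})

test_that("posterior draws export in long chain/iteration format", {
  ch <- run_mcmc(function(theta) 0, prior_spec(c("a", "b"), c(0, 0),
                                               c(1, 2)),
                 n_chains = 2, n_iter = 400, burn_in = 200, seed = 3)
  tab <- posterior_draws_table(ch)
  expect_equal(names(tab), c("chain", "iteration", "a", "b"))
  expect_equal(nrow(tab), 2 * 200)
  expect_true(all(tab$b <= 2))
})
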