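# Shared fixture builders for the test suite.

make_sentinels <- function(week = 1, n_exposed = 10, n_infested = 3,
                           duration = 7, n = length(week)) {
  data.frame(trial_id = sprintf("t%02d", seq_len(max(n, length(week)))),
             week_index = week, n_exposed = n_exposed,
             n_infested = n_infested, duration_days = duration,
             stringsAsFactors = FALSE)
}

make_fields <- function(week = 1, n_f = 2, i_f = 1, n_a = 0, i_a = 0,
                        site = "s1") {
  rbind(data.frame(week_index = week, site_id = site, species = "focal",
                   density = n_f, infested_density = i_f,
                   stringsAsFactors = FALSE),
        data.frame(week_index = week, site_id = site,
                   species = "alternative", density = n_a,
                   infested_density = i_a, stringsAsFactors = FALSE))
}

make_replicate <- function(id = "r1", treatment = "intraspecific",
                           source = "focal_sourced", added = 10,
                           on_donor = 5, on_receiver = 5, donor_cup = 0,
                           exp_cup = 0, receiver_cup = 0, hours = 18) {
  data.frame(replicate_id = id, treatment = treatment, source = source,
             worms_added = added, on_donor = on_donor,
             on_receiver = on_receiver, in_donor_cup = donor_cup,
             in_experimental_cup = exp_cup, in_receiver_cup = receiver_cup,
             duration_hours = hours, stringsAsFactors = FALSE)
}

# binomial dispersal cells as aggregate pseudo-replicates
make_cell_replicates <- function(treatment, source, dispersed, attached,
                                 id_prefix = "c") {
  make_replicate(id = paste0(id_prefix, treatment, source),
                 treatment = treatment, source = source,
                 added = attached, on_donor = attached - dispersed,
                 on_receiver = dispersed)
}

# wrap a draws matrix (or iters x params x chains array) as posterior_chains
chains_from_draws <- function(draws, params = colnames(draws),
                              n_chains = 2) {
  force(params)  # before draws is reshaped below
  if (length(dim(draws)) != 3) {
    n <- nrow(draws) %/% n_chains
    arr <- array(NA_real_, dim = c(n, ncol(draws), n_chains))
    for (ch in seq_len(n_chains)) {
      arr[, , ch] <- as.matrix(draws[((ch - 1) * n + 1):(ch * n), ,
                                     drop = FALSE])
    }
    draws <- arr
  }
  structure(list(draws = draws, parameters = params, rhat = NULL,
                 acceptance_rates = rep(0.3, dim(draws)[3]), seed = 1,
                 pd = NULL, dic = NULL), class = "posterior_chains")
}

# independent brute-force GLM maximum-likelihood oracle
glm_mle_oracle <- function(X, loglik_fun, start = rep(0, ncol(X))) {
  fit <- stats::optim(start, function(b) -loglik_fun(b), method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  fit2 <- stats::optim(fit$par, function(b) -loglik_fun(b),
                       method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 1000))
  fit2$par
}
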