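# Dispersal proportions, binomial/Poisson GLMs, worm-fate accounting.

test_that("dispersal_summary pools attached worms per group", {
  one <- make_replicate(on_donor = 5, on_receiver = 5)
  s <- dispersal_summary(one)
  row <- s[s$treatment == "intraspecific" & s$source == "focal_sourced", ]
  expect_equal(row$proportion, 0.5)
  expect_equal(row$attached, 10)
  # all worms stay on donors -> proportion 0 with exact lower bound 0
  zero <- rbind(make_replicate(id = "a", on_donor = 8, on_receiver = 0),
                make_replicate(id = "b", on_donor = 6, on_receiver = 0))
  sz <- dispersal_summary(zero)
  rowz <- sz[sz$treatment == "intraspecific" &
               sz$source == "focal_sourced", ]
  expect_equal(rowz$proportion, 0)
  expect_equal(rowz$lower, 0)
  # empty groups are flagged, not an error
  expect_true(any(sz$empty))
  # zero-attached replicates are excluded and counted
  excl <- rbind(one, make_replicate(id = "x", on_donor = 0,
                                    on_receiver = 0, donor_cup = 10))
  se <- dispersal_summary(excl)
  rowe <- se[se$treatment == "intraspecific" &
               se$source == "focal_sourced", ]
  expect_equal(rowe$n_excluded, 1)
  expect_equal(rowe$proportion, 0.5)
})

test_that("pooled proportion is invariant to ordering and row splitting", {
  set.seed(3)
  reps <- gen_transmission_experiment(seed = 31)
  a <- dispersal_summary(reps)
  b <- dispersal_summary(reps[sample(nrow(reps)), ])
  expect_equal(a, b)
  # merge each cell's rows into one aggregate pseudo-replicate
  merged <- do.call(rbind, lapply(split(reps,
                                        list(reps$treatment, reps$source),
                                        drop = TRUE), function(g) {
    g <- g[g$on_donor + g$on_receiver >= 1, ]
    make_cell_replicates(g$treatment[1], g$source[1],
                         sum(g$on_receiver),
                         sum(g$on_donor + g$on_receiver))
  }))
  m <- dispersal_summary(merged)
  key <- function(d) paste(d$treatment, d$source)
  m <- m[match(key(a), key(m)), ]
  expect_equal(a$proportion, m$proportion, tolerance = 1e-12)
})

test_that("two-group binomial coefficient equals the closed-form log OR", {
  reps <- rbind(
    make_cell_replicates("intraspecific", "focal_sourced", 10, 100),
    make_cell_replicates("interspecific", "focal_sourced", 30, 100))
  fit <- fit_binomial_glm(reps)
  expect_equal(unname(fit$coefficients["treatmentinterspecific"]),
               log((30 / 70) / (10 / 90)), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]), qlogis(0.1),
               tolerance = 1e-8)
  expect_equal(fit$link, "logit")
})

test_that("identical cell proportions give all-zero effects", {
  cells <- expand.grid(treatment = c("intraspecific", "interspecific"),
                       source = c("focal_sourced", "alternative_sourced"),
                       stringsAsFactors = FALSE)
  reps <- do.call(rbind, lapply(seq_len(4), function(i) {
    make_cell_replicates(cells$treatment[i], cells$source[i], 20, 80,
                         id_prefix = paste0("g", i))
  }))
  fit <- fit_binomial_glm(reps)
  expect_equal(unname(fit$coefficients[-1]), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.25),
               tolerance = 1e-8)
})

test_that("binomial IRLS matches a brute-force MLE oracle", {
  set.seed(21)
  for (i in 1:5) {
    reps <- gen_transmission_experiment(
      default_dispersal_truth(attach_fail_matched = 0.05,
                              attach_fail_mismatched = 0.15,
                              mortality_matched = 0.1,
                              mortality_mismatched = 0.3), seed = 300 + i)
    fit <- fit_binomial_glm(reps)
    x <- prepare_transmission(reps)
    x <- x[x$included, ]
    X <- model.matrix(~ treatment * source, x)
    y <- x$on_receiver
    n <- x$attached
    ll <- function(b) {
      eta <- drop(X %*% b)
      sum(y * eta - n * log1p(exp(eta)))
    }
    oracle <- glm_mle_oracle(X, ll)
    expect_equal(unname(fit$coefficients), unname(oracle),
                 tolerance = 1e-6)
    # standard errors vs the inverse observed-information oracle
    p_hat <- plogis(drop(X %*% fit$coefficients))
    info <- t(X) %*% (X * (n * p_hat * (1 - p_hat)))
    expect_equal(unname(fit$standard_errors),
                 unname(sqrt(diag(solve(info)))), tolerance = 1e-6)
  }
})

test_that("cell-aggregated and per-replicate binomial fits agree", {
  reps <- gen_transmission_experiment(seed = 77)
  fit_rows <- fit_binomial_glm(reps)
  merged <- do.call(rbind, lapply(split(reps,
                                        list(reps$treatment, reps$source),
                                        drop = TRUE), function(g) {
    g <- g[g$on_donor + g$on_receiver >= 1, ]
    make_cell_replicates(g$treatment[1], g$source[1],
                         sum(g$on_receiver),
                         sum(g$on_donor + g$on_receiver))
  }))
  fit_cells <- fit_binomial_glm(merged)
  expect_equal(fit_rows$coefficients, fit_cells$coefficients,
               tolerance = 1e-8)
})

test_that("Poisson GLM coefficient is the log ratio of group means", {
  reps <- rbind(
    do.call(rbind, lapply(1:4, function(i) {
      make_replicate(id = paste0("i", i), treatment = "intraspecific",
                     on_donor = c(3, 5, 4, 4)[i], on_receiver = 0)
    })),
    do.call(rbind, lapply(1:4, function(i) {
      make_replicate(id = paste0("e", i), treatment = "interspecific",
                     on_donor = c(7, 9, 8, 8)[i], on_receiver = 0)
    })))
  fit <- fit_poisson_glm(reps)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(4),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["treatmentinterspecific"]), log(2),
               tolerance = 1e-8)
  # identical groups -> null treatment effect
  same <- reps
  same$on_donor <- 5
  expect_equal(unname(fit_poisson_glm(same)$coefficients[2]), 0,
               tolerance = 1e-8)
})

test_that("Poisson IRLS matches a brute-force MLE oracle", {
  set.seed(13)
  for (i in 1:5) {
    reps <- gen_transmission_experiment(seed = 400 + i)
    fit <- fit_poisson_glm(reps)
    x <- prepare_transmission(reps)
    X <- model.matrix(~ treatment, x)
    y <- x$recovered_total
    ll <- function(b) {
      eta <- drop(X %*% b)
      sum(y * eta - exp(eta))
    }
    oracle <- glm_mle_oracle(X, ll, start = c(log(mean(y) + 0.1), 0))
    expect_equal(unname(fit$coefficients), unname(oracle),
                 tolerance = 1e-6)
  }
})

test_that("diverging coefficients are flagged, not silently reported", {
  # complete separation: receiver gets everything in one treatment only
  reps <- rbind(
    make_cell_replicates("intraspecific", "focal_sourced", 0, 50),
    make_cell_replicates("interspecific", "focal_sourced", 50, 50))
  w <- capture_warnings(fit <- fit_binomial_glm(reps))
  expect_true(any(grepl("diverging", w)))
  expect_true(fit$diverging)
})

test_that("worm_accounting conserves counts and reports fate breakdowns", {
  full <- make_replicate(on_donor = 6, on_receiver = 4)
  acc <- worm_accounting(full)
  expect_equal(acc$missing, 0)
  expect_equal(acc$excess, 0)
  # unattached split 33/3/2 -> 86.8 / 7.9 / 5.3 percent
  cups <- make_replicate(id = "c", treatment = "intraspecific",
                         source = "alternative_sourced", added = 48,
                         on_donor = 9, on_receiver = 1, donor_cup = 33,
                         exp_cup = 3, receiver_cup = 2)
  acc2 <- worm_accounting(cups)
  expect_equal(acc2$pct_unattached_donor_cup, 100 * 33 / 38,
               tolerance = 1e-10)
  expect_equal(acc2$pct_unattached_experimental_cup, 100 * 3 / 38,
               tolerance = 1e-10)
  expect_equal(acc2$pct_unattached_receiver_cup, 100 * 2 / 38,
               tolerance = 1e-10)
  expect_equal(round(c(acc2$pct_unattached_donor_cup,
                       acc2$pct_unattached_experimental_cup,
                       acc2$pct_unattached_receiver_cup), 1),
               c(86.8, 7.9, 5.3))
  # reproduction: recovered beyond added is excess, missing floors at zero
  repro <- make_replicate(id = "r", added = 10, on_donor = 9,
                          on_receiver = 6)
  acc3 <- worm_accounting(repro)
  expect_equal(acc3$missing, 0)
  expect_equal(acc3$excess, 5)
})
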