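# Pipeline orchestration: simulate -> fit -> compare -> report.
#
# Each command is a plain R function taking a run configuration (an R list
# or a YAML file path) and an output directory; outputs are pure functions
# of (inputs, config, seed). A thin command-line wrapper lives at
# inst/scripts/foidecomp.R.

#' Load a run configuration
#'
#' @param config A named list, or the path to a YAML file. Recognized
#'   blocks: `seed`, `mcmc` (`n_chains`, `n_iter`, `burn_in`), `paths`
#'   (input CSVs), plus free-form simulation overrides passed to
#'   [simulation_config()].
#' @return The configuration list.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$mcmc <- utils::modifyList(
    list(n_chains = 3, n_iter = 30000, burn_in = 15000), config$mcmc %||%
      list())
  if (config$mcmc$burn_in >= config$mcmc$n_iter) {
    stop("burn_in must be < n_iter", call. = FALSE)
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_run <- function(out_dir, command, seed, t0) {
  line <- sprintf("[%s] %s seed=%s elapsed=%.1fs %s v%s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), command,
                  as.character(seed),
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  "foidecomp",
                  as.character(utils::packageVersion("foidecomp")))
  message(line)
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Simulate all four datasets to disk
#'
#' Writes `field_survey.csv`, `sentinel_trials.csv`, `contact_trials.csv`,
#' `transmission.csv` and `truth.json` (the generating parameters) to
#' `out_dir`. Byte-identical across runs with the same config and seed.
#'
#' @param config Run configuration (list or YAML path); simulation
#'   overrides are taken from its `simulation` block if present.
#' @param out_dir Output directory.
#' @param seed Integer seed (overrides `config$seed`).
#' @return Named vector of written file paths, invisibly.
#' @export
cmd_simulate <- function(config = list(), out_dir, seed = NULL) {
  t0 <- Sys.time()
  config <- load_run_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("an explicit seed is required", call. = FALSE)
  .ensure_dir(out_dir)
  sim_args <- config$simulation %||% list()
  sc <- do.call(simulation_config, sim_args)
  season <- gen_field_season(sc, seed = seed)
  contacts <- gen_contact_experiment(sc$contact_truth, seed = seed + 1,
                                     densities = sc$contact_densities,
                                     reps = sc$contact_reps,
                                     obs_minutes = sc$obs_minutes,
                                     n_focal = sc$n_focal)
  trans <- gen_transmission_experiment(sc$dispersal_truth, seed = seed + 2,
                                       worms_added = sc$worms_added,
                                       duration_hours = sc$duration_hours,
                                       reproduction_rate =
                                         sc$reproduction_rate)
  paths <- c(field = file.path(out_dir, "field_survey.csv"),
             sentinel = file.path(out_dir, "sentinel_trials.csv"),
             contact = file.path(out_dir, "contact_trials.csv"),
             transmission = file.path(out_dir, "transmission.csv"))
  write_tables(season$fields, paths["field"], "field")
  write_tables(season$sentinels, paths["sentinel"], "sentinel")
  write_tables(contacts, paths["contact"], "contact")
  write_tables(trans, paths["transmission"], "transmission")
  truth <- list(seed = seed, foi = unclass(sc$foi_truth),
                contact = unclass(sc$contact_truth),
                dispersal = sc$dispersal_truth)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .log_run(out_dir, "simulate", seed, t0)
  invisible(paths)
}

.mcmc_settings <- function(config, fast = FALSE) {
  m <- config$mcmc
  if (fast) m <- list(n_chains = 3, n_iter = 4000, burn_in = 2000)
  m
}

#' Fit the multi-host and single-host FOI models
#'
#' Fits both models to the sentinel/field CSVs, writes posterior draws,
#' credible intervals, Rhat and a DIC comparison table, and (by default)
#' fails when any Rhat >= 1.01 — the convergence criterion applied to the
#' field fits.
#'
#' @param config Run configuration; `config$paths$sentinel` and
#'   `config$paths$field` name the input CSVs.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param fast Use the reduced 3 x 4000/2000 MCMC profile.
#' @param allow_unconverged Do not error on Rhat >= 1.01.
#' @return List with `multi` and `single` `posterior_chains` and the
#'   `dic_table`, invisibly.
#' @export
cmd_fit_foi <- function(config = list(), out_dir, seed = NULL,
                        fast = FALSE, allow_unconverged = FALSE) {
  t0 <- Sys.time()
  config <- load_run_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("an explicit seed is required", call. = FALSE)
  .ensure_dir(out_dir)
  sentinels <- read_tables(config$paths$sentinel, "sentinel")
  fields <- read_tables(config$paths$field, "field")
  m <- .mcmc_settings(config, fast)
  fits <- list(
    multi = fit_foi(sentinels, fields, "multi", m$n_chains, m$n_iter,
                    m$burn_in, seed = seed),
    single = fit_foi(sentinels, fields, "single", m$n_chains, m$n_iter,
                     m$burn_in, seed = seed + 100))
  for (nm in names(fits)) {
    utils::write.csv(posterior_draws_table(fits[[nm]]),
                     file.path(out_dir, paste0("foi_posterior_", nm,
                                               ".csv")),
                     row.names = FALSE)
  }
  dic_table <- data.frame(
    model = c("multi_host", "single_host"),
    pd = c(fits$multi$pd, fits$single$pd),
    dic = c(fits$multi$dic, fits$single$dic))
  utils::write.csv(dic_table, file.path(out_dir, "foi_dic.csv"),
                   row.names = FALSE)
  summaries <- lapply(fits, function(f) {
    list(credible_intervals = credible_interval(f), rhat = as.list(f$rhat),
         acceptance_rates = f$acceptance_rates, pd = f$pd, dic = f$dic)
  })
  jsonlite::write_json(summaries, file.path(out_dir, "foi_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  rhat_all <- c(fits$multi$rhat, fits$single$rhat)
  if (any(rhat_all >= 1.01) && !allow_unconverged) {
    stop(sprintf("MCMC not converged (max Rhat = %.3f); rerun longer or ",
                 max(rhat_all)), "pass allow_unconverged", call. = FALSE)
  }
  .log_run(out_dir, "fit-foi", seed, t0)
  invisible(list(multi = fits$multi, single = fits$single,
                 dic_table = dic_table))
}

#' Fit the Holling Type II contact model
#'
#' @inheritParams cmd_fit_foi
#' @return The `posterior_chains` fit, invisibly; writes posterior draws,
#'   a summary JSON and the fitted-curve table
#'   (`contact_curve.csv`: density, predicted mean, 95% band).
#' @export
cmd_fit_contacts <- function(config = list(), out_dir, seed = NULL,
                             fast = FALSE, allow_unconverged = FALSE) {
  t0 <- Sys.time()
  config <- load_run_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("an explicit seed is required", call. = FALSE)
  .ensure_dir(out_dir)
  trials <- read_tables(config$paths$contact, "contact")
  m <- .mcmc_settings(config, fast)
  fit <- fit_contacts(trials, m$n_chains, m$n_iter, m$burn_in, seed = seed)
  utils::write.csv(posterior_draws_table(fit),
                   file.path(out_dir, "contact_posterior.csv"),
                   row.names = FALSE)
  curve <- contact_curve_table(fit, densities =
                                 seq(1, max(trials$alt_density)))
  utils::write.csv(curve, file.path(out_dir, "contact_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(credible_intervals = credible_interval(fit),
         rhat = as.list(fit$rhat), acceptance_rates = fit$acceptance_rates),
    file.path(out_dir, "contact_summary.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  if (any(fit$rhat >= 1.01) && !allow_unconverged) {
    stop(sprintf("MCMC not converged (max Rhat = %.3f)", max(fit$rhat)),
         call. = FALSE)
  }
  .log_run(out_dir, "fit-contacts", seed, t0)
  invisible(fit)
}

#' Fit the transmission-success GLMs and fate table
#'
#' @inheritParams cmd_fit_foi
#' @return List with `binomial` and `binomial_main_effects` fits (the
#'   interaction and main-effects parameterizations), the `poisson` fit,
#'   `dispersal` summary and `fates` table, invisibly; each also written
#'   as CSV.
#' @export
cmd_fit_transmission <- function(config = list(), out_dir, seed = NULL) {
  t0 <- Sys.time()
  config <- load_run_config(config)
  .ensure_dir(out_dir)
  reps <- read_tables(config$paths$transmission, "transmission")
  binom_fit <- fit_binomial_glm(reps)
  binom_main <- fit_binomial_glm(reps, interaction = FALSE)
  pois_fit <- fit_poisson_glm(reps)
  disp <- dispersal_summary(reps)
  fates <- worm_accounting(reps)
  coef_table <- function(f) data.frame(term = names(f$coefficients),
                                       estimate = f$coefficients,
                                       se = f$standard_errors,
                                       z = f$z_values, p = f$p_values,
                                       row.names = NULL)
  utils::write.csv(coef_table(binom_fit),
                   file.path(out_dir, "glm_binomial.csv"),
                   row.names = FALSE)
  utils::write.csv(coef_table(binom_main),
                   file.path(out_dir, "glm_binomial_main_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(coef_table(pois_fit),
                   file.path(out_dir, "glm_poisson.csv"),
                   row.names = FALSE)
  utils::write.csv(disp, file.path(out_dir, "dispersal_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(fates, file.path(out_dir, "worm_fates.csv"),
                   row.names = FALSE)
  .log_run(out_dir, "fit-transmission", config$seed %||% "none", t0)
  invisible(list(binomial = binom_fit, binomial_main_effects = binom_main,
                 poisson = pois_fit, dispersal = disp, fates = fates))
}

#' Assemble a human-readable summary report
#'
#' Collects whatever outputs of the fit commands exist in `out_dir` into a
#' single markdown document (`report.md`); absent sections are marked as
#' such rather than failing.
#'
#' @param config Run configuration (unused except for logging).
#' @param out_dir Directory holding fit outputs; the report is written
#'   there.
#' @return Path of the report, invisibly.
#' @export
cmd_report <- function(config = list(), out_dir) {
  t0 <- Sys.time()
  .ensure_dir(out_dir)
  lines <- c("# Transmission decomposition report", "")
  section <- function(title, file, render) {
    path <- file.path(out_dir, file)
    c(paste("##", title), "",
      if (file.exists(path)) render(utils::read.csv(path))
      else "_Section absent: no fit output found._", "")
  }
  tab <- function(df) {
    hdr <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r) paste("|",
                                           paste(format(r, digits = 4),
                                                 collapse = " | "), "|"))
    c(hdr, sep, body)
  }
  lines <- c(lines,
             section("FOI model comparison (DIC)", "foi_dic.csv", tab),
             section("Contact-rate fitted curve", "contact_curve.csv",
                     function(df) tab(utils::head(df, 10))),
             section("Dispersal proportions", "dispersal_summary.csv",
                     tab),
             section("Binomial GLM (treatment x source)",
                     "glm_binomial.csv", tab),
             section("Poisson GLM (surviving symbionts)",
                     "glm_poisson.csv", tab),
             section("Worm-fate accounting", "worm_fates.csv", tab))
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  .log_run(out_dir, "report", "none", t0)
  invisible(path)
}
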