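# Synthetic-data generators mirroring the three study stages, with known
# ground truth so every fit can be validated by parameter recovery.

#' Default simulation configuration
#'
#' The defaults encode the study conditions: a 22-week season (weeks 0-21)
#' surveyed at 8 sites where alternative-host density peaks early (max mean
#' 24 snails per 0.1 m^2) and focal density later, with infestation
#' prevalence for both species peaking late in the season; 8 sentinel
#' enclosure trials of ~1 week; a contact experiment with alternative-host
#' densities 1-14, 16, 18 at 3 replicates each and 45-min observations;
#' and a 2x2 transmission-success experiment (treatment x symbiont source)
#' with replicate counts 20/21/40/49 and 10 worms added per replicate.
#'
#' @param foi_truth [foi_params()] generating the sentinel data.
#' @param weeks Integer vector of survey weeks.
#' @param n_sites Survey sites per week.
#' @param alt_mean,focal_mean Per-week mean densities (recycled/evaluated
#'   over `weeks`); defaults are smooth unimodal trajectories.
#' @param prevalence Per-week infestation prevalence shared by both species.
#' @param trial_weeks,n_exposed,duration_days Sentinel design.
#' @param contact_truth [holling_params()] generating contact data.
#' @param contact_densities,contact_reps,obs_minutes,n_focal Contact design.
#' @param dispersal_truth Data.frame with one row per treatment x source
#'   cell: `treatment`, `source`, `n_replicates`, `dispersal_prob`,
#'   `attach_fail`, `mortality`; defaults reproduce the observed pattern
#'   that symbionts attach poorly (and die more often) when the donor
#'   species differs from their wild source species.
#' @param worms_added Worms added per replicate (default 10).
#' @param duration_hours Pairing duration (default 18).
#' @param reproduction_rate Poisson mean of clonal additions per occupied
#'   snail at the end of the window (default 0).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(
    foi_truth = foi_params(0.10, 1.0, 0.01, 0.5),
    weeks = 0:21, n_sites = 8,
    alt_mean = 24 * exp(-((weeks - 5) / 4)^2),
    focal_mean = 8 * exp(-((weeks - 14) / 5)^2),
    prevalence = 0.75 * exp(-((weeks - 16) / 8)^2),
    trial_weeks = c(1, 3, 5, 7, 9, 11, 15, 19),
    n_exposed = 20, duration_days = 7,
    contact_truth = holling_params(0.012, 3.25, 1),
    contact_densities = c(1:14, 16, 18), contact_reps = 3,
    obs_minutes = 45, n_focal = 3,
    dispersal_truth = default_dispersal_truth(),
    worms_added = 10, duration_hours = 18, reproduction_rate = 0) {
  stopifnot(length(alt_mean) == length(weeks),
            length(focal_mean) == length(weeks),
            length(prevalence) == length(weeks),
            all(prevalence >= 0), all(prevalence <= 1),
            all(alt_mean >= 0), all(focal_mean >= 0),
            all(trial_weeks %in% weeks), n_sites >= 1)
  if (any(prevalence > 1)) stop("prevalence > 1", call. = FALSE)
  structure(list(foi_truth = foi_truth, weeks = weeks, n_sites = n_sites,
                 alt_mean = alt_mean, focal_mean = focal_mean,
                 prevalence = prevalence, trial_weeks = trial_weeks,
                 n_exposed = n_exposed, duration_days = duration_days,
                 contact_truth = contact_truth,
                 contact_densities = contact_densities,
                 contact_reps = contact_reps, obs_minutes = obs_minutes,
                 n_focal = n_focal, dispersal_truth = dispersal_truth,
                 worms_added = worms_added, duration_hours = duration_hours,
                 reproduction_rate = reproduction_rate),
            class = "sim_config")
}

#' Default transmission-experiment ground truth
#'
#' Cell dispersal probabilities (0.32, 0.83, 0.08, 0.03) at replicate
#' counts 20/21/40/49. Attachment failure and off-host mortality are low
#' when the donor species matches the symbionts' wild source species and
#' high when it does not.
#'
#' @param attach_fail_matched,attach_fail_mismatched Probability a worm
#'   never attaches to the donor (ends in the donor cup).
#' @param mortality_matched,mortality_mismatched Probability an attached
#'   worm dies and goes missing during the trial.
#' @return Data.frame with one row per treatment x source cell.
#' @export
default_dispersal_truth <- function(attach_fail_matched = 0.01,
                                    attach_fail_mismatched = 0.24,
                                    mortality_matched = 0.2,
                                    mortality_mismatched = 0.6) {
  cells <- data.frame(
    treatment = c("intraspecific", "interspecific",
                  "intraspecific", "interspecific"),
    source = c("focal_sourced", "focal_sourced",
               "alternative_sourced", "alternative_sourced"),
    n_replicates = c(20, 21, 40, 49),
    dispersal_prob = c(0.32, 0.83, 0.08, 0.03),
    stringsAsFactors = FALSE)
  # donor species is focal in the intraspecific treatment, alternative in
  # the interspecific treatment; "matched" = donor equals source species
  matched <- (cells$treatment == "intraspecific" &
                cells$source == "focal_sourced") |
    (cells$treatment == "interspecific" &
       cells$source == "alternative_sourced")
  cells$attach_fail <- ifelse(matched, attach_fail_matched,
                              attach_fail_mismatched)
  cells$mortality <- ifelse(matched, mortality_matched,
                            mortality_mismatched)
  cells
}

#' Simulate a field season and its sentinel trials
#'
#' Weekly site densities are Poisson around the configured trajectory
#' means; infested densities are Binomial(N, prevalence). Sentinel
#' infestations are Binomial(n_exposed, 1 - exp(-FOI * t)) where the FOI
#' is computed from the generating parameters and the same week's
#' simulated (site-averaged) field state — so the fitted model sees
#' exactly the covariates its likelihood assumes.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List with validated `fields` and `sentinels` data.frames and
#'   `truth` (the generating [foi_params()]).
#' @export
gen_field_season <- function(config = simulation_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  wk <- rep(config$weeks, each = config$n_sites)
  site <- rep(sprintf("site%02d", seq_len(config$n_sites)),
              times = length(config$weeks))
  alt_mu <- rep(config$alt_mean, each = config$n_sites)
  foc_mu <- rep(config$focal_mean, each = config$n_sites)
  prev <- rep(config$prevalence, each = config$n_sites)
  n_a <- stats::rpois(length(wk), alt_mu)
  n_f <- stats::rpois(length(wk), foc_mu)
  i_a <- stats::rbinom(length(wk), n_a, prev)
  i_f <- stats::rbinom(length(wk), n_f, prev)
  fields <- rbind(
    data.frame(week_index = wk, site_id = site, species = "focal",
               density = n_f, infested_density = i_f,
               stringsAsFactors = FALSE),
    data.frame(week_index = wk, site_id = site, species = "alternative",
               density = n_a, infested_density = i_a,
               stringsAsFactors = FALSE))
  fields <- fields[order(fields$week_index, fields$site_id,
                         fields$species), ]
  rownames(fields) <- NULL

  state <- .weekly_field_state(fields)
  idx <- match(config$trial_weeks, state$week_index)
  foi <- foi_multi_host(config$foi_truth, state$n_f[idx], state$i_f[idx],
                        state$n_a[idx], state$i_a[idx])
  p <- prob_infested(foi, config$duration_days)
  sentinels <- data.frame(
    trial_id = sprintf("trial%02d", seq_along(config$trial_weeks)),
    week_index = config$trial_weeks,
    n_exposed = config$n_exposed,
    n_infested = stats::rbinom(length(p), config$n_exposed, p),
    duration_days = config$duration_days, stringsAsFactors = FALSE)
  list(fields = validate_table(fields, "field"),
       sentinels = validate_table(sentinels, "sentinel"),
       truth = config$foi_truth)
}

#' Simulate the contact-rate experiment
#'
#' Container means are the Holling Type II expectation plus Normal(0,
#' sigma) noise, truncated at zero (mean contacts cannot be negative).
#' Containers are laid out over trial days of eight containers each, as in
#' the experimental design.
#'
#' @param contact_truth A [holling_params()].
#' @param seed Integer seed.
#' @param densities,reps,obs_minutes,n_focal Design (defaults: densities
#'   1-14, 16, 18; 3 replicates; 45 min; 3 focal snails).
#' @return A validated contact-trial data.frame.
#' @export
gen_contact_experiment <- function(contact_truth = holling_params(0.012,
                                                                  3.25, 1),
                                   seed, densities = c(1:14, 16, 18),
                                   reps = 3, obs_minutes = 45,
                                   n_focal = 3) {
  set.seed(seed)
  N <- rep(densities, times = reps)
  mu <- holling_mean_contacts(contact_truth, N, obs_minutes)
  y <- pmax(0, stats::rnorm(length(N), mu, contact_truth$sigma))
  out <- data.frame(
    container_id = sprintf("tank%02d", seq_along(N)),
    trial_day = rep(seq_len(ceiling(length(N) / 8)), each = 8,
                    length.out = length(N)),
    alt_density = N, n_focal = n_focal, mean_contacts = y,
    obs_minutes = obs_minutes, stringsAsFactors = FALSE)
  validate_table(out, "contact")
}

#' Simulate the transmission-success experiment
#'
#' Each added worm independently: fails to attach to the donor (ending in
#' the donor cup) with the cell's attachment-failure probability;
#' otherwise dies and goes missing with the cell's mortality probability;
#' otherwise disperses to the receiver with the cell's dispersal
#' probability or stays on the donor. Optional asexual reproduction adds
#' Poisson(rate) clonal worms to each occupied snail at the end of the
#' window.
#'
#' @param dispersal_truth Cell table as in [default_dispersal_truth()].
#' @param seed Integer seed.
#' @param worms_added Worms added per replicate (default 10).
#' @param duration_hours Pairing duration (default 18).
#' @param reproduction_rate Poisson mean of clonal additions (default 0).
#' @return A validated transmission data.frame.
#' @export
gen_transmission_experiment <- function(dispersal_truth =
                                          default_dispersal_truth(),
                                        seed, worms_added = 10,
                                        duration_hours = 18,
                                        reproduction_rate = 0) {
  stopifnot(all(c("treatment", "source", "n_replicates", "dispersal_prob",
                  "attach_fail", "mortality") %in% names(dispersal_truth)))
  set.seed(seed)
  rows <- list()
  rid <- 0
  for (g in seq_len(nrow(dispersal_truth))) {
    cell <- dispersal_truth[g, ]
    for (r in seq_len(cell$n_replicates)) {
      rid <- rid + 1
      fail <- stats::rbinom(1, worms_added, cell$attach_fail)
      attached <- worms_added - fail
      dead <- stats::rbinom(1, attached, cell$mortality)
      alive <- attached - dead
      on_receiver <- stats::rbinom(1, alive, cell$dispersal_prob)
      on_donor <- alive - on_receiver
      if (reproduction_rate > 0) {
        if (on_donor > 0) on_donor <- on_donor +
            stats::rpois(1, reproduction_rate)
        if (on_receiver > 0) on_receiver <- on_receiver +
            stats::rpois(1, reproduction_rate)
      }
      rows[[rid]] <- data.frame(
        replicate_id = sprintf("rep%03d", rid),
        treatment = cell$treatment, source = cell$source,
        worms_added = worms_added, on_donor = on_donor,
        on_receiver = on_receiver, in_donor_cup = fail,
        in_experimental_cup = 0, in_receiver_cup = 0,
        duration_hours = duration_hours, stringsAsFactors = FALSE)
    }
  }
  validate_table(do.call(rbind, rows), "transmission")
}
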