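# Laboratory transmission-success analysis: dispersal proportions, binomial
# and Poisson GLMs, and worm-fate accounting.
#
# Dispersal is defined as the proportion of snail-attached worms found on
# the receiver snail at dissection; worms recovered loose in cups (or
# missing) never made the donor-to-receiver choice and are excluded from
# that denominator. Reference levels are treatment = intraspecific and
# source = focal_sourced, so the "interspecific" coefficient is the
# treatment effect within focal-sourced replicates.

.tr_factors <- function(replicates) {
  replicates$treatment <- factor(replicates$treatment,
                                 levels = .treatment_levels)
  replicates$source <- factor(replicates$source, levels = .source_levels)
  replicates
}

#' Prepare transmission replicates for model fitting
#'
#' Adds derived columns (`attached`, `recovered_total`) and flags rows
#' excluded from model fits: short-duration replicates (< `min_hours`,
#' default 18 h — the early 1 h replicates are kept in the data but not
#' modelled) and replicates with no snail-attached worms.
#'
#' @param replicates Transmission records (see [table_schemas]).
#' @param min_hours Minimum pairing duration for inclusion (default 18).
#' @return The validated data.frame with columns `attached`,
#'   `recovered_total`, `included` added.
#' @export
prepare_transmission <- function(replicates, min_hours = 18) {
  x <- validate_table(replicates, "transmission")
  x$attached <- x$on_donor + x$on_receiver
  x$recovered_total <- x$on_donor + x$on_receiver + x$in_donor_cup +
    x$in_experimental_cup + x$in_receiver_cup
  x$included <- x$duration_hours >= min_hours & x$attached >= 1
  .tr_factors(x)
}

#' Pooled dispersal proportions with exact intervals
#'
#' Per group (default treatment x source), the pooled proportion of
#' attached worms found on the receiver, `sum(on_receiver) /
#' sum(on_donor + on_receiver)`, with a Clopper-Pearson interval.
#' Replicates with zero attached worms are excluded and counted in
#' `n_excluded`; empty groups are returned with `NA` estimates and
#' `empty = TRUE` rather than raising an error.
#'
#' @param replicates Transmission records.
#' @param group_by Character vector of grouping columns (subset of
#'   `c("treatment", "source")`).
#' @param level Interval level (default 0.95).
#' @param min_hours Passed to [prepare_transmission()].
#' @return Data.frame with one row per group: totals, `proportion`,
#'   `lower`, `upper`, `n_replicates`, `n_excluded`, `empty`.
#' @export
dispersal_summary <- function(replicates,
                              group_by = c("treatment", "source"),
                              level = 0.95, min_hours = 18) {
  stopifnot(all(group_by %in% c("treatment", "source")))
  x <- prepare_transmission(replicates, min_hours)
  grid <- expand.grid(lapply(x[group_by], levels),
                      stringsAsFactors = FALSE)
  names(grid) <- group_by
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sel <- rep(TRUE, nrow(x))
    for (cc in group_by) sel <- sel & x[[cc]] == grid[[cc]][g]
    grp <- x[sel & x$included, ]
    n_excl <- sum(sel) - nrow(grp)
    if (nrow(grp) == 0) {
      return(cbind(grid[g, , drop = FALSE],
                   data.frame(dispersed = NA, attached = NA,
                              proportion = NA, lower = NA, upper = NA,
                              n_replicates = 0, n_excluded = n_excl,
                              empty = TRUE)))
    }
    s <- sum(grp$on_receiver)
    tot <- sum(grp$attached)
    ci <- binom_ci(s, tot, level)
    cbind(grid[g, , drop = FALSE],
          data.frame(dispersed = s, attached = tot, proportion = ci$point,
                     lower = ci$lower, upper = ci$upper,
                     n_replicates = nrow(grp), n_excluded = n_excl,
                     empty = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.glm_fit_record <- function(fit, link) {
  sm <- summary(fit)$coefficients
  diverging <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (diverging) {
    warning("diverging coefficient (|coef| > 15 on the link scale); ",
            "possible complete separation or an all-zero group",
            call. = FALSE)
  }
  structure(list(coefficients = sm[, 1], standard_errors = sm[, 2],
                 z_values = sm[, 3], p_values = sm[, 4],
                 residual_df = fit$df.residual, deviance = fit$deviance,
                 link = link, converged = fit$converged,
                 diverging = diverging, model = fit),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("GLM (%s link), residual d.f. = %d, deviance = %.2f%s\n",
              x$link, x$residual_df, x$deviance,
              if (x$diverging) " [diverging coefficient]" else ""))
  print(data.frame(estimate = x$coefficients, se = x$standard_errors,
                   z = x$z_values, p = x$p_values))
  invisible(x)
}

#' Binomial GLM for dispersal success
#'
#' Fits `cbind(on_receiver, on_donor) ~ treatment * source` with a logit
#' link by IRLS on the included replicates (18 h duration, at least one
#' attached worm). Factors that take a single level in the data are
#' dropped from the formula automatically, and the interaction is included
#' only when both factors vary. Coefficients with `|estimate| > 15` on the
#' logit scale are flagged as diverging (complete separation).
#'
#' @param replicates Transmission records.
#' @param interaction Include the treatment x source interaction when both
#'   factors vary (default TRUE); set FALSE for the main-effects model.
#' @param min_hours Passed to [prepare_transmission()].
#' @return A `glm_fit` object.
#' @export
fit_binomial_glm <- function(replicates, interaction = TRUE,
                             min_hours = 18) {
  x <- prepare_transmission(replicates, min_hours)
  x <- droplevels(x[x$included, ])
  if (nrow(x) < 2) stop("too few usable replicates", call. = FALSE)
  vary <- vapply(c("treatment", "source"),
                 function(cc) length(unique(x[[cc]])) > 1, TRUE)
  terms <- names(vary)[vary]
  rhs <- if (length(terms) == 0) "1"
         else if (length(terms) == 2 && interaction) "treatment * source"
         else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste("cbind(on_receiver, on_donor) ~", rhs))
  fit <- stats::glm(f, family = stats::binomial("logit"), data = x,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  if (!fit$converged) stop("IRLS failed to converge", call. = FALSE)
  .glm_fit_record(fit, "logit")
}

#' Poisson GLM for symbiont survival
#'
#' Fits `recovered_total ~ treatment` with a log link: the exponentiated
#' treatment coefficient is the ratio of group mean surviving-worm counts.
#'
#' @param replicates Transmission records.
#' @param min_hours Passed to [prepare_transmission()]; zero-attached
#'   replicates are retained here (survival does not require attachment).
#' @return A `glm_fit` object.
#' @export
fit_poisson_glm <- function(replicates, min_hours = 18) {
  x <- prepare_transmission(replicates, min_hours)
  x <- droplevels(x[x$duration_hours >= min_hours, ])
  if (nrow(x) < 2) stop("too few usable replicates", call. = FALSE)
  vary <- length(unique(x$treatment)) > 1
  f <- if (vary) recovered_total ~ treatment else recovered_total ~ 1
  fit <- stats::glm(f, family = stats::poisson("log"), data = x,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  if (!fit$converged) stop("IRLS failed to converge", call. = FALSE)
  .glm_fit_record(fit, "log")
}

#' Worm-fate accounting table
#'
#' Per treatment x source cell: worms added, worms on each snail at
#' dissection, unattached worms by cup type with percentage breakdowns,
#' worms missing (`max(0, added - recovered)` per replicate) and excess
#' recovered beyond additions (asexual reproduction during the trial).
#'
#' @param replicates Transmission records.
#' @return Data.frame, one row per non-empty cell plus totals in columns.
#' @export
worm_accounting <- function(replicates) {
  x <- prepare_transmission(replicates, min_hours = 0)
  cells <- unique(x[c("treatment", "source")])
  cells <- cells[order(cells$treatment, cells$source), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(g) {
    grp <- x[x$treatment == cells$treatment[g] &
               x$source == cells$source[g], ]
    unatt <- c(donor_cup = sum(grp$in_donor_cup),
               experimental_cup = sum(grp$in_experimental_cup),
               receiver_cup = sum(grp$in_receiver_cup))
    tot_unatt <- sum(unatt)
    pct <- if (tot_unatt > 0) 100 * unatt / tot_unatt else unatt * NA
    recovered <- sum(grp$recovered_total)
    data.frame(treatment = as.character(cells$treatment[g]),
               source = as.character(cells$source[g]),
               n_replicates = nrow(grp),
               added = sum(grp$worms_added),
               on_donor = sum(grp$on_donor),
               on_receiver = sum(grp$on_receiver),
               in_donor_cup = unatt[["donor_cup"]],
               in_experimental_cup = unatt[["experimental_cup"]],
               in_receiver_cup = unatt[["receiver_cup"]],
               unattached = tot_unatt,
               recovered = recovered,
               pct_unattached = if (recovered > 0)
                 100 * tot_unatt / recovered else NA_real_,
               pct_unattached_donor_cup = pct[["donor_cup"]],
               pct_unattached_experimental_cup = pct[["experimental_cup"]],
               pct_unattached_receiver_cup = pct[["receiver_cup"]],
               missing = sum(pmax(0, grp$worms_added -
                                    grp$recovered_total)),
               excess = sum(pmax(0, grp$recovered_total -
                                   grp$worms_added)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
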