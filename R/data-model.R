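# Domain records and CSV I/O for the transmission-decomposition analysis.
#
# All tables are plain data.frames in long format, one record per row.
# Densities are expressed package-wide as snails per 0.1 m^2.

#' Column schemas for the four canonical CSV dialects
#'
#' Names are the dataset kinds accepted by [read_tables()] and
#' [write_tables()]; each entry gives the required columns in order.
#'
#' @format A named list of character vectors.
#' @export
table_schemas <- list(
  field = c("week_index", "site_id", "species", "density", "infested_density"),
  sentinel = c("trial_id", "week_index", "n_exposed", "n_infested",
               "duration_days"),
  contact = c("container_id", "trial_day", "alt_density", "n_focal",
              "mean_contacts", "obs_minutes"),
  transmission = c("replicate_id", "treatment", "source", "worms_added",
                   "on_donor", "on_receiver", "in_donor_cup",
                   "in_experimental_cup", "in_receiver_cup", "duration_hours")
)

.species_levels <- c("focal", "alternative")
.treatment_levels <- c("intraspecific", "interspecific")
.source_levels <- c("focal_sourced", "alternative_sourced")

.stop_rows <- function(bad, msg) {
  if (any(bad)) {
    stop(sprintf("%s (row%s %s)", msg, if (sum(bad) > 1) "s" else "",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
}

#' Validate a table of domain records
#'
#' Checks the type invariants of one of the four canonical record kinds:
#' non-negative densities and counts, infested density never exceeding total
#' density, infested sentinels never exceeding exposed sentinels, and valid
#' factor levels. Errors are row-addressed.
#'
#' @param x A data.frame with the columns of `table_schemas[[schema]]`.
#' @param schema One of `"field"`, `"sentinel"`, `"contact"`,
#'   `"transmission"`.
#' @return `x`, invisibly column-ordered to the schema, with numeric columns
#'   coerced.
#' @export
validate_table <- function(x, schema = c("field", "sentinel", "contact",
                                         "transmission")) {
  schema <- match.arg(schema)
  cols <- table_schemas[[schema]]
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop(sprintf("schema error: %s table is missing column%s %s", schema,
                 if (length(missing) > 1) "s" else "",
                 paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
  x <- as.data.frame(x)[cols]
  num_cols <- setdiff(cols, c("site_id", "trial_id", "container_id",
                              "replicate_id", "species", "treatment",
                              "source"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    .stop_rows(is.na(v), sprintf("non-numeric value in column '%s'", cc))
    x[[cc]] <- v
  }
  switch(schema,
    field = {
      .stop_rows(!x$species %in% .species_levels,
                 "species must be 'focal' or 'alternative'")
      .stop_rows(x$density < 0, "density must be >= 0")
      .stop_rows(x$infested_density < 0, "infested_density must be >= 0")
      .stop_rows(x$infested_density > x$density,
                 "infested_density exceeds density")
    },
    sentinel = {
      .stop_rows(x$n_exposed < 1, "n_exposed must be >= 1")
      .stop_rows(x$n_infested < 0, "n_infested must be >= 0")
      .stop_rows(x$n_infested > x$n_exposed, "n_infested exceeds n_exposed")
      .stop_rows(x$duration_days <= 0, "duration_days must be > 0")
    },
    contact = {
      .stop_rows(x$alt_density < 1, "alt_density must be >= 1")
      .stop_rows(x$mean_contacts < 0, "mean_contacts must be >= 0")
      .stop_rows(x$obs_minutes <= 0, "obs_minutes must be > 0")
      .stop_rows(x$n_focal < 1, "n_focal must be >= 1")
    },
    transmission = {
      .stop_rows(!x$treatment %in% .treatment_levels,
                 "treatment must be 'intraspecific' or 'interspecific'")
      .stop_rows(!x$source %in% .source_levels,
                 "source must be 'focal_sourced' or 'alternative_sourced'")
      counts <- c("worms_added", "on_donor", "on_receiver", "in_donor_cup",
                  "in_experimental_cup", "in_receiver_cup")
      for (cc in counts) .stop_rows(x[[cc]] < 0,
                                    sprintf("%s must be >= 0", cc))
      .stop_rows(x$duration_hours <= 0, "duration_hours must be > 0")
    }
  )
  invisible(x)
}

#' Read a canonical CSV table
#'
#' Reads one of the four CSV dialects (comma-separated, UTF-8, header row
#' required) and validates every row against the record invariants.
#'
#' @param path Path to the CSV file.
#' @param schema Dataset kind; see [table_schemas].
#' @return A validated data.frame.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_tables(data.frame(trial_id = "t1", week_index = 1, n_exposed = 10,
#'                         n_infested = 3, duration_days = 7), tf, "sentinel")
#' read_tables(tf, "sentinel")
read_tables <- function(path, schema = c("field", "sentinel", "contact",
                                         "transmission")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  out <- validate_table(x, schema)
  out
}

#' Write a canonical CSV table
#'
#' @param x Data.frame of records; validated before writing.
#' @param path Output CSV path.
#' @param schema Dataset kind; see [table_schemas].
#' @return `path`, invisibly.
#' @export
write_tables <- function(x, path, schema = c("field", "sentinel", "contact",
                                             "transmission")) {
  schema <- match.arg(schema)
  x <- validate_table(x, schema)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Interval estimate record
#'
#' Lightweight container for a point estimate with an asymmetric interval.
#'
#' @param point Point estimate.
#' @param lower,upper Interval endpoints, `lower <= point <= upper`.
#' @param level Coverage level in (0, 1).
#' @param method One of `"binomial_exact"`, `"poisson_exact"`,
#'   `"posterior_quantile"`.
#' @return An object of class `interval_estimate` (a named list).
#' @export
interval_estimate <- function(point, lower, upper, level = 0.95,
                              method = c("binomial_exact", "poisson_exact",
                                         "posterior_quantile")) {
  method <- match.arg(method)
  stopifnot(level > 0, level < 1)
  if (!(lower <= point + 1e-12 && point <= upper + 1e-12)) {
    stop("interval must satisfy lower <= point <= upper", call. = FALSE)
  }
  structure(list(point = point, lower = lower, upper = upper, level = level,
                 method = method), class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.4g [%.4g, %.4g] (%s, %g%%)\n", x$point, x$lower, x$upper,
              x$method, 100 * x$level))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The asymmetric exact interval for a binomial proportion, based on beta
#' quantiles. `lower = 0` iff `x = 0` and `upper = 1` iff `x = n`.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Coverage level (default 0.95).
#' @return An [interval_estimate()] with `point = x/n`.
#' @export
#' @examples
#' binom_ci(3, 10)
binom_ci <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1)
  if (n < 1 || x < 0 || x > n) {
    stop("binom_ci requires 0 <= x <= n and n >= 1", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  interval_estimate(x / n, lower, upper, level, "binomial_exact")
}

#' Exact Poisson confidence interval for a single count
#'
#' Gamma (equivalently chi-square) based exact interval for a Poisson mean
#' observed as a single count. `lower = 0` iff `count = 0`; for a zero count
#' the upper bound is `-log(alpha/2)`.
#'
#' @param count Observed count, `>= 0`.
#' @param level Coverage level (default 0.95).
#' @return An [interval_estimate()] with `point = count`.
#' @export
#' @examples
#' poisson_ci(10)
poisson_ci <- function(count, level = 0.95) {
  stopifnot(length(count) == 1)
  if (count < 0) stop("poisson_ci requires count >= 0", call. = FALSE)
  alpha <- 1 - level
  lower <- if (count == 0) 0 else stats::qgamma(alpha / 2, count)
  upper <- stats::qgamma(1 - alpha / 2, count + 1)
  interval_estimate(count, lower, upper, level, "poisson_exact")
}
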