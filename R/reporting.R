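# Publication-style reporting: age-group/race-sex aggregates of a
# trajectory and the arithmetic statistics derived from them (shares, fold
# changes, average annual changes, undiagnosed-adjusted totals, scenario
# differences).
#
# Rounding conventions: counts to 2 decimals in millions, percents and
# derived statistics to 1 decimal, headline scenario differences to whole
# millions.  Percent denominators are the model's alive population
# (n_nd + n_d), the only denominator consistent with the engine's
# conservation of the census population.

.dp_age_groups <- function() {
  list("18-44" = 18:44, "45-64" = 45:64, "65-74" = 65:74, ">=75" = 75:85)
}

#' Aggregate a trajectory into a projection report
#'
#' @param traj A `dp_trajectory`.
#' @param groups `"age"` (bins 18-44, 45-64, 65-74, >=75 plus `total`) or
#'   `"racesex"` (six race-sex cohorts plus `total`).
#' @param years Years to report (must lie in the trajectory span).
#' @param digits_count,digits_pct Rounding applied to counts (millions) and
#'   percents; `NA` keeps full precision.
#' @return A `dp_report` data.frame: `year, group, count, percent` with
#'   counts in millions.
#' @export
aggregate_report <- function(traj, groups = c("age", "racesex"),
                             years = NULL,
                             digits_count = 2, digits_pct = 1) {
  groups <- match.arg(groups)
  span <- as.integer(names(traj$states))
  if (is.null(years)) years <- span
  if (!all(years %in% span))
    stop("years outside the trajectory span: ",
         paste(setdiff(years, span), collapse = ", "), call. = FALSE)
  rows <- list()
  for (y in years) {
    s <- traj$states[[as.character(y)]]
    memb <- if (groups == "age") {
      lapply(.dp_age_groups(), function(a) s$age %in% a)
    } else {
      cs <- paste(s$race, s$sex, sep = ":")
      lab <- unique(cs)
      stats::setNames(lapply(lab, function(l) cs == l), lab)
    }
    memb$total <- rep(TRUE, nrow(s))
    for (g in names(memb)) {
      i <- memb[[g]]
      cnt <- sum(s$n_d[i]) / 1e6
      pct <- 100 * sum(s$n_d[i]) / sum(s$n_nd[i] + s$n_d[i])
      rows[[length(rows) + 1L]] <- data.frame(year = y, group = g,
                                              count = cnt, percent = pct)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.na(digits_count)) out$count <- round(out$count, digits_count)
  if (!is.na(digits_pct)) out$percent <- round(out$percent, digits_pct)
  rownames(out) <- NULL
  class(out) <- c("dp_report", "data.frame")
  out
}

#' Construct a report from externally supplied values
#'
#' Useful for computing derived statistics from published projection
#' tables: supply `year`, `group`, `count` (millions) and optionally
#' `percent`.
#'
#' @param df Data.frame with at least `year`, `group`, `count`.
#' @return A `dp_report`.
#' @export
as_report <- function(df) {
  stopifnot(all(c("year", "group", "count") %in% names(df)))
  if (is.null(df$percent)) df$percent <- rep(NA_real_, nrow(df))
  class(df) <- c("dp_report", "data.frame")
  df
}

.report_value <- function(report, year, group, col = "count") {
  i <- report$year == year & report$group %in% group
  if (!any(i)) stop(sprintf("report has no %s rows for year %s",
                            paste(group, collapse = "/"), year), call. = FALSE)
  report[[col]][i]
}

#' Share of the total diabetes population held by a set of groups
#'
#' @param report A `dp_report` containing a `total` row for `year`.
#' @param year Reporting year.
#' @param groups Subset of the report's group labels (e.g. the 65+ pair
#'   `c("65-74", ">=75")`).
#' @return Percentage share, rounded to 1 decimal.
#' @export
share_of_total <- function(report, year, groups) {
  tot <- .report_value(report, year, "total")
  if (tot <= 0) stop("total count is zero; share undefined", call. = FALSE)
  part <- sum(.report_value(report, year, groups))
  round(100 * part / tot, 1)
}

#' Fold change between two values
#' @param v0 Baseline value (`> 0`).
#' @param v1 Comparison value.
#' @return `v1 / v0` rounded to 1 decimal.
#' @export
fold_change <- function(v0, v1) {
  if (v0 <= 0) stop("baseline value must be > 0", call. = FALSE)
  round(v1 / v0, 1)
}

#' Average annual change between two years
#' @param v0,v1 Values at `y0` and `y1`.
#' @param y0,y1 Years with `y1 > y0`.
#' @return `(v1 - v0) / (y1 - y0)` rounded to 1 decimal.
#' @export
annual_average_change <- function(v0, v1, y0, y1) {
  if (y1 <= y0) stop("y1 must exceed y0", call. = FALSE)
  round((v1 - v0) / (y1 - y0), 1)
}

#' Total diabetes burden adjusted for the undiagnosed proportion
#'
#' Scales a diagnosed count up by the externally estimated fraction of the
#' total diabetes population that is undiagnosed (27.8% in the cited
#' national examination-survey estimate): `diagnosed / (1 - fraction)`.
#'
#' @param diagnosed Diagnosed count in millions.
#' @param undiagnosed_fraction Proportion of total diabetes that is
#'   undiagnosed, in `[0, 1)`.
#' @return Total (diagnosed + undiagnosed) millions, 1 decimal.
#' @export
undiagnosed_total <- function(diagnosed, undiagnosed_fraction = 0.278) {
  if (undiagnosed_fraction < 0 || undiagnosed_fraction >= 1)
    stop("undiagnosed_fraction must lie in [0, 1)", call. = FALSE)
  round(diagnosed / (1 - undiagnosed_fraction), 1)
}

#' Difference between base-case and alternative-scenario totals
#'
#' @param base_report,alt_report `dp_report`s containing `total` rows for
#'   `year`.
#' @param year Reporting year.
#' @return List with `exact` (full-precision difference, millions) and
#'   `headline` (rounded to the nearest million).
#' @export
scenario_difference <- function(base_report, alt_report, year) {
  d <- .report_value(base_report, year, "total") -
    .report_value(alt_report, year, "total")
  list(exact = d, headline = round(d))
}

#' Write a projection report to CSV or JSON
#'
#' Deterministic column order `year,group,count,percent[,lo,hi,level]`;
#' `read_report` restores an equal `dp_report`.
#'
#' @param report A `dp_report`.
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- intersect(c("year", "group", "count", "percent", "lo", "hi", "level"),
                    names(report))
  out <- as.data.frame(report)[, cols, drop = FALSE]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
        else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  as_report(df)
}
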