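# Ground-truth parameter set for the synthetic world.
#
# The generators draw from a known set of epidemiological curves so every
# downstream stage (regression fits, predictive margins, the Markov engine)
# can be tested against a truth that is fully specified in code:
#   * diagnosed-diabetes prevalence: logistic in age with race/sex offsets
#     and a linear-on-logit calendar trend, anchored at 2014;
#   * annual incidence among the non-diabetic: logistic in age with period
#     effects that rise to a 2006-2014 plateau;
#   * non-diabetic mortality: Gompertz (log-linear in age);
#   * relative mortality risk of diabetes: quadratic in age through the
#     anchor points (20, 3.0), (65, 2.0), (85, 1.2), monotone decreasing.
# Overall levels are calibrated numerically so that, on the default
# population composition, 2014 prevalence is 9.1% and 2006-2014 incidence
# is 0.8% per year.

# Default standardizing population composition over the cell grid: a roughly
# US-2014-like adult age pyramid (flat to age 50, exponential decline after,
# a thicker open-ended bucket) with race shares 66/12/22 and a 51/49
# female/male split.
#' Default synthetic population composition
#'
#' @return A data.frame over the full cell grid with a `weight` column
#'   summing to 1.
#' @export
dp_default_composition <- function() {
  g <- dp_cell_grid()
  age_w <- ifelse(g$age <= 50, 1, exp(-0.035 * (g$age - 50)))
  age_w[g$age == .dp_age_top] <- 1.5 * exp(-0.035 * 35) # bucket ~ tail mass
  race_w <- c(white = 0.66, black = 0.12, other = 0.22)[g$race]
  sex_w <- c(female = 0.51, male = 0.49)[g$sex]
  g$weight <- age_w * race_w * sex_w
  g$weight <- g$weight / sum(g$weight)
  g
}

# shape pieces (log-odds / log-rate scale), age via z = (age - 50)/10.
# Truth functions take literal age-years; callers translate the "85+"
# census bucket to its effective age 87 before lookup.
#
# The cubic age profiles are least-squares fits (on the logit scale) to a
# realistic diagnosed-diabetes age pattern: ~1% prevalence at age 20 (the
# type 1 floor), rising to ~20% around 70-80 and easing in the open-ended
# bucket, and incidence ~0.1%/yr at 20 peaking ~1.4%/yr in the 60s.  Both
# lie exactly inside the regression families used for estimation.
.prev_shape <- function(age, race, sex) {
  z <- (age - 50) / 10
  0.795 * z - 0.031 * z^2 - 0.026 * z^3 +
    c(white = 0, black = 0.41, other = -0.01)[race] +
    c(female = 0, male = 0.02)[sex]
}

.inc_shape <- function(age, race, sex) {
  z <- (age - 50) / 10
  0.476 * z - 0.095 * z^2 - 0.006 * z^3 +
    c(white = 0, black = 0.45, other = 0.25)[race] +
    c(female = 0, male = 0.05)[sex]
}

.inc_period_effect <- c("1985-1989" = -0.70, "1990-1994" = -0.55,
                        "1995-1999" = -0.35, "2000-2005" = -0.15,
                        "2006-2014" = 0)

# log-quadratic in z = (age - 50)/10 through (20, 3.0), (65, 2.0),
# (85, 1.2) -- the same family the mortality regression spans, so the fits
# are consistent for the default truth.  The unconstrained quadratic has
# its vertex near age 21; below it the curve is held flat at the vertex
# value (3.0015) so the default stays monotone non-increasing in age.
# Positive and below 3.01 everywhere on [18, 100] (0.81 at age 100).
.rr_curve <- function(age) {
  z <- (age - 50) / 10
  zs <- c(-3, 1.5, 3.5) # anchor ages 20, 65, 85
  ys <- log(c(3, 2, 1.2))
  d1 <- (ys[2] - ys[1]) / (zs[2] - zs[1])
  d2 <- ((ys[3] - ys[2]) / (zs[3] - zs[2]) - d1) / (zs[3] - zs[1])
  q <- function(u) ys[1] + d1 * (u - zs[1]) + d2 * (u - zs[1]) * (u - zs[2])
  vertex <- (zs[1] + zs[2]) / 2 - d1 / (2 * d2)
  exp(q(pmax(z, vertex)))
}

.mort_nd <- function(age, race, sex) {
  a <- age
  exp(-9.7 + 0.088 * a +
        c(white = 0, black = 0.15, other = -0.1)[race] +
        c(female = 0, male = 0.25)[sex])
}

#' Construct the default ground-truth parameter set
#'
#' Returns a `dp_truth` object holding the four rate functions used by the
#' synthetic-data generators, each mapping `(age, race, sex, ...)` cells to
#' annual probabilities or ratios:
#'
#' * `baseline_prevalence(age, race, sex, year = 2014)` -- diagnosed-diabetes
#'   prevalence; the calendar trend is linear on the logit scale with slope
#'   `prev_trend_logit` per year, anchored so the composition-weighted 2014
#'   mean is 9.1%.
#' * `incidence(age, race, sex, period)` -- annual probability of diagnosis
#'   among the non-diabetic, calibrated so the 2006-2014 at-risk mean is
#'   0.8% per year.
#' * `mortality_nd(age, race, sex)` -- annual death probability without
#'   diabetes (Gompertz in age).
#' * `rel_risk(age, race, sex)` -- relative mortality risk of diabetes,
#'   passing through 3.0 at age 20, 2.0 at age 65, and 1.2 at age 85,
#'   monotone non-increasing in age.
#'
#' @param ... Named overrides.  Any of `baseline_prevalence`, `incidence`,
#'   `mortality_nd`, `rel_risk` may be replaced by a function with the same
#'   signature or a single constant; `prev_trend_logit` (default 0.035, the
#'   slope reproducing the 3.5% (1985) to 9.1% (2014) rise) and
#'   `composition` may also be overridden.  Unknown names are an error.
#' @return A `dp_truth` list with the four rate functions, the trend slope,
#'   the composition table, and `cohort_labels` (the six race-sex cohorts).
#' @examples
#' tr <- default_truth()
#' tr$rel_risk(20, "white", "female")  # 3.0
#' @export
default_truth <- function(...) {
  overrides <- list(...)
  known <- c("baseline_prevalence", "incidence", "mortality_nd", "rel_risk",
             "prev_trend_logit", "composition")
  bad <- setdiff(names(overrides), known)
  if (length(bad) || (length(overrides) && is.null(names(overrides)))) {
    stop("unknown truth parameter(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }

  comp <- overrides$composition %||% dp_default_composition()
  trend <- overrides$prev_trend_logit %||% 0.035

  # calibrate the prevalence intercept: composition-weighted 2014 mean = 9.1%
  # (grid bucket cells enter at their effective age)
  comp_age <- dp_effective_age(comp$age)
  ps <- .prev_shape(comp_age, comp$race, comp$sex)
  c0 <- stats::uniroot(function(b) {
    sum(comp$weight * dp_invlogit(b + ps)) - 0.091
  }, c(-10, 5), tol = 1e-12)$root

  baseline_prevalence <- function(age, race, sex, year = 2014) {
    dp_invlogit(c0 + .prev_shape(age, race, sex) + trend * (year - 2014))
  }

  # calibrate incidence: at-risk-weighted 2006-2014 mean = 0.8%/yr
  atrisk_w <- comp$weight * (1 - baseline_prevalence(comp_age, comp$race, comp$sex))
  atrisk_w <- atrisk_w / sum(atrisk_w)
  is_shape <- .inc_shape(comp_age, comp$race, comp$sex)
  d0 <- stats::uniroot(function(b) {
    sum(atrisk_w * dp_invlogit(b + is_shape)) - 0.008
  }, c(-15, 0), tol = 1e-12)$root

  incidence <- function(age, race, sex, period = "2006-2014") {
    pe <- .inc_period_effect[period]
    if (anyNA(pe)) {
      stop("unknown incidence period label: ",
           paste(unique(period[is.na(pe)]), collapse = ", "), call. = FALSE)
    }
    dp_invlogit(d0 + .inc_shape(age, race, sex) + unname(pe))
  }

  mortality_nd <- function(age, race, sex) .mort_nd(age, race, sex)
  rel_risk <- function(age, race, sex) .rr_curve(age)

  as_rate_fun <- function(x, nargs_default) {
    if (is.function(x)) return(x)
    force(x)
    function(...) rep_len(x, max(1L, length(..1)))
  }
  if (!is.null(overrides$baseline_prevalence)) {
    f <- as_rate_fun(overrides$baseline_prevalence)
    baseline_prevalence <- function(age, race, sex, year = 2014) f(age, race, sex, year)
  }
  if (!is.null(overrides$incidence)) {
    f <- as_rate_fun(overrides$incidence)
    incidence <- function(age, race, sex, period = "2006-2014") f(age, race, sex, period)
  }
  if (!is.null(overrides$mortality_nd)) mortality_nd <- as_rate_fun(overrides$mortality_nd)
  if (!is.null(overrides$rel_risk)) rel_risk <- as_rate_fun(overrides$rel_risk)

  structure(list(
    baseline_prevalence = baseline_prevalence,
    incidence = incidence,
    mortality_nd = mortality_nd,
    rel_risk = rel_risk,
    prev_trend_logit = trend,
    composition = comp,
    cohort_labels = paste(rep(dp_races(), each = 2), rep(dp_sexes(), 3), sep = ":")
  ), class = "dp_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dp_truth <- function(x, ...) {
  cat("<dp_truth> ground-truth parameter set\n")
  cat("  cohorts:", paste(x$cohort_labels, collapse = ", "), "\n")
  cat(sprintf("  rel_risk anchors: %.2f (20), %.2f (65), %.2f (85+->87)\n",
              x$rel_risk(20, "white", "female"),
              x$rel_risk(65, "white", "female"),
              x$rel_risk(85, "white", "female")))
  invisible(x)
}
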