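# Rate tables: per-cell probabilities / ratios derived from fitted models.
# These are the transition inputs of the Markov engine.

#' Construct a rate table
#'
#' @param df Data.frame with columns `age, race, sex` (optionally `period`
#'   or `year`) and `value`.
#' @param role One of `"prevalence"`, `"incidence"`, `"rel-risk"`.
#' @return A `dp_rate_table`; prevalence/incidence values must lie in
#'   `[0, 1]`, relative-risk values must be `> 0`.
#' @export
new_rate_table <- function(df, role = c("prevalence", "incidence", "rel-risk")) {
  role <- match.arg(role)
  stopifnot(all(c("age", "race", "sex", "value") %in% names(df)))
  if (role == "rel-risk") {
    if (any(df$value <= 0)) stop("rel-risk values must be > 0", call. = FALSE)
  } else if (any(df$value < 0 | df$value > 1)) {
    stop(role, " values must lie in [0, 1]", call. = FALSE)
  }
  attr(df, "role") <- role
  class(df) <- c("dp_rate_table", "data.frame")
  df
}

#' Role tag of a rate table
#' @param rates A `dp_rate_table`.
#' @return The role string.
#' @export
rate_role <- function(rates) attr(rates, "role")

.predict_response <- function(model, data, extra = NULL) {
  if (!is.null(extra)) data[names(extra)] <- extra
  X <- dp_design_matrix(model$spec, data)
  eta <- unname(drop(X %*% model$coefficients))
  if (model$spec$family == "binomial") dp_invlogit(eta) else exp(eta)
}

#' Predictive-margin prevalence over a standardizing population
#'
#' For each (age, race, sex) cell, the weighted average of the model's
#' predicted probability over the standardizing population with the survey
#' year fixed to `at_year` -- the single-year predictive margin.  With a
#' census slice as the standardizing population each cell holds one row, so
#' the margin is the model prediction at that cell.
#'
#' @param model A logistic `dp_fitted_model` (prevalence fit).
#' @param population Standardizing population: a `dp_survey` (its `weight`
#'   column is used) or a single-year `dp_census` slice (its `population`
#'   column is used).  Must cover every cell of the reporting grid.
#' @param at_year Calendar year at which the margin is evaluated.  Years
#'   outside the fitted span trigger an extrapolation warning and are
#'   flagged in the result's `extrapolated` attribute.
#' @return A `dp_rate_table` with role `"prevalence"`, one row per cell.
#' @export
predictive_margin <- function(model, population, at_year) {
  stopifnot(inherits(model, "dp_fitted_model"))
  if (model$spec$family != "binomial")
    stop("predictive_margin needs a logistic fit", call. = FALSE)
  extrap <- FALSE
  if (!is.null(model$year_span) &&
      (at_year < model$year_span[1] || at_year > model$year_span[2])) {
    warning(sprintf("at_year %d is outside the fitted span %d-%d (extrapolating)",
                    at_year, model$year_span[1], model$year_span[2]),
            call. = FALSE)
    extrap <- TRUE
  }
  w <- if (!is.null(population$weight)) population$weight else population$population
  stopifnot(!is.null(w), all(w >= 0))
  p <- .predict_response(model, as.data.frame(population),
                         extra = list(year = at_year))
  key <- dp_cell_key(population)
  num <- rowsum(w * p, key)
  den <- rowsum(w, key)
  frame <- unique_key_frame(key, num / pmax(den, 1e-300))
  frame <- dp_align_cells(frame, dp_cell_grid(sort(unique(population$age))),
                          "standardizing population")
  out <- new_rate_table(frame, "prevalence")
  attr(out, "extrapolated") <- extrap
  attr(out, "at_year") <- at_year
  out
}

# rebuild (age, race, sex, value) rows from rowsum keys "race|sex|age"
unique_key_frame <- function(key, value) {
  ks <- rownames(value)
  parts <- strsplit(ks, "|", fixed = TRUE)
  data.frame(age = as.integer(vapply(parts, `[`, "", 3L)),
             race = vapply(parts, `[`, "", 1L),
             sex = vapply(parts, `[`, "", 2L),
             value = as.numeric(value))
}

#' Relative mortality risk by cell
#'
#' The ratio of the model-predicted death rate with diabetes to the rate
#' without, holding all other covariates at the cell's values.  With the
#' frozen mortality design this depends only on the diabetes main effect
#' and the diabetes:age interaction.
#'
#' @param model The Poisson mortality `dp_fitted_model`.
#' @param cells Cell grid (default the full grid).
#' @param literal_ages If `FALSE` (default) ages are grid codes and the
#'   "85+" bucket (85) is evaluated at its effective age 87; if `TRUE`
#'   ages are taken literally (e.g. to read the fitted risk curve at exact
#'   ages).
#' @return A `dp_rate_table` with role `"rel-risk"`, keyed by the input
#'   ages.
#' @export
relative_mortality <- function(model, cells = dp_cell_grid(),
                               literal_ages = FALSE) {
  stopifnot(inherits(model, "dp_fitted_model"))
  if (model$spec$family != "poisson")
    stop("relative_mortality needs the Poisson mortality fit", call. = FALSE)
  pcells <- cells
  if (!literal_ages) pcells$age <- dp_effective_age(cells$age)
  r1 <- .predict_response(model, pcells, extra = list(diabetes = 1))
  r0 <- .predict_response(model, pcells, extra = list(diabetes = 0))
  if (any(r0 <= 0)) {
    i <- which(r0 <= 0)[1L]
    stop(sprintf("predicted non-diabetic rate is 0 at (age=%s, race=%s, sex=%s)",
                 cells$age[i], cells$race[i], cells$sex[i]), call. = FALSE)
  }
  out <- cells
  out$value <- r1 / r0
  new_rate_table(out, "rel-risk")
}

#' Annual incidence probabilities by cell
#'
#' Model-predicted annual probability of a diabetes diagnosis for each cell
#' at a given period; the base-case projection consumes period
#' `"2006-2014"`.
#'
#' @param model The incidence `dp_fitted_model`.
#' @param cells Cell grid (default the full grid).
#' @param period One of the five period labels.
#' @return A `dp_rate_table` with role `"incidence"`.
#' @export
annual_incidence <- function(model, cells = dp_cell_grid(),
                             period = "2006-2014") {
  stopifnot(inherits(model, "dp_fitted_model"))
  if (model$spec$kind != "logistic-incidence")
    stop("annual_incidence needs the incidence fit", call. = FALSE)
  if (!period %in% dp_periods())
    stop("unknown period label: ", period, call. = FALSE)
  if (!is.null(model$aliased) && any(model$aliased)) {
    hit <- grepl(period, names(model$coefficients), fixed = TRUE) & model$aliased
    if (any(hit))
      warning("period ", period, " was aliased in the fit; ",
              "predictions use the reference level", call. = FALSE)
  }
  out <- cells
  out$value <- .predict_response(model, cells, extra = list(period = period))
  new_rate_table(out, "incidence")
}

#' Poisson rate to annual probability
#'
#' Converts a per-year event rate to the probability of at least one event
#' in a year, `1 - exp(-rate)`, keeping engine inputs in `[0, 1]`.
#'
#' @param rate Non-negative rate per person-year.
#' @return Probability vector.
#' @export
rate_to_annual_prob <- function(rate) {
  stopifnot(all(rate >= 0))
  1 - exp(-rate)
}
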