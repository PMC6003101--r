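# Incidence sensitivity scenarios: the base case holds 2006-2014 incidence
# constant; worst/best cases scale every incidence probability by +/-20%.
# The multiplier acts on the probability scale, and only incidence varies
# (initial prevalence and relative risk are shared across scenarios).

#' Scale the incidence table of an engine parameter set
#'
#' @param params A `dp_engine_params`.
#' @param lambda Positive multiplier; every scaled incidence value must
#'   remain `<= 1` (a range error names the first offending cell).
#' @return `params` with every incidence entry multiplied by `lambda`; all
#'   other tables untouched.
#' @export
scale_incidence <- function(params, lambda) {
  stopifnot(inherits(params, "dp_engine_params"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive scalar", call. = FALSE)
  inc <- params$incidence
  v <- inc$value * lambda
  if (any(v > 1)) {
    i <- which(v > 1)[1L]
    stop(sprintf("scaled incidence %.4f > 1 at (age=%s, race=%s, sex=%s)",
                 v[i], inc$age[i], inc$race[i], inc$sex[i]), call. = FALSE)
  }
  inc$value <- v
  params$incidence <- inc
  params
}

#' Define a scenario
#'
#' @param name Unique scenario name.
#' @param lambda Incidence multiplier (`> 0`); 1.2 and 0.8 give the
#'   worst-case and best-case alternatives to the base case.
#' @return A `dp_scenario_spec`.
#' @export
scenario_spec <- function(name, lambda) {
  stopifnot(is.character(name), length(name) == 1L, lambda > 0)
  structure(list(name = name, lambda = lambda), class = "dp_scenario_spec")
}

#' Run a set of incidence scenarios
#'
#' One deterministic trajectory per scenario plus the base case, all on the
#' same census table.
#'
#' @param base A `dp_engine_params` (the base case).
#' @param census A `dp_census` spanning the projection years.
#' @param specs Non-empty list of `dp_scenario_spec`s with unique names.
#' @param year0,horizon Projection span.
#' @return Named list of `dp_trajectory` objects: `base` plus one per
#'   scenario name.
#' @export
run_scenarios <- function(base, census, specs, year0, horizon) {
  if (!length(specs)) stop("specs must be non-empty", call. = FALSE)
  if (inherits(specs, "dp_scenario_spec")) specs <- list(specs)
  nms <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nms) || "base" %in% nms)
    stop("scenario names must be unique and not 'base'", call. = FALSE)
  out <- list(base = project(census, base, year0, horizon))
  for (s in specs) {
    out[[s$name]] <- project(census, scale_incidence(base, s$lambda),
                             year0, horizon)
  }
  out
}
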