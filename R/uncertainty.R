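# Uncertainty propagation: draw coefficient vectors from the asymptotic
# joint (multivariate normal on the link scale) distribution of each fit,
# rebuild the engine's rate tables per draw, re-run the projection, and
# summarize with percentile intervals.  The default production draw count
# is 5000; tests and examples use a few hundred.

#' Draw coefficient vectors from a fitted model's joint distribution
#'
#' Multivariate normal draws centred at the coefficient vector with the
#' model-based covariance, generated row by row so that extending
#' `n_draws` under the same seed leaves the leading draws unchanged.
#' Covariance eigenvalues in `[-1e-8, 0)` are clipped to 0 (logged via a
#' message); more negative values are an error.
#'
#' @param model A `dp_fitted_model`.
#' @param n_draws Number of draws (`>= 1`); 5000 is the production default.
#' @param seed Integer seed.
#' @return A `dp_coef_draws`: `draws` matrix (`n_draws` x coefficients),
#'   the source `model`, `seed`, `n_draws`.
#' @export
draw_coefficients <- function(model, n_draws = 5000L, seed = 1L) {
  stopifnot(inherits(model, "dp_fitted_model"), n_draws >= 1)
  V <- model$vcov
  eg <- eigen(V, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < -1e-8)
    stop("vcov is not positive semi-definite (min eigenvalue ",
         format(min(lam)), "); refit or clip eigenvalues", call. = FALSE)
  if (any(lam < 0)) {
    message("clipping ", sum(lam < 0), " slightly negative vcov eigenvalue(s)")
    lam[lam < 0] <- 0
  }
  A <- eg$vectors %*% (sqrt(lam) * t(eg$vectors)) # symmetric square root
  p <- length(model$coefficients)
  draws <- with_local_seed(seed, {
    z <- matrix(stats::rnorm(n_draws * p), nrow = n_draws, byrow = TRUE)
    sweep(z %*% A, 2L, model$coefficients, `+`)
  })
  colnames(draws) <- names(model$coefficients)
  structure(list(draws = draws, model = model, seed = seed,
                 n_draws = n_draws),
            class = "dp_coef_draws")
}

# a fitted model with its coefficients replaced by one draw
.model_with_coefs <- function(model, coefs) {
  m <- model
  m$coefficients <- stats::setNames(as.numeric(coefs), names(model$coefficients))
  m
}

#' Project the trajectory ensemble implied by coefficient draws
#'
#' For each draw index, rebuilds the three rate tables (initial-prevalence
#' margin, base-period incidence, relative risk) from the drawn
#' coefficients of the prevalence, incidence, and mortality models jointly,
#' and runs the deterministic projection.  Link-scale draws guarantee all
#' rebuilt probabilities lie in (0, 1).
#'
#' @param draws Named list with components `prevalence`, `incidence`,
#'   `mortality`, each a `dp_coef_draws` with the same number of draws.
#' @param census A `dp_census` spanning the projection years.
#' @param year0,horizon Projection span.
#' @param period Incidence period consumed by the projection (base case
#'   `"2006-2014"`).
#' @param entrant_prevalence_source,migration_prevalence_source Passed to
#'   [engine_params()].
#' @return A `dp_ensemble` whose first-class `base` element is the
#'   point-estimate trajectory and whose `trajectories` hold one member per
#'   draw.
#' @export
ensemble_project <- function(draws, census, year0, horizon,
                             period = "2006-2014",
                             entrant_prevalence_source = "model-age-18",
                             migration_prevalence_source = "cell-prevalence") {
  stopifnot(all(c("prevalence", "incidence", "mortality") %in% names(draws)))
  for (nm in c("prevalence", "incidence", "mortality"))
    stopifnot(inherits(draws[[nm]], "dp_coef_draws"))
  n <- unique(vapply(draws, function(d) nrow(d$draws), 0L))
  stopifnot(length(n) == 1L)

  grid <- dp_cell_grid(sort(unique(census$age[census$year == year0])))
  slice0 <- .census_year_slice(census, year0, grid)
  build_params <- function(pm, im, mm) {
    prev <- suppressWarnings(predictive_margin(pm, slice0, at_year = year0))
    inc <- annual_incidence(im, grid, period = period)
    rr <- relative_mortality(mm, grid)
    stopifnot(all(prev$value > 0 & prev$value < 1),
              all(inc$value > 0 & inc$value < 1))
    engine_params(inc, rr, prev,
                  entrant_prevalence_source = entrant_prevalence_source,
                  migration_prevalence_source = migration_prevalence_source)
  }
  base <- project(census, build_params(draws$prevalence$model,
                                       draws$incidence$model,
                                       draws$mortality$model),
                  year0, horizon)
  trajs <- vector("list", n)
  for (k in seq_len(n)) {
    pars <- build_params(
      .model_with_coefs(draws$prevalence$model, draws$prevalence$draws[k, ]),
      .model_with_coefs(draws$incidence$model, draws$incidence$draws[k, ]),
      .model_with_coefs(draws$mortality$model, draws$mortality$draws[k, ]))
    trajs[[k]] <- project(census, pars, year0, horizon)
  }
  structure(list(trajectories = trajs, base = base,
                 meta = list(year0 = year0, horizon = horizon,
                             replicates = n, mode = "coefficient-draws")),
            class = "dp_ensemble")
}

#' Percentile intervals from a trajectory ensemble
#'
#' Applies `aggregator` to every ensemble member and takes empirical
#' `(1 - level)/2` and `1 - (1 - level)/2` percentiles (linear
#' interpolation between order statistics) per year and group; the point
#' estimate comes from the base-case run when the ensemble carries one.
#'
#' @param ensemble A `dp_ensemble` (non-empty).
#' @param level Nominal interval level in (0, 1), default 0.95.
#' @param aggregator Function mapping a `dp_trajectory` to a data.frame
#'   with columns `year`, `group`, `value` (default: total diabetes
#'   population in millions per year).
#' @return A `dp_interval_table` data.frame with columns
#'   `year, group, estimate, lo, hi, level`.
#' @export
percentile_interval <- function(ensemble, level = 0.95,
                                aggregator = aggregate_total_millions) {
  stopifnot(inherits(ensemble, "dp_ensemble"))
  if (!length(ensemble$trajectories)) stop("empty ensemble", call. = FALSE)
  stopifnot(level > 0, level < 1)
  vals <- lapply(ensemble$trajectories, aggregator)
  ref <- vals[[1L]][, c("year", "group")]
  mat <- vapply(vals, function(v) v$value, numeric(nrow(ref)))
  mat <- matrix(mat, nrow = nrow(ref))
  alpha <- (1 - level) / 2
  lo <- apply(mat, 1L, stats::quantile, probs = alpha, type = 7, names = FALSE)
  hi <- apply(mat, 1L, stats::quantile, probs = 1 - alpha, type = 7, names = FALSE)
  est <- if (!is.null(ensemble$base)) aggregator(ensemble$base)$value
         else rowMeans(mat)
  out <- data.frame(ref, estimate = est, lo = lo, hi = hi, level = level)
  if (any(out$lo > out$estimate + 1e-9) || any(out$hi < out$estimate - 1e-9)) {
    # base case can fall outside the envelope only by sampling noise at
    # tiny draw counts; keep invariant lower <= point <= upper by widening
    out$lo <- pmin(out$lo, out$estimate)
    out$hi <- pmax(out$hi, out$estimate)
  }
  class(out) <- c("dp_interval_table", "data.frame")
  out
}

#' Default interval aggregator: total diabetes population in millions
#'
#' @param traj A `dp_trajectory`.
#' @return Data.frame with `year`, `group` (`"total"`), `value` (millions).
#' @export
aggregate_total_millions <- function(traj) {
  tt <- trajectory_totals(traj)
  data.frame(year = tt$year, group = "total", value = tt$n_d / 1e6)
}

#' Write an interval table to CSV
#'
#' Columns `year,group,estimate,lo,hi,level`.
#'
#' @param intervals A `dp_interval_table`.
#' @param path File path.
#' @export
write_intervals_csv <- function(intervals, path) {
  utils::write.csv(as.data.frame(intervals), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
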