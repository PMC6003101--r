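# Monte Carlo solution of the projection: integer person counts with
# binomial incidence draws and census death totals apportioned between
# states by a seeded draw conditioned to sum to the census count (a
# binomial split at the allocation weight, clamped to state occupancy).
# Replicate means converge to the deterministic expectation run.

#' Stochastic (Monte Carlo) projection ensemble
#'
#' @param census A `dp_census` spanning `[year0, horizon]`.
#' @param params A `dp_engine_params`.
#' @param year0,horizon Projection span.
#' @param replicates Number of Monte Carlo replicates (`>= 1`).
#' @param seed Integer seed; the full ensemble is deterministic given the
#'   seed, and extending `replicates` keeps the leading replicates
#'   unchanged (one RNG stream per replicate, derived from `seed`).
#' @return A `dp_ensemble`: list of `dp_trajectory` objects (mode
#'   `"stochastic"`) plus `meta`.
#' @export
simulate_stochastic <- function(census, params, year0, horizon,
                                replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1)
  yrs <- sort(unique(census$year))
  if (!all(year0:horizon %in% yrs))
    stop("census does not span the projection years", call. = FALSE)
  trajs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    trajs[[r]] <- with_local_seed(seed * 1000L + r, {
      .simulate_one(census, params, year0, horizon)
    })
  }
  structure(list(trajectories = trajs,
                 meta = list(year0 = year0, horizon = horizon,
                             replicates = replicates, seed = seed,
                             mode = "stochastic")),
            class = "dp_ensemble")
}

.simulate_one <- function(census, params, year0, horizon) {
  grid <- dp_cell_grid(sort(unique(census$age[census$year == year0])))
  slice0 <- .census_year_slice(census, year0, grid)
  prev <- dp_align_cells(as.data.frame(params$initial_prevalence), grid,
                         "prevalence table")
  n_d <- stats::rbinom(nrow(grid), slice0$population, prev$value)
  st <- data.frame(age = grid$age, race = grid$race, sex = grid$sex,
                   n_nd = slice0$population - n_d, n_d = n_d)
  attr(st, "year") <- year0
  class(st) <- c("dp_state", "data.frame")

  states <- list(st)
  ledgers <- list()
  if (horizon > year0) {
    for (y in year0:(horizon - 1L)) {
      slice <- .census_year_slice(census[census$year == y, , drop = FALSE],
                                  y, st[, c("age", "race", "sex")])
      fl <- .step_flows(st, params, slice, st[, c("age", "race", "sex")],
                        stochastic = TRUE)
      ledgers[[length(ledgers) + 1L]] <-
        data.frame(st[, c("age", "race", "sex")], deaths_nd = fl$d_nd,
                   deaths_d = fl$d_d, year = y)
      st <- .age_advance(st[, c("age", "race", "sex")], fl)
      attr(st, "year") <- y + 1L
      class(st) <- c("dp_state", "data.frame")
      states[[length(states) + 1L]] <- st
    }
  }
  names(states) <- as.character(year0:horizon)
  structure(list(states = states,
                 ledger = if (length(ledgers)) do.call(rbind, ledgers),
                 meta = list(year0 = year0, horizon = horizon,
                             mode = "stochastic")),
            class = "dp_trajectory")
}

#' @export
print.dp_ensemble <- function(x, ...) {
  cat(sprintf("<dp_ensemble> %d replicate(s), years %d-%d\n",
              length(x$trajectories), x$meta$year0, x$meta$horizon))
  invisible(x)
}
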