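# The dynamic three-state Markov engine.
#
# States are No Diabetes, Diabetes, and Death; Death is kept as a per-year
# outflow ledger rather than a stock.  Each race-sex sub-cohort advances
# year by year:
#   1. census-projected deaths are allocated between the two alive states
#      by the relative mortality risk;
#   2. an incidence fraction of the surviving No Diabetes population moves
#      to Diabetes (no remission flow exists anywhere in the engine);
#   3. net migration is applied (split by the destination cell's current
#      prevalence, or diabetes-free; negative migration removes pro-rata);
#   4. everyone ages one year, the "85+" bucket absorbing age-84 survivors;
#   5. the new 18-year-old entrant cohort is added.
# Because every demographic flow comes from the census table, the alive
# population (n_nd + n_d) reproduces the census population in every
# cell-year: prevalence is the only free quantity.
# Fractional persons are carried in deterministic mode; rounding happens
# only at reporting.

#' Bundle the engine's transition inputs
#'
#' @param incidence `dp_rate_table`, role `"incidence"`: annual probability
#'   of diagnosis for the No Diabetes population, per cell.
#' @param rel_risk `dp_rate_table`, role `"rel-risk"`: relative mortality
#'   risk used to allocate census deaths.
#' @param initial_prevalence `dp_rate_table`, role `"prevalence"`: the
#'   starting-year prevalence, also used for entrant/migrant splitting.
#' @param entrant_prevalence_source `"model-age-18"` (entrants carry the
#'   age-18 prevalence margin of their cohort) or `"diabetes-free"`.
#' @param migration_prevalence_source `"cell-prevalence"` (in-migrants carry
#'   the destination cell's current prevalence) or `"diabetes-free"`.
#' @return A `dp_engine_params` list.
#' @export
engine_params <- function(incidence, rel_risk, initial_prevalence,
                          entrant_prevalence_source = c("model-age-18", "diabetes-free"),
                          migration_prevalence_source = c("cell-prevalence", "diabetes-free")) {
  stopifnot(identical(rate_role(incidence), "incidence"),
            identical(rate_role(rel_risk), "rel-risk"),
            identical(rate_role(initial_prevalence), "prevalence"))
  structure(list(incidence = incidence, rel_risk = rel_risk,
                 initial_prevalence = initial_prevalence,
                 entrant_prevalence_source = match.arg(entrant_prevalence_source),
                 migration_prevalence_source = match.arg(migration_prevalence_source)),
            class = "dp_engine_params")
}

.census_year_slice <- function(census, year, grid) {
  s <- census[census$year == year, , drop = FALSE]
  if (!nrow(s)) stop("census has no rows for year ", year, call. = FALSE)
  dp_align_cells(s, grid, sprintf("census year %d", year))
}

#' Initialize the state table from a census year and a prevalence table
#'
#' @param census A `dp_census` table.
#' @param prevalence A `dp_rate_table` with role `"prevalence"` covering
#'   every cell.
#' @param year0 Starting year (must be present in `census`).
#' @return A `dp_state` data.frame (`age, race, sex, n_nd, n_d`) with a
#'   `year` attribute; `n_d = population * prevalence`, `n_nd` the
#'   remainder.
#' @export
init_state <- function(census, prevalence, year0) {
  grid <- dp_cell_grid(sort(unique(census$age[census$year == year0])))
  slice <- .census_year_slice(census, year0, grid)
  prev <- dp_align_cells(as.data.frame(prevalence), grid, "prevalence table")
  st <- data.frame(age = grid$age, race = grid$race, sex = grid$sex,
                   n_nd = slice$population * (1 - prev$value),
                   n_d = slice$population * prev$value)
  attr(st, "year") <- as.integer(year0)
  class(st) <- c("dp_state", "data.frame")
  st
}

#' Year of a state table
#' @param state A `dp_state`.
#' @return Integer year stamp.
#' @export
state_year <- function(state) attr(state, "year")

#' Allocate deaths between the No Diabetes and Diabetes states
#'
#' Solves the two-equation system `m_nd = deaths / (n_nd + rr * n_d)`,
#' `m_d = rr * m_nd` and returns `(m_nd * n_nd, m_d * n_d)`.  If either
#' implied rate exceeds 1 it is capped at 1, the residual deaths are
#' reassigned to the other state, and a warning is issued.  All arguments
#' are vectorized.
#'
#' @param n_nd,n_d Non-negative persons in each alive state.
#' @param deaths Total deaths, `0 <= deaths <= n_nd + n_d`.
#' @param rr Relative mortality risk, `> 0`.
#' @return A list with components `deaths_nd` and `deaths_d`.
#' @export
allocate_deaths <- function(n_nd, n_d, deaths, rr) {
  k <- max(length(n_nd), length(n_d), length(deaths), length(rr))
  n_nd <- rep_len(n_nd, k); n_d <- rep_len(n_d, k)
  deaths <- rep_len(deaths, k); rr <- rep_len(rr, k)
  if (any(rr <= 0)) stop("rel_risk must be > 0", call. = FALSE)
  if (any(n_nd < 0) || any(n_d < 0) || any(deaths < 0))
    stop("negative inputs to allocate_deaths", call. = FALSE)
  if (any(deaths > n_nd + n_d + 1e-9)) {
    i <- which(deaths > n_nd + n_d + 1e-9)[1L]
    stop(sprintf("infeasible deaths: %g > alive %g", deaths[i],
                 n_nd[i] + n_d[i]), call. = FALSE)
  }
  denom <- n_nd + rr * n_d
  m_nd <- ifelse(denom > 0, deaths / denom, 0)
  m_d <- rr * m_nd
  d_nd <- m_nd * n_nd
  d_d <- m_d * n_d
  over_d <- m_d > 1
  if (any(over_d)) { # diabetic rate capped; residual dies in No Diabetes
    d_d[over_d] <- n_d[over_d]
    d_nd[over_d] <- deaths[over_d] - n_d[over_d]
    warning(sum(over_d), " cell(s) hit the diabetic death-rate cap; ",
            "residual deaths reassigned", call. = FALSE)
  }
  over_nd <- d_nd > n_nd + 1e-12
  if (any(over_nd)) {
    d_nd[over_nd] <- n_nd[over_nd]
    d_d[over_nd] <- deaths[over_nd] - n_nd[over_nd]
    warning(sum(over_nd), " cell(s) hit the non-diabetic death-rate cap; ",
            "residual deaths reassigned", call. = FALSE)
  }
  list(deaths_nd = d_nd, deaths_d = d_d)
}

# shared flow computation for one year; `draw` switches stochastic mode
.step_flows <- function(state, params, slice, grid, stochastic = FALSE) {
  inc <- dp_align_cells(as.data.frame(params$incidence), grid, "incidence table")$value
  rr <- dp_align_cells(as.data.frame(params$rel_risk), grid, "rel-risk table")$value
  prev0 <- dp_align_cells(as.data.frame(params$initial_prevalence), grid,
                          "prevalence table")
  n_nd <- state$n_nd; n_d <- state$n_d
  deaths <- slice$deaths

  if (stochastic) {
    al <- allocate_deaths(n_nd, n_d, pmin(deaths, n_nd + n_d), rr)
    w_d <- ifelse(deaths > 0, al$deaths_d / pmax(deaths, 1), 0)
    d_d <- stats::rbinom(length(deaths), deaths, pmin(pmax(w_d, 0), 1))
    d_d <- pmin(d_d, n_d)                      # clamp to occupancy
    d_nd <- deaths - d_d
    over <- d_nd > n_nd
    d_nd[over] <- n_nd[over]
    d_d[over] <- deaths[over] - n_nd[over]
  } else {
    al <- allocate_deaths(n_nd, n_d, deaths, rr)
    d_nd <- al$deaths_nd; d_d <- al$deaths_d
  }
  s_nd <- n_nd - d_nd
  s_d <- n_d - d_d

  new_dx <- if (stochastic) stats::rbinom(length(s_nd), round(s_nd), inc)
            else inc * s_nd
  s_nd <- s_nd - new_dx
  s_d <- s_d + new_dx

  mig <- slice$net_migration
  alive <- s_nd + s_d
  p_cell <- ifelse(alive > 0, s_d / alive, 0)
  p_in <- if (params$migration_prevalence_source == "cell-prevalence") p_cell else 0
  m_d <- numeric(length(mig))
  pos <- mig > 0; neg <- mig < 0
  if (stochastic) {
    if (any(pos)) m_d[pos] <- stats::rbinom(sum(pos), mig[pos], rep_len(p_in, length(mig))[pos])
    if (any(neg)) { # remove pro-rata without replacement
      m_d[neg] <- -stats::rhyper(sum(neg), m = round(s_d[neg]),
                                 n = round(s_nd[neg]), k = -mig[neg])
    }
  } else {
    m_d[pos] <- mig[pos] * rep_len(p_in, length(mig))[pos]
    m_d[neg] <- mig[neg] * p_cell[neg] # negative migration: pro-rata
  }
  m_nd <- mig - m_d
  s_nd <- s_nd + m_nd
  s_d <- s_d + m_d
  if (any(s_nd < -1e-9) || any(s_d < -1e-9)) {
    i <- which.min(pmin(s_nd, s_d))
    stop(sprintf("negative count at (age=%s, race=%s, sex=%s)",
                 grid$age[i], grid$race[i], grid$sex[i]), call. = FALSE)
  }
  s_nd <- pmax(s_nd, 0); s_d <- pmax(s_d, 0)

  # entrants split
  at18 <- grid$age == min(grid$age)
  entr <- ifelse(is.na(slice$entrants), 0, slice$entrants)
  e_d_all <- numeric(nrow(grid))
  if (any(at18 & entr > 0)) {
    i18 <- which(at18)
    p_e <- if (params$entrant_prevalence_source == "model-age-18")
      prev0$value[i18] else rep(0, length(i18))
    e_d_all[i18] <- if (stochastic) stats::rbinom(length(i18), entr[i18], p_e)
                    else entr[i18] * p_e
  }
  list(s_nd = s_nd, s_d = s_d, d_nd = d_nd, d_d = d_d,
       entr = entr, e_d = e_d_all)
}

#' Advance the state one year
#'
#' Applies, in fixed order per cell: death allocation, incidence flow,
#' net migration, age advance (with the top bucket absorbing), and the new
#' entrant cohort at the youngest age.  The order matches the convention
#' that deaths occur among the start-of-year population.
#'
#' @param state A `dp_state` for year `y`.
#' @param params A `dp_engine_params`.
#' @param census_slice The `dp_census` rows for year `y` (same cell grid).
#' @return The `dp_state` for year `y + 1`, with a `ledger` attribute
#'   (data.frame of `deaths_nd`, `deaths_d` per cell of year `y`).
#' @export
step_year <- function(state, params, census_slice) {
  y <- state_year(state)
  stopifnot(!is.null(y), all(census_slice$year == y))
  grid <- state[, c("age", "race", "sex")]
  slice <- dp_align_cells(census_slice, grid, sprintf("census year %d", y))
  fl <- .step_flows(state, params, slice, grid, stochastic = FALSE)
  out <- .age_advance(grid, fl)
  attr(out, "year") <- as.integer(y) + 1L
  attr(out, "ledger") <- data.frame(grid, deaths_nd = fl$d_nd, deaths_d = fl$d_d,
                                    year = y)
  class(out) <- c("dp_state", "data.frame")
  out
}

# shift counts up one age within each cohort; bucket absorbs; entrants at
# the youngest age
.age_advance <- function(grid, fl) {
  ages <- sort(unique(grid$age))
  n_age <- length(ages)
  out <- grid
  out$n_nd <- 0; out$n_d <- 0
  for (r in unique(grid$race)) for (s in unique(grid$sex)) {
    i <- which(grid$race == r & grid$sex == s)
    i <- i[order(grid$age[i])]
    nd <- fl$s_nd[i]; d <- fl$s_d[i]
    nd2 <- numeric(n_age); d2 <- numeric(n_age)
    if (n_age > 1) {
      nd2[2:n_age] <- nd[1:(n_age - 1)]
      d2[2:n_age] <- d[1:(n_age - 1)]
    }
    nd2[n_age] <- nd2[n_age] + nd[n_age] # top bucket keeps its survivors
    d2[n_age] <- d2[n_age] + d[n_age]
    e <- fl$entr[i][1L]; e_d <- fl$e_d[i][1L]
    nd2[1L] <- nd2[1L] + e - e_d # += so a single-age grid keeps survivors
    d2[1L] <- d2[1L] + e_d
    out$n_nd[i] <- nd2
    out$n_d[i] <- d2
  }
  out
}

#' Deterministic projection over a span of years
#'
#' Starts from the census population at `year0` split by the initial
#' prevalence table, then applies [step_year()] through `horizon`.
#'
#' @param census A `dp_census` spanning `[year0, horizon]`.
#' @param params A `dp_engine_params`.
#' @param year0,horizon First and last projected years.
#' @return A `dp_trajectory`: list with `states` (one `dp_state` per year),
#'   `ledger` (per-year death split), and `meta`.
#' @export
project <- function(census, params, year0, horizon) {
  stopifnot(horizon >= year0)
  yrs <- sort(unique(census$year))
  if (!all(year0:horizon %in% yrs))
    stop("census does not span the projection years", call. = FALSE)
  st <- init_state(census, params$initial_prevalence, year0)
  states <- list(st)
  ledgers <- list()
  if (horizon > year0) {
    for (y in year0:(horizon - 1L)) {
      slice <- census[census$year == y, , drop = FALSE]
      st <- step_year(st, params, slice)
      ledgers[[length(ledgers) + 1L]] <- attr(st, "ledger")
      states[[length(states) + 1L]] <- st
    }
  }
  names(states) <- as.character(year0:horizon)
  structure(list(states = states,
                 ledger = if (length(ledgers)) do.call(rbind, ledgers),
                 meta = list(year0 = year0, horizon = horizon,
                             mode = "deterministic",
                             entrant_prevalence_source = params$entrant_prevalence_source,
                             migration_prevalence_source = params$migration_prevalence_source)),
            class = "dp_trajectory")
}

#' @export
print.dp_trajectory <- function(x, ...) {
  cat(sprintf("<dp_trajectory> %s, years %d-%d (%d states)\n",
              x$meta$mode, x$meta$year0, x$meta$horizon, length(x$states)))
  invisible(x)
}

#' Per-year totals of a trajectory
#'
#' @param traj A `dp_trajectory`.
#' @return Data.frame with `year`, `n_nd`, `n_d`, `alive`, `prevalence`
#'   (percent).
#' @export
trajectory_totals <- function(traj) {
  out <- do.call(rbind, lapply(names(traj$states), function(y) {
    s <- traj$states[[y]]
    data.frame(year = as.integer(y), n_nd = sum(s$n_nd), n_d = sum(s$n_d))
  }))
  out$alive <- out$n_nd + out$n_d
  out$prevalence <- 100 * out$n_d / out$alive
  rownames(out) <- NULL
  out
}

#' Serialize a trajectory to long-format CSV
#'
#' Columns `year,age,race,sex,n_nd,n_d,deaths_nd,deaths_d` (death columns
#' are `NA` for the horizon year, which has no outflow ledger).
#'
#' @param traj A `dp_trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  rows <- lapply(names(traj$states), function(y) {
    s <- as.data.frame(traj$states[[y]])
    s$year <- as.integer(y)
    s
  })
  df <- do.call(rbind, rows)
  if (!is.null(traj$ledger)) {
    key <- paste(df$year, dp_cell_key(df))
    lkey <- paste(traj$ledger$year, dp_cell_key(traj$ledger))
    df$deaths_nd <- traj$ledger$deaths_nd[match(key, lkey)]
    df$deaths_d <- traj$ledger$deaths_d[match(key, lkey)]
  } else {
    df$deaths_nd <- NA_real_; df$deaths_d <- NA_real_
  }
  df$age <- .age_to_chr(df$age)
  utils::write.csv(df[, c("year", "age", "race", "sex", "n_nd", "n_d",
                          "deaths_nd", "deaths_d")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
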