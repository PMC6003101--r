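# Synthetic cohort-component population projection.
#
# Emulates a census national projection table: start-of-year population by
# (year, single age 18-84 / "85+", race, sex) together with the components
# of change -- deaths, net migration, and new 18-year-old entrants -- that
# advance it.  The accounting identity
#   population(y+1, a+1) = population(y, a) - deaths(y, a) + migration(y, a)
# holds exactly (the "85+" bucket absorbs age-84 survivors plus its own;
# age 18 of year y+1 is the entrant cohort of year y), because deaths are
# integerized by largest-remainder apportionment within each race-sex
# cohort-year and migration is drawn as integers.

#' Generate a synthetic census-style population projection
#'
#' @param truth A `dp_truth` parameter set; cell death rates are the
#'   prevalence-blended mix of non-diabetic and diabetic mortality implied
#'   by `truth` (prevalence evaluated at `start_year`).
#' @param start_year,end_year First and last projection years
#'   (`start_year < end_year`).
#' @param scale Total start-of-year persons in `start_year` across all 402
#'   cells.  Must be large enough that every cell receives at least one
#'   person (roughly `>= 5000`), otherwise a degenerate-input error.
#' @param seed Integer seed; the table is a pure function of
#'   `(truth, arguments, seed)`.
#' @param migration_rate Mean annual net-migration rate per cell (default
#'   0.2% of cell population).
#' @param migration_sd Cell-level standard deviation of the migration rate;
#'   set both migration arguments to 0 to disable migration entirely.
#' @return A `dp_census` data.frame with columns
#'   `year, age, race, sex, population, deaths, net_migration, entrants`
#'   (`entrants` is populated on age-18 rows only, `NA` elsewhere).
#' @export
gen_census_projection <- function(truth, start_year, end_year, scale,
                                  seed = 1L, migration_rate = 0.002,
                                  migration_sd = 0.002) {
  stopifnot(inherits(truth, "dp_truth"), start_year < end_year, scale > 0)
  grid <- dp_cell_grid()
  n_cell <- nrow(grid)

  w <- dp_default_composition()
  w <- dp_align_cells(w, grid, "composition")$weight
  pop0 <- dp_largest_remainder(scale * w, round(scale))
  if (any(pop0 < 1)) {
    stop(sprintf(
      "scale %s is too small to populate all %d cells (smallest cell rounds to 0)",
      format(scale), n_cell), call. = FALSE)
  }

  ea <- dp_effective_age(grid$age)
  prev <- truth$baseline_prevalence(ea, grid$race, grid$sex, year = start_year)
  m_nd <- truth$mortality_nd(ea, grid$race, grid$sex)
  rr <- truth$rel_risk(ea, grid$race, grid$sex)
  m_blend <- pmin(m_nd * (1 - prev) + m_nd * rr * prev, 0.99)

  cohort <- paste(grid$race, grid$sex)
  cohorts <- unique(cohort)
  race_sex_share <- vapply(cohorts, function(cs) sum(w[cohort == cs]), 0)

  years <- start_year:end_year
  out <- vector("list", length(years))
  with_local_seed(seed, {
    pop <- pop0
    for (k in seq_along(years)) {
      d_real <- pop * m_blend
      deaths <- integer(n_cell)
      for (cs in cohorts) { # integer deaths, conserved within cohort-year
        i <- cohort == cs
        deaths[i] <- dp_largest_remainder(d_real[i])
      }
      mig <- if (migration_rate == 0 && migration_sd == 0) integer(n_cell)
             else as.integer(round(pop * stats::rnorm(n_cell, migration_rate,
                                                      migration_sd)))
      mig <- pmax(mig, -(pop - deaths)) # keep survivors + migration >= 0
      entr <- integer(n_cell)
      at18 <- grid$age == .dp_age_min
      entr_cohort <- round(scale * race_sex_share[cohort[at18]] * 0.016 *
                             exp(stats::rnorm(sum(at18), 0, 0.05)))
      entr[at18] <- as.integer(pmax(entr_cohort, 0))

      out[[k]] <- data.frame(year = years[k], age = grid$age, race = grid$race,
                             sex = grid$sex, population = pop, deaths = deaths,
                             net_migration = mig,
                             entrants = ifelse(at18, entr, NA_integer_))

      if (k < length(years)) { # advance via the accounting identity
        surv <- pop - deaths + mig
        nxt <- integer(n_cell)
        for (cs in cohorts) {
          i <- which(cohort == cs)
          a <- grid$age[i] # ascending 18..85 within cohort
          stopifnot(identical(a, dp_ages()))
          nxt_c <- integer(length(i))
          nxt_c[1L] <- entr[i][1L]
          nxt_c[2:(length(i) - 1L)] <- surv[i][1:(length(i) - 2L)]
          nxt_c[length(i)] <- surv[i][length(i) - 1L] + surv[i][length(i)]
          nxt[i] <- nxt_c
        }
        pop <- pmax(nxt, 0L)
      }
    }
  })
  res <- do.call(rbind, out)
  class(res) <- c("dp_census", "data.frame")
  res
}

#' Validate a census projection table
#'
#' Checks the complete-grid, non-negativity, death-feasibility, and
#' cohort-component accounting-identity invariants.
#'
#' @param census A `dp_census` table (or a data.frame in the same schema).
#' @param tol Absolute tolerance on identity residuals (default 0: exact).
#' @return Invisibly `TRUE`; errors describing the first violated invariant.
#' @export
validate_census <- function(census, tol = 0) {
  need <- c("year", "age", "race", "sex", "population", "deaths",
            "net_migration", "entrants")
  stopifnot(all(need %in% names(census)))
  years <- sort(unique(census$year))
  grid <- dp_cell_grid()
  for (y in years) {
    s <- census[census$year == y, ]
    if (nrow(s) != nrow(grid) || anyDuplicated(dp_cell_key(s)))
      stop("census grid for year ", y, " is not a complete single cover")
  }
  if (any(census$population < 0)) stop("negative population")
  if (any(census$deaths < 0)) stop("negative deaths")
  if (any(census$deaths > census$population + pmax(census$net_migration, 0)))
    stop("deaths exceed population plus in-migration")
  for (k in seq_len(length(years) - 1L)) {
    cur <- dp_align_cells(census[census$year == years[k], ], grid, "census")
    nxt <- dp_align_cells(census[census$year == years[k + 1L], ], grid, "census")
    surv <- cur$population - cur$deaths + cur$net_migration
    for (r in dp_races()) for (s in dp_sexes()) {
      i <- which(cur$race == r & cur$sex == s) # ages ascending 18..85
      res_int <- nxt$population[i][2:(length(i) - 1L)] - surv[i][1:(length(i) - 2L)]
      res_top <- nxt$population[i][length(i)] -
        (surv[i][length(i) - 1L] + surv[i][length(i)])
      res_18 <- nxt$population[i][1L] - cur$entrants[i][1L]
      if (max(abs(c(res_int, res_top, res_18))) > tol)
        stop(sprintf("accounting identity violated for %s %s between %d and %d",
                     r, s, years[k], years[k + 1L]))
    }
  }
  invisible(TRUE)
}
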