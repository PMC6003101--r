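# Shared fixtures and independent oracles, built in code at test time.

# small default-truth census kept across tests (generation is cheap)
tiny_census <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_census_projection(default_truth(), 2014, 2024,
                                      scale = 2e5, seed = 11)
    }
    cache
  }
})

# constant rate tables over an arbitrary grid
const_rates <- function(grid, prevalence = 0.091, incidence = 0.008, rr = 2) {
  p <- grid; p$value <- prevalence
  i <- grid; i$value <- incidence
  r <- grid; r$value <- rr
  engine_params(new_rate_table(i, "incidence"),
                new_rate_table(r, "rel-risk"),
                new_rate_table(p, "prevalence"))
}

# hand-built census for toy worlds: one race-sex cohort ("white"/"female"
# rows must still carry all races/sexes for the engine grid, so the toy
# uses the full 6 cohorts with population concentrated in one of them when
# needed -- here we simply give every cohort the same schedule)
toy_census <- function(ages, years, population, deaths = 0, migration = 0,
                       entrants = 0) {
  g <- dp_cell_grid(ages)
  rows <- do.call(rbind, lapply(years, function(y) {
    d <- g
    d$year <- y
    d$population <- rep_len(population, nrow(g))
    d$deaths <- rep_len(deaths, nrow(g))
    d$net_migration <- rep_len(migration, nrow(g))
    d$entrants <- ifelse(d$age == min(ages), rep_len(entrants, nrow(g)), NA)
    d
  }))
  rows <- rows[, c("year", "age", "race", "sex", "population", "deaths",
                   "net_migration", "entrants")]
  class(rows) <- c("dp_census", "data.frame")
  rows
}

# advance a toy census so the accounting identity holds (needed when the
# engine's conservation is under test with nonzero flows)
consistent_toy_census <- function(ages, years, pop0, deaths = 0,
                                  migration = 0, entrants = 0) {
  g <- dp_cell_grid(ages)
  n <- nrow(g)
  pop <- rep_len(pop0, n)
  out <- list()
  for (y in years) {
    d <- rep_len(deaths, n)
    m <- rep_len(migration, n)
    e <- ifelse(g$age == min(ages), rep_len(entrants, n), NA)
    out[[length(out) + 1L]] <- data.frame(
      year = y, age = g$age, race = g$race, sex = g$sex, population = pop,
      deaths = d, net_migration = m, entrants = e)
    surv <- pop - d + m
    nxt <- numeric(n)
    for (r in dp_races()) for (s in dp_sexes()) {
      i <- which(g$race == r & g$sex == s)
      k <- length(i)
      nxt_c <- numeric(k)
      nxt_c[1] <- ifelse(is.na(e[i][1]), 0, e[i][1])
      if (k > 1) nxt_c[2:k] <- surv[i][1:(k - 1)]
      nxt_c[k] <- nxt_c[k] + surv[i][k]
      nxt[i] <- nxt_c
    }
    pop <- nxt
  }
  res <- do.call(rbind, out)
  class(res) <- c("dp_census", "data.frame")
  res
}

# ---- independent projection oracle -----------------------------------
# A deliberately naive scalar-loop recomputation of the projection's
# difference equations, written against the documented update order
# (deaths -> incidence -> migration -> aging -> entrants), used to verify
# the vectorized engine on small grids.
oracle_project <- function(census, params, year0, horizon) {
  grid <- dp_cell_grid(sort(unique(census$age[census$year == year0])))
  key <- function(y, a, r, s) paste(y, a, r, s)
  cpop <- stats::setNames(census$population,
                          key(census$year, census$age, census$race, census$sex))
  cdea <- stats::setNames(census$deaths, names(cpop))
  cmig <- stats::setNames(census$net_migration, names(cpop))
  cent <- stats::setNames(census$entrants, names(cpop))
  rate <- function(tab, a, r, s) {
    tab$value[tab$age == a & tab$race == r & tab$sex == s]
  }
  ages <- sort(unique(grid$age))
  st <- list()
  for (i in seq_len(nrow(grid))) {
    a <- grid$age[i]; r <- grid$race[i]; s <- grid$sex[i]
    p <- rate(params$initial_prevalence, a, r, s)
    pop <- cpop[[key(year0, a, r, s)]]
    st[[paste(a, r, s)]] <- c(nd = pop * (1 - p), d = pop * p)
  }
  states <- list(st)
  y <- year0
  while (y < horizon) {
    nxt <- list()
    for (r in dp_races()) for (s in dp_sexes()) {
      carry <- NULL # survivors flowing into the next age
      for (a in ages) {
        cur <- st[[paste(a, r, s)]]
        D <- cdea[[key(y, a, r, s)]]
        rr <- rate(params$rel_risk, a, r, s)
        m_nd <- if (cur[["nd"]] + rr * cur[["d"]] > 0)
          D / (cur[["nd"]] + rr * cur[["d"]]) else 0
        d_nd <- m_nd * cur[["nd"]]; d_d <- rr * m_nd * cur[["d"]]
        nd <- cur[["nd"]] - d_nd; d <- cur[["d"]] - d_d
        flow <- rate(params$incidence, a, r, s) * nd
        nd <- nd - flow; d <- d + flow
        M <- cmig[[key(y, a, r, s)]]
        pcell <- if (nd + d > 0) d / (nd + d) else 0
        pin <- if (params$migration_prevalence_source == "cell-prevalence")
          pcell else 0
        if (M >= 0) { d <- d + M * pin; nd <- nd + M * (1 - pin) }
        else { d <- d + M * pcell; nd <- nd + M * (1 - pcell) }
        # aging: survivors of age a land at a+1 (top bucket keeps its own)
        tgt <- if (a == ages[length(ages)]) a else ages[match(a, ages) + 1L]
        k <- paste(tgt, r, s)
        if (is.null(nxt[[k]])) nxt[[k]] <- c(nd = 0, d = 0)
        nxt[[k]] <- nxt[[k]] + c(nd = nd, d = d)
      }
      e <- cent[[key(y, ages[1], r, s)]]
      e <- if (is.na(e)) 0 else e
      p18 <- if (params$entrant_prevalence_source == "model-age-18")
        rate(params$initial_prevalence, ages[1], r, s) else 0
      k <- paste(ages[1], r, s)
      if (is.null(nxt[[k]])) nxt[[k]] <- c(nd = 0, d = 0)
      nxt[[k]] <- nxt[[k]] + c(nd = e * (1 - p18), d = e * p18)
    }
    st <- nxt
    states[[length(states) + 1L]] <- st
    y <- y + 1L
  }
  names(states) <- as.character(year0:horizon)
  states
}

oracle_totals <- function(oracle_states) {
  do.call(rbind, lapply(names(oracle_states), function(y) {
    m <- do.call(rbind, oracle_states[[y]])
    data.frame(year = as.integer(y), n_nd = sum(m[, "nd"]), n_d = sum(m[, "d"]))
  }))
}
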