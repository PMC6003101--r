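# Markov engine: death allocation, single steps, full projections,
# stochastic mode.

test_that("allocate_deaths solves its two-equation system", {
  # rr = 1: exact pro-rata
  al <- allocate_deaths(900, 100, 10, 1)
  expect_equal(al$deaths_nd, 9)
  expect_equal(al$deaths_d, 1)

  # closed-form example: m_nd = 22/1100 = 0.02
  al <- allocate_deaths(900, 100, 22, 2)
  expect_equal(al$deaths_nd, 18)
  expect_equal(al$deaths_d, 4)

  # single occupied state takes all deaths
  al <- allocate_deaths(0, 100, 5, 3)
  expect_equal(al$deaths_nd, 0)
  expect_equal(al$deaths_d, 5)

  expect_error(allocate_deaths(10, 10, 25, 1), "infeasible")
  expect_error(allocate_deaths(10, 10, 5, 0), "rel_risk")
})

test_that("allocate_deaths algebra holds on random feasible inputs", {
  set.seed(99)
  n <- 10000
  n_nd <- runif(n, 0, 1e5)
  n_d <- runif(n, 0, 1e4)
  deaths <- runif(n) * (n_nd + n_d)
  rr <- exp(runif(n, log(0.3), log(5)))
  al <- suppressWarnings(allocate_deaths(n_nd, n_d, deaths, rr))
  # totals conserved
  expect_equal(al$deaths_nd + al$deaths_d, deaths, tolerance = 1e-12)
  # two-equation system: m_d = rr * m_nd wherever no cap engaged
  m_nd <- al$deaths_nd / n_nd
  m_d <- al$deaths_d / n_d
  free <- m_d < 1 - 1e-9 & m_nd < 1 - 1e-9
  expect_gt(mean(free), 0.5)
  expect_equal(m_d[free], rr[free] * m_nd[free], tolerance = 1e-9)
  # no state exceeds its occupancy
  expect_true(all(al$deaths_nd <= n_nd + 1e-9))
  expect_true(all(al$deaths_d <= n_d + 1e-9))
  # rr = 1 reduces to pro-rata exactly
  al1 <- allocate_deaths(n_nd, n_d, deaths, 1)
  expect_equal(al1$deaths_nd, deaths * n_nd / (n_nd + n_d), tolerance = 1e-12)
})

test_that("allocate_deaths caps rates at 1 with residual reassignment", {
  # rr huge: diabetic rate would exceed 1
  expect_warning(al <- allocate_deaths(1000, 10, 100, 50), "cap")
  expect_equal(al$deaths_d, 10)
  expect_equal(al$deaths_nd, 90)
})

test_that("init_state splits population by prevalence", {
  cen <- toy_census(ages = 30, years = 2014, population = 1000)
  g <- dp_cell_grid(30)
  prev <- new_rate_table(transform(g, value = 0.091), "prevalence")
  st <- init_state(cen, prev, 2014)
  expect_equal(st$n_d, rep(91, 6))
  expect_equal(st$n_nd, rep(909, 6))
  expect_identical(state_year(st), 2014L)

  prev0 <- new_rate_table(transform(g, value = 0), "prevalence")
  st0 <- init_state(cen, prev0, 2014)
  expect_true(all(st0$n_d == 0))

  # weighted-mean oracle: overall prevalence equals brute-force weighted mean
  cen2 <- tiny_census()
  g2 <- dp_cell_grid()
  set.seed(5)
  prev2 <- new_rate_table(transform(g2, value = runif(nrow(g2), 0, 0.3)),
                          "prevalence")
  st2 <- init_state(cen2, prev2, 2014)
  s14 <- cen2[cen2$year == 2014, ]
  key <- paste(s14$race, s14$sex, s14$age)
  pv <- prev2$value[match(key, paste(prev2$race, prev2$sex, prev2$age))]
  expect_equal(sum(st2$n_d) / sum(st2$n_nd + st2$n_d),
               weighted.mean(pv, s14$population), tolerance = 1e-12)

  # missing cell errors with the cell named
  expect_error(init_state(cen, new_rate_table(transform(dp_cell_grid(31),
                                                        value = 0.1),
                                              "prevalence"), 2014),
               "missing cell")
})

test_that("step_year: pure aging when all flows are zero", {
  cen <- toy_census(ages = 30:31, years = 2014:2015,
                    population = c(100, 200))
  g <- dp_cell_grid(30:31)
  par <- const_rates(g, prevalence = 0.2, incidence = 0, rr = 1)
  st <- init_state(cen, par$initial_prevalence, 2014)
  expect_identical(state_year(st), 2014L)
  st2 <- step_year(st, par, cen[cen$year == 2014, ])
  expect_identical(state_year(st2), 2015L)
  # age 30 moved to 31, bucket (31) absorbed its own
  w31 <- st2$age == 31
  expect_equal(st2$n_nd[w31], rep(0.8 * 300, 6))
  expect_equal(st2$n_d[w31], rep(0.2 * 300, 6))
  expect_equal(st2$n_nd[st2$age == 30], rep(0, 6))
})

test_that("step_year applies incidence to death survivors", {
  # one age, no deaths/migration: next-year diabetes = 0.008 * 1000 = 8,
  # landed in the top bucket
  cen <- toy_census(ages = 40, years = 2014:2015, population = 1000)
  g <- dp_cell_grid(40)
  par <- const_rates(g, prevalence = 0, incidence = 0.008, rr = 1)
  st <- init_state(cen, par$initial_prevalence, 2014)
  st2 <- step_year(st, par, cen[cen$year == 2014, ])
  expect_equal(st2$n_d, rep(8, 6))
  expect_equal(st2$n_nd, rep(992, 6))
})

test_that("step_year reproduces a hand-computed ledger on a 3-age toy", {
  # 3 ages (top = bucket), one-cohort arithmetic identical across cohorts:
  # pop 1000 each age, deaths 10, rr 2, incidence 0.05, migration +20,
  # initial prevalence 0.1, entrants 50 at the youngest age.
  ages <- 60:62
  cen <- toy_census(ages, years = 2014:2015, population = 1000,
                    deaths = 10, migration = 20, entrants = 50)
  g <- dp_cell_grid(ages)
  par <- const_rates(g, prevalence = 0.1, incidence = 0.05, rr = 2)
  st <- init_state(cen, par$initial_prevalence, 2014)
  st2 <- step_year(st, par, cen[cen$year == 2014, ])

  # hand computation, per age cell:
  # deaths: m_nd = 10 / (900 + 2*100) = 1/110; d_nd = 900/110 = 8.1818..,
  #   d_d = 2*(1/110)*100 = 1.8181..; survivors nd = 891.8181, d = 98.1818
  # incidence: 0.05 * 891.8181 = 44.5909 -> nd = 847.2272, d = 142.7727
  # migration +20 at cell prevalence 142.7727/990 = 0.1442...:
  #   m_d = 20 * 142.7727/990 = 2.8843, m_nd = 17.1157
  # aged totals: nd = 864.3429, d = 145.6570 (sum 1010)
  d_nd <- 900 * 10 / 1100
  d_d <- 200 * 10 / 1100
  nd1 <- 900 - d_nd
  d1 <- 100 - d_d
  flow <- 0.05 * nd1
  nd2 <- nd1 - flow
  d2 <- d1 + flow
  p_cell <- d2 / (nd2 + d2)
  nd3 <- nd2 + 20 * (1 - p_cell)
  d3 <- d2 + 20 * p_cell

  led <- attr(st2, "ledger")
  expect_equal(led$deaths_nd, rep(d_nd, 18), tolerance = 1e-9)
  expect_equal(led$deaths_d, rep(d_d, 18), tolerance = 1e-9)
  # middle age (61) of next year holds exactly the aged age-60 cell
  expect_equal(st2$n_nd[st2$age == 61], rep(nd3, 6), tolerance = 1e-9)
  expect_equal(st2$n_d[st2$age == 61], rep(d3, 6), tolerance = 1e-9)
  # bucket holds age-61 + its own survivors
  expect_equal(st2$n_nd[st2$age == 62], rep(2 * nd3, 6), tolerance = 1e-9)
  # entrants at the youngest age carry the age-60 prevalence (0.1)
  expect_equal(st2$n_nd[st2$age == 60], rep(45, 6))
  expect_equal(st2$n_d[st2$age == 60], rep(5, 6))
})

test_that("project conserves the census population every year", {
  cen <- tiny_census()
  g <- dp_cell_grid()
  tr <- default_truth()
  ea <- dp_effective_age(g$age)
  par <- engine_params(
    new_rate_table(transform(g, value = tr$incidence(ea, g$race, g$sex)),
                   "incidence"),
    new_rate_table(transform(g, value = tr$rel_risk(ea, g$race, g$sex)),
                   "rel-risk"),
    new_rate_table(transform(g, value = tr$baseline_prevalence(ea, g$race, g$sex)),
                   "prevalence"))
  traj <- project(cen, par, 2014, 2024)
  for (y in 2014:2024) {
    s <- traj$states[[as.character(y)]]
    cs <- cen[cen$year == y, ]
    key <- paste(s$race, s$sex, s$age)
    expect_lt(max(abs(s$n_nd + s$n_d -
                        cs$population[match(key, paste(cs$race, cs$sex, cs$age))])),
              1e-6)
  }
  # ledger deaths match census deaths cell by cell
  led <- traj$ledger
  cs <- cen[cen$year < 2024, ]
  key <- paste(led$year, led$race, led$sex, led$age)
  ckey <- paste(cs$year, cs$race, cs$sex, cs$age)
  expect_lt(max(abs(led$deaths_nd + led$deaths_d -
                      cs$deaths[match(key, ckey)])), 1e-6)
})

test_that("project matches the brute-force enumeration oracle on toys", {
  ages <- 70:72
  cen <- consistent_toy_census(ages, 2014:2016, pop0 = 500, deaths = 5,
                               migration = -10, entrants = 30)
  g <- dp_cell_grid(ages)
  par <- const_rates(g, prevalence = 0.15, incidence = 0.03, rr = 1.8)
  traj <- project(cen, par, 2014, 2016)
  orc <- oracle_project(cen, par, 2014, 2016)
  for (y in as.character(2014:2016)) {
    s <- traj$states[[y]]
    for (i in seq_len(nrow(s))) {
      o <- orc[[y]][[paste(s$age[i], s$race[i], s$sex[i])]]
      expect_equal(s$n_nd[i], o[["nd"]], tolerance = 1e-9)
      expect_equal(s$n_d[i], o[["d"]], tolerance = 1e-9)
    }
  }

  # diabetes-free entrant/migrant variant
  par2 <- engine_params(par$incidence, par$rel_risk, par$initial_prevalence,
                        entrant_prevalence_source = "diabetes-free",
                        migration_prevalence_source = "diabetes-free")
  traj2 <- project(cen, par2, 2014, 2016)
  orc2 <- oracle_project(cen, par2, 2014, 2016)
  s <- traj2$states[["2016"]]
  for (i in seq_len(nrow(s))) {
    o <- orc2[["2016"]][[paste(s$age[i], s$race[i], s$sex[i])]]
    expect_equal(s$n_nd[i], o[["nd"]], tolerance = 1e-9)
    expect_equal(s$n_d[i], o[["d"]], tolerance = 1e-9)
  }
})

test_that("project horizon = year0 returns the initial state only", {
  cen <- tiny_census()
  g <- dp_cell_grid()
  par <- const_rates(g)
  traj <- project(cen, par, 2014, 2014)
  expect_length(traj$states, 1)
  expect_null(traj$ledger)
})

test_that("no remission: diabetes count never decreases faster than deaths", {
  # with zero incidence, rel_risk 1 and diabetes-free entrants/migrants,
  # percent prevalence is non-increasing year over year
  cen <- tiny_census()
  g <- dp_cell_grid()
  par0 <- engine_params(
    new_rate_table(transform(g, value = 0), "incidence"),
    new_rate_table(transform(g, value = 1), "rel-risk"),
    new_rate_table(transform(g, value = 0.15), "prevalence"),
    entrant_prevalence_source = "diabetes-free",
    migration_prevalence_source = "diabetes-free")
  tt <- trajectory_totals(project(cen, par0, 2014, 2024))
  expect_true(all(diff(tt$prevalence) <= 1e-12))
})

test_that("scaling incidence never decreases diabetes counts (monotonicity)", {
  cen <- tiny_census()
  g <- dp_cell_grid()
  par <- const_rates(g, prevalence = 0.09, incidence = 0.008, rr = 1.8)
  tt1 <- trajectory_totals(project(cen, par, 2014, 2024))
  par_hi <- scale_incidence(par, 1.5)
  tt2 <- trajectory_totals(project(cen, par_hi, 2014, 2024))
  expect_true(all(tt2$n_d >= tt1$n_d - 1e-9))
})

test_that("stochastic simulation is seeded, conserves, and matches certainty", {
  ages <- 40:42
  cen <- consistent_toy_census(ages, 2014:2016, pop0 = 300, deaths = 3,
                               migration = 4, entrants = 20)
  g <- dp_cell_grid(ages)
  par <- const_rates(g, prevalence = 0.1, incidence = 0.02, rr = 2)
  ens <- simulate_stochastic(cen, par, 2014, 2016, replicates = 5, seed = 9)
  ens2 <- simulate_stochastic(cen, par, 2014, 2016, replicates = 5, seed = 9)
  expect_identical(ens, ens2)
  # integer conservation against census populations
  for (tr in ens$trajectories) {
    for (y in as.character(2014:2016)) {
      s <- tr$states[[y]]
      cs <- cen[cen$year == as.integer(y), ]
      key <- paste(s$race, s$sex, s$age)
      expect_equal(s$n_nd + s$n_d,
                   cs$population[match(key, paste(cs$race, cs$sex, cs$age))])
    }
    led <- tr$ledger
    expect_true(all(led$deaths_nd + led$deaths_d == 3))
  }

  # certain transition: incidence 1 on a deathless toy drains n_nd fully
  cen0 <- toy_census(ages = 50, years = 2014:2015, population = 100)
  g0 <- dp_cell_grid(50)
  par0 <- const_rates(g0, prevalence = 0, incidence = 1, rr = 1)
  ens0 <- simulate_stochastic(cen0, par0, 2014, 2015, replicates = 3, seed = 2)
  for (tr in ens0$trajectories) {
    s <- tr$states[["2015"]]
    expect_true(all(s$n_nd == 0))
    expect_true(all(s$n_d == 100))
  }
})

test_that("stochastic replicate mean approaches the deterministic run", {
  ages <- 40:44
  cen <- consistent_toy_census(ages, 2014:2018, pop0 = 2000, deaths = 20,
                               migration = 10, entrants = 100)
  g <- dp_cell_grid(ages)
  par <- const_rates(g, prevalence = 0.1, incidence = 0.02, rr = 2)
  det <- trajectory_totals(project(cen, par, 2014, 2018))
  ens <- simulate_stochastic(cen, par, 2014, 2018, replicates = 300, seed = 4)
  fin <- vapply(ens$trajectories,
                function(tr) sum(tr$states[["2018"]]$n_d), 0)
  se <- sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - det$n_d[det$year == 2018]), 3 * se + 1e-9)
})
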