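# Regression fits, predictive margins, and rate-table construction.

test_that("IRLS logistic fit matches the glm() oracle", {
  tr <- default_truth()
  sv <- gen_prevalence_survey(tr, 20000, years = c(2008, 2011, 2014), seed = 51)
  fit <- fit_prevalence_model(sv)
  expect_true(fit$converged)

  # independent route: stats::glm on the same design matrix (quasibinomial
  # silences the non-integer-weights warning but maximizes the identical
  # weighted likelihood)
  X <- diabproj:::dp_design_matrix(fit$spec, sv)
  oracle <- stats::glm.fit(X, sv$outcome, weights = sv$weight,
                           family = stats::quasibinomial())
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-6)
})

test_that("IRLS Poisson fit matches the glm() oracle and the offset property", {
  tr <- default_truth(mortality_nd = 0.02)
  fu <- gen_mortality_followup(tr, 15000, max_periods = 4, seed = 52)
  fit <- fit_mortality_model(fu)
  X <- diabproj:::dp_design_matrix(fit$spec, fu)
  oracle <- suppressWarnings(
    stats::glm.fit(X, fu$died, family = stats::poisson(),
                   offset = log(fu$exposure)))
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-6)

  # doubling exposure with deaths unchanged exactly halves predicted rates
  fu2 <- fu
  fu2$exposure <- fu$exposure * 2
  fit2 <- fit_mortality_model(fu2)
  cells <- dp_cell_grid(c(40, 70))
  r1 <- diabproj:::.predict_response(fit, cells, extra = list(diabetes = 0))
  r2 <- diabproj:::.predict_response(fit2, cells, extra = list(diabetes = 0))
  expect_equal(r2, r1 / 2, tolerance = 1e-8)
})

test_that("fits are invariant to record order and weight splitting", {
  tr <- default_truth()
  sv <- gen_prevalence_survey(tr, 8000, years = c(2010, 2014), seed = 53)
  fit <- fit_prevalence_model(sv)

  perm <- sv[sample.int(nrow(sv)), ]
  attr(perm, "mode") <- "prevalence"
  class(perm) <- class(sv)
  expect_equal(fit_prevalence_model(perm)$coefficients, fit$coefficients,
               tolerance = 1e-10)

  dup <- rbind(sv, sv)
  dup$weight <- dup$weight / 2
  attr(dup, "mode") <- "prevalence"
  class(dup) <- class(sv)
  expect_equal(fit_prevalence_model(dup)$coefficients, fit$coefficients,
               tolerance = 1e-8)
})

test_that("degenerate inputs raise informative fit errors", {
  tr0 <- default_truth(baseline_prevalence = 0)
  sv0 <- gen_prevalence_survey(tr0, 4000, years = c(2010, 2014), seed = 54)
  expect_error(fit_prevalence_model(sv0), "separation")

  # missing factor level
  sv <- gen_prevalence_survey(default_truth(), 4000,
                              years = c(2010, 2014), seed = 55)
  sv_no_black <- sv[sv$race != "black", ]
  attr(sv_no_black, "mode") <- "prevalence"
  class(sv_no_black) <- class(sv)
  expect_error(fit_prevalence_model(sv_no_black), "absent")

  # single survey year rejected
  sv1 <- gen_prevalence_survey(default_truth(), 4000, years = 2014, seed = 56)
  expect_error(fit_prevalence_model(sv1), "2 distinct")

  # mortality: no deaths in a stratum
  fu <- gen_mortality_followup(default_truth(mortality_nd = 0), 300,
                               max_periods = 2, seed = 57)
  expect_error(fit_mortality_model(fu), "no deaths")

  # wrong modes
  expect_error(fit_incidence_model(sv), "not in incidence mode")
  iv <- gen_incidence_survey(default_truth(), 1000, seed = 58)
  expect_error(fit_prevalence_model(iv), "not in prevalence mode")
})

test_that("vcov is symmetric positive semi-definite with matching names", {
  sv <- gen_prevalence_survey(default_truth(), 10000,
                              years = c(2006, 2010, 2014), seed = 59)
  fit <- fit_prevalence_model(sv)
  expect_identical(rownames(fit$vcov), names(fit$coefficients))
  expect_equal(fit$vcov, t(fit$vcov))
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("predictive margin equals the brute-force per-record average", {
  tr <- default_truth()
  sv <- gen_prevalence_survey(tr, 15000, years = c(2010, 2012, 2014), seed = 61)
  fit <- fit_prevalence_model(sv)
  marg <- predictive_margin(fit, sv, at_year = 2014)
  expect_identical(rate_role(marg), "prevalence")

  # brute force: predict each record with year := 2014, average by cell
  sv14 <- as.data.frame(sv)
  sv14$year <- 2014
  p <- diabproj:::.predict_response(fit, sv14)
  for (i in sample.int(nrow(marg), 25)) {
    sel <- sv$age == marg$age[i] & sv$race == marg$race[i] &
      sv$sex == marg$sex[i]
    expect_equal(marg$value[i], weighted.mean(p[sel], sv$weight[sel]),
                 tolerance = 1e-12)
  }

  # invariant to uniform weight rescaling
  sv2 <- sv
  sv2$weight <- sv$weight * 7.3
  attr(sv2, "mode") <- "prevalence"
  class(sv2) <- class(sv)
  marg2 <- predictive_margin(fit, sv2, at_year = 2014)
  expect_equal(marg2$value, marg$value, tolerance = 1e-12)

  # extrapolation warns and flags
  expect_warning(m3 <- predictive_margin(fit, sv, at_year = 2030),
                 "outside the fitted span")
  expect_true(attr(m3, "extrapolated"))
})

test_that("overall 2014 margin recovers the calibrated 9.1% prevalence", {
  tr <- default_truth()
  sv <- gen_prevalence_survey(tr, 120000, years = 2009:2014, seed = 62)
  fit <- fit_prevalence_model(sv)
  cen <- tiny_census()
  s14 <- cen[cen$year == 2014, ]
  marg <- predictive_margin(fit, s14, at_year = 2014)
  overall <- 100 * sum(marg$value * s14$population) / sum(s14$population)
  expect_equal(overall, 9.1, tolerance = 0.3)
})

test_that("annual incidence predictions match the linear-predictor oracle", {
  tr <- default_truth()
  iv <- gen_incidence_survey(tr, 60000, seed = 63)
  fit <- fit_incidence_model(iv)
  inc <- annual_incidence(fit, period = "2006-2014")
  expect_identical(rate_role(inc), "incidence")
  expect_true(all(inc$value > 0 & inc$value < 1))

  # brute-force inverse-logit of the cell linear predictor
  cells <- as.data.frame(inc)[, c("age", "race", "sex")]
  cells$age <- dp_effective_age(cells$age)
  cells$period <- "2006-2014"
  X <- diabproj:::dp_design_matrix(fit$spec, cells)
  expect_equal(inc$value, unname(1 / (1 + exp(-drop(X %*% fit$coefficients)))),
               tolerance = 1e-12)

  expect_error(annual_incidence(fit, period = "2007-2015"), "unknown period")
})

test_that("constant-truth incidence fit predicts 0.8% everywhere", {
  tr <- default_truth(incidence = 0.008)
  iv <- gen_incidence_survey(tr, 100000, seed = 64)
  fit <- fit_incidence_model(iv)
  inc <- annual_incidence(fit, period = "2006-2014")
  # every cell prediction within 3 delta-method SEs of the constant truth
  cells <- as.data.frame(inc)[, c("age", "race", "sex")]
  cells$age <- dp_effective_age(cells$age)
  cells$period <- "2006-2014"
  X <- diabproj:::dp_design_matrix(fit$spec, cells)
  se_eta <- sqrt(rowSums((X %*% fit$vcov) * X))
  se_p <- se_eta * inc$value * (1 - inc$value)
  expect_true(all(abs(inc$value - 0.008) < 3 * se_p + 1e-5))
})

test_that("relative mortality equals the direct prediction ratio and nulls to 1", {
  tr <- default_truth()
  fu <- gen_mortality_followup(tr, 40000, max_periods = 6, seed = 65)
  fit <- fit_mortality_model(fu)
  rrt <- relative_mortality(fit)
  expect_identical(rate_role(rrt), "rel-risk")
  cells <- as.data.frame(rrt)[, c("age", "race", "sex")]
  cells$age <- dp_effective_age(cells$age)
  r1 <- diabproj:::.predict_response(fit, cells, extra = list(diabetes = 1))
  r0 <- diabproj:::.predict_response(fit, cells, extra = list(diabetes = 0))
  expect_equal(rrt$value, r1 / r0, tolerance = 1e-12)

  # zeroing every diabetes term gives RR identically 1
  null_fit <- diabproj:::.model_with_coefs(
    fit, ifelse(grepl("diabetes", names(fit$coefficients)), 0,
                fit$coefficients))
  rr_null <- relative_mortality(null_fit)
  expect_equal(rr_null$value, rep(1, nrow(rr_null)), tolerance = 1e-12)
})

test_that("permuted diabetes labels yield jointly non-significant effects", {
  tr <- default_truth()
  set.seed(66)
  reps <- 20
  pvals <- numeric(reps)
  for (k in seq_len(reps)) {
    fu <- gen_mortality_followup(tr, 8000, max_periods = 5, seed = 600 + k)
    fu$diabetes <- sample(fu$diabetes)
    fit <- fit_mortality_model(fu)
    idx <- grepl("diabetes", names(fit$coefficients))
    b <- fit$coefficients[idx]
    V <- fit$vcov[idx, idx]
    w <- drop(t(b) %*% solve(V, b)) # Wald chi-square, df = #diabetes terms
    pvals[k] <- stats::pchisq(w, df = sum(idx), lower.tail = FALSE)
  }
  expect_gte(mean(pvals > 0.01), 0.95)
})
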