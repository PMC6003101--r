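# Synthetic cross-sectional survey microdata.
#
# Records carry (age, race, sex, year or period, weight, binary outcome) in
# two modes: prevalence (outcome = diagnosed diabetes) and incidence
# (outcome = diagnosis during the prior year, among the non-diabetic).
# Sampling weights are log-uniform on [0.5, 2] and self-normalized to mean 1;
# records are independent (no strata/PSU -- the restricted design variables
# of a real interview survey cannot be emulated faithfully).

.new_survey <- function(df, mode) {
  stopifnot(mode %in% c("prevalence", "incidence"))
  attr(df, "mode") <- mode
  class(df) <- c("dp_survey", "data.frame")
  df
}

#' Survey mode tag
#' @param survey A `dp_survey` table.
#' @return `"prevalence"` or `"incidence"`.
#' @export
survey_mode <- function(survey) attr(survey, "mode")

#' Mark a data.frame as survey microdata
#'
#' For user-supplied records in the documented schema
#' (`age, race, sex, year|period, weight, outcome`).
#'
#' @param df Data.frame of records.
#' @param mode `"prevalence"` or `"incidence"`.
#' @return A `dp_survey`.
#' @export
as_survey <- function(df, mode = c("prevalence", "incidence")) {
  mode <- match.arg(mode)
  need <- c("age", "race", "sex", "weight", "outcome",
            if (mode == "prevalence") "year" else "period")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survey is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$weight <= 0)) stop("weights must be > 0", call. = FALSE)
  if (!all(df$outcome %in% 0:1)) stop("outcome must be binary", call. = FALSE)
  .new_survey(as.data.frame(df), mode)
}

.sample_cells <- function(n, weights_df) {
  idx <- sample.int(nrow(weights_df), n, replace = TRUE, prob = weights_df$weight)
  weights_df[idx, c("age", "race", "sex")]
}

.survey_weights <- function(n) {
  w <- exp(stats::runif(n, log(0.5), log(2)))
  w / mean(w)
}

#' Generate a synthetic prevalence survey
#'
#' Cross-sectional records whose diagnosed-diabetes outcome is Bernoulli
#' with probability `truth$baseline_prevalence` at the record's cell and
#' survey year (the calendar trend is linear on the logit scale).
#'
#' @param truth A `dp_truth` parameter set.
#' @param n Number of records (`>= 1`).
#' @param years Non-empty integer vector of survey years, sampled uniformly.
#' @param seed Integer seed.
#' @return A `dp_survey` in prevalence mode with columns
#'   `age, race, sex, year, weight, outcome`.
#' @export
gen_prevalence_survey <- function(truth, n, years, seed = 1L) {
  stopifnot(inherits(truth, "dp_truth"), n >= 1, length(years) >= 1)
  with_local_seed(seed, {
    cells <- .sample_cells(n, truth$composition)
    year <- years[sample.int(length(years), n, replace = TRUE)]
    p <- truth$baseline_prevalence(dp_effective_age(cells$age), cells$race,
                                   cells$sex, year = year)
    stopifnot(all(p >= 0 & p <= 1))
    df <- data.frame(age = cells$age, race = cells$race, sex = cells$sex,
                     year = year, weight = .survey_weights(n),
                     outcome = stats::rbinom(n, 1L, p))
    rownames(df) <- NULL
    .new_survey(df, "prevalence")
  })
}

#' Generate a synthetic incidence survey
#'
#' Records restricted to the at-risk (non-diabetic) synthetic population;
#' the outcome is a diagnosis during the prior year with probability
#' `truth$incidence` at the record's cell and period.
#'
#' @param truth A `dp_truth` parameter set.
#' @param n Number of records.
#' @param periods Character vector of period labels drawn from
#'   [dp_periods()]; records are stamped uniformly across them.
#' @param seed Integer seed.
#' @return A `dp_survey` in incidence mode with columns
#'   `age, race, sex, period, weight, outcome`.
#' @export
gen_incidence_survey <- function(truth, n, periods = dp_periods(), seed = 1L) {
  stopifnot(inherits(truth, "dp_truth"), n >= 1, length(periods) >= 1)
  bad <- setdiff(periods, dp_periods())
  if (length(bad)) stop("unknown period label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  comp <- truth$composition
  atrisk <- comp
  atrisk$weight <- comp$weight *
    (1 - truth$baseline_prevalence(dp_effective_age(comp$age), comp$race, comp$sex))
  atrisk$weight <- atrisk$weight / sum(atrisk$weight)
  with_local_seed(seed, {
    cells <- .sample_cells(n, atrisk)
    period <- periods[sample.int(length(periods), n, replace = TRUE)]
    p <- truth$incidence(dp_effective_age(cells$age), cells$race, cells$sex,
                         period = period)
    stopifnot(all(p >= 0 & p <= 1))
    df <- data.frame(age = cells$age, race = cells$race, sex = cells$sex,
                     period = period, weight = .survey_weights(n),
                     outcome = stats::rbinom(n, 1L, p))
    rownames(df) <- NULL
    .new_survey(df, "incidence")
  })
}

#' Generate synthetic mortality follow-up (person-period) data
#'
#' Each synthetic person is assigned a cell and a diabetes status (Bernoulli
#' at the cell's baseline prevalence), then followed one annual period at a
#' time: the per-period death probability is `truth$mortality_nd` for the
#' non-diabetic and `truth$mortality_nd * truth$rel_risk` for the diabetic,
#' ages advance each period, and follow-up ends at death or `max_periods`.
#'
#' @param truth A `dp_truth` parameter set.
#' @param n_persons Number of persons (`>= 1`).
#' @param max_periods Maximum follow-up periods per person (`>= 1`).
#' @param seed Integer seed.
#' @return A `dp_followup` data.frame with columns
#'   `id, age, race, sex, diabetes, exposure, died` (one row per
#'   person-period, `exposure = 1` year).
#' @export
gen_mortality_followup <- function(truth, n_persons, max_periods = 10L, seed = 1L) {
  stopifnot(inherits(truth, "dp_truth"), n_persons >= 1, max_periods >= 1)
  grid <- dp_cell_grid()
  # validity: every reachable (age + period) hazard must be a probability
  reach <- expand.grid(age = .dp_age_min:(.dp_age_bucket_eff + max_periods),
                       race = dp_races(), sex = dp_sexes(),
                       stringsAsFactors = FALSE)
  h_d <- truth$mortality_nd(reach$age, reach$race, reach$sex) *
    truth$rel_risk(reach$age, reach$race, reach$sex)
  h_nd <- truth$mortality_nd(reach$age, reach$race, reach$sex)
  bad <- which(pmax(h_d, h_nd) > 1 | pmin(h_d, h_nd) < 0)
  if (length(bad)) {
    b <- reach[bad[1L], ]
    stop(sprintf("death probability outside [0,1] at (age=%s, race=%s, sex=%s)",
                 b$age, b$race, b$sex), call. = FALSE)
  }
  with_local_seed(seed, {
    cells <- .sample_cells(n_persons, truth$composition)
    diab <- stats::rbinom(n_persons, 1L,
                          truth$baseline_prevalence(dp_effective_age(cells$age),
                                                    cells$race, cells$sex))
    alive <- rep(TRUE, n_persons)
    age <- as.numeric(dp_effective_age(cells$age))
    rows <- vector("list", max_periods)
    for (t in seq_len(max_periods)) {
      i <- which(alive)
      if (!length(i)) break
      h <- truth$mortality_nd(age[i], cells$race[i], cells$sex[i])
      h <- h * ifelse(diab[i] == 1L, truth$rel_risk(age[i], cells$race[i], cells$sex[i]), 1)
      d <- stats::rbinom(length(i), 1L, h)
      rows[[t]] <- data.frame(id = i, age = age[i], race = cells$race[i],
                              sex = cells$sex[i], diabetes = diab[i],
                              exposure = 1, died = d)
      alive[i[d == 1L]] <- FALSE
      age[i] <- age[i] + 1
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    df <- df[order(df$id, df$age), ]
    rownames(df) <- NULL
    class(df) <- c("dp_followup", "data.frame")
    df
  })
}
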