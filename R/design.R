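# Frozen regression design specifications.
#
# Three models feed the projection engine:
#   prevalence -- survey-weighted logistic regression of diagnosed diabetes
#     on race, sex, age (linear/quadratic/cubic), survey year, and the
#     pairwise interactions sex:age, sex:year, age:year;
#   incidence  -- the same structure with the continuous year replaced by
#     the five-period factor (sex:period and age:period interactions);
#   mortality  -- Poisson log-linear model of deaths with log person-years
#     offset, on race, sex, age, age^2, diabetes status, and the
#     interactions of age and age^2 with diabetes plus age with race and
#     sex.  The age^2:diabetes term is needed because the relative-risk
#     curve the model must reproduce (about 3 at age 20, 2 at 65, 1.2 at
#     85) has log-scale curvature no linear age:diabetes term can carry.
#
# Age enters as z = (age - 50)/10 before polynomial expansion and calendar
# year as (year - 2000)/10: centering/scaling is needed for the cubic terms
# to be numerically stable, and coefficients stay interpretable (z = 0 at
# age 50).  Survey/census ages top-code the "85+" bucket to its effective
# age 87; follow-up ages are literal person ages.  "Second order
# interactions between sex, age, and survey year" is read as the three
# pairwise products with linear age only (not with age^2 or age^3).

.dp_scale_age <- function(age, topcode = TRUE) {
  a <- if (topcode) dp_effective_age(age) else as.numeric(age)
  (a - 50) / 10
}
.dp_scale_year <- function(year) (year - 2000) / 10

#' Frozen design specification for one of the three regressions
#'
#' @param kind One of `"logistic-prevalence"`, `"logistic-incidence"`,
#'   `"poisson-mortality"` (unambiguous prefixes `"prevalence"` etc. are
#'   accepted).
#' @return A `dp_design_spec` with the model formula, family, and the term
#'   list; the period mapping for incidence covers 1985--2014 with the five
#'   labels of [dp_periods()].
#' @export
design_spec <- function(kind) {
  kind <- match.arg(kind, c("logistic-prevalence", "logistic-incidence",
                            "poisson-mortality", "prevalence", "incidence",
                            "mortality"))
  kind <- switch(kind, prevalence = "logistic-prevalence",
                 incidence = "logistic-incidence",
                 mortality = "poisson-mortality", kind)
  spec <- switch(kind,
    "logistic-prevalence" = list(
      formula = ~ race + sex + z + z2 + z3 + yr + sex:z + sex:yr + z:yr,
      family = "binomial"),
    "logistic-incidence" = list(
      formula = ~ race + sex + z + z2 + z3 + period + sex:z + sex:period + z:period,
      family = "binomial"),
    "poisson-mortality" = list(
      formula = ~ race + sex + z + z2 + diabetes + race:z + sex:z +
        diabetes:z + diabetes:z2,
      family = "poisson"))
  structure(list(kind = kind, formula = spec$formula, family = spec$family,
                 periods = if (kind == "logistic-incidence") dp_periods()),
            class = "dp_design_spec")
}

# Assemble the model frame (factors with frozen levels, scaled age/year)
# and the design matrix for a spec.
.dp_model_frame <- function(spec, data) {
  mf <- data.frame(
    race = factor(data$race, levels = dp_races()),
    sex = factor(data$sex, levels = dp_sexes()),
    z = .dp_scale_age(data$age, topcode = spec$kind != "poisson-mortality"))
  if (anyNA(mf$race)) stop("unknown race level in data", call. = FALSE)
  if (anyNA(mf$sex)) stop("unknown sex level in data", call. = FALSE)
  mf$z2 <- mf$z^2
  mf$z3 <- mf$z^3
  if (spec$kind == "logistic-prevalence") {
    mf$yr <- .dp_scale_year(data$year)
  } else if (spec$kind == "logistic-incidence") {
    mf$period <- factor(data$period, levels = spec$periods)
    if (anyNA(mf$period))
      stop("unknown incidence period label in data", call. = FALSE)
  } else {
    mf$diabetes <- as.numeric(data$diabetes)
  }
  mf
}

dp_design_matrix <- function(spec, data) {
  stats::model.matrix(spec$formula, .dp_model_frame(spec, data))
}
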