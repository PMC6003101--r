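# Maximum-likelihood fitting by iteratively reweighted least squares.
#
# One IRLS routine serves the weighted Bernoulli (logit link) and Poisson
# (log link, offset) models.  Variance is model-based -- the inverse
# observed information (X' W X)^-1 -- because synthetic records are
# independent; design-based variance for real survey data is out of scope.
# Aliased columns (e.g. period levels absent from the data) get coefficient
# 0 and zero variance, mirroring how glm() reports NA coefficients.

.irls_max_iter <- 100L
.irls_tol <- 1e-10
# |logit coefficient| beyond this flags separation; with scaled covariates
# legitimate coefficients stay in single digits, and the working-variance
# floor stops runaway estimates near |beta| ~ 28
.irls_beta_cap <- 20

dp_irls <- function(X, y, w = NULL, family = c("binomial", "poisson"),
                    offset = NULL) {
  family <- match.arg(family)
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(offset)) offset <- rep(0, n)
  stopifnot(length(y) == n, length(w) == n, all(w > 0))

  linkinv <- if (family == "binomial") dp_invlogit else exp
  varfun <- if (family == "binomial") function(mu) mu * (1 - mu) else identity
  dev_fun <- if (family == "binomial") {
    function(y, mu) {
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    }
  } else {
    function(y, mu) {
      t1 <- ifelse(y > 0, y * log(y / pmax(mu, 1e-300)), 0)
      2 * sum(w * (t1 - (y - mu)))
    }
  }

  # start from the weighted mean outcome through the link
  mu0 <- sum(w * y) / sum(w)
  eta <- rep(if (family == "binomial") dp_logit(min(max(mu0, 1e-8), 1 - 1e-8))
             else log(max(mu0, 1e-8)), n)
  beta <- rep(0, p)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(.irls_max_iter)) {
    mu <- linkinv(eta + offset)
    v <- pmax(varfun(mu), 1e-12)
    W <- w * v
    zwork <- eta + (y - mu) / v
    fit <- stats::lm.wfit(X, zwork, W)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    eta <- drop(X %*% beta)
    mu <- linkinv(eta + offset)
    dev <- dev_fun(y, mu)
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < .irls_tol) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  if (!converged)
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 .irls_max_iter, dev_old), call. = FALSE)
  est <- !is.na(fit$coefficients)
  if (family == "binomial" && max(abs(beta)) > .irls_beta_cap)
    stop(sprintf(paste0("apparent separation: |coefficient| > %g ",
                        "(largest %.2f at '%s')"), .irls_beta_cap,
                 max(abs(beta)), colnames(X)[which.max(abs(beta))]),
         call. = FALSE)

  # model-based covariance on the estimable columns, zero elsewhere
  mu <- linkinv(eta + offset)
  W <- w * pmax(varfun(mu), 1e-12)
  Xe <- X[, est, drop = FALSE]
  XtWX <- crossprod(Xe * sqrt(W))
  Vk <- tryCatch(chol2inv(chol(XtWX)), error = function(e)
    stop("information matrix is singular: ", conditionMessage(e), call. = FALSE))
  V <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  V[est, est] <- Vk
  V <- (V + t(V)) / 2

  loglik <- if (family == "binomial") {
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(w * (y * log(mu_c) + (1 - y) * log(1 - mu_c)))
  } else {
    sum(w * (y * log(pmax(mu, 1e-300)) - mu - lgamma(y + 1)))
  }
  list(coefficients = stats::setNames(beta, colnames(X)), vcov = V,
       deviance = dev_old, loglik = loglik, iterations = it,
       converged = converged, aliased = !est)
}

new_fitted_model <- function(spec, coefficients, vcov, n, converged,
                             loglik = NA_real_, year_span = NULL,
                             aliased = NULL) {
  stopifnot(identical(names(coefficients), rownames(vcov)),
            isTRUE(all.equal(vcov, t(vcov), tolerance = 1e-8)))
  ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("vcov is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  structure(list(spec = spec, coefficients = coefficients, vcov = vcov,
                 n = n, converged = converged, loglik = loglik,
                 year_span = year_span, aliased = aliased),
            class = "dp_fitted_model")
}

#' @export
print.dp_fitted_model <- function(x, ...) {
  cat(sprintf("<dp_fitted_model> %s: %d coefficients, n = %s, %s\n",
              x$spec$kind, length(x$coefficients), format(x$n),
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the diagnosed-diabetes prevalence model
#'
#' Survey-weighted logistic regression with the frozen prevalence design:
#' race, sex, scaled age with quadratic and cubic terms, scaled survey year,
#' and the pairwise interactions sex:age, sex:year, age:year.
#'
#' @param survey A `dp_survey` in prevalence mode with every race and sex
#'   level present and at least two distinct survey years.
#' @return A `dp_fitted_model` (coefficients, model-based covariance,
#'   convergence flag, record count, fitted year span).
#' @export
fit_prevalence_model <- function(survey) {
  if (!identical(survey_mode(survey), "prevalence"))
    stop("survey is not in prevalence mode", call. = FALSE)
  .check_levels(survey)
  if (length(unique(survey$year)) < 2)
    stop("prevalence fit needs >= 2 distinct survey years", call. = FALSE)
  spec <- design_spec("prevalence")
  X <- dp_design_matrix(spec, survey)
  fit <- dp_irls(X, survey$outcome, survey$weight, "binomial")
  new_fitted_model(spec, fit$coefficients, fit$vcov, n = nrow(survey),
                   converged = fit$converged, loglik = fit$loglik,
                   year_span = range(survey$year), aliased = fit$aliased)
}

#' Fit the diabetes incidence model
#'
#' As the prevalence model but with the five-period factor replacing the
#' continuous survey year in the main effect and interactions.
#'
#' @param survey A `dp_survey` in incidence mode.
#' @return A `dp_fitted_model`.  Period levels absent from the data are
#'   aliased to the reference level (coefficient 0) with a warning.
#' @export
fit_incidence_model <- function(survey) {
  if (!identical(survey_mode(survey), "incidence"))
    stop("survey is not in incidence mode", call. = FALSE)
  .check_levels(survey)
  spec <- design_spec("incidence")
  X <- dp_design_matrix(spec, survey)
  fit <- dp_irls(X, survey$outcome, survey$weight, "binomial")
  if (any(fit$aliased))
    warning("aliased terms (period levels absent from data?): ",
            paste(names(fit$coefficients)[fit$aliased], collapse = ", "),
            call. = FALSE)
  new_fitted_model(spec, fit$coefficients, fit$vcov, n = nrow(survey),
                   converged = fit$converged, loglik = fit$loglik,
                   aliased = fit$aliased)
}

#' Fit the mortality model
#'
#' Poisson log-linear regression of per-period death indicators with a
#' log person-years offset (discretized survival time): race, sex, scaled
#' age and age squared, diabetes status, and interactions of age with race,
#' sex, and diabetes.
#'
#' @param followup A `dp_followup` person-period table with deaths observed
#'   in both diabetes strata.
#' @return A `dp_fitted_model` whose predictions are death rates per
#'   person-year.
#' @export
fit_mortality_model <- function(followup) {
  stopifnot(all(c("age", "race", "sex", "diabetes", "exposure", "died")
                %in% names(followup)))
  if (any(followup$exposure <= 0)) stop("exposure must be > 0", call. = FALSE)
  for (d in 0:1) {
    if (sum(followup$died[followup$diabetes == d]) == 0)
      stop(sprintf(paste0("no deaths observed in the diabetes=%d stratum; ",
                          "fit needs a larger synthetic sample"), d),
           call. = FALSE)
  }
  spec <- design_spec("mortality")
  X <- dp_design_matrix(spec, followup)
  fit <- dp_irls(X, followup$died, family = "poisson",
                 offset = log(followup$exposure))
  new_fitted_model(spec, fit$coefficients, fit$vcov, n = nrow(followup),
                   converged = fit$converged, loglik = fit$loglik,
                   aliased = fit$aliased)
}

.check_levels <- function(survey) {
  for (r in dp_races()) if (!any(survey$race == r))
    stop("race level absent from survey: ", r, call. = FALSE)
  for (s in dp_sexes()) if (!any(survey$sex == s))
    stop("sex level absent from survey: ", s, call. = FALSE)
}
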