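# Plain-text serialization.  Ages serialize with the open-ended bucket
# written literally as "85+"; all readers restore the integer coding.

.age_to_chr <- function(age) ifelse(age >= .dp_age_top, "85+", as.character(age))
.chr_to_age <- function(x) {
  a <- ifelse(trimws(x) == "85+", .dp_age_top, suppressWarnings(as.integer(x)))
  if (anyNA(a)) stop("unparseable age value(s): ",
                     paste(unique(x[is.na(a)]), collapse = ", "), call. = FALSE)
  as.integer(a)
}

#' Write / read a census projection table as CSV
#'
#' Columns: `year,age,race,sex,population,deaths,net_migration,entrants`;
#' the open-ended age bucket is written literally as `85+`.
#'
#' @param census A `dp_census` table.
#' @param path File path.
#' @return `write_census_csv` the path invisibly; `read_census_csv` a
#'   `dp_census` table.
#' @export
write_census_csv <- function(census, path) {
  out <- as.data.frame(census)
  out$age <- .age_to_chr(out$age)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_census_csv
#' @export
read_census_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(age = "character"))
  df$age <- .chr_to_age(df$age)
  class(df) <- c("dp_census", "data.frame")
  df
}

#' Write / read survey microdata as CSV
#'
#' Columns `age,race,sex,year,weight,outcome` (prevalence mode) or
#' `age,race,sex,period,weight,outcome` (incidence mode); the mode is
#' inferred on read from which time column is present.
#'
#' @param survey A `dp_survey` table.
#' @param path File path.
#' @export
write_survey_csv <- function(survey, path) {
  out <- as.data.frame(survey)
  out$age <- .age_to_chr(out$age)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(age = "character"))
  df$age <- .chr_to_age(df$age)
  mode <- if ("period" %in% names(df)) "incidence" else "prevalence"
  .new_survey(df, mode)
}

#' Write / read mortality follow-up person-periods as CSV
#'
#' Columns `id,age,race,sex,diabetes,exposure,died`.
#'
#' @param followup A `dp_followup` table.
#' @param path File path.
#' @export
write_followup_csv <- function(followup, path) {
  utils::write.csv(as.data.frame(followup), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_followup_csv
#' @export
read_followup_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("dp_followup", "data.frame")
  df
}

#' Write / read a rate table as CSV
#'
#' Columns `age,race,sex[,period|,year],value,role`.
#'
#' @param rates A `dp_rate_table`.
#' @param path File path.
#' @export
write_rates_csv <- function(rates, path) {
  out <- as.data.frame(rates)
  out$age <- .age_to_chr(out$age)
  out$role <- rate_role(rates)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(age = "character"))
  df$age <- .chr_to_age(df$age)
  role <- unique(df$role)
  stopifnot(length(role) == 1L)
  df$role <- NULL
  new_rate_table(df, role)
}

#' Serialize a fitted model to JSON
#'
#' Stores coefficients, covariance, the design-specification fingerprint,
#' and fit metadata; `read_fitted_model` restores a `dp_fitted_model` that
#' predicts identically to the original.
#'
#' @param model A `dp_fitted_model`.
#' @param path File path.
#' @export
write_fitted_model <- function(model, path) {
  payload <- list(kind = model$spec$kind,
                  coefficients = as.list(model$coefficients),
                  vcov = model$vcov,
                  n = model$n, converged = model$converged,
                  loglik = model$loglik, year_span = model$year_span)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fitted_model
#' @export
read_fitted_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(p$coefficients)
  vcov <- matrix(as.numeric(p$vcov), nrow = length(coefs),
                 dimnames = list(names(coefs), names(coefs)))
  new_fitted_model(spec = design_spec(p$kind), coefficients = coefs,
                   vcov = vcov, n = p$n, converged = p$converged,
                   loglik = p$loglik, year_span = p$year_span)
}
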