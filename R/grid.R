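# Demographic grid conventions shared by every module.
#
# Ages are single years 18..84 plus an open-ended bucket coded as the integer
# 85 and serialized as "85+".  Rate lookups for the bucket use a fixed
# effective age of 87 so that age-polynomial models are evaluated near the
# bucket's population centre rather than at its lower edge.

#' Race levels of the projection grid
#'
#' The population is split into three race groups (white, black, other) and
#' two sexes, giving six sub-cohorts that each run their own Markov chain.
#'
#' @return Character vector of race levels, reference level first.
#' @export
dp_races <- function() c("white", "black", "other")

#' Sex levels of the projection grid
#' @return Character vector of sex levels, reference level first.
#' @export
dp_sexes <- function() c("female", "male")

#' Incidence period labels
#'
#' Calendar years 1985--2014 are grouped into five periods for the incidence
#' model (annual diagnosis events are too sparse for single-year estimation).
#'
#' @return Character vector of the five period labels.
#' @export
dp_periods <- function() {
  c("1985-1989", "1990-1994", "1995-1999", "2000-2005", "2006-2014")
}

#' Map a calendar year to its incidence period label
#' @param year Integer vector of calendar years in 1985--2014.
#' @return Character vector of period labels.
#' @export
dp_year_to_period <- function(year) {
  stopifnot(all(year >= 1985 & year <= 2014))
  cut_pts <- c(1985, 1990, 1995, 2000, 2006, 2015)
  dp_periods()[findInterval(year, cut_pts)]
}

# age coding constants
.dp_age_min <- 18L
.dp_age_top <- 85L       # integer code of the open-ended bucket
.dp_age_bucket_eff <- 87 # effective age used for rate lookup in the bucket

#' Ages of the projection grid
#' @return Integer vector 18..85 where 85 codes the open-ended "85+" bucket.
#' @export
dp_ages <- function() .dp_age_min:.dp_age_top

#' Effective age used for rate lookups
#'
#' Identity for single ages; the "85+" bucket (coded 85) maps to 87.
#'
#' @param age Integer vector of grid ages.
#' @return Numeric vector of effective ages.
#' @export
dp_effective_age <- function(age) {
  ifelse(age >= .dp_age_top, .dp_age_bucket_eff, as.numeric(age))
}

#' Full (age, race, sex) cell grid
#'
#' @param ages Integer vector of ages (default the full 18..85 grid).
#' @return A data.frame with columns `age`, `race`, `sex` in canonical order
#'   (race slowest, then sex, then age), one row per cell.
#' @export
dp_cell_grid <- function(ages = dp_ages()) {
  g <- expand.grid(age = as.integer(ages), sex = dp_sexes(), race = dp_races(),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("age", "race", "sex")]
}

# canonical cell key for alignment joins
dp_cell_key <- function(df) paste(df$race, df$sex, df$age, sep = "|")

# Align rows of `df` to the cell order of `grid`; errors naming the first
# missing cell.  Returns df reordered.
dp_align_cells <- function(df, grid, what = "table") {
  idx <- match(dp_cell_key(grid), dp_cell_key(df))
  if (anyNA(idx)) {
    miss <- grid[which(is.na(idx))[1L], ]
    stop(sprintf("%s is missing cell (age=%s, race=%s, sex=%s)",
                 what, miss$age, miss$race, miss$sex), call. = FALSE)
  }
  df[idx, , drop = FALSE]
}

# ---- small numeric helpers ----

dp_logit <- function(p) log(p / (1 - p))
dp_invlogit <- function(x) 1 / (1 + exp(-x))

#' Largest-remainder integer apportionment
#'
#' Rounds a non-negative real vector to integers that sum exactly to
#' `total`, flooring first and then distributing the shortfall by descending
#' fractional remainder.  Used so that synthetic census tables satisfy the
#' cohort-component accounting identity with integer counts.
#'
#' @param x Non-negative numeric vector.
#' @param total Integer target sum (default `round(sum(x))`).
#' @return Integer vector summing to `total`.
#' @export
dp_largest_remainder <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0), total >= 0)
  fl <- floor(x)
  short <- as.integer(round(total - sum(fl)))
  if (short < 0) { # total below sum of floors: take back from smallest remainders
    ord <- order(x - fl, fl)
    k <- -short
    take <- ord[fl[ord] > 0][seq_len(k)]
    fl[take] <- fl[take] - 1
  } else if (short > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
  }
  as.integer(fl)
}
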