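# Published base-case projection (counts in millions by age group) used as
# worked-example input for the derived-statistic operations, plus the
# low-incidence scenario totals.  These are external reference numbers, the
# kind a user would type in from a published projection table.
reference_report <- function() {
  as_report(data.frame(
    year = rep(c(2014, 2030, 2060), each = 5),
    group = rep(c("18-44", "45-64", "65-74", ">=75", "total"), 3),
    count = c(2.86, 10.27, 5.51, 3.67, 22.31,
              5.01, 13.67, 10.92, 10.11, 39.71,
              5.75, 19.71, 15.69, 19.48, 60.63)))
}

reference_low_scenario_report <- function() {
  as_report(data.frame(year = c(2030, 2060), group = "total",
                       count = c(34.70, 50.40)))
}
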