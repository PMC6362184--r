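# Total chlorophyll from two-wavelength absorbance readings, with
# stage-to-stage change reporting.

#' Two-wavelength total-chlorophyll coefficient set
#'
#' Total chlorophyll (ug/ml) = `c1 * A(lambda1) + c2 * A(lambda2)`. The
#' default is the classic 645/663 nm total-chlorophyll combination
#' (20.2 and 8.02 ug/ml per absorbance unit); both wavelengths and
#' coefficients are user-configurable for other solvent calibrations.
#'
#' @param wavelengths_nm numeric pair `c(lambda1, lambda2)`.
#' @param coefficients positive numeric pair `c(c1, c2)`.
#' @export
chlorophyll_coefficients <- function(wavelengths_nm = c(645, 663),
                                     coefficients = c(20.2, 8.02)) {
  if (length(wavelengths_nm) != 2 || length(coefficients) != 2)
    stopf("need exactly two wavelengths and two coefficients")
  if (any(coefficients <= 0)) stopf("coefficients must be > 0")
  structure(list(wavelengths_nm = wavelengths_nm,
                 coefficients = coefficients),
            class = "chlorophyll_coefficients")
}

#' Total chlorophyll concentration of one extract
#'
#' @param reading named numeric vector of absorbances, names = wavelengths
#'   in nm (e.g. `c("645" = 0.5, "663" = 0.8)`); values must be >= 0.
#' @param coeffs a [chlorophyll_coefficients()] set.
#' @return concentration in ug/ml.
#' @export
total_chlorophyll <- function(reading, coeffs = chlorophyll_coefficients()) {
  stopifnot(inherits(coeffs, "chlorophyll_coefficients"))
  if (any(reading < 0)) stopf("absorbances must be >= 0")
  keys <- as.character(coeffs$wavelengths_nm)
  if (!all(keys %in% names(reading)))
    stopf("reading lacks required wavelength(s): %s",
          paste(setdiff(keys, names(reading)), collapse = ", "))
  unname(sum(coeffs$coefficients * reading[keys]))
}

#' Stage-to-stage chlorophyll change report
#'
#' Percent changes of the stage means (yellow vs green, red vs green, red vs
#' yellow, in this fixed order) with unpaired two-tailed t-tests.
#'
#' @param values_by_stage named list with numeric elements `green`,
#'   `yellow`, `red` (>= 2 values each).
#' @return data.frame with `comparison`, `reference_mean`, `value_mean`,
#'   `percent_change`, `p_two_tailed`, `significance_tier`.
#' @export
stage_change_report <- function(values_by_stage) {
  need <- c("green", "yellow", "red")
  if (!all(need %in% names(values_by_stage)))
    stopf("values_by_stage needs elements %s", paste(need, collapse = ", "))
  pairs <- list(c("green", "yellow"), c("green", "red"), c("yellow", "red"))
  rows <- lapply(pairs, function(p) {
    ref <- values_by_stage[[p[1]]]
    val <- values_by_stage[[p[2]]]
    tt <- ttest_unpaired(ref, val)
    data.frame(comparison = paste(p[2], "vs", p[1]),
               reference_mean = mean(ref), value_mean = mean(val),
               percent_change = percent_change(mean(ref), mean(val)),
               p_two_tailed = tt$p_two_tailed,
               significance_tier = tt$significance_tier)
  })
  do.call(rbind, rows)
}
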