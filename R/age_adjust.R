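#' Age distributions
#'
#' A per-integer-age weighting of a cohort or population, used to
#' marginalise the age-adjusted frequency surface.
#'
#' @param age Integer ages within 0-110.
#' @param weight Non-negative person counts or weights; total must be
#'   positive.
#' @return An object of class `age_distribution` (data frame `age`,
#'   `weight`).
#' @export
age_distribution <- function(age, weight) {
  if (length(age) != length(weight) || !length(age))
    stop("age and weight must be non-empty and of equal length")
  if (any(age != round(age)) || any(age < 0) || any(age > 110))
    stop("ages must be integers in 0-110")
  if (any(!is.finite(weight)) || any(weight < 0) || sum(weight) <= 0)
    stop("weights must be non-negative with positive total")
  agg <- stats::aggregate(list(weight = weight), list(age = as.integer(age)),
                          sum)
  agg <- agg[order(agg$age), ]
  rownames(agg) <- NULL
  structure(agg, class = c("age_distribution", "data.frame"))
}

#' @rdname age_distribution
#' @param file TSV file with header `age<TAB>count`.
#' @export
read_age_distribution <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("age", "count") %in% names(x)))
    stop("age distribution file must have columns age and count: ", file)
  age_distribution(x$age, x$count)
}

#' Age-adjusted carrier frequency
#'
#' The decay model gives carrier frequencies at birth (unexpanded repeats
#' do not affect survival, so the fitted spectrum is a birth spectrum).
#' Disease-associated repeats deplete with age: inside the adjustment band
#' (CAG 40-50 by default, where death models are reliable) the birth
#' carrier frequency is multiplied by the combined carrier survival
#' \eqn{S_{HD} \times S_{pop}}. Outside the band (e.g. reduced-penetrance
#' repeats 36-39) the birth frequency is used unchanged — no survival
#' factor is applied rather than guessing one from inadequate data. The
#' population-survival factor deliberately does not renormalise by the
#' surviving general population: the quantity modelled is carriers per
#' birth-cohort member, matching the prevalence convention downstream.
#'
#' @param model A [decay_model()].
#' @param cs A [combined_survival()]; its `band` is the adjustment band.
#' @param cag A single CAG length within the model range.
#' @param age Integer age(s) covered by the life table.
#' @return Carrier fraction(s) in `[0, 1]`.
#' @export
age_adjusted_frequency <- function(model, cs, cag, age) {
  stopifnot(inherits(model, "decay_model"), inherits(cs, "combined_survival"))
  birth <- 2 * allele_frequency(model, cag)
  if (cag >= cs$band[1] && cag <= cs$band[2])
    birth * carrier_survival(cs, cag, age)
  else
    rep(birth, length(age))
}

#' Age-adjusted frequency surface
#'
#' Tabulates [age_adjusted_frequency()] over a CAG band and an age grid.
#'
#' @inheritParams age_adjusted_frequency
#' @param cag_range Inclusive CAG interval.
#' @param ages Integer age grid (default 0 to the life-table maximum).
#' @return A matrix of class `frequency_surface` (rows CAG, columns age)
#'   with attributes `band` and `model`.
#' @export
frequency_surface <- function(model, cs, cag_range = NULL, ages = NULL) {
  if (is.null(cag_range)) cag_range <- cs$band
  cag_range <- check_cag_range(cag_range)
  if (is.null(ages)) ages <- 0:max(cs$life_table$age)
  cags <- cag_range[1]:cag_range[2]
  m <- t(vapply(cags, function(c) age_adjusted_frequency(model, cs, c, ages),
                numeric(length(ages))))
  dimnames(m) <- list(cag = cags, age = ages)
  structure(m, band = cs$band, class = c("frequency_surface", "matrix"))
}

#' @export
plot.frequency_surface <- function(x, log = "y", ...) {
  ages <- as.integer(colnames(x))
  graphics::matplot(ages, t(unclass(x)), type = "l", log = log,
                    xlab = "age (years)", ylab = "carrier frequency", ...)
  invisible(x)
}

#' Expected carrier spectrum of an aged cohort
#'
#' Marginalises the age-adjusted frequency surface over a cohort age
#' distribution: for each CAG the expected carrier count is
#' \eqn{\sum_a w(a) f(c, a)}. The expectation is computed exactly (no
#' sampling); a seeded Poisson-sampled mode exists for generating
#' illustrative noisy spectra.
#'
#' @inheritParams age_adjusted_frequency
#' @param ages An [age_distribution()] whose weights are person counts.
#' @param cag_range Inclusive CAG interval to report.
#' @param unit `"carrier"` (default) or `"allele"` (half the carrier
#'   expectation: two chromosomes per person, one expanded per carrier).
#' @param mode `"expected"` or `"sampled"`.
#' @param seed Seed for sampled mode.
#' @return An [allele_table()] of expected (possibly fractional) counts.
#' @export
cohort_expected_spectrum <- function(model, cs, ages, cag_range,
                                     unit = c("carrier", "allele"),
                                     mode = c("expected", "sampled"),
                                     seed = NULL) {
  unit <- match.arg(unit); mode <- match.arg(mode)
  stopifnot(inherits(ages, "age_distribution"))
  cag_range <- check_cag_range(cag_range)
  cags <- cag_range[1]:cag_range[2]
  expected <- vapply(cags, function(c)
    sum(ages$weight * age_adjusted_frequency(model, cs, c, ages$age)),
    numeric(1))
  if (unit == "allele") expected <- expected / 2
  if (mode == "sampled") {
    if (!is.null(seed)) set.seed(seed)
    expected <- stats::rpois(length(expected), expected)
  }
  allele_table(cags, expected, unit = if (unit == "carrier") "carrier"
               else "allele")
}

#' Pearson chi-squared comparison of observed and expected spectra
#'
#' Compares an observed allele-count spectrum against model-expected
#' counts. Expected counts are rescaled so their total matches the
#' observed total (the comparison is of shape, not yield), bins with
#' expected count below `min_expected` are pooled into their lower
#' neighbour, and the Pearson statistic
#' \eqn{\sum (O - E)^2 / E} is referred to a chi-squared distribution with
#' `bins - 1` degrees of freedom.
#'
#' @param observed An [allele_table()] of observed counts.
#' @param expected An [allele_table()] (or data frame `cag`, `count`) of
#'   expected counts over the same CAG range.
#' @param min_expected Pooling threshold (default 5).
#' @return A list of class `cohort_comparison`: `table` (per retained bin:
#'   cag label, observed, expected), `statistic`, `df`, `p_value`.
#' @examples
#' o <- allele_table(1:2, c(10, 0))
#' e <- allele_table(1:2, c(5, 5))
#' chi_squared_compare(o, e, min_expected = 1)$statistic  # 10
#' @export
chi_squared_compare <- function(observed, expected, min_expected = 5) {
  stopifnot(inherits(observed, "allele_table"))
  if (!inherits(expected, "allele_table"))
    expected <- allele_table(expected$cag, expected$count)
  cags <- sort(union(observed$cag, expected$cag))
  O <- count_at(observed, cags)
  E <- count_at(expected, cags)
  if (any(E <= 0))
    stop("expected counts must be strictly positive in every compared bin")
  E <- E * sum(O) / sum(E)
  # pool low-expectation bins into their lower neighbour
  repeat {
    low <- which(E < min_expected)
    low <- low[low > 1L]
    if (!length(low)) break
    i <- low[1L]
    E[i - 1L] <- E[i - 1L] + E[i]
    O[i - 1L] <- O[i - 1L] + O[i]
    E <- E[-i]; O <- O[-i]; cags <- cags[-i]
  }
  if (length(E) >= 2L && E[1L] < min_expected) {
    E[2L] <- E[2L] + E[1L]; O[2L] <- O[2L] + O[1L]
    E <- E[-1L]; O <- O[-1L]; cags <- cags[-1L]
  }
  if (length(E) < 2L)
    stop("fewer than 2 bins with expected >= ", min_expected,
         " after pooling")
  stat <- sum((O - E)^2 / E)
  df <- length(E) - 1L
  structure(list(
    table = data.frame(cag = cags, observed = O, expected = E),
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE)
  ), class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf(
    "Pearson chi-squared comparison: X^2 = %.3f, df = %d, p = %.3g (%d bins)\n",
    x$statistic, x$df, x$p_value, nrow(x$table)))
  invisible(x)
}
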