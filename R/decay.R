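#' Fit the log-linear exponential decay law to an allele spectrum
#'
#' Beyond its modal length (17 repeats in European-ancestry populations) the
#' HTT CAG allele spectrum falls off log-linearly: the expected count at
#' repeat length \eqn{c} follows \eqn{10^{\beta_0 + \beta_1 c}} with
#' \eqn{\beta_1 < 0}. `fit_decay()` estimates \eqn{(\beta_0, \beta_1)} by
#' ordinary least squares of `log10(count)` on CAG over a stated fit range,
#' the same procedure as `lm(log10(count) ~ cag)`.
#'
#' Zero-count bins inside the fit range are a hard error rather than being
#' dropped: the canonical fit ranges (18-35 unexpanded, 42-55 expanded) are
#' chosen to avoid empty bins, and silently omitting one would change the
#' fitted law.
#'
#' @param table An [allele_table()].
#' @param range Inclusive CAG interval `c(lo, hi)` to fit over; defaults to
#'   the unexpanded range 18-35.
#' @return An object of class `decay_fit` with components `slope`,
#'   `intercept` (log10-count units), `r_squared`, `p_value` (slope t-test,
#'   equal to the regression F-test with one predictor), `fit_range`, and
#'   the underlying `lm` fit.
#' @examples
#' cag <- 18:35
#' at <- allele_table(cag, 10^(5.552482 - 0.13925 * cag))
#' fit_decay(at, c(18, 35))
#' @export
fit_decay <- function(table, range = c(18, 35)) {
  stopifnot(inherits(table, "allele_table"))
  range <- check_cag_range(range)
  cag <- range[1]:range[2]
  count <- count_at(table, cag)
  zero <- cag[count <= 0]
  if (length(zero))
    stop(sprintf("zero or missing count inside fit range at CAG %s",
                 paste(zero, collapse = ", ")))
  if (length(cag) < 3L)
    stop("fewer than 3 informative bins: degenerate fit")
  fit <- stats::lm(log10(count) ~ cag, data = data.frame(cag, count))
  # a noiseless spectrum fits perfectly; the perfect-fit note is expected
  sm <- suppressWarnings(summary(fit))
  p <- if (sm$sigma == 0) 0 else unname(sm$coefficients["cag", "Pr(>|t|)"])
  structure(list(
    slope = unname(stats::coef(fit)[["cag"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = if (is.nan(sm$r.squared)) 1 else sm$r.squared,
    p_value = p,
    fit_range = range,
    lm = fit
  ), class = "decay_fit")
}

#' Construct a decay fit directly from known coefficients
#'
#' Used when the law's coefficients are given rather than estimated, e.g.
#' when reproducing a published model.
#'
#' @param intercept,slope Coefficients on the log10-count scale.
#' @param fit_range CAG interval the coefficients were estimated on.
#' @param r_squared,p_value Optional goodness-of-fit metadata.
#' @return A `decay_fit`.
#' @export
decay_fit <- function(intercept, slope, fit_range = c(18, 35),
                      r_squared = NA_real_, p_value = NA_real_) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, p_value = p_value,
                 fit_range = check_cag_range(fit_range), lm = NULL),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, digits = 6, ...) {
  cat("Log-linear decay fit: log10(count) =",
      format(x$intercept, digits = digits), ifelse(x$slope < 0, "-", "+"),
      format(abs(x$slope), digits = digits), "x CAG\n")
  cat(sprintf("  fit range CAG %d-%d", x$fit_range[1], x$fit_range[2]))
  if (is.finite(x$r_squared))
    cat(sprintf(", R^2 = %.4g, p = %.3g", x$r_squared, x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Extend a decay fit into a population allele-frequency model
#'
#' A `decay_model` carries the fitted law, the CAG interval over which the
#' extrapolation is asserted to hold (canonically 17-55, extending the
#' unexpanded-range fit into the pathogenic range), and the allele-pool
#' denominator that converts a model count into a population allele
#' fraction. For a cohort of N subjects each contributing one unexpanded
#' allele to the fitted histogram, the pool is N (7578 in the reference
#' calibration), so `count / pool` is the allele fraction among
#' chromosomes of the general population.
#'
#' @param fit A `decay_fit` with strictly negative slope (extrapolating a
#'   non-decaying law into the expanded range is refused as meaningless).
#' @param model_range Inclusive CAG interval over which the model applies
#'   (within 1-200). Default `c(17, 55)`.
#' @param allele_pool Positive allele-pool denominator.
#' @return An object of class `decay_model`.
#' @examples
#' m <- decay_model(decay_fit(5.552482, -0.13925), c(17, 55), 7578)
#' predict(m, cag = 42, type = "frequency")
#' @export
decay_model <- function(fit, model_range = c(17, 55), allele_pool) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!is.finite(fit$slope) || fit$slope >= 0)
    stop("decay model requires a strictly negative slope; got ",
         format(fit$slope))
  model_range <- check_cag_range(model_range)
  if (model_range[1] < 1 || model_range[2] > 200)
    stop("model_range must lie within CAG 1-200")
  if (!is.numeric(allele_pool) || length(allele_pool) != 1L ||
      !is.finite(allele_pool) || allele_pool <= 0)
    stop("allele_pool must be a single positive number")
  structure(list(fit = fit, model_range = model_range,
                 allele_pool = allele_pool),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat("Exponential decay model for CAG repeat frequencies\n")
  print(x$fit)
  cat(sprintf("  model range CAG %d-%d, allele pool %s\n",
              x$model_range[1], x$model_range[2],
              format(x$allele_pool, big.mark = " ")))
  invisible(x)
}

#' @export
coef.decay_model <- function(object, ...) coef(object$fit)

#' @export
summary.decay_model <- function(object, ...) {
  cag <- object$model_range[1]:object$model_range[2]
  data.frame(cag = cag,
             count = model_count(object, cag),
             frequency = allele_frequency(object, cag))
}

#' Evaluate a decay model
#'
#' `model_count()` returns the expected count \eqn{10^{\beta_0 + \beta_1 c}}
#' in the units of the fitted histogram; `allele_frequency()` divides by the
#' allele pool to give a population allele fraction; `predict()` dispatches
#' between the two (plus `"carrier"`, twice the allele fraction under the
#' rare-allele heterozygote approximation).
#'
#' @param model A [decay_model()].
#' @param cag Integer CAG length(s) within the model range.
#' @return Numeric vector the length of `cag`.
#' @export
model_count <- function(model, cag) {
  stopifnot(inherits(model, "decay_model"))
  check_in_range(cag, model$model_range, "CAG")
  10^(model$fit$intercept + model$fit$slope * cag)
}

#' @rdname model_count
#' @export
allele_frequency <- function(model, cag) {
  model_count(model, cag) / model$allele_pool
}

#' @rdname model_count
#' @param object A `decay_model`.
#' @param type `"count"`, `"frequency"` or `"carrier"`.
#' @param ... Unused.
#' @export
predict.decay_model <- function(object, cag,
                                type = c("count", "frequency", "carrier"),
                                ...) {
  type <- match.arg(type)
  switch(type,
         count = model_count(object, cag),
         frequency = allele_frequency(object, cag),
         carrier = 2 * allele_frequency(object, cag))
}

#' @export
plot.decay_model <- function(x, ..., log = "y") {
  cag <- x$model_range[1]:x$model_range[2]
  graphics::plot(cag, model_count(x, cag), type = "l", log = log,
                 xlab = "CAG repeat length", ylab = "expected count", ...)
  invisible(x)
}

#' Carrier frequency of a CAG band and its reciprocal
#'
#' Sums allele frequencies over an inclusive CAG band and doubles the sum:
#' at these allele frequencies essentially all carriers are heterozygous, so
#' the carrier fraction is twice the summed allele fraction. The reciprocal
#' is reported as "one in N" with `N = floor(1 / fraction)`, the convention
#' that turns a prevalence of 12.4e-5 into "one in 8064".
#'
#' @param model A [decay_model()].
#' @param band Inclusive CAG interval within the model range. Standard HD
#'   bands: intermediate 27-35, reduced penetrance 36-39, fully penetrant
#'   40+.
#' @return A list with `fraction` (carrier fraction) and `one_in`
#'   (its floored reciprocal).
#' @examples
#' m <- decay_model(decay_fit(5.552482, -0.13925), c(17, 55), 7578)
#' carrier_frequency_band(m, c(36, 39))  # reduced-penetrance carriers
#' @export
carrier_frequency_band <- function(model, band) {
  band <- check_cag_range(band)
  check_in_range(band, model$model_range, "band")
  frac <- 2 * sum(allele_frequency(model, band[1]:band[2]))
  list(fraction = frac, one_in = one_in(frac))
}

#' Report a small fraction as "one in N"
#'
#' @param fraction A positive fraction.
#' @return `floor(1 / fraction)` as an integer-valued double.
#' @export
one_in <- function(fraction) {
  stopifnot(is.numeric(fraction), all(fraction > 0))
  floor(1 / fraction)
}

# -- shared range helpers ----------------------------------------------------

check_cag_range <- function(range) {
  if (length(range) != 2L || any(!is.finite(range)) ||
      any(range != round(range)) || range[1] > range[2])
    stop("CAG range must be an ordered pair of integers")
  as.integer(range)
}

check_in_range <- function(x, range, what = "value") {
  bad <- x < range[1] | x > range[2] | x != round(x)
  if (any(bad))
    stop(sprintf("%s %s outside model range %d-%d",
                 what, paste(x[bad], collapse = ", "), range[1], range[2]))
  invisible(x)
}
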