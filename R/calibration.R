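#' Packaged model calibration
#'
#' Builds the full set of calibrated model objects the pipeline runs on
#' when no cohort data are supplied. The construction is deterministic and
#' anchored to published reference values:
#'
#' * **Decay law**: `log10(count) = 5.552482 - 0.13925 x CAG` over CAG
#'   17-55, allele pool 7578 (one unexpanded allele per cohort subject).
#' * **Onset medians**: a log-linear curve `log(median age) ~ CAG`
#'   least-squares fitted through the reference ages at 50% onset
#'   probability for CAG 41-45 (56.5, 52, 48, 43.5, 40.5 years) and
#'   extrapolated over CAG 40-50. Onset ages are log-normal with
#'   `sdlog = onset_sdlog` (default 0.2).
#' * **Death models**: per-CAG log-normal with median
#'   `onset median + onset_to_death_years` (default 15, the typical
#'   disease duration). A single `sdlog` shared across CAGs is solved by
#'   root-finding so the CAG-42 model gives survival 0.612 at age 64.
#' * **Life table**: Gompertz-Makeham hazard `q(a) = A + B exp(G a)` with
#'   `A = 5e-4`, `G = 0.085` (a realistic background hazard and adult
#'   mortality-doubling rate of about 8 years), and `B` solved so
#'   cumulative survival to age 64 is 0.845.
#'
#' Every anchor is re-checked after construction (onset medians within
#' 0.5 years of their reference values; survival anchors within 0.005) and
#' an infeasible anchor raises an error rather than returning a
#' mis-calibrated set.
#'
#' @param onset_sdlog Log-scale spread of onset ages.
#' @param onset_to_death_years Additive onset-to-death gap in years.
#' @param band CAG interval of the onset/death adjustment band.
#' @return A list of class `hd_calibration` with elements `model`
#'   ([decay_model()]), `onset_models`, `death_models`, `life_table`,
#'   `survival` ([combined_survival()]), `onset_curve`
#'   (`function(cag) -> median years`), and the solved scalars
#'   `death_sdlog`, `makeham` (A, B, G).
#' @examples
#' cal <- hd_calibration()
#' event_median(cal$onset_models[["42"]])
#' @export
hd_calibration <- function(onset_sdlog = 0.2, onset_to_death_years = 15,
                           band = c(40, 50)) {
  band <- check_cag_range(band)
  model <- decay_model(decay_fit(5.552482, -0.13925, fit_range = c(18, 35)),
                       model_range = c(17, 55), allele_pool = 7578)

  anchor_cag <- 41:45
  anchor_med <- c(56.5, 52, 48, 43.5, 40.5)
  cf <- unname(stats::lm.fit(cbind(1, anchor_cag),
                             log(anchor_med))$coefficients)
  onset_curve <- function(cag) exp(cf[1] + cf[2] * cag)
  dev <- abs(onset_curve(anchor_cag) - anchor_med)
  if (any(dev > 0.5))
    stop("onset median curve misses its anchors by up to ",
         format(max(dev), digits = 3), " years")

  cags <- band[1]:band[2]
  onset_models <- lapply(cags, function(c)
    lognormal_event_model(log(onset_curve(c)), onset_sdlog, cag = c,
                          kind = "onset"))
  names(onset_models) <- cags

  # shared death sdlog anchored to survival 0.612 at 64 for CAG 42
  death_median <- function(c) onset_curve(c) + onset_to_death_years
  if (death_median(42) <= 64)
    stop("death-survival anchor infeasible: CAG-42 death median <= 64")
  froot <- function(s) 1 - stats::plnorm(64, log(death_median(42)), s) - 0.612
  death_sdlog <- stats::uniroot(froot, c(1e-4, 2), tol = 1e-12)$root
  death_models <- lapply(cags, function(c)
    lognormal_event_model(log(death_median(c)), death_sdlog, cag = c,
                          kind = "death"))
  names(death_models) <- cags

  makeham <- solve_life_table(A = 5e-4, G = 0.085, s64 = 0.845)
  lt <- generate_life_table(makeham["A"], makeham["B"], makeham["G"])
  cs <- combined_survival(death_models, lt, band = band)

  if (abs(hd_survival(death_models[["42"]], 64) - 0.612) > 0.005)
    stop("CAG-42 death-survival anchor missed")
  if (abs(population_survival(lt, 64) - 0.845) > 0.005)
    stop("population-survival anchor missed")

  structure(list(model = model, onset_models = onset_models,
                 death_models = death_models, life_table = lt,
                 survival = cs, onset_curve = onset_curve,
                 onset_sdlog = onset_sdlog,
                 onset_to_death_years = onset_to_death_years,
                 death_sdlog = death_sdlog, makeham = makeham,
                 band = band),
            class = "hd_calibration")
}

#' @export
print.hd_calibration <- function(x, ...) {
  cat("HD model calibration\n")
  print(x$model)
  cat(sprintf("  onset medians CAG %d-%d: %s years (sdlog %.3g)\n",
              x$band[1], x$band[2],
              paste(sprintf("%.1f", x$onset_curve(x$band[1]:x$band[2])),
                    collapse = ", "), x$onset_sdlog))
  cat(sprintf("  death = onset + %g y, sdlog %.4f (CAG-42 survival at 64: %.3f)\n",
              x$onset_to_death_years, x$death_sdlog,
              hd_survival(x$death_models[["42"]], 64)))
  cat(sprintf("  life table: Gompertz-Makeham A=%.3g B=%.3g G=%.3g, survival at 64: %.3f\n",
              x$makeham["A"], x$makeham["B"], x$makeham["G"],
              population_survival(x$life_table, 64)))
  invisible(x)
}

# Solve the Gompertz-Makeham B so cumulative survival to 64 hits s64.
solve_life_table <- function(A, G, s64) {
  f <- function(B) prod(1 - pmin(1, A + B * exp(G * (0:63)))) - s64
  B <- stats::uniroot(f, c(1e-10, 1e-2), tol = 1e-15)$root
  c(A = A, B = B, G = G)
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Produces a [life_table()] with per-year death probability
#' `q(age) = min(1, A + B exp(G age))`, identical for both sexes unless
#' sex-specific coefficients are given. A stand-in for actuarial period
#' tables when those cannot be shipped; the packaged fixture
#' `synthetic_us_life_table.csv` is this form calibrated so survival to
#' age 64 is 0.845.
#'
#' @param A,B,G Makeham background hazard, Gompertz scale and Gompertz
#'   rate.
#' @param max_age Last tabulated age (default 110).
#' @param sex_ratio Multiplier applied to male q relative to female
#'   (default 1: identical).
#' @return A [life_table()].
#' @export
generate_life_table <- function(A, B, G, max_age = 110, sex_ratio = 1) {
  age <- 0:max_age
  q <- A + B * exp(G * age)
  if (any(q > 1)) {
    warning("hazard exceeds 1 before max_age; truncated at 1",
            call. = FALSE)
    q <- pmin(1, q)
  }
  qm <- pmin(1, q * sex_ratio)
  life_table(age, qm, q, note = sprintf(
    "synthetic Gompertz-Makeham (A=%.3g, B=%.3g, G=%.3g)", A, B, G))
}
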