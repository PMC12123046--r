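#' Simulate a clinically ascertained HD cohort
#'
#' Draws a synthetic cohort with the statistical structure the pipeline
#' assumes: each subject carries one unexpanded and one expanded allele.
#' Unexpanded alleles follow the calibrated decay law restricted to CAG
#' 17-35, with a steep sub-17 shoulder (geometric, ratio 0.3 per repeat)
#' so the full spectrum peaks at 17; expanded alleles follow the same law
#' restricted to 36-55. Onset ages are log-normal around the calibrated
#' median curve; death ages are onset plus a gamma-distributed disease
#' duration with mean `onset_to_death_years` (shape 4, giving a realistic
#' right-skewed spread of about 7.5 years).
#'
#' Identical seeds produce identical tables.
#'
#' @param cal An [hd_calibration()].
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param expanded_range Inclusive CAG interval for the expanded allele
#'   (default `c(36, 55)`).
#' @param sub17_ratio Per-repeat geometric ratio of the sub-17 shoulder.
#' @param duration_shape Gamma shape of the onset-to-death duration.
#' @return A list with `genotypes` (`sample_id`, `allele1` unexpanded,
#'   `allele2` expanded), `onset` and `death` (`sample_id`, `cag`,
#'   `age_years`).
#' @examples
#' coh <- simulate_hd_cohort(hd_calibration(), 500, seed = 1)
#' table(coh$genotypes$allele1)[1:5]
#' @export
simulate_hd_cohort <- function(cal, n_subjects, seed = NULL,
                               expanded_range = c(36, 55),
                               sub17_ratio = 0.3, duration_shape = 4) {
  stopifnot(inherits(cal, "hd_calibration"), n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  co <- coef(cal$model)

  unexp_cag <- 10:35
  w <- 10^(co["intercept"] + co["slope"] * unexp_cag)
  lobe <- unexp_cag < 17
  w[lobe] <- w[unexp_cag == 17] * sub17_ratio^(17 - unexp_cag[lobe])
  a1 <- sample(unexp_cag, n_subjects, replace = TRUE, prob = w / sum(w))

  expanded_range <- check_cag_range(expanded_range)
  exp_cag <- expanded_range[1]:expanded_range[2]
  we <- 10^(co["intercept"] + co["slope"] * exp_cag)
  a2 <- sample(exp_cag, n_subjects, replace = TRUE, prob = we / sum(we))

  med <- cal$onset_curve(a2)
  onset_age <- stats::rlnorm(n_subjects, meanlog = log(med),
                             sdlog = cal$onset_sdlog)
  duration <- stats::rgamma(n_subjects, shape = duration_shape,
                            rate = duration_shape / cal$onset_to_death_years)
  ids <- sprintf("S%05d", seq_len(n_subjects))
  list(
    genotypes = data.frame(sample_id = ids, allele1 = a1, allele2 = a2),
    onset = data.frame(sample_id = ids, cag = a2, age_years = onset_age),
    death = data.frame(sample_id = ids, cag = a2,
                       age_years = onset_age + duration)
  )
}

#' Simulate a general-population cohort with carriers and diagnoses
#'
#' Emulates a volunteer biobank cohort: persons are assigned ages from an
#' age distribution; each person is an expanded-repeat carrier of CAG `c`
#' with probability `age_adjusted_frequency(c, age) * depletion`
#' (`depletion < 1` models healthy-volunteer bias, the under-enrolment of
#' carriers in volunteer cohorts); carriers are symptomatic with the
#' onset-CDF probability at their age; symptomatic carriers are diagnosed
#' with probability `diagnosis_p`.
#'
#' @param model A [decay_model()].
#' @param cs A [combined_survival()].
#' @param onset_models Named list of onset models covering `band`.
#' @param n Cohort size.
#' @param ages An [age_distribution()] (weights are sampling
#'   probabilities).
#' @param band CAG interval of simulated carrier alleles (default the
#'   survival band).
#' @param depletion Carrier-frequency multiplier in `[0, 1]`.
#' @param diagnosis_p Diagnosis probability for symptomatic carriers.
#' @param seed Integer seed.
#' @return A data frame with one row per person: `age`, `cag` (NA for
#'   non-carriers), `carrier`, `symptomatic`, `diagnosed`.
#' @export
simulate_population_cohort <- function(model, cs, onset_models, n, ages,
                                       band = NULL, depletion = 1,
                                       diagnosis_p = 1, seed = NULL) {
  stopifnot(inherits(ages, "age_distribution"))
  if (depletion < 0 || depletion > 1)
    stop("depletion must be in [0, 1]")
  if (diagnosis_p < 0 || diagnosis_p > 1)
    stop("diagnosis_p must be in [0, 1]")
  if (is.null(band)) band <- cs$band
  band <- check_cag_range(band)
  if (!is.null(seed)) set.seed(seed)
  age <- sample(ages$age, n, replace = TRUE,
                prob = ages$weight / sum(ages$weight))
  cags <- band[1]:band[2]
  # per-age carrier probabilities for each CAG in the band
  uage <- sort(unique(age))
  pmat <- vapply(cags, function(c)
    age_adjusted_frequency(model, cs, c, uage) * depletion,
    numeric(length(uage)))
  if (length(uage) == 1L) pmat <- matrix(pmat, nrow = 1L)
  idx <- match(age, uage)
  cag <- rep(NA_integer_, n)
  for (k in seq_along(cags)) {
    hit <- stats::runif(n) < pmat[idx, k]
    cag[hit & is.na(cag)] <- cags[k]
  }
  carrier <- !is.na(cag)
  symptomatic <- rep(FALSE, n)
  if (any(carrier)) {
    pc <- vapply(which(carrier), function(i)
      event_cdf(onset_models[[as.character(cag[i])]], age[i]), numeric(1))
    symptomatic[carrier] <- stats::runif(sum(carrier)) < pc
  }
  diagnosed <- symptomatic & stats::runif(n) < diagnosis_p
  data.frame(age = age, cag = cag, carrier = carrier,
             symptomatic = symptomatic, diagnosed = diagnosed)
}
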