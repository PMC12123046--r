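test_that("pyramid realisation spreads band weights uniformly", {
  pyr <- eu_pyramid_2020()
  ad <- realize_age_structure(pyr, 1e5, c(30, 79))
  expect_equal(sum(ad$weight), 1e5)
  # printed decade weights: 1409 / 6229 of the 30-79 population is 30-39
  expect_equal(sum(ad$weight[ad$age <= 39]),
               1409000 / 6229000 * 1e5, tolerance = 1e-9)
  # uniform within a band
  expect_equal(length(unique(round(ad$weight[ad$age <= 39], 9))), 1)

  single <- population_pyramid(30, 39, 1000)
  ad1 <- realize_age_structure(single, 500)
  expect_equal(ad1$weight, rep(50, 10))

  full <- realize_age_structure(pyr, 1e5)
  expect_equal(range(full$age), c(0, 104))
  # band totals proportional to the printed weights
  band_tot <- vapply(seq_len(nrow(pyr)), function(i)
    sum(full$weight[full$age >= pyr$age_lo[i] & full$age <= pyr$age_hi[i]]),
    numeric(1))
  expect_equal(band_tot / sum(band_tot),
               pyr$population / sum(pyr$population), tolerance = 1e-12)
  expect_error(realize_age_structure(pyr, 100, c(200, 210)), "intersect")
})

test_that("carrier census reproduces the reference 30-79 headline", {
  ad <- realize_age_structure(eu_pyramid_2020(), 1e5, c(30, 79))
  cen <- carrier_census(CAL$model, CAL$survival, CAL$onset_models, ad)
  expect_equal(cen$carriers, 64, tolerance = 0.15)
  expect_equal(cen$symptomatic, 22, tolerance = 0.20)
  expect_equal(cen$symptomatic + cen$asymptomatic, cen$carriers,
               tolerance = 1e-9)
})

test_that("census is additive over disjoint age ranges", {
  pyr <- eu_pyramid_2020()
  mk <- function(rng) {
    # fixed per-age person counts so disjoint ranges stack exactly
    ad <- realize_age_structure(pyr, 1, rng)
    age_distribution(ad$age, rep(100, length(ad$age)))
  }
  c1 <- carrier_census(CAL$model, CAL$survival, CAL$onset_models,
                       mk(c(30, 49)))
  c2 <- carrier_census(CAL$model, CAL$survival, CAL$onset_models,
                       mk(c(50, 79)))
  cu <- carrier_census(CAL$model, CAL$survival, CAL$onset_models,
                       mk(c(30, 79)))
  expect_equal(c1$carriers + c2$carriers, cu$carriers, tolerance = 1e-9)
  expect_equal(c1$symptomatic + c2$symptomatic, cu$symptomatic,
               tolerance = 1e-9)
})

test_that("never-onset models make every carrier asymptomatic", {
  ad <- realize_age_structure(eu_pyramid_2020(), 1e4, c(30, 79))
  never <- lapply(CAL$onset_models, function(m)
    lognormal_event_model(log(119), 0.01, cag = m$cag, kind = "onset"))
  cen <- carrier_census(CAL$model, CAL$survival, never, ad)
  expect_lt(cen$symptomatic, 1e-6 * cen$carriers)
  expect_equal(cen$asymptomatic, cen$carriers, tolerance = 1e-6)
  expect_error(carrier_census(CAL$model, CAL$survival,
                              CAL$onset_models[as.character(40:44)], ad),
               "45")
})

test_that("ascertainment rate follows the prevalence arithmetic", {
  ad <- realize_age_structure(eu_pyramid_2020(), 1e5, c(30, 79))
  cen <- carrier_census(CAL$model, CAL$survival, CAL$onset_models, ad)
  rep <- ascertainment_rate(cen, adjusted_prevalence = 11.6e-5)
  expect_equal(rep$ascertainment_rate,
               11.6e-5 * 1e5 / cen$symptomatic, tolerance = 1e-12)
  expect_equal(rep$ascertainment_rate, 0.527, tolerance = 0.02)
  # explicit band-share path
  rep2 <- ascertainment_rate(cen, adjusted_prevalence = NULL)
  expect_equal(rep2$prevalence_adjusted, 12.4e-5 * 0.9)
  expect_equal(ascertainment_rate(cen)$prevalence_adjusted, 11.6e-5)
  # doubling symptomatic halves the rate
  cen2 <- cen; cen2$symptomatic <- 2 * cen$symptomatic
  expect_equal(ascertainment_rate(cen2,
                                  adjusted_prevalence = 11.6e-5)$ascertainment_rate,
               rep$ascertainment_rate / 2)
  # scale invariance: population and counts scaled together
  cen3 <- cen
  cen3$n_population <- cen$n_population * 10
  cen3$carriers <- cen$carriers * 10
  cen3$symptomatic <- cen$symptomatic * 10
  cen3$asymptomatic <- cen$asymptomatic * 10
  expect_equal(ascertainment_rate(cen3,
                                  adjusted_prevalence = 11.6e-5)$ascertainment_rate,
               rep$ascertainment_rate, tolerance = 1e-12)
  # rate > 1 flags, does not clamp
  cen4 <- cen; cen4$symptomatic <- 1
  expect_warning(r4 <- ascertainment_rate(cen4,
                                          adjusted_prevalence = 11.6e-5),
                 "exceeds 1")
  expect_gt(r4$ascertainment_rate, 1)
})

test_that("observed ascertainment matches the diagnosed/symptomatic ratio", {
  # reference UK-Biobank-like arithmetic: 36 diagnosed of 84.3 expected
  om <- list("41" = lognormal_event_model(log(56.5), 0.2, 41, "onset"))
  carriers <- data.frame(cag = rep(41L, 100),
                         age = rep(c(60, 70), 50),
                         diagnosed = rep(c(TRUE, FALSE), c(36, 64)))
  got <- observed_ascertainment(carriers, om)
  expect_equal(got$n_diagnosed, 36)
  expect_equal(got$expected_symptomatic,
               50 * (event_cdf(om[["41"]], 60) + event_cdf(om[["41"]], 70)),
               tolerance = 1e-12)
  expect_equal(got$rate, 36 / got$expected_symptomatic)
  expect_equal(36 / 84.3, 0.427, tolerance = 1e-2)

  # all diagnosed, onset certain -> rate 1
  certain <- list("41" = lognormal_event_model(log(2), 0.05, 41, "onset"))
  all_d <- data.frame(cag = 41L, age = rep(110, 10), diagnosed = TRUE)
  expect_equal(observed_ascertainment(all_d, certain)$rate, 1,
               tolerance = 1e-6)
  expect_warning(
    observed_ascertainment(data.frame(cag = 41L, age = 30,
                                      diagnosed = TRUE), om),
    "> 1")
})

test_that("Bernoulli diagnosis thinning is recovered across seeds", {
  ad <- realize_age_structure(eu_pyramid_2020(), 1, c(40, 79))
  rates <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 2000
    cag <- sample(40:45, n, replace = TRUE)
    age <- sample(ad$age, n, replace = TRUE, prob = ad$weight)
    pc <- vapply(seq_len(n), function(i)
      event_cdf(CAL$onset_models[[as.character(cag[i])]], age[i]),
      numeric(1))
    symptomatic <- runif(n) < pc
    diagnosed <- symptomatic & runif(n) < 0.5
    observed_ascertainment(data.frame(cag, age, diagnosed),
                           CAL$onset_models)$rate
  }, numeric(1))
  # unbiased across the battery, each seed within sampling error
  expect_lt(abs(mean(rates) - 0.5), 0.05)
  expect_true(all(abs(rates - 0.5) < 0.15))
})
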