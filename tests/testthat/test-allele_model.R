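test_that("genotype tabulation partitions all chromosomes at the split", {
  g <- data.frame(allele1 = c(17, 17, 20), allele2 = c(17, 42, 44))
  tabs <- tabulate_alleles(g, split = 35)
  expect_equal(pool_size(tabs$unexpanded), 4)
  expect_equal(pool_size(tabs$expanded), 2)
  expect_equal(pool_size(tabs$unexpanded) + pool_size(tabs$expanded),
               2 * nrow(g))

  # cohort-shaped input: one unexpanded and one expanded allele per person
  n <- 750
  g2 <- data.frame(allele1 = rep(17:26, length.out = n),
                   allele2 = rep(40:44, length.out = n))
  tabs2 <- tabulate_alleles(g2)
  expect_equal(pool_size(tabs2$unexpanded), n)
  expect_equal(pool_size(tabs2$expanded), n)

  empty <- tabulate_alleles(data.frame(allele1 = numeric(0),
                                       allele2 = numeric(0)))
  expect_equal(pool_size(empty$unexpanded), 0)
  expect_equal(pool_size(empty$expanded), 0)

  bad <- data.frame(sample_id = c("a", "b"), allele1 = c(17, 17.5),
                    allele2 = c(42, 42))
  expect_error(tabulate_alleles(bad), "b")
})

test_that("log-linear fit recovers exact coefficients on noiseless counts", {
  # battery over several (intercept, slope) pairs
  for (co in list(c(5.552482, -0.13925), c(3, -0.2), c(1.5, -0.05))) {
    fit <- fit_decay(law_table(co[1], co[2], 18:35), c(18, 35))
    expect_equal(fit$slope, co[2], tolerance = 1e-9)
    expect_equal(fit$intercept, co[1], tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  # constant counts: slope 0, intercept log10(10) = 1
  flat <- fit_decay(allele_table(18:35, rep(10, 18)), c(18, 35))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 1, tolerance = 1e-12)
})

test_that("fit rejects zero bins and degenerate ranges", {
  at <- allele_table(c(18:20, 22:35), rep(5, 17))  # CAG 21 missing
  expect_error(fit_decay(at, c(18, 35)), "21")
  expect_error(fit_decay(law_table(3, -0.1, 18:19), c(18, 19)),
               "degenerate|3 informative")
})

test_that("multinomial sampling at cohort size recovers the slope", {
  co <- c(5.552482, -0.13925)
  cags <- 18:35
  p <- 10^(co[1] + co[2] * cags); p <- p / sum(p)
  set.seed(11)
  counts <- as.numeric(rmultinom(1, 7578, p))
  fit <- fit_decay(allele_table(cags, counts), c(18, 35))
  expect_lt(abs(fit$slope - co[2]), 0.01)
  # sampling error vanishes at large n
  counts_big <- as.numeric(rmultinom(1, 1e6, p))
  fit_big <- fit_decay(allele_table(cags, counts_big), c(18, 35))
  expect_lt(abs(fit_big$slope - co[2]), 0.005)
})

test_that("decay model construction enforces a decaying law", {
  fit <- decay_fit(5.552482, -0.13925)
  expect_s3_class(decay_model(fit, c(17, 55), 7578), "decay_model")
  expect_error(decay_model(decay_fit(1, 0.1), c(17, 55), 7578), "slope")
  expect_error(decay_model(fit, c(0, 55), 7578), "1-200")
  expect_error(decay_model(fit, c(17, 55), 0), "positive")
})

test_that("model evaluation matches the closed form and decays monotonically", {
  m <- ref_model()
  expect_equal(model_count(m, 42), 10^(5.552482 - 0.13925 * 42),
               tolerance = 1e-12)
  expect_equal(model_count(m, 42), 0.50578, tolerance = 1e-4)
  expect_equal(model_count(m, 17), 1531.9, tolerance = 1e-4)
  counts <- model_count(m, 17:55)
  expect_true(all(diff(counts) < 0))
  expect_equal(counts[-1] / counts[-length(counts)],
               rep(10^-0.13925, 38), tolerance = 1e-12)
  expect_error(model_count(m, 56), "outside")
  expect_error(model_count(m, 16), "outside")
})

test_that("allele frequency scales by the pool and doubles for carriers", {
  m <- ref_model()
  f42 <- allele_frequency(m, 42)
  expect_equal(f42, 6.674e-5, tolerance = 1e-3)
  expect_equal(100 * f42, 0.00667, tolerance = 1e-3)
  expect_equal(allele_frequency(m, 17), 0.2022, tolerance = 1e-3)
  m2 <- decay_model(m$fit, m$model_range, 2 * m$allele_pool)
  expect_equal(allele_frequency(m2, 17:55), allele_frequency(m, 17:55) / 2)
  expect_equal(predict(m, 42, type = "carrier"), 2 * f42)
})

test_that("band carrier frequency equals the brute-force per-CAG sum", {
  m <- ref_model()
  set.seed(42)
  for (i in 1:25) {
    b <- sort(sample(17:55, 2, replace = TRUE))
    got <- carrier_frequency_band(m, b)
    brute <- 2 * sum(vapply(b[1]:b[2], function(c) allele_frequency(m, c),
                            numeric(1)))
    expect_equal(got$fraction, brute, tolerance = 1e-12)
    expect_equal(got$one_in, floor(1 / brute))
  }
  single <- carrier_frequency_band(m, c(42, 42))
  expect_equal(single$fraction, 2 * allele_frequency(m, 42))
  expect_error(carrier_frequency_band(m, c(50, 60)), "outside")
})

test_that("penetrance-band reciprocals reproduce the reference magnitudes", {
  m <- ref_model()
  expect_equal(carrier_frequency_band(m, c(36, 39))$fraction, 2.408e-3,
               tolerance = 1e-3)
  expect_equal(carrier_frequency_band(m, c(36, 39))$one_in, 415)
  expect_equal(1 / carrier_frequency_band(m, c(27, 35))$fraction, 17.7,
               tolerance = 0.01)
})

test_that("prevalence anchor arithmetic is exact", {
  a <- prevalence_anchor(12.4e-5)
  expect_equal(a$one_in_n, 8064)
  expect_equal(required_population_size(7578, a), 61108992)
  expect_equal(required_population_size(1, a), 8064)
  expect_error(prevalence_anchor(0), "fraction")
  expect_error(prevalence_anchor(1.5), "fraction")
})

test_that("prevalence-anchored distribution conserves totals and is seeded", {
  unexp <- law_table(5.552482, -0.13925, 17:35)
  expd <- allele_table(36:55, round(10^(5.552482 - 0.13925 * (36:55))) + 1)
  # rescale unexpanded to integer counts totalling 7578
  p <- unexp$count / pool_size(unexp)
  unexp <- allele_table(unexp$cag, as.numeric(rmultinom(1, 7578, p)))
  expd_n <- pool_size(expd)
  anchor <- prevalence_anchor(12.4e-5)
  target <- 2 * required_population_size(expd_n, anchor) - expd_n

  out <- prevalence_anchored_distribution(expd, unexp, anchor, "expected")
  expect_equal(sum(out$count[out$cag <= 35]), target)
  expect_equal(out$count[out$cag >= 36], expd$count)

  s1 <- prevalence_anchored_distribution(expd, unexp, anchor, "sampled",
                                         seed = 7)
  s2 <- prevalence_anchored_distribution(expd, unexp, anchor, "sampled",
                                         seed = 7)
  expect_identical(s1, s2)
  expect_equal(sum(s1$count[s1$cag <= 35]), target)
})

test_that("sampled spectra converge to the expected spectrum", {
  unexp <- allele_table(18:25, round(1000 * 0.7^(0:7)) + 10)
  expd <- allele_table(40, 5)
  # anchor chosen so the bootstrapped pool is about a million alleles
  anchor <- prevalence_anchor(1e-5)
  e <- prevalence_anchored_distribution(expd, unexp, anchor, "expected")
  s <- prevalence_anchored_distribution(expd, unexp, anchor, "sampled",
                                        seed = 1)
  keep <- e$cag <= 35
  chi <- sum((s$count[keep] - e$count[keep])^2 / e$count[keep])
  p <- pchisq(chi, sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("reference distribution families are fitted by maximum likelihood", {
  set.seed(5)
  x <- rnorm(1e5, 18.41, 3.28)
  rep <- fit_reference_distributions(x)
  expect_named(rep, c("normal", "poisson", "nbinom", "cauchy", "gamma",
                      "lnorm", "logistic", "weibull"))
  expect_equal(unname(rep$normal$estimate["mean"]), 18.41, tolerance = 0.05 / 18)
  expect_equal(unname(rep$normal$estimate["sd"]), 3.28, tolerance = 0.05 / 3)
  # Poisson MLE is the sample mean, exactly
  xi <- rpois(5000, 18.411)
  repp <- fit_reference_distributions(xi)
  expect_equal(unname(repp$poisson$estimate["lambda"]), mean(xi),
               tolerance = 1e-6)
  # gamma moment identity: shape/rate ~ sample mean
  g <- rep$gamma$estimate
  expect_equal(unname(g["shape"] / g["rate"]), mean(x), tolerance = 0.01)
  expect_true(all(vapply(rep, function(f) f$ok, logical(1))))
  expect_error(fit_reference_distributions(rnorm(10)), "30")
})

test_that("allele tables round-trip through TSV", {
  at <- allele_table(17:20, c(120, 90, 60, 40))
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_allele_table(at, f)
  expect_equal(read_allele_table(f), at, ignore_attr = TRUE)
})
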