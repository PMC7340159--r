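test_that("population score and analytic scale follow their closed forms", {
  panel <- make_panel(c(0.2, -0.4, 1), c(0.5, 0.25, 0.5))
  expect_equal(population_score(panel, "EUR"), c(0.2, -0.2, 1))
  one <- make_panel(1, 0.5)
  expect_equal(population_sd(one, "EUR"), sqrt(0.5), tolerance = 1e-12)
  null_panel <- make_panel(c(0, 0), c(0.3, 0.4))
  expect_error(population_sd(null_panel, "EUR"),
               class = "dtcprs_zero_variance_panel")
  expect_error(population_score(panel, "XXX"),
               class = "dtcprs_unknown_population")
})

test_that("analytic scale matches the SD of the exhaustive HWE genotype distribution", {
  # 3 SNPs: enumerate all 27 genotype combinations with HWE probabilities
  betas <- c(0.5, -0.3, 0.8)
  freqs <- c(0.2, 0.5, 0.7)
  panel <- make_panel(betas, freqs)
  combos <- expand.grid(g1 = 0:2, g2 = 0:2, g3 = 0:2)
  probs <- apply(combos, 1, function(g) {
    prod(stats::dbinom(g, 2, freqs))
  })
  scores <- apply(combos, 1, function(g) sum(betas * (g - 2 * freqs)))
  exact_sd <- sqrt(sum(probs * scores^2) - sum(probs * scores)^2)
  expect_equal(population_sd(panel, "EUR"), exact_sd, tolerance = 1e-12)
})

test_that("zero-centered score sums per-SNP centered terms", {
  # 5-SNP hand-built case, verified term by term
  betas <- c(0.2, -0.1, 0.4, 0.05, -0.3)
  freqs <- c(0.1, 0.5, 0.9, 0.25, 0.6)
  dosages <- c(1, 2, 0, 2, 1)
  panel <- make_panel(betas, freqs)
  manual <- sum(betas * dosages - 2 * freqs * betas)
  expect_equal(zero_centered_score(dosages, panel, "EUR"), manual,
               tolerance = 1e-14)
  # exact centering: dosage == 2f gives exactly zero
  expect_identical(zero_centered_score(2 * freqs, panel, "EUR"), 0)
  # one SNP: dosage 2, f = 0.5, beta = 1 -> 2 - 1 = 1
  expect_equal(zero_centered_score(2, make_panel(1, 0.5), "EUR"), 1)
  # all-missing profile warns and returns an uninformative zero
  expect_warning(z0 <- zero_centered_score(c(NA, NA, NA, NA, NA), panel, "EUR"),
                 class = "dtcprs_empty_overlap")
  expect_identical(as.numeric(z0), 0)
})

test_that("z-score is the plain ratio with no truncation", {
  expect_identical(z_score(0, 2.5), 0)
  expect_identical(z_score(1, 1), 1)
  expect_identical(z_score(0.35, 0.7), 0.5)
  expect_error(z_score(1, 0), class = "dtcprs_zero_variance_panel")
})

test_that("empirical normalization matches the analytic scaling on a matched cohort", {
  expect_error(empirical_normalize(1, rnorm(10)),
               class = "dtcprs_insufficient_reference")
  expect_error(empirical_normalize(1, rep(2, 50)),
               class = "dtcprs_insufficient_reference")
  ref <- c(1, 2, 3, rep(2, 30))
  expect_identical(empirical_normalize(mean(ref), ref), 0)
  panel <- simulate_weights(150, seed = 31)
  cohort <- simulate_cohort(panel, 1000, 0.5, 0.3, seed = 32)
  scores <- cohort$genetic_value
  z_emp <- empirical_normalize(scores[1], scores[-1])
  z_ana <- z_score(scores[1], population_sd(panel, "EUR"))
  expect_lt(abs(z_emp - z_ana), 3 / sqrt(999))
})

test_that("score_profile composes the pipeline with full coverage accounting", {
  betas <- c(0.2, -0.1, 0.4, 0.05, -0.3)
  freqs <- c(0.1, 0.5, 0.9, 0.25, 0.6)
  panel <- make_panel(betas, freqs)
  sites <- make_sites(panel)
  dosages <- c(1, 2, 0, 2, 1)
  prof <- make_profile(calls_from_dosages(dosages, panel, sites))
  res <- score_profile(prof, panel, sites, "EUR")
  manual_zc <- sum(betas * dosages - 2 * freqs * betas)
  manual_z <- manual_zc / sqrt(sum(betas^2 * 2 * freqs * (1 - freqs)))
  expect_equal(res$zero_centered, manual_zc, tolerance = 1e-14)
  expect_equal(res$z_score, manual_z, tolerance = 1e-14)
  expect_equal(res$raw_sum, sum(betas * dosages), tolerance = 1e-14)
  expect_identical(res$n_used + res$n_frequency_filled + res$n_missing, 5L)
  expect_identical(res$n_used, 5L)
  # determinism: scoring twice is bit-identical
  expect_identical(res, score_profile(prof, panel, sites, "EUR"))
  # all-missing profile under frequency fill: z = 0, everything filled
  empty <- prof
  empty$calls <- empty$calls[0, ]
  empty$aligned <- NULL
  res0 <- suppressWarnings(
    score_profile(empty, panel, sites, "EUR", missing_policy = "frequency_fill"))
  expect_identical(res0$z_score, 0)
  expect_identical(res0$n_frequency_filled, 5L)
})

test_that("frequency fill and skip give the same centered score, exactly", {
  set.seed(61)
  panel <- simulate_weights(80, seed = 61)
  sites <- simulate_sites(panel)
  cohort <- simulate_cohort(panel, 1, 0.4, 0.3, seed = 62)
  prof <- cohort_profile(cohort, 1, sites)
  prof$calls <- prof$calls[-sample(80, 35), ]  # drop 35 SNPs
  skip <- score_profile(prof, panel, sites, "EUR", missing_policy = "skip")
  fill <- score_profile(prof, panel, sites, "EUR", missing_policy = "frequency_fill")
  expect_identical(skip$zero_centered, fill$zero_centered)
  expect_identical(skip$z_score, fill$z_score)
})

test_that("disjoint panels add in score and in variance", {
  set.seed(71)
  betas <- runif(20, -0.5, 0.5)
  freqs <- runif(20, 0.1, 0.9)
  dosages <- rbinom(20, 2, freqs)
  pa <- make_panel(betas[1:10], freqs[1:10])
  pb <- make_panel(betas[11:20], freqs[11:20])
  pab <- make_panel(betas, freqs)
  za <- zero_centered_score(dosages[1:10], pa, "EUR")
  zb <- zero_centered_score(dosages[11:20], pb, "EUR")
  zab <- zero_centered_score(dosages, pab, "EUR")
  expect_equal(zab, za + zb, tolerance = 1e-12)
  expect_equal(population_sd(pab, "EUR")^2,
               population_sd(pa, "EUR")^2 + population_sd(pb, "EUR")^2,
               tolerance = 1e-12)
})

test_that("raising a positive-beta dosage never lowers the z-score", {
  set.seed(81)
  panel <- simulate_weights(30, seed = 81)
  pos_snps <- which(panel$weights$beta > 0)
  d <- rbinom(30, 2, panel$weights$freq_EUR)
  base <- z_score(zero_centered_score(d, panel, "EUR"),
                  population_sd(panel, "EUR"))
  for (j in pos_snps[d[pos_snps] < 2][1:min(5, sum(d[pos_snps] < 2))]) {
    d2 <- d
    d2[j] <- d2[j] + 1
    bumped <- z_score(zero_centered_score(d2, panel, "EUR"),
                      population_sd(panel, "EUR"))
    expect_gte(bumped, base)
  }
})

test_that("carrier reports apply the magnitude filter and count risk alleles", {
  panel <- make_panel(rep(0.1, 4), rep(0.5, 4))
  sites <- make_sites(panel)
  prof <- make_profile(calls_from_dosages(c(0, 0, 1, 0), panel, sites))
  rv <- data.frame(rsid = panel$weights$rsid,
                   risk_allele = panel$weights$effect_allele,
                   magnitude = c(2.0, 1.2, 2.5, 0.3))
  rep1 <- carrier_report(prof, rv, magnitude_min = 1.5)
  expect_true(rep1$carrier)
  expect_identical(nrow(rep1$hits), 1L)
  expect_identical(rep1$hits$rsid, "rs3")
  expect_identical(rep1$n_considered, 2L)  # magnitudes 1.2 and 0.3 excluded
  # homozygous non-risk everywhere -> not a carrier
  prof0 <- make_profile(calls_from_dosages(c(0, 0, 0, 0), panel, sites))
  expect_false(carrier_report(prof0, rv)$carrier)
  # missing genotype counts as non-carrier for that variant
  profm <- make_profile(calls_from_dosages(c(0, 0, NA, 0), panel, sites))
  expect_false(carrier_report(profm, rv)$carrier)
})
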