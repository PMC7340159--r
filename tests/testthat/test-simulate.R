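test_that("simulated panels are reproducible and honour their parameters", {
  p1 <- simulate_weights(100, seed = 201)
  p2 <- simulate_weights(100, seed = 201)
  expect_identical(p1, p2)
  expect_identical(nrow(p1$weights), 100L)
  expect_true(all(p1$weights$freq_EUR >= 0.05 & p1$weights$freq_EUR <= 0.95))
  # no strand-ambiguous allele pairs are ever generated
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_false(any(comp[p1$weights$effect_allele] == p1$weights$other_allele))
  null_p <- simulate_weights(50, beta_sd = 0, seed = 202)
  expect_true(all(null_p$weights$beta == 0))
  expect_error(simulate_weights(10), class = "dtcprs_bad_input")  # seed mandatory
  div <- simulate_weights(50, fst = 0.1, seed = 203)
  expect_false(all(div$weights$freq_AFR == div$weights$freq_EUR))
})

test_that("cohorts realize the liability-threshold model", {
  panel <- simulate_weights(200, seed = 211)
  cohort <- simulate_cohort(panel, 5000, 0.5, 0.3, seed = 212)
  expect_identical(cohort,
                   simulate_cohort(panel, 5000, 0.5, 0.3, seed = 212))
  # prevalence recovered within 3 binomial SDs
  expect_lt(abs(mean(cohort$phenotype) - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
  # dosage column means track 2f
  expect_lt(max(abs(colMeans(cohort$dosages) - 2 * panel$weights$freq_EUR)),
            0.12)
  # liability regression on standardized G recovers h2
  fit <- stats::lm(cohort$liability ~ scale(cohort$genetic_value))
  expect_lt(abs(summary(fit)$r.squared - 0.5), 0.05)
  # h2 = 0 gives chance-level prediction
  null_cohort <- simulate_cohort(panel, 3000, 0, 0.3, seed = 213)
  expect_lt(abs(auc(null_cohort$genetic_value, null_cohort$phenotype) - 0.5),
            0.04)
  # phenotype is exactly the thresholded liability
  expect_identical(cohort$phenotype,
                   as.integer(cohort$liability > stats::qnorm(0.7)))
})

test_that("vendor masks subset cohorts and mixed draws follow their proportions", {
  panel <- simulate_weights(100, seed = 221)
  cohort <- simulate_cohort(panel, 50, 0.4, 0.3, seed = 222)
  rsids <- panel$weights$rsid
  full_mask <- vendor_mask("all", rsids)
  expect_identical(apply_vendor_mask(cohort, full_mask)$dosages,
                   cohort$dosages)
  half <- vendor_mask("half", rsids[1:50])
  masked <- apply_vendor_mask(cohort, half)
  expect_identical(unname(rowSums(!is.na(masked$dosages))), rep(50, 50))
  expect_error(vendor_mask("none", character()), class = "dtcprs_empty_mask")

  masks <- make_vendor_masks(panel, coverage = 0.5, seed = 223)
  expect_length(masks, 3L)
  expect_true(all(vapply(masks, function(m) length(m$snps), integer(1)) == 50L))

  a1 <- draw_mixed_masks(masks, c(0.55, 0.30, 0.15), 10000, seed = 224)
  a2 <- draw_mixed_masks(masks, c(0.55, 0.30, 0.15), 10000, seed = 224)
  expect_identical(a1, a2)
  shares <- tabulate(a1, 3) / 10000
  for (j in 1:3) {
    target <- c(0.55, 0.30, 0.15)[j]
    expect_lt(abs(shares[j] - target), 3 * sqrt(target * (1 - target) / 10000))
  }
  expect_identical(unique(sort(draw_mixed_masks(masks, c(1, 0, 0), 100,
                                                seed = 225))), 1L)
  expect_error(draw_mixed_masks(masks, c(0.5, 0.5), 10, seed = 1),
               class = "dtcprs_bad_input")
})

test_that("degenerate full-coverage masks make all experiment conditions identical", {
  panel <- simulate_weights(60, seed = 231)
  cohort <- simulate_cohort(panel, 400, 0.4, 0.3, seed = 232)
  masks <- lapply(c("a", "b", "c"),
                  function(v) vendor_mask(v, panel$weights$rsid))
  tab <- run_snpset_experiment(cohort, panel, masks = masks, n_draws = 5,
                               seed = 233)
  expect_equal(stats::sd(tab$auc_mean), 0, tolerance = 1e-12)
  expect_equal(stats::sd(tab$r2_mean), 0, tolerance = 1e-12)
  expect_identical(tab$auc_sd[tab$condition == "MIXED"], 0)
})

test_that("a null cohort shows chance-level prediction in every condition", {
  panel <- simulate_weights(100, seed = 241)
  cohort <- simulate_cohort(panel, 1500, 0, 0.3, seed = 242)
  tab <- run_snpset_experiment(cohort, panel, coverage = 0.5, n_draws = 20,
                               seed = 243)
  expect_true(all(abs(tab$auc_mean - 0.5) < 0.06))
})

test_that("full-data AUC rises monotonically with heritability", {
  aucs <- vapply(c(0, 0.2, 0.5, 0.8), function(h2) {
    panel <- simulate_weights(150, seed = 251)
    cohort <- simulate_cohort(panel, 2000, h2, 0.3, seed = 252)
    auc(cohort$genetic_value, cohort$phenotype)
  }, numeric(1))
  expect_identical(order(aucs), 1:4)
})

test_that("experiment output is reproducible and structurally complete", {
  panel <- simulate_weights(80, seed = 261)
  cohort <- simulate_cohort(panel, 500, 0.4, 0.3, seed = 262)
  t1 <- run_snpset_experiment(cohort, panel, coverage = 0.5, n_draws = 10,
                              seed = 263)
  t2 <- run_snpset_experiment(cohort, panel, coverage = 0.5, n_draws = 10,
                              seed = 263)
  expect_identical(t1, t2)
  expect_identical(t1$condition, c("FULL", "UNIFORM", "UNIFORM", "UNIFORM", "MIXED"))
  expect_identical(t1$vendor[2:4], c("23andme", "ancestry", "myheritage"))
  expect_false(is.null(attr(t1, "uniform_summary")))
})

test_that("cross-vendor reproducibility is perfect at full coverage, partial below", {
  panel <- simulate_weights(300, seed = 271)
  cohort <- simulate_cohort(panel, 500, 0.4, 0.3, seed = 272)
  expect_identical(cross_vendor_reproducibility(cohort, panel, coverage = 1,
                                                seed = 273)$r, 1)
  r8 <- cross_vendor_reproducibility(cohort, panel, coverage = 0.8, seed = 273)$r
  expect_gt(r8, 0.7)
  expect_lt(r8, 1)
  # at half coverage the correlation tracks the shared fraction (~coverage),
  # with slack for the beta-weighted sampling noise of the realized masks
  r5 <- cross_vendor_reproducibility(cohort, panel, coverage = 0.5, seed = 273)$r
  expect_gt(r5, 0.25)
  expect_lt(r5, 0.75)
  expect_lt(r5, r8)
})

test_that("carrier status does not separate cases from controls even when the PRS does", {
  panel <- simulate_weights(120, beta_sd = 0.12, seed = 281)
  sites <- simulate_sites(panel)
  cohort <- simulate_cohort(panel, 400, 0.5, 0.3, seed = 282)
  # risk variants: the ten largest positive effects, all common alleles
  top <- order(panel$weights$beta, decreasing = TRUE)[1:10]
  rv <- data.frame(rsid = panel$weights$rsid[top],
                   risk_allele = panel$weights$effect_allele[top],
                   magnitude = 2)
  carriers <- vapply(seq_len(400), function(i) {
    carrier_report(cohort_profile(cohort, i, sites), rv)$carrier
  }, logical(1))
  y <- cohort$phenotype
  k1 <- sum(carriers[y == 1]); n1 <- sum(y == 1)
  k0 <- sum(carriers[y == 0]); n0 <- sum(y == 0)
  p <- two_proportion_test(k1, n1, k0, n0)$p.value
  prs_auc <- auc(cohort$genetic_value / population_sd(panel, "EUR"), y)
  expect_gt(p, 0.05)
  expect_gt(prs_auc, 0.6)
})
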