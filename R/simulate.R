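# Synthetic-data engine: weight panels, Hardy-Weinberg / linkage-equilibrium
# cohorts with liability-threshold phenotypes, vendor SNP-set masks, and the
# uniform-vs-mixed vendor experiment driver.

#' Simulate a weight panel
#'
#' SNP frequencies are drawn uniformly on `freq_range` and betas from
#' `Normal(0, beta_sd^2)`. By default the same frequencies are copied to all
#' five super-populations; with `fst > 0` per-population frequencies are
#' drawn from the Balding-Nichols beta model around the shared ancestral
#' frequency, giving divergent populations for ancestry tests. Allele pairs
#' are sampled from the strand-unambiguous classes only, so every simulated
#' SNP is alignable.
#'
#' @param n_snps Number of SNPs (>= 1).
#' @param beta_sd Standard deviation of the effect sizes (0 gives a null
#'   panel).
#' @param freq_range Range of the ancestral allele-frequency sampler
#'   (default `c(0.05, 0.95)`, the common-variant regime a chip measures
#'   well).
#' @param fst Balding-Nichols divergence between populations (default 0:
#'   identical frequencies everywhere).
#' @param seed Mandatory integer seed.
#' @param trait_id Trait identifier (default `"synthetic_trait"`).
#' @param mode Panel mode label.
#' @return A `weight_panel`.
#' @export
simulate_weights <- function(n_snps, beta_sd = 0.1, freq_range = c(0.05, 0.95),
                             fst = 0, seed, trait_id = "synthetic_trait",
                             mode = "TOP_SNP") {
  if (missing(seed)) dtc_error("dtcprs_bad_input", "seed is mandatory")
  if (n_snps < 1L) dtc_error("dtcprs_bad_input", "n_snps must be >= 1")
  with_seed(seed, {
    f0 <- stats::runif(n_snps, freq_range[1], freq_range[2])
    beta <- if (beta_sd > 0) stats::rnorm(n_snps, 0, beta_sd) else rep(0, n_snps)
    # Unambiguous allele pairs only (no A/T, no C/G).
    pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(length(pairs), n_snps, replace = TRUE)
    eff <- vapply(pairs[pick], `[`, character(1), 1L)
    oth <- vapply(pairs[pick], `[`, character(1), 2L)
    weights <- data.frame(
      rsid = sprintf("rs%07d", seq_len(n_snps)),
      effect_allele = eff,
      other_allele = oth,
      beta = beta,
      stringsAsFactors = FALSE
    )
    for (pop in super_populations()) {
      fp <- if (fst > 0) {
        shape1 <- f0 * (1 - fst) / fst
        shape2 <- (1 - f0) * (1 - fst) / fst
        pmin(pmax(stats::rbeta(n_snps, shape1, shape2), 0.001), 0.999)
      } else {
        f0
      }
      weights[[freq_col(pop)]] <- fp
    }
    weight_panel(trait_id, weights, mode = mode,
                 provenance = sprintf("simulated (beta_sd=%g, fst=%g, seed=%d)",
                                      beta_sd, fst, seed))
  })
}

#' Derive a reference site table from a weight panel
#'
#' Deterministic companion sites for a simulated panel: ref is the other
#' allele, alt is the effect allele (so the panel frequencies are the alt
#' frequencies), and coordinates cycle over the 22 autosomes on GRCh37-style
#' 1-based positions.
#'
#' @param panel A `weight_panel`.
#' @return A reference site data frame compatible with [read_sites()].
#' @export
simulate_sites <- function(panel) {
  w <- panel$weights
  n <- nrow(w)
  sites <- data.frame(
    rsid = w$rsid,
    chromosome = as.character(rep_len(1:22, n)),
    position = 10000L + 1000L * seq_len(n),
    ref = w$other_allele,
    alt = w$effect_allele,
    stringsAsFactors = FALSE
  )
  for (pop in super_populations()) {
    sites[[freq_col(pop)]] <- w[[freq_col(pop)]]
  }
  sites
}

#' Simulate a genotype cohort with a liability-threshold phenotype
#'
#' Dosages are drawn as `Binomial(2, f)` independently per SNP (linkage
#' equilibrium), with `f` taken from the panel's frequencies for the chosen
#' population. The genetic value `G` is the zero-centered score; the latent
#' liability is `a G + e` with `e ~ Normal(0, 1 - h2)` and `a` chosen so the
#' genetic part contributes exactly `h2` of the liability variance (using
#' the analytic population scale). Disease status is `liability >
#' qnorm(1 - prevalence)`.
#'
#' @param panel A `weight_panel`.
#' @param n_individuals Cohort size.
#' @param h2 Liability-scale SNP heritability in `[0, 1]`.
#' @param prevalence Disease prevalence `K` in `(0, 1)`.
#' @param population Super-population whose frequencies generate the cohort.
#' @param seed Mandatory integer seed.
#' @return A `synthetic_cohort`: dosage matrix (individuals x SNPs, columns
#'   named by rsid), `genetic_value`, `liability`, binary `phenotype`,
#'   labels and generation parameters.
#' @export
simulate_cohort <- function(panel, n_individuals, h2, prevalence,
                            population = "EUR", seed) {
  if (missing(seed)) dtc_error("dtcprs_bad_input", "seed is mandatory")
  check_population(population)
  if (h2 < 0 || h2 > 1) dtc_error("dtcprs_bad_input", "h2 must lie in [0, 1]")
  if (prevalence <= 0 || prevalence >= 1) {
    dtc_error("dtcprs_bad_input", "prevalence must lie in (0, 1)")
  }
  w <- panel$weights
  m <- nrow(w)
  f <- w[[freq_col(population)]]
  with_seed(seed, {
    dosages <- matrix(stats::rbinom(n_individuals * m, 2L, rep(f, each = n_individuals)),
                      nrow = n_individuals, ncol = m,
                      dimnames = list(NULL, w$rsid))
    g <- drop(dosages %*% w$beta) - sum(population_score(panel, population))
    a <- 0
    if (h2 > 0) {
      sd_g <- population_sd(panel, population)  # errors on zero-variance panels
      a <- sqrt(h2) / sd_g
    }
    e <- stats::rnorm(n_individuals, 0, sqrt(1 - h2))
    liability <- a * g + e
    threshold <- stats::qnorm(1 - prevalence)
    structure(
      list(dosages = dosages,
           genetic_value = g,
           liability = liability,
           phenotype = as.integer(liability > threshold),
           population = population,
           trait_id = panel$trait_id,
           h2 = h2,
           prevalence = prevalence,
           seed = seed),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d individuals x %d SNPs [%s], h2 = %g, K = %g, %d cases\n",
              nrow(x$dosages), ncol(x$dosages), x$population, x$h2,
              x$prevalence, sum(x$phenotype)))
  invisible(x)
}

#' Construct a vendor SNP mask
#'
#' @param vendor Vendor name.
#' @param snps Character vector of included SNP ids.
#' @return A `vendor_mask`.
#' @export
vendor_mask <- function(vendor, snps) {
  if (length(snps) == 0L) {
    dtc_error("dtcprs_empty_mask", "a vendor mask must include at least one SNP")
  }
  structure(list(vendor = vendor, snps = unique(snps)), class = "vendor_mask")
}

#' Random vendor masks over a panel
#'
#' Each vendor receives an independent random subset covering `coverage` of
#' the panel SNPs — a stand-in for real chip manifests, which differ between
#' vendors and are not published alongside scoring SNP sets.
#'
#' @param panel A `weight_panel`.
#' @param vendors Vendor names (default the three major DTC vendors).
#' @param coverage Fraction of panel SNPs each vendor genotypes.
#' @param seed Mandatory integer seed.
#' @return List of `vendor_mask` objects.
#' @export
make_vendor_masks <- function(panel, vendors = c("23andme", "ancestry", "myheritage"),
                              coverage = 0.5, seed) {
  if (missing(seed)) dtc_error("dtcprs_bad_input", "seed is mandatory")
  rsids <- panel$weights$rsid
  k <- max(1L, round(coverage * length(rsids)))
  with_seed(seed, {
    lapply(vendors, function(v) vendor_mask(v, sample(rsids, k)))
  })
}

#' Mask a cohort to one vendor's SNP set
#'
#' Uniform setting: every individual keeps exactly the mask's SNPs; all
#' other dosages become missing.
#'
#' @param cohort A `synthetic_cohort`.
#' @param mask A `vendor_mask` whose SNPs are a subset of the cohort's.
#' @return The masked cohort (off-mask dosages `NA`), tagged with the vendor.
#' @export
apply_vendor_mask <- function(cohort, mask) {
  if (!inherits(mask, "vendor_mask")) {
    dtc_error("dtcprs_bad_input", "mask must be a vendor_mask")
  }
  snps <- colnames(cohort$dosages)
  if (!all(mask$snps %in% snps)) {
    dtc_error("dtcprs_bad_input", "mask SNP ids must be a subset of the cohort's panel")
  }
  cohort$dosages[, !(snps %in% mask$snps)] <- NA_integer_
  cohort$vendor <- mask$vendor
  cohort
}

#' Draw per-individual vendor assignments
#'
#' Each individual is independently assigned one of the vendors with the
#' given probabilities, emulating the observed vendor mix of online uploads
#' (default 55/30/15).
#'
#' @param masks List of `vendor_mask` objects.
#' @param proportions Mixing proportions, summing to 1.
#' @param n_individuals Number of individuals.
#' @param seed Mandatory integer seed.
#' @return Integer vector of mask indices with the vendor names as an
#'   attribute.
#' @export
draw_mixed_masks <- function(masks, proportions = c(0.55, 0.30, 0.15),
                             n_individuals, seed) {
  if (missing(seed)) dtc_error("dtcprs_bad_input", "seed is mandatory")
  if (length(proportions) != length(masks)) {
    dtc_error("dtcprs_bad_input", "one proportion per mask is required")
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    dtc_error("dtcprs_bad_input", "proportions must sum to 1")
  }
  with_seed(seed, {
    assignment <- sample.int(length(masks), n_individuals, replace = TRUE,
                             prob = proportions)
    structure(assignment,
              vendors = vapply(masks, function(m) m$vendor, character(1)))
  })
}

# Naive fixed-reference scores: sum of beta * dosage over the attained SNPs
# minus the FULL panel population score, divided by the full-panel SD. This
# is what an external scorer produces when raw vendor data is pushed through
# a model expecting the complete SNP set: neither the centering constant nor
# the scale is renormalized to the attained SNPs, so vendor-specific SNP
# sets acquire vendor-specific mean offsets.
naive_masked_scores <- function(cohort, panel, mask_snps = NULL, population) {
  w <- panel$weights
  b <- w$beta
  if (!is.null(mask_snps)) {
    b[!(w$rsid %in% mask_snps)] <- 0
  }
  center <- sum(population_score(panel, population))
  sd_full <- population_sd(panel, population)
  (drop(cohort$dosages %*% b) - center) / sd_full
}

#' Uniform-vs-mixed vendor SNP-set experiment
#'
#' Quantifies what happens when a polygenic score trained for a prespecified
#' SNP set is applied to un-imputed vendor data. Three conditions are
#' evaluated against the cohort's phenotype with Nagelkerke R2 and AUC:
#'
#' * `FULL` — complete dosages (the imputed/complete-data condition);
#' * `UNIFORM` — every individual restricted to one vendor's SNP set,
#'   evaluated once per vendor (reported per vendor, and summarized as
#'   mean and SD over the vendors);
#' * `MIXED` — each individual assigned a vendor with the given mixing
#'   proportions, redrawn `n_draws` times (reported as mean and SD over
#'   draws).
#'
#' Masked conditions use the naive fixed-reference scorer: missing SNPs
#' contribute nothing to the weighted sum while the centering constant and
#' scale remain those of the complete panel. Under a uniform SNP set this is
#' a constant shift with no effect on ranking; under mixed SNP sets each
#' vendor's score acquires a different offset, which is the precise
#' mechanism that destroys cross-vendor ranking.
#'
#' @param cohort A `synthetic_cohort` with complete dosages.
#' @param panel The generating `weight_panel`.
#' @param masks Optional list of three `vendor_mask`s; generated with
#'   [make_vendor_masks()] at `coverage` when omitted.
#' @param coverage Vendor coverage used when generating masks.
#' @param n_draws Number of mixed-assignment redraws (default 100).
#' @param proportions Vendor mixing proportions (default 55/30/15).
#' @param seed Mandatory integer seed.
#' @return A `snpset_experiment` data frame with one row for `FULL`, one per
#'   uniform vendor, and one for `MIXED` (columns `condition`, `vendor`,
#'   `r2_mean`, `r2_sd`, `auc_mean`, `auc_sd`, `n_draws`), with the
#'   across-vendor uniform summary attached as attribute `uniform_summary`.
#' @export
run_snpset_experiment <- function(cohort, panel, masks = NULL, coverage = 0.5,
                                  n_draws = 100L,
                                  proportions = c(0.55, 0.30, 0.15), seed) {
  if (missing(seed)) dtc_error("dtcprs_bad_input", "seed is mandatory")
  pop <- cohort$population
  n <- nrow(cohort$dosages)
  with_seed(seed, {
    if (is.null(masks)) {
      rsids <- panel$weights$rsid
      k <- max(1L, round(coverage * length(rsids)))
      masks <- lapply(c("23andme", "ancestry", "myheritage"),
                      function(v) vendor_mask(v, sample(rsids, k)))
    }
    s_full <- naive_masked_scores(cohort, panel, NULL, pop)
    s_vendor <- vapply(masks, function(m) {
      naive_masked_scores(cohort, panel, m$snps, pop)
    }, numeric(n))

    ev <- function(s) {
      c(r2 = nagelkerke_r2(s, cohort$phenotype),
        auc = auc(s, cohort$phenotype))
    }
    full <- ev(s_full)
    uniform <- t(vapply(seq_along(masks), function(j) ev(s_vendor[, j]),
                        numeric(2)))
    mixed <- t(vapply(seq_len(n_draws), function(d) {
      assignment <- sample.int(length(masks), n, replace = TRUE,
                               prob = proportions)
      ev(s_vendor[cbind(seq_len(n), assignment)])
    }, numeric(2)))

    out <- data.frame(
      condition = c("FULL", rep("UNIFORM", length(masks)), "MIXED"),
      vendor = c(NA_character_,
                 vapply(masks, function(m) m$vendor, character(1)),
                 NA_character_),
      r2_mean = c(full["r2"], uniform[, "r2"], mean(mixed[, "r2"])),
      r2_sd = c(NA_real_, rep(NA_real_, length(masks)), stats::sd(mixed[, "r2"])),
      auc_mean = c(full["auc"], uniform[, "auc"], mean(mixed[, "auc"])),
      auc_sd = c(NA_real_, rep(NA_real_, length(masks)), stats::sd(mixed[, "auc"])),
      n_draws = c(1L, rep(1L, length(masks)), n_draws),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    attr(out, "uniform_summary") <- list(
      r2_mean = mean(uniform[, "r2"]), r2_sd = stats::sd(uniform[, "r2"]),
      auc_mean = mean(uniform[, "auc"]), auc_sd = stats::sd(uniform[, "auc"])
    )
    class(out) <- c("snpset_experiment", "data.frame")
    out
  })
}

#' @export
print.snpset_experiment <- function(x, ...) {
  cat("<snpset_experiment>\n")
  print.data.frame(x, digits = 4)
  us <- attr(x, "uniform_summary")
  cat(sprintf("uniform summary: R2 %.4f +/- %.4f, AUC %.4f +/- %.4f\n",
              us$r2_mean, us$r2_sd, us$auc_mean, us$auc_sd))
  invisible(x)
}

#' Cross-vendor score reproducibility
#'
#' The same individuals are scored through two independently drawn vendor
#' masks under the `frequency_fill` policy, and the per-individual centered
#' scores are correlated. With complete coverage the two scores are
#' identical (r = 1); with partial coverage r falls toward the shared
#' fraction of the panel — analytically, independent masks each covering a
#' fraction `q` of the panel share `q^2` of it and correlate at `r ~ q`.
#'
#' @param cohort A `synthetic_cohort` with complete dosages.
#' @param panel The generating `weight_panel`.
#' @param coverage Vendor coverage per mask (default 0.8, representative of
#'   how much of a well-imputed scoring SNP set a consumer chip attains).
#' @param seed Mandatory integer seed.
#' @return A list with `r` (Pearson correlation across individuals),
#'   `n_shared` (SNPs in both masks) and `coverage`.
#' @export
cross_vendor_reproducibility <- function(cohort, panel, coverage = 0.8, seed) {
  if (missing(seed)) dtc_error("dtcprs_bad_input", "seed is mandatory")
  pop <- cohort$population
  w <- panel$weights
  rsids <- w$rsid
  k <- max(1L, round(coverage * length(rsids)))
  with_seed(seed, {
    mask_a <- if (k == length(rsids)) rsids else sample(rsids, k)
    mask_b <- if (k == length(rsids)) rsids else sample(rsids, k)
    # frequency_fill: off-mask SNPs contribute exactly zero to the centered
    # score, so the score restricted to a mask is the per-term centered sum.
    centered <- function(mask) {
      b <- w$beta
      b[!(rsids %in% mask)] <- 0
      keep <- rsids %in% mask
      drop(cohort$dosages %*% b) -
        sum(population_score(panel, pop)[keep])
    }
    s_a <- centered(mask_a)
    s_b <- centered(mask_b)
    list(r = if (identical(s_a, s_b)) 1 else stats::cor(s_a, s_b),
         n_shared = length(intersect(mask_a, mask_b)),
         coverage = coverage)
  })
}

#' Extract one simulated individual as a genome profile
#'
#' Converts a cohort row into the common profile representation (allele
#' letters taken from the companion site table), so simulated people can be
#' exported through the vendor file dialects and pushed through the full
#' intake pipeline.
#'
#' @param cohort A `synthetic_cohort`.
#' @param i Individual index.
#' @param sites Companion site table (see [simulate_sites()]).
#' @return A `genome_profile`.
#' @export
cohort_profile <- function(cohort, i, sites) {
  d <- cohort$dosages[i, ]
  idx <- match(names(d), sites$rsid)
  ref <- sites$ref[idx]
  alt <- sites$alt[idx]
  a1 <- ifelse(is.na(d), NA_character_, ifelse(d >= 1, alt, ref))
  a2 <- ifelse(is.na(d), NA_character_, ifelse(d == 2, alt, ref))
  calls <- data.frame(
    rsid = names(d),
    chrom = as.character(sites$chromosome[idx]),
    pos = sites$position[idx],
    a1 = unname(a1),
    a2 = unname(a2),
    stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL
  stats <- list(total_lines = nrow(calls), n_calls = nrow(calls),
                n_missing = sum(is.na(a1)), n_rejected = 0L,
                reject_reasons = list())
  new_genome_profile(calls, "generic", stats)
}
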