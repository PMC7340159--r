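# Polygenic risk score computation: frequency-centered scores, analytic
# population scaling under Hardy-Weinberg and linkage equilibrium, empirical
# normalization against prior ancestry-matched scores, and single-variant
# carrier reports.

#' Construct a weight panel
#'
#' A trait's scoring model: per-SNP effect alleles, betas (log odds ratio or
#' linear-trait effect per effect allele), and effect-allele frequencies per
#' super-population. Top-SNP panels hold the LD-clumped genome-wide
#' significant subset (p < 5e-8); all-SNP panels carry externally derived
#' shrunk weights (e.g. LDpred output) — weight derivation is an input to
#' this package, not something it performs.
#'
#' @param trait_id Trait identifier string.
#' @param weights Data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, and `freq_AFR` .. `freq_SAS`.
#' @param mode `"TOP_SNP"` or `"ALL_SNP"`.
#' @param provenance Optional free-text note (GWAS source, p-threshold).
#' @return A `weight_panel` object.
#' @export
weight_panel <- function(trait_id, weights, mode = c("TOP_SNP", "ALL_SNP"),
                         provenance = NULL) {
  mode <- match.arg(mode)
  need <- c("rsid", "effect_allele", "other_allele", "beta",
            freq_col(super_populations()))
  missing_cols <- setdiff(need, names(weights))
  if (length(missing_cols) > 0L) {
    dtc_error("dtcprs_bad_input",
              paste("weight table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(weights$rsid)) {
    dtc_error("dtcprs_bad_input", "weight panel rsids must be unique")
  }
  if (any(weights$effect_allele == weights$other_allele)) {
    dtc_error("dtcprs_bad_input", "effect and other allele must differ")
  }
  if (any(!is.finite(weights$beta))) {
    dtc_error("dtcprs_bad_input", "betas must be finite")
  }
  fr <- as.matrix(weights[, freq_col(super_populations())])
  if (any(fr < 0 | fr > 1)) {
    dtc_error("dtcprs_bad_input", "effect allele frequencies must lie in [0, 1]")
  }
  structure(
    list(trait_id = trait_id, mode = mode,
         weights = weights, provenance = provenance),
    class = "weight_panel"
  )
}

#' @export
print.weight_panel <- function(x, ...) {
  cat(sprintf("<weight_panel> %s [%s], %d SNPs\n",
              x$trait_id, x$mode, nrow(x$weights)))
  invisible(x)
}

#' Read a weight panel from a tab-delimited file
#'
#' The file carries `#trait_id=`, `#mode=` (and optionally `#provenance=`)
#' comment headers followed by a tab-delimited table with columns `rsid`,
#' `effect_allele`, `other_allele`, `beta`, `freq_AFR` .. `freq_SAS`.
#'
#' @param path Path to the panel file.
#' @return A `weight_panel`.
#' @export
read_weight_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#\\s*\\w+\\s*=", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    meta[[key]] <- val
  }
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  weight_panel(
    trait_id = meta$trait_id %||% tools::file_path_sans_ext(basename(path)),
    weights = tab,
    mode = meta$mode %||% "TOP_SNP",
    provenance = meta$provenance
  )
}

#' Write a weight panel to a tab-delimited file
#' @param panel A `weight_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_weight_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#trait_id=", panel$trait_id),
               paste0("#mode=", panel$mode),
               if (!is.null(panel$provenance)) paste0("#provenance=", panel$provenance)),
             con)
  utils::write.table(panel$weights, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expected per-SNP score contribution in a population
#'
#' The population score of a SNP is `frequency * 2 * beta`: the expected
#' contribution of that SNP to a raw weighted allele-count sum for a member
#' of the population, under Hardy-Weinberg proportions.
#'
#' @param panel A `weight_panel` (or a data frame of weights).
#' @param population Super-population label.
#' @return Numeric vector of per-SNP population scores, in panel order.
#' @export
#' @examples
#' # one SNP with f = 0.5, beta = 0.2 contributes 0.2
population_score <- function(panel, population) {
  check_population(population)
  w <- if (inherits(panel, "weight_panel")) panel$weights else panel
  w[[freq_col(population)]] * 2 * w$beta
}

#' Zero-centered polygenic score
#'
#' `sum(beta * dosage - population_score)` over the SNPs with a usable
#' dosage. Missing SNPs contribute exactly zero, and a frequency-filled SNP
#' also contributes exactly zero (`beta * 2f - 2f * beta`), so the centered
#' score is invariant to the choice between the `skip` and `frequency_fill`
#' policies.
#'
#' @param dosages A `dosage_vector` from [dosage_against_panel()], or a bare
#'   numeric vector of effect-allele counts aligned to the panel order
#'   (`NA` = missing).
#' @param panel A `weight_panel`.
#' @param population Super-population whose frequencies center the score.
#' @return The centered score. When every SNP is missing, returns 0 carrying
#'   attribute `empty_overlap = TRUE` and signals a `dtcprs_empty_overlap`
#'   warning rather than presenting the value as informative.
#' @export
zero_centered_score <- function(dosages, panel, population) {
  check_population(population)
  w <- panel$weights
  d <- if (is.data.frame(dosages)) dosages$dosage else as.numeric(dosages)
  if (length(d) != nrow(w)) {
    dtc_error("dtcprs_bad_input",
              "dosage vector length must equal the panel SNP count")
  }
  usable <- !is.na(d)
  if (!any(usable)) {
    dtc_warn("dtcprs_empty_overlap",
             "no panel SNP has a usable dosage; centered score is uninformative")
    return(structure(0, empty_overlap = TRUE))
  }
  pop_sc <- population_score(panel, population)
  sum(w$beta[usable] * d[usable] - pop_sc[usable])
}

#' Analytic population standard deviation of a score
#'
#' `sqrt(sum(beta^2 * 2 f (1 - f)))`: the standard deviation of the centered
#' score under Hardy-Weinberg proportions and linkage equilibrium. For
#' LD-clumped top-SNP panels the independence assumption holds to a good
#' approximation, which is what makes the analytic scale usable as the
#' Z-score denominator.
#'
#' @param panel A `weight_panel`.
#' @param population Super-population label.
#' @return The positive scale. Signals `dtcprs_zero_variance_panel` when the
#'   variance sum is zero (Z undefined).
#' @export
#' @examples
#' # one SNP, f = 0.5, beta = 1: sqrt(0.5)
population_sd <- function(panel, population) {
  check_population(population)
  w <- panel$weights
  if (nrow(w) == 0L) {
    dtc_error("dtcprs_bad_input", "weight panel is empty")
  }
  f <- w[[freq_col(population)]]
  v <- sum(w$beta^2 * 2 * f * (1 - f))
  if (v <= 0) {
    dtc_error("dtcprs_zero_variance_panel",
              "panel has zero score variance in this population; Z-score undefined")
  }
  sqrt(v)
}

#' Standardized Z-score
#'
#' Ratio of the centered score to the population scale; no truncation or
#' winsorizing is applied.
#'
#' @param zero_centered Centered score.
#' @param sd Positive scale (e.g. from [population_sd()]).
#' @return `zero_centered / sd`.
#' @export
z_score <- function(zero_centered, sd) {
  if (!is.finite(sd) || sd <= 0) {
    dtc_error("dtcprs_zero_variance_panel", "Z-score requires a positive scale")
  }
  as.numeric(zero_centered) / sd
}

#' Empirical normalization against prior ancestry-matched scores
#'
#' Standardizes a score against the centered scores of previously processed
#' profiles of matching ancestry: `(score - mean(ref)) / sd(ref)` with the
#' sample (n-1) standard deviation. When the reference cohort is drawn from
#' the same population whose frequencies drive the analytic scaling, the
#' empirical Z matches the analytic Z up to sampling error.
#'
#' @param score Centered score to normalize.
#' @param reference_scores Numeric vector of prior centered scores.
#' @param min_n Minimum reference cohort size (default 30; scale estimates
#'   below that are unstable).
#' @return The empirical Z-score. Signals `dtcprs_insufficient_reference`
#'   when the cohort is too small or has zero variance.
#' @export
empirical_normalize <- function(score, reference_scores, min_n = 30L) {
  reference_scores <- reference_scores[is.finite(reference_scores)]
  if (length(reference_scores) < min_n) {
    dtc_error("dtcprs_insufficient_reference",
              sprintf("need at least %d reference scores, got %d",
                      min_n, length(reference_scores)))
  }
  s <- stats::sd(reference_scores)
  if (!is.finite(s) || s <= 0) {
    dtc_error("dtcprs_insufficient_reference",
              "reference scores have zero variance")
  }
  (as.numeric(score) - mean(reference_scores)) / s
}

#' Score a genome profile against a weight panel
#'
#' Composes [dosage_against_panel()], [zero_centered_score()] and either the
#' analytic 1000 Genomes scaling ([population_sd()] + [z_score()]) or
#' [empirical_normalize()], with full coverage accounting.
#'
#' @param profile A `genome_profile`.
#' @param panel A `weight_panel`.
#' @param sites Reference site table.
#' @param population Super-population used for centering/scaling.
#' @param missing_policy Passed to [dosage_against_panel()].
#' @param scaling `"analytic"` (1000 Genomes super-population scale) or
#'   `"empirical"` (prior user scores).
#' @param reference_scores Reference centered scores for empirical scaling.
#' @return A `prs_result`: `trait_id`, `raw_sum`, `zero_centered`, `z_score`,
#'   `population`, `scaling`, and the counts `n_used`, `n_frequency_filled`,
#'   `n_missing` (summing to the panel size).
#' @export
score_profile <- function(profile, panel, sites, population,
                          missing_policy = c("frequency_fill", "skip", "fail"),
                          scaling = c("analytic", "empirical"),
                          reference_scores = NULL) {
  missing_policy <- match.arg(missing_policy)
  scaling <- match.arg(scaling)
  dos <- dosage_against_panel(profile, panel, sites,
                              missing_policy = missing_policy,
                              population = population)
  w <- panel$weights
  genotyped <- dos$provenance == "genotyped"
  raw_sum <- sum(w$beta[!is.na(dos$dosage)] * dos$dosage[!is.na(dos$dosage)])
  zc <- zero_centered_score(dos, panel, population)
  z <- if (scaling == "analytic") {
    z_score(zc, population_sd(panel, population))
  } else {
    empirical_normalize(zc, reference_scores)
  }
  structure(
    list(
      trait_id = panel$trait_id,
      raw_sum = raw_sum,
      zero_centered = as.numeric(zc),
      z_score = z,
      population = population,
      scaling = if (scaling == "analytic") "ANALYTIC_1KG" else "EMPIRICAL",
      n_used = sum(genotyped),
      n_frequency_filled = sum(dos$provenance == "frequency_filled"),
      n_missing = sum(dos$provenance == "missing"),
      empty_overlap = isTRUE(attr(zc, "empty_overlap"))
    ),
    class = "prs_result"
  )
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("<prs_result> %s [%s, %s]\n", x$trait_id, x$population, x$scaling))
  cat(sprintf("  z = %.4f (centered %.4f, raw %.4f)\n",
              x$z_score, x$zero_centered, x$raw_sum))
  cat(sprintf("  SNPs: %d genotyped, %d frequency-filled, %d missing\n",
              x$n_used, x$n_frequency_filled, x$n_missing))
  invisible(x)
}

#' Single-variant carrier report
#'
#' The single-SNP reporting style used by variant-lookup services: a person
#' is a "carrier" when at least one listed risk allele is present in their
#' genotype, after filtering the variant list by a magnitude threshold.
#' Missing genotypes count as non-carrier for that variant. This report is
#' deliberately naive — it is the comparator whose lack of predictive value
#' the polygenic score demonstrates.
#'
#' @param profile A `genome_profile`.
#' @param risk_variants Data frame with columns `rsid`, `risk_allele`,
#'   `magnitude`.
#' @param magnitude_min Only variants with magnitude strictly above this are
#'   considered (default 1.5).
#' @return A `carrier_report` list: `carrier` flag, `hits` data frame, and
#'   the counts of considered/excluded variants.
#' @export
carrier_report <- function(profile, risk_variants, magnitude_min = 1.5) {
  need <- c("rsid", "risk_allele", "magnitude")
  if (!all(need %in% names(risk_variants)) || nrow(risk_variants) == 0L) {
    dtc_error("dtcprs_bad_input",
              "risk_variants must be a non-empty table with rsid, risk_allele, magnitude")
  }
  considered <- risk_variants[risk_variants$magnitude > magnitude_min, , drop = FALSE]
  calls <- profile$calls
  idx <- match(considered$rsid, calls$rsid)
  a1 <- calls$a1[idx]
  a2 <- calls$a2[idx]
  n_risk <- ifelse(is.na(a1), 0L,
                   (a1 == considered$risk_allele) + (a2 == considered$risk_allele))
  hits <- data.frame(
    rsid = considered$rsid,
    risk_allele = considered$risk_allele,
    magnitude = considered$magnitude,
    genotype = ifelse(is.na(a1), NA_character_, paste0(a1, a2)),
    n_risk_alleles = as.integer(n_risk),
    stringsAsFactors = FALSE
  )
  hits <- hits[hits$n_risk_alleles > 0L, , drop = FALSE]
  rownames(hits) <- NULL
  structure(
    list(carrier = nrow(hits) > 0L,
         hits = hits,
         n_considered = nrow(considered),
         n_excluded = nrow(risk_variants) - nrow(considered)),
    class = "carrier_report"
  )
}

#' @export
print.carrier_report <- function(x, ...) {
  cat(sprintf("<carrier_report> carrier: %s (%d hit(s) among %d variants above magnitude threshold; %d excluded)\n",
              x$carrier, nrow(x$hits), x$n_considered, x$n_excluded))
  invisible(x)
}
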