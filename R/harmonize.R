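# Alignment of profile alleles to a reference panel (strand flips, effect
# orientation), Hardy-Weinberg exact test, QC filtering, and construction of
# effect-allele dosage vectors against a weight panel.

#' Quality-control thresholds
#'
#' Site-level filters applied before scoring: minor allele frequency,
#' Hardy-Weinberg exact-test p-value, genotype yield, and (when an imputation
#' quality column is supplied) the best-guess INFO threshold.
#'
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p_min Minimum Hardy-Weinberg exact p-value (default 1e-5).
#' @param yield_min Minimum genotype yield (default 0.95).
#' @param info_min Minimum imputation INFO score (default 0.9); only applied
#'   when an `info` column is present.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.05, hwe_p_min = 1e-5,
                          yield_min = 0.95, info_min = 0.9) {
  vals <- c(maf_min = maf_min, hwe_p_min = hwe_p_min,
            yield_min = yield_min, info_min = info_min)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    dtc_error("dtcprs_bad_input", "all QC thresholds must lie in [0, 1]")
  }
  structure(as.list(vals), class = "qc_thresholds")
}

#' Read a reference panel site table
#'
#' Tab-delimited table with columns `rsid`, `chromosome`, `position`, `ref`,
#' `alt` and per-super-population alt-allele frequencies `freq_AFR`,
#' `freq_AMR`, `freq_EAS`, `freq_EUR`, `freq_SAS` (GRCh37 coordinates).
#'
#' @param path Path to the table.
#' @return A data frame of reference sites.
#' @export
read_sites <- function(path) {
  sites <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
  validate_sites(sites)
}

validate_sites <- function(sites) {
  need <- c("rsid", "chromosome", "position", "ref", "alt",
            freq_col(super_populations()))
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols) > 0L) {
    dtc_error("dtcprs_bad_input",
              paste("site table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(sites$ref == sites$alt)) {
    dtc_error("dtcprs_bad_input", "reference sites must have ref != alt")
  }
  fr <- as.matrix(sites[, freq_col(super_populations())])
  if (any(fr < 0 | fr > 1)) {
    dtc_error("dtcprs_bad_input", "site frequencies must lie in [0, 1]")
  }
  sites$chromosome <- as.character(sites$chromosome)
  sites
}

#' Write a reference site table
#' @param sites Site data frame (see [read_sites()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Vectorized allele alignment core. Returns status plus aligned alleles and
# alt dosage. Strand-ambiguous site classes (A/T, C/G) are rejected outright:
# no vendor strand metadata is trustworthy across dialects.
align_core <- function(a1, a2, ref, alt) {
  n <- length(a1)
  status <- rep("mismatch", n)
  g1 <- rep(NA_character_, n)
  g2 <- rep(NA_character_, n)

  ambiguous <- ref == revcomp(alt)
  missing <- is.na(a1) | is.na(a2)
  direct <- !missing & (a1 == ref | a1 == alt) & (a2 == ref | a2 == alt)
  r1 <- revcomp(a1)
  r2 <- revcomp(a2)
  flipped <- !missing & !direct &
    (r1 == ref | r1 == alt) & (r2 == ref | r2 == alt)

  status[direct] <- "aligned"
  status[flipped] <- "flipped"
  status[missing] <- "missing"
  status[ambiguous] <- "ambiguous"

  g1[direct] <- a1[direct]
  g2[direct] <- a2[direct]
  g1[flipped] <- r1[flipped]
  g2[flipped] <- r2[flipped]
  keep <- status %in% c("aligned", "flipped")
  dosage <- rep(NA_real_, n)
  dosage[keep] <- (g1[keep] == alt[keep]) + (g2[keep] == alt[keep])
  list(status = status, a1 = g1, a2 = g2, dosage = dosage)
}

#' Align one variant call to a reference site
#'
#' Matches the genotype alleles to the site's ref/alt pair directly, or via
#' reverse complement when the call was reported on the opposite strand.
#' Strand-ambiguous sites (A/T, C/G) are rejected because the flip cannot be
#' detected; alleles matching neither orientation are rejected as mismatches.
#'
#' @param call A list or one-row data frame with alleles `a1`, `a2`.
#' @param site A list or one-row data frame with `ref`, `alt`.
#' @return A list with `status` (one of `aligned`, `flipped`, `ambiguous`,
#'   `missing`, `mismatch`), the aligned `genotype`, and the alt-allele
#'   `dosage` (`NA` unless aligned or flipped).
#' @export
#' @examples
#' align_alleles(list(a1 = "T", a2 = "C"), list(ref = "A", alt = "G"))
align_alleles <- function(call, site) {
  res <- align_core(call$a1, call$a2, site$ref, site$alt)
  list(status = res$status,
       genotype = c(res$a1, res$a2),
       dosage = res$dosage)
}

#' Harmonize a genome profile against a reference panel
#'
#' Joins the profile's calls to the reference sites by rsid (the panel is the
#' coordinate authority: a chromosome/position mismatch at a shared rsid
#' rejects the site), aligns alleles with strand-flip resolution, and records
#' alt-allele dosages plus categorized rejection counts.
#'
#' @param profile A `genome_profile`.
#' @param sites Reference site table.
#' @return The profile with an `aligned` table (`rsid`, `chrom`, `pos`,
#'   `ref`, `alt`, `status`, `dosage`) and `harmony_stats` counts.
#' @export
harmonize_profile <- function(profile, sites) {
  sites <- validate_sites(sites)
  calls <- profile$calls
  idx <- match(calls$rsid, sites$rsid)
  on_panel <- !is.na(idx)
  cs <- calls[on_panel, , drop = FALSE]
  ss <- sites[idx[on_panel], , drop = FALSE]

  res <- align_core(cs$a1, cs$a2, ss$ref, ss$alt)
  pos_bad <- cs$chrom != ss$chromosome | cs$pos != ss$position
  res$status[pos_bad] <- "position_mismatch"
  res$dosage[pos_bad] <- NA_real_

  aligned <- data.frame(
    rsid = cs$rsid,
    chrom = ss$chromosome,
    pos = ss$position,
    ref = ss$ref,
    alt = ss$alt,
    status = res$status,
    dosage = res$dosage,
    stringsAsFactors = FALSE
  )
  rownames(aligned) <- NULL
  profile$aligned <- aligned
  counts <- table(factor(aligned$status,
                         levels = c("aligned", "flipped", "missing",
                                    "ambiguous", "mismatch",
                                    "position_mismatch")))
  profile$harmony_stats <- c(as.list(as.integer(counts)) |>
                               stats::setNames(names(counts)),
                             list(off_panel = sum(!on_panel)))
  profile
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test: conditional on the observed allele counts, the
#' p-value is the sum of probabilities of all heterozygote-count
#' configurations whose probability does not exceed that of the observed
#' configuration.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return The exact two-sided p-value. Monomorphic sites return 1. Signals
#'   `dtcprs_degenerate_input` when all counts are zero.
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25)
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) {
    dtc_error("dtcprs_bad_input", "genotype counts must be non-negative")
  }
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) {
    dtc_error("dtcprs_degenerate_input", "all genotype counts are zero")
  }
  nA <- 2L * n_AA + n_Aa
  hets <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  # log P(h het | n, nA) up to the shared normalizing constant
  logp <- hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - nA - hets) / 2)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Apply QC filters to a table of per-site genotype counts
#'
#' A site is retained iff its minor allele frequency exceeds `maf_min`, its
#' Hardy-Weinberg exact p-value exceeds `hwe_p_min`, its genotype yield
#' exceeds `yield_min`, and (when an `info` column is supplied) its INFO
#' score is at least `info_min`. The exclusion ledger records the first
#' failing criterion per site, in that order.
#'
#' MAF is estimated from the cohort counts when at least `min_cohort_n`
#' genotypes are available, and otherwise falls back to the `panel_freq`
#' column (single-profile uploads cannot estimate MAF).
#'
#' @param counts Data frame with columns `rsid`, `n_AA`, `n_Aa`, `n_aa`,
#'   optional `n_missing` (for yield), optional `info`, optional `panel_freq`.
#' @param thresholds A [qc_thresholds()] object.
#' @param min_cohort_n Minimum cohort size for count-based MAF (default 50).
#' @return A list with `retained` (character rsids) and `ledger` (per-site
#'   data frame with the computed metrics, retention flag and first failing
#'   reason).
#' @export
apply_qc <- function(counts, thresholds = qc_thresholds(), min_cohort_n = 50L) {
  if (nrow(counts) == 0L) {
    dtc_error("dtcprs_bad_input", "QC requires at least one site")
  }
  for (col in c("n_AA", "n_Aa", "n_aa")) {
    if (is.null(counts[[col]])) {
      dtc_error("dtcprs_bad_input", paste("counts table lacks column", col))
    }
  }
  n_typed <- counts$n_AA + counts$n_Aa + counts$n_aa
  n_missing <- counts$n_missing %||% rep(0L, nrow(counts))
  yield <- n_typed / pmax(1L, n_typed + n_missing)

  f_alt <- (2 * counts$n_AA + counts$n_Aa) / (2 * pmax(1L, n_typed))
  maf_counts <- pmin(f_alt, 1 - f_alt)
  maf <- ifelse(n_typed >= min_cohort_n, maf_counts,
                if (is.null(counts$panel_freq)) NA_real_
                else pmin(counts$panel_freq, 1 - counts$panel_freq))
  hwe_p <- mapply(hwe_exact_p, counts$n_AA, counts$n_Aa, counts$n_aa)
  info <- counts$info

  reason <- rep(NA_character_, nrow(counts))
  reason[is.na(reason) & !is.na(maf) & maf <= thresholds$maf_min] <- "MAF"
  reason[is.na(reason) & hwe_p <= thresholds$hwe_p_min] <- "HWE"
  reason[is.na(reason) & yield <= thresholds$yield_min] <- "YIELD"
  if (!is.null(info)) {
    reason[is.na(reason) & info < thresholds$info_min] <- "INFO"
  }
  retained <- is.na(reason)
  ledger <- data.frame(
    rsid = counts$rsid,
    maf = maf,
    hwe_p = hwe_p,
    yield = yield,
    info = if (is.null(info)) NA_real_ else info,
    retained = retained,
    reason = reason,
    stringsAsFactors = FALSE
  )
  list(retained = counts$rsid[retained], ledger = ledger)
}

#' Write a QC exclusion ledger as TSV
#' @param qc Result of [apply_qc()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_ledger <- function(qc, path) {
  utils::write.table(qc$ledger, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Build an effect-allele dosage vector against a weight panel
#'
#' For each SNP of the weight panel, in panel order: the aligned
#' effect-allele count when the profile has an alignable genotype at the
#' SNP's reference site, otherwise the missing-SNP policy applies.
#' Non-autosomal sites are never scored (the score equations assume diploid
#' dosage 0/1/2).
#'
#' @param profile A `genome_profile` (harmonized on the fly if needed).
#' @param panel A `weight_panel`.
#' @param sites Reference site table.
#' @param missing_policy `"skip"` (contribute nothing; mirrors naive raw-data
#'   scoring), `"frequency_fill"` (dosage set to twice the population effect
#'   allele frequency, a deliberately crude stand-in for imputation), or
#'   `"fail"` (error on any gap).
#' @param population Super-population used for frequency fill.
#' @return A `dosage_vector` data frame with `rsid`, `dosage` and per-SNP
#'   `provenance` (`genotyped`, `frequency_filled`, `missing`), aligned to
#'   the panel's SNP order. Signals `dtcprs_incomplete_panel` under the
#'   `"fail"` policy.
#' @export
dosage_against_panel <- function(profile, panel, sites,
                                 missing_policy = c("frequency_fill", "skip", "fail"),
                                 population = "EUR") {
  missing_policy <- match.arg(missing_policy)
  check_population(population)
  if (nrow(panel$weights) == 0L) {
    dtc_error("dtcprs_bad_input", "weight panel is empty")
  }
  if (is.null(profile$aligned)) {
    profile <- harmonize_profile(profile, sites)
  }
  w <- panel$weights
  sidx <- match(w$rsid, sites$rsid)
  aidx <- match(w$rsid, profile$aligned$rsid)

  dosage <- rep(NA_real_, nrow(w))
  provenance <- rep("missing", nrow(w))

  has_site <- !is.na(sidx)
  autosomal <- has_site & is_autosome(as.character(sites$chromosome[sidx]))
  ok_call <- !is.na(aidx) &
    profile$aligned$status[aidx] %in% c("aligned", "flipped")
  usable <- autosomal & ok_call

  if (any(usable)) {
    ref <- sites$ref[sidx[usable]]
    alt <- sites$alt[sidx[usable]]
    d_alt <- profile$aligned$dosage[aidx[usable]]
    eff <- w$effect_allele[usable]
    oth <- w$other_allele[usable]
    d_eff <- rep(NA_real_, sum(usable))
    direct <- eff == alt & oth == ref
    direct_rev <- eff == ref & oth == alt
    flip <- revcomp(eff) == alt & revcomp(oth) == ref
    flip_rev <- revcomp(eff) == ref & revcomp(oth) == alt
    d_eff[direct | flip] <- d_alt[direct | flip]
    d_eff[direct_rev | flip_rev] <- 2 - d_alt[direct_rev | flip_rev]
    dosage[usable] <- d_eff
    provenance[usable][!is.na(d_eff)] <- "genotyped"
  }

  gap <- provenance == "missing"
  if (missing_policy == "fail" && any(gap)) {
    dtc_error("dtcprs_incomplete_panel",
              sprintf("%d of %d panel SNPs have no usable genotype",
                      sum(gap), nrow(w)))
  }
  if (missing_policy == "frequency_fill" && any(gap)) {
    f <- w[[freq_col(population)]][gap]
    dosage[gap] <- 2 * f
    provenance[gap] <- "frequency_filled"
  }
  structure(
    data.frame(rsid = w$rsid, dosage = dosage, provenance = provenance,
               stringsAsFactors = FALSE),
    population = population,
    trait_id = panel$trait_id,
    class = c("dosage_vector", "data.frame")
  )
}
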