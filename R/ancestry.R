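# Continental ancestry assignment from genotype dosages, so the correct
# super-population is used for frequency-based score scaling.

#' Assign a 1000 Genomes super-population from genotype dosages
#'
#' Naive-Bayes classifier under Hardy-Weinberg proportions: for each
#' super-population the sum over non-missing autosomal sites of the log
#' genotype likelihood `log P(g | f_pop)` is computed, with frequencies
#' clamped to `[eps, 1 - eps]` so fixed alleles cannot produce `-Inf`. The
#' label is the arg-max; ties break deterministically in the fixed order
#' AFR, AMR, EAS, EUR, SAS.
#'
#' @param dosages Named numeric vector of alt-allele counts (0/1/2, `NA` for
#'   missing), names matching the site table rsids. See
#'   [profile_alt_dosages()] for extracting these from a harmonized profile.
#' @param sites Reference site table with per-population alt frequencies.
#' @param min_sites Minimum number of usable autosomal sites (default 100).
#' @param eps Frequency clamp (default 1e-4).
#' @return An `ancestry_call`: `label`, per-population average log-likelihood,
#'   `margin` (best minus second-best average log-likelihood, >= 0) and
#'   `n_sites`. Signals `dtcprs_insufficient_sites` below the floor.
#' @export
assign_population <- function(dosages, sites, min_sites = 100L, eps = 1e-4) {
  idx <- match(names(dosages), sites$rsid)
  ok <- !is.na(idx) & !is.na(dosages) &
    dosages %in% c(0, 1, 2) &
    is_autosome(as.character(sites$chromosome[idx]))
  n <- sum(ok)
  if (n < min_sites) {
    dtc_error("dtcprs_insufficient_sites",
              sprintf("ancestry assignment needs >= %d usable autosomal sites, got %d",
                      min_sites, n))
  }
  d <- as.integer(dosages[ok])
  srow <- idx[ok]
  avg_ll <- vapply(super_populations(), function(pop) {
    f <- sites[[freq_col(pop)]][srow]
    f <- pmin(pmax(f, eps), 1 - eps)
    sum(stats::dbinom(d, size = 2L, prob = f, log = TRUE)) / n
  }, numeric(1))
  best <- which.max(avg_ll)  # first max wins: fixed AFR..SAS tie-break order
  sorted <- sort(avg_ll, decreasing = TRUE)
  structure(
    list(label = super_populations()[best],
         avg_loglik = avg_ll,
         margin = unname(sorted[1] - sorted[2]),
         n_sites = n),
    class = "ancestry_call"
  )
}

#' @export
print.ancestry_call <- function(x, ...) {
  cat(sprintf("<ancestry_call> %s (margin %.4f over %d sites)\n",
              x$label, x$margin, x$n_sites))
  invisible(x)
}

#' Extract alt-allele dosages from a harmonized profile
#'
#' @param profile A `genome_profile`.
#' @param sites Reference site table (used to harmonize when needed).
#' @return Named numeric vector of alt-allele dosages at aligned sites.
#' @export
profile_alt_dosages <- function(profile, sites) {
  if (is.null(profile$aligned)) {
    profile <- harmonize_profile(profile, sites)
  }
  al <- profile$aligned[profile$aligned$status %in% c("aligned", "flipped"), ]
  stats::setNames(al$dosage, al$rsid)
}
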