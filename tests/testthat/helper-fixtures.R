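# Programmatic fixtures shared across test files.

# A hand-sized weight panel with identical frequencies in all populations.
make_panel <- function(betas, freqs, trait_id = "toy_trait",
                       effect = NULL, other = NULL, mode = "TOP_SNP") {
  m <- length(betas)
  stopifnot(length(freqs) == m)
  if (is.null(effect)) effect <- rep(c("A", "T", "G", "C"), length.out = m)
  if (is.null(other)) other <- rep(c("G", "C", "A", "T"), length.out = m)
  w <- data.frame(
    rsid = sprintf("rs%d", seq_len(m)),
    effect_allele = effect,
    other_allele = other,
    beta = betas,
    stringsAsFactors = FALSE
  )
  for (pop in super_populations()) w[[paste0("freq_", pop)]] <- freqs
  weight_panel(trait_id, w, mode = mode)
}

# Companion sites for make_panel (ref = other, alt = effect).
make_sites <- function(panel) simulate_sites(panel)

# Profile built directly from calls, skipping file parsing.
make_profile <- function(calls, dialect = "generic") {
  lines <- write_fixture(calls, dialect)
  suppressWarnings(read_profile(lines, dialect))
}

# Calls data frame for a set of effect-allele dosages against a panel.
calls_from_dosages <- function(dosages, panel, sites = make_sites(panel)) {
  w <- panel$weights
  idx <- match(w$rsid, sites$rsid)
  ref <- sites$ref[idx]
  alt <- sites$alt[idx]
  data.frame(
    rsid = w$rsid,
    chrom = as.character(sites$chromosome[idx]),
    pos = sites$position[idx],
    a1 = ifelse(is.na(dosages), NA_character_, ifelse(dosages >= 1, alt, ref)),
    a2 = ifelse(is.na(dosages), NA_character_, ifelse(dosages == 2, alt, ref)),
    stringsAsFactors = FALSE
  )
}
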