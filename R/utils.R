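# Internal helpers shared across modules.

#' 1000 Genomes super-population labels
#'
#' The five continental groups used for frequency-based score scaling and
#' ancestry assignment, in the fixed tie-break order used throughout the
#' package.
#'
#' @return Character vector `c("AFR", "AMR", "EAS", "EUR", "SAS")`.
#' @export
#' @examples
#' super_populations()
super_populations <- function() {
  c("AFR", "AMR", "EAS", "EUR", "SAS")
}

# Chromosome labels accepted from consumer files, in VCF contig order.
chrom_levels <- function() c(as.character(1:22), "X", "Y", "MT")

is_autosome <- function(chrom) chrom %in% as.character(1:22)

freq_col <- function(population) paste0("freq_", population)

# Classed conditions so callers (and the CLI) can map failures to exit codes.
dtc_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "dtcprs_error", "error", "condition")))
}

dtc_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "dtcprs_warning", "warning", "condition")))
}

# Run code under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Reverse complement of single-base alleles; NA stays NA.
revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- unname(map[x])
  out[is.na(x)] <- NA_character_
  out
}

check_population <- function(population) {
  if (length(population) != 1L || !population %in% super_populations()) {
    dtc_error("dtcprs_unknown_population",
              sprintf("unknown super-population '%s'; expected one of %s",
                      paste(population, collapse = ","),
                      paste(super_populations(), collapse = ", ")))
  }
  population
}
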