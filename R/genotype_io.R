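# Intake of consumer genotype exports: dialect detection, parsing into a
# common profile representation, anonymous identifiers, and VCF export.

DIALECTS <- c("23andme", "ancestry", "myheritage", "generic")

new_genome_profile <- function(calls, dialect, stats,
                               unique_id = NA_character_,
                               source_digest = NA_character_) {
  structure(
    list(
      unique_id = unique_id,
      source_digest = source_digest,
      vendor_dialect = dialect,
      calls = calls,
      call_stats = stats,
      aligned = NULL,
      harmony_stats = NULL
    ),
    class = "genome_profile"
  )
}

#' @export
print.genome_profile <- function(x, ...) {
  cat("<genome_profile>\n")
  cat("  dialect:  ", x$vendor_dialect, "\n", sep = "")
  cat("  unique_id:", if (is.na(x$unique_id)) " (unassigned)" else paste0(" ", x$unique_id), "\n", sep = "")
  s <- x$call_stats
  cat(sprintf("  calls: %d (%d missing), rejected lines: %d of %d\n",
              s$n_calls, s$n_missing, s$n_rejected, s$total_lines))
  if (!is.null(x$aligned)) {
    cat(sprintf("  harmonized against %d panel sites\n", nrow(x$aligned)))
  }
  invisible(x)
}

#' Detect the vendor dialect of a raw consumer genotype export
#'
#' Inspects header comments, delimiter and column count of the first data
#' lines. A four-column tab-separated rsid/chromosome/position/genotype shape
#' without a recognized vendor header is classified as `"generic"`.
#'
#' @param lines Character vector of raw file lines (e.g. from [readLines()]).
#' @return One of `"23andme"`, `"ancestry"`, `"myheritage"`, `"generic"`.
#'   Signals a condition of class `dtcprs_unrecognized_format` when no
#'   dialect matches.
#' @export
#' @examples
#' detect_format(c("# rsid\tchromosome\tposition\tgenotype",
#'                 "rs1\t1\t1000\tAG"))
detect_format <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    dtc_error("dtcprs_unrecognized_format", "input stream is empty")
  }
  head_lines <- utils::head(lines, 200L)
  comments <- head_lines[startsWith(head_lines, "#")]
  data_lines <- head_lines[!startsWith(head_lines, "#")]
  if (length(data_lines) == 0L) {
    dtc_error("dtcprs_unrecognized_format", "no data lines found")
  }
  first <- data_lines[[1L]]

  # MyHeritage-style: comma-separated with quoted fields.
  if (grepl("^\\s*\"", first) && grepl(",", first)) {
    nfield <- length(strsplit(first, ",", fixed = TRUE)[[1L]])
    if (nfield == 4L) return("myheritage")
    dtc_error("dtcprs_unrecognized_format",
              sprintf("quoted CSV with %d fields is not a recognized dialect", nfield))
  }

  fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  # AncestryDNA-style: 5 columns with split allele1/allele2.
  if (length(fields) == 5L ||
      grepl("allele1", first, ignore.case = TRUE)) {
    return("ancestry")
  }
  if (length(fields) == 4L) {
    header_23 <- any(grepl("rsid\\s+chromosome\\s+position\\s+genotype", comments,
                           ignore.case = TRUE)) ||
      any(grepl("23andMe", comments, fixed = TRUE))
    return(if (header_23) "23andme" else "generic")
  }
  dtc_error("dtcprs_unrecognized_format",
            sprintf("line with %d tab-separated fields matches no known dialect",
                    length(fields)))
}

# Validate a vector of genotype allele pairs; returns a list with a1, a2 and a
# per-row status in {ok, missing, indel, bad_allele}.
classify_alleles <- function(a1, a2) {
  status <- rep("ok", length(a1))
  miss <- (is.na(a1) | a1 %in% c("-", "0", "")) &
    (is.na(a2) | a2 %in% c("-", "0", ""))
  half_miss <- !miss & (is.na(a1) | is.na(a2) |
                          a1 %in% c("-", "0", "") | a2 %in% c("-", "0", ""))
  status[miss | half_miss] <- "missing"
  a1[status == "missing"] <- NA_character_
  a2[status == "missing"] <- NA_character_
  ok <- status == "ok"
  indel <- ok & (a1 %in% c("I", "D") | a2 %in% c("I", "D"))
  status[indel] <- "indel"
  bad <- status == "ok" & !(a1 %in% c("A", "C", "G", "T") &
                              a2 %in% c("A", "C", "G", "T"))
  status[bad] <- "bad_allele"
  list(a1 = a1, a2 = a2, status = status)
}

# Split merged genotype strings ("AG", "--", "A", "II") into allele pairs.
split_genotype <- function(g) {
  g <- trimws(g)
  n <- length(g)
  a1 <- rep(NA_character_, n)
  a2 <- rep(NA_character_, n)
  status <- rep("ok", n)
  miss <- g %in% c("--", "", "-", "00", "0")
  nchar_g <- nchar(g)
  two <- !miss & nchar_g == 2L
  one <- !miss & nchar_g == 1L  # haploid call (X/Y/MT); stored as homozygous
  bad <- !miss & !two & !one
  a1[two] <- substr(g[two], 1L, 1L)
  a2[two] <- substr(g[two], 2L, 2L)
  a1[one] <- g[one]
  a2[one] <- g[one]
  status[bad] <- "bad_genotype"
  list(a1 = a1, a2 = a2, status = status, missing = miss)
}

parse_table <- function(rsid, chrom, pos, a1, a2, gt_status, n_total) {
  status <- gt_status
  pos_num <- suppressWarnings(as.integer(pos))
  bad_pos <- status == "ok" & (is.na(pos_num) | pos_num < 1L)
  status[bad_pos] <- "bad_position"
  bad_chrom <- status %in% c("ok", "missing") & !(chrom %in% chrom_levels())
  status[bad_chrom] <- "bad_chromosome"

  al <- classify_alleles(a1, a2)
  take <- status %in% c("ok", "missing")
  status[take & al$status == "indel"] <- "indel"
  status[take & al$status == "bad_allele"] <- "bad_allele"
  status[status == "ok" & al$status == "missing"] <- "missing"

  keep <- status %in% c("ok", "missing")
  calls <- data.frame(
    rsid = rsid[keep],
    chrom = chrom[keep],
    pos = pos_num[keep],
    a1 = al$a1[keep],
    a2 = al$a2[keep],
    stringsAsFactors = FALSE
  )
  # Dedupe policy: keep the first occurrence of an rsid, count the rest.
  dup <- duplicated(calls$rsid)
  n_dup <- sum(dup)
  calls <- calls[!dup, , drop = FALSE]
  rownames(calls) <- NULL

  reject_status <- status[!status %in% c("ok", "missing")]
  reasons <- table(c(reject_status, rep("duplicate_rsid", n_dup)))
  stats <- list(
    total_lines = n_total,
    n_calls = nrow(calls),
    n_missing = sum(is.na(calls$a1)),
    n_rejected = n_total - nrow(calls),
    reject_reasons = as.list(as.integer(reasons)) |>
      stats::setNames(names(reasons))
  )
  list(calls = calls, stats = stats)
}

#' Parse a consumer genotype export into a genome profile
#'
#' Every well-formed data line becomes one variant call; `"--"` (merged
#' dialects) and `0`/empty allele pairs (split-allele dialects) become missing
#' genotypes; malformed lines, insertion/deletion codes and duplicate rsids
#' are counted as rejected rather than being fatal. Haploid calls (single
#' allele, as emitted for X/Y/MT) are stored as homozygous.
#'
#' @param lines Character vector of raw file lines.
#' @param dialect One of [detect_format()]'s return values; detected
#'   automatically when omitted.
#' @return A `genome_profile` object: variant calls (`rsid`, `chrom`, `pos`,
#'   alleles `a1`/`a2` with `NA` marking missing genotypes) plus parsing
#'   statistics. Signals `dtcprs_empty_profile` when no line yields a valid
#'   call, and a `dtcprs_missing_chromosome` warning when an entire autosome
#'   is absent.
#' @export
read_profile <- function(lines, dialect = detect_format(lines)) {
  dialect <- match.arg(dialect, DIALECTS)
  lines <- lines[nzchar(trimws(lines))]
  data_lines <- lines[!startsWith(lines, "#")]

  if (dialect %in% c("23andme", "generic")) {
    parts <- strsplit(data_lines, "\t", fixed = TRUE)
    ok_shape <- lengths(parts) == 4L
    m <- matrix(unlist(parts[ok_shape]), ncol = 4L, byrow = TRUE)
    gt <- split_genotype(m[, 4L])
    res <- parse_table(m[, 1L], m[, 2L], m[, 3L], gt$a1, gt$a2,
                       ifelse(gt$missing, "missing", gt$status),
                       n_total = length(data_lines))
    res$stats$reject_reasons$malformed <-
      (res$stats$reject_reasons$malformed %||% 0L) + sum(!ok_shape)
  } else if (dialect == "ancestry") {
    # Drop the unquoted header line if present.
    is_header <- grepl("^rsid\t", data_lines, ignore.case = TRUE)
    data_lines <- data_lines[!is_header]
    parts <- strsplit(data_lines, "\t", fixed = TRUE)
    ok_shape <- lengths(parts) == 5L
    m <- matrix(unlist(parts[ok_shape]), ncol = 5L, byrow = TRUE)
    res <- parse_table(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L],
                       rep("ok", sum(ok_shape)),
                       n_total = length(data_lines))
    res$stats$reject_reasons$malformed <-
      (res$stats$reject_reasons$malformed %||% 0L) + sum(!ok_shape)
  } else { # myheritage
    is_header <- grepl("RSID", data_lines, ignore.case = TRUE) &
      grepl("CHROMOSOME", data_lines, ignore.case = TRUE)
    data_lines <- data_lines[!is_header]
    stripped <- gsub("\"", "", data_lines, fixed = TRUE)
    parts <- strsplit(stripped, ",", fixed = TRUE)
    ok_shape <- lengths(parts) == 4L
    m <- matrix(unlist(parts[ok_shape]), ncol = 4L, byrow = TRUE)
    gt <- split_genotype(m[, 4L])
    res <- parse_table(m[, 1L], m[, 2L], m[, 3L], gt$a1, gt$a2,
                       ifelse(gt$missing, "missing", gt$status),
                       n_total = length(data_lines))
    res$stats$reject_reasons$malformed <-
      (res$stats$reject_reasons$malformed %||% 0L) + sum(!ok_shape)
  }

  if (res$stats$n_calls == 0L) {
    dtc_error("dtcprs_empty_profile", "no valid variant calls were parsed")
  }
  absent <- setdiff(as.character(1:22), unique(res$calls$chrom))
  if (length(absent) > 0L) {
    dtc_warn("dtcprs_missing_chromosome",
             sprintf("autosome(s) entirely absent from profile: %s",
                     paste(absent, collapse = ", ")))
  }
  new_genome_profile(res$calls, dialect, res$stats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a consumer genotype file from disk
#'
#' Convenience wrapper: reads the file, detects the dialect, parses the
#' profile and records the md5 digest of the raw bytes.
#'
#' @param path Path to a raw DTC export file.
#' @return A `genome_profile` with `source_digest` filled in.
#' @export
read_profile_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  profile <- read_profile(lines)
  profile$source_digest <- source_digest(path)
  profile
}

#' Assign an anonymous nine-character identifier
#'
#' Generates a token of the form `id_` followed by nine characters drawn from
#' `[0-9a-z]`. The token carries no personally linkable information and is
#' used as the identity key in all downstream reporting. Generation is
#' deterministic under a fixed seed and regenerates on collision with a
#' supplied registry.
#'
#' @param seed Optional integer seed for reproducible assignment.
#' @param existing Character vector of identifiers already in use.
#' @return A single identifier string matching `^id_[0-9a-z]{9}$`.
#' @export
#' @examples
#' assign_unique_id(seed = 1)
assign_unique_id <- function(seed = NULL, existing = character()) {
  alphabet <- c(as.character(0:9), letters)
  with_seed(seed, {
    repeat {
      token <- paste0("id_", paste(sample(alphabet, 9L, replace = TRUE),
                                   collapse = ""))
      if (!token %in% existing) return(token)
    }
  })
}

#' md5 digest of raw input bytes
#'
#' Identical uploads map to one digest, which is how distinct users are
#' counted without retaining any traceable information.
#'
#' @param x A raw vector, a path to an existing file, or a character scalar
#'   (digested as its bytes).
#' @return 32-character lowercase hex string.
#' @export
#' @examples
#' source_digest("")  # d41d8cd98f00b204e9800998ecf8427e
source_digest <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && !dir.exists(x)) {
    return(unname(tools::md5sum(x)))
  }
  if (is.character(x)) {
    x <- charToRaw(paste(x, collapse = ""))
  }
  if (!is.raw(x)) {
    dtc_error("dtcprs_bad_input", "source_digest expects raw bytes, a string, or a file path")
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(x, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a fixture file in a given vendor dialect
#'
#' Emits the canonical grammar of each supported dialect from a profile's
#' calls; used to build round-trip tests and synthetic end-to-end inputs.
#'
#' @param profile A `genome_profile`, or a data frame of calls with columns
#'   `rsid`, `chrom`, `pos`, `a1`, `a2`.
#' @param dialect Target dialect.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), the file lines.
#' @export
write_fixture <- function(profile, dialect = DIALECTS, path = NULL) {
  dialect <- match.arg(dialect, DIALECTS)
  calls <- if (inherits(profile, "genome_profile")) profile$calls else profile
  miss <- is.na(calls$a1)
  lines <- switch(
    dialect,
    "23andme" = {
      gt <- ifelse(miss, "--", paste0(calls$a1, calls$a2))
      c("# This data file was generated by a consumer genotyping service.",
        "# rsid\tchromosome\tposition\tgenotype",
        paste(calls$rsid, calls$chrom, calls$pos, gt, sep = "\t"))
    },
    "generic" = {
      gt <- ifelse(miss, "--", paste0(calls$a1, calls$a2))
      paste(calls$rsid, calls$chrom, calls$pos, gt, sep = "\t")
    },
    "ancestry" = {
      a1 <- ifelse(miss, "0", calls$a1)
      a2 <- ifelse(miss, "0", calls$a2)
      c("rsid\tchromosome\tposition\tallele1\tallele2",
        paste(calls$rsid, calls$chrom, calls$pos, a1, a2, sep = "\t"))
    },
    "myheritage" = {
      gt <- ifelse(miss, "--", paste0(calls$a1, calls$a2))
      quote_ <- function(v) paste0("\"", v, "\"")
      c(paste(quote_(c("RSID", "CHROMOSOME", "POSITION", "RESULT")),
              collapse = ","),
        paste(quote_(calls$rsid), quote_(calls$chrom), quote_(calls$pos),
              quote_(gt), sep = ","))
    }
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export a harmonized profile as single-sample VCF
#'
#' Writes VCFv4.2 with one sample column. Genotypes come from the aligned
#' alt-allele dosage produced by [harmonize_profile()]; sites absent from the
#' reference panel are omitted and contigs are ordered 1..22, X, Y, MT.
#'
#' @param profile A harmonized `genome_profile` (see [harmonize_profile()]).
#' @param sites Reference site table (see [read_sites()]).
#' @param path Optional output path; when `NULL` the VCF lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), the VCF lines.
#'   Signals `dtcprs_unharmonized_profile` when the profile has not been
#'   aligned to the panel.
#' @export
write_vcf <- function(profile, sites, path = NULL) {
  if (is.null(profile$aligned)) {
    dtc_error("dtcprs_unharmonized_profile",
              "profile must be harmonized against the reference panel before VCF export")
  }
  al <- profile$aligned
  al <- al[al$status %in% c("aligned", "flipped", "missing"), , drop = FALSE]
  ord <- order(match(al$chrom, chrom_levels()), al$pos)
  al <- al[ord, , drop = FALSE]
  gt <- rep("./.", nrow(al))
  gt[!is.na(al$dosage) & al$dosage == 0] <- "0/0"
  gt[!is.na(al$dosage) & al$dosage == 1] <- "0/1"
  gt[!is.na(al$dosage) & al$dosage == 2] <- "1/1"
  sample_name <- if (is.na(profile$unique_id)) "SAMPLE" else profile$unique_id
  contigs <- unique(al$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=dtcprs-", as.character(utils::packageVersion("dtcprs"))),
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  records <- paste(al$chrom, al$pos, al$rsid, al$ref, al$alt, ".", ".", ".",
                   "GT", gt, sep = "\t")
  lines <- c(header, records)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
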