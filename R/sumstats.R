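#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table of per-variant association records and
#' validates each row. Rows violating the record invariants (p outside
#' (0, 1], non-positive standard error, effect allele not among the
#' variant's two alleles, unparseable numbers) are rejected rather than
#' aborting the read; the number of rejections is reported via a message
#' and attached as the `n_rejected` attribute.
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Optional named character vector mapping the canonical
#'   field names (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`, `n`) to the file's column names, for foreign
#'   dialects. Unmapped optional fields (`chrom`, `pos`) may be absent.
#' @return A tibble of association records with canonical columns, one row
#'   per accepted input row. Attribute `n_rejected` counts dropped rows.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  canonical <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "p", "n")
  if (is.null(column_map)) {
    column_map <- stats::setNames(canonical, canonical)
  }
  required <- setdiff(canonical, c("chrom", "pos"))
  for (field in required) {
    src <- column_map[[field]]
    if (is.null(src) || !src %in% names(raw)) {
      rlang::abort(paste0("mapped column for '", field, "' not in header"))
    }
  }
  get_col <- function(field) {
    src <- column_map[[field]]
    if (!is.null(src) && src %in% names(raw)) raw[[src]] else NA_character_
  }
  records <- tibble::tibble(
    rsid = get_col("rsid"),
    chrom = get_col("chrom"),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    p = suppressWarnings(as.numeric(get_col("p"))),
    n = suppressWarnings(as.integer(get_col("n")))
  )
  ok <- valid_sumstat_rows(records)
  n_rejected <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  message(sprintf("read %d records, rejected %d rows: %s",
                  nrow(records), n_rejected, basename(path)))
  attr(records, "n_rejected") <- n_rejected
  records
}

#' @noRd
valid_sumstat_rows <- function(records) {
  allele_ok <- function(a) {
    !is.na(a) & nzchar(a) & grepl("^[ACGT]+$", a)
  }
  !is.na(records$rsid) & nzchar(records$rsid) &
    allele_ok(records$effect_allele) & allele_ok(records$other_allele) &
    records$effect_allele != records$other_allele &
    !is.na(records$beta) &
    !is.na(records$se) & records$se > 0 &
    !is.na(records$p) & records$p > 0 & records$p <= 1 &
    !is.na(records$n) & records$n > 0
}

#' Write association records as a summary-statistics TSV
#'
#' Writes the canonical nine-column table (`rsid`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `beta`, `se`, `p`, `n`). Numeric fields
#' are written at full precision so that `read_sumstats()` round-trips
#' records exactly.
#'
#' @param records Association-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se", "p", "n")
  out <- tibble::as_tibble(records)
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  out <- out[cols]
  fmt <- function(x) {
    ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 17))
  }
  lines <- c(
    paste(cols, collapse = "\t"),
    do.call(paste, c(list(
      out$rsid,
      ifelse(is.na(out$chrom), "NA", out$chrom),
      ifelse(is.na(out$pos), "NA", as.character(out$pos)),
      out$effect_allele, out$other_allele,
      fmt(out$beta), fmt(out$se), fmt(out$p),
      ifelse(is.na(out$n), "NA", as.character(out$n))
    ), sep = "\t"))
  )
  if (nrow(out) == 0) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

#' Align association records to a reference allele
#'
#' Re-expresses each record's signed effect per copy of `reference_allele`:
#' if the record's effect allele already is the reference allele the record
#' is returned unchanged; if it is the other allele the beta sign is
#' flipped and the allele columns are swapped. Standard error, p-value and
#' sample size never change. Aligning to one allele and back is an exact
#' involution.
#'
#' @param records Association-record tibble.
#' @param reference_allele Character vector (length 1 or `nrow(records)`)
#'   giving the allele each record must be expressed against.
#' @return The aligned record tibble.
#' @export
align_to_allele <- function(records, reference_allele) {
  records <- tibble::as_tibble(records)
  reference_allele <- toupper(rep_len(reference_allele, nrow(records)))
  is_ref <- records$effect_allele == reference_allele
  is_other <- records$other_allele == reference_allele
  bad <- !is_ref & !is_other
  if (any(bad)) {
    rlang::abort(paste0(
      "reference allele matches neither allele for variant(s): ",
      paste(unique(records$rsid[bad]), collapse = ", ")
    ))
  }
  flipped <- records
  flipped$other_allele[is_other] <- records$effect_allele[is_other]
  flipped$effect_allele[is_other] <- reference_allele[is_other]
  flipped$beta[is_other] <- -records$beta[is_other]
  flipped
}

#' Flag strand-ambiguous (palindromic) variants
#'
#' A/T and C/G variants cannot be checked for strand consistency from
#' allele labels alone. All inputs here come from one cohort on one genome
#' build, so no strand flipping is attempted; this helper only lists the
#' ambiguous variants so harmonization can warn about them.
#'
#' @param records Association-record tibble.
#' @return Character vector of palindromic rsids (possibly empty).
#' @export
palindromic_variants <- function(records) {
  pair <- paste(pmin(records$effect_allele, records$other_allele),
                pmax(records$effect_allele, records$other_allele))
  unique(records$rsid[pair %in% c("A T", "C G")])
}
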