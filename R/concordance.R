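#' Flag human-expression vs mouse-knockout direction concordance
#'
#' A gene is concordant when the two evidence sources point the same way:
#' the protective allele increases the gene's expression and knocking the
#' gene out harms lean mass/strength (expression +1, knockout -1), or the
#' protective allele decreases expression and the knockout improves lean
#' mass/strength (expression -1, knockout +1). Both directions known but
#' matching neither pattern is discordant; an unknown direction on either
#' side leaves the gene undetermined.
#'
#' @param evidence Gene-evidence tibble with `expression_direction` and
#'   `knockout_direction` columns (+1, -1 or NA).
#' @return The tibble with a `concordance` column
#'   (`concordant`/`discordant`/`undetermined`).
#' @export
concordant <- function(evidence) {
  evidence <- tibble::as_tibble(evidence)
  e <- evidence$expression_direction
  k <- evidence$knockout_direction
  evidence$concordance <- dplyr::case_when(
    is.na(e) | is.na(k) ~ "undetermined",
    e == -k ~ "concordant",
    TRUE ~ "discordant"
  )
  evidence
}

#' Summarise gene-level concordance and exercise-response evidence
#'
#' @param evidence Gene-evidence tibble (see [gene_evidence_fixture()] for
#'   the expected columns; absent columns count as unknown/none).
#' @return A one-row tibble: `concordant`, `discordant`, `undetermined`,
#'   `knockout_tested`, `knockout_significant`, `exercise_responsive`.
#' @export
concordance_summary <- function(evidence) {
  evidence <- tibble::as_tibble(evidence)
  n <- nrow(evidence)
  col_or <- function(name, default) {
    if (name %in% names(evidence)) evidence[[name]] else rep(default, n)
  }
  flags <- concordant(tibble::tibble(
    expression_direction = col_or("expression_direction", NA_integer_),
    knockout_direction = col_or("knockout_direction", NA_integer_)
  ))$concordance
  ko_dir <- col_or("knockout_direction", NA_integer_)
  ko_sig <- col_or("knockout_significant", NA)
  tested <- !is.na(ko_dir) | (!is.na(ko_sig) & ko_sig)
  significant <- dplyr::coalesce(ko_sig, !is.na(ko_dir)) & tested
  exercise <- col_or("exercise_response", "none")
  tibble::tibble(
    concordant = sum(flags == "concordant"),
    discordant = sum(flags == "discordant"),
    undetermined = sum(flags == "undetermined"),
    knockout_tested = sum(tested),
    knockout_significant = sum(significant),
    exercise_responsive = sum(exercise %in% c("up", "down"))
  )
}

#' Read a gene-evidence table from TSV
#'
#' Columns: `gene`, `expression_direction`, `knockout_direction`
#' (+1/-1/NA), optional `knockout_significant` (logical) and
#' `exercise_response` (`up`/`down`/`none`).
#'
#' @param path TSV path.
#' @return A gene-evidence tibble.
#' @export
read_gene_evidence <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  x <- readr::read_tsv(path, comment = "#", progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  x$expression_direction <- suppressWarnings(as.integer(x$expression_direction))
  x$knockout_direction <- suppressWarnings(as.integer(x$knockout_direction))
  if ("knockout_significant" %in% names(x)) {
    x$knockout_significant <- as.logical(x$knockout_significant)
  }
  bad <- function(d) !is.na(d) & !d %in% c(-1L, 1L)
  if (any(bad(x$expression_direction)) || any(bad(x$knockout_direction))) {
    rlang::abort("directions must be +1, -1 or NA")
  }
  x
}
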