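#' @noRd
pleiosarc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pleiosarc")
  if (!nzchar(path)) rlang::abort(paste0("packaged fixture not found: ", file))
  path
}

#' Published sarcopenia variant panel (78 SNPs)
#'
#' The packaged transcription of the published table of 78 DNA polymorphisms
#' associated with handgrip strength, appendicular lean mass and usual
#' walking pace with consistent effect directions, together with their
#' body-fat-percentage and type-2-diabetes association p-values. P-values
#' are carried both as printed strings (`*_text` columns, with the explicit
#' `NS` marker meaning "not significant, p > 0.005") and as parsed doubles
#' (`NA` where the printed value is `NS`).
#'
#' @return A tibble with one row per variant: `gene`, `rsid`,
#'   `protective_allele`, `risk_allele`, parsed `p_grip`, `p_lean`,
#'   `p_walk`, `p_fat`, `p_t2d` and the printed `*_text` columns.
#' @export
table2_fixture <- function() {
  x <- readr::read_tsv(pleiosarc_extdata("table2_sarcopenia_snps.tsv"),
                       comment = "#", col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  pcols <- c("p_grip", "p_lean", "p_walk", "p_fat", "p_t2d")
  for (pc in pcols) {
    x[[paste0(pc, "_text")]] <- x[[pc]]
    x[[pc]] <- suppressWarnings(as.numeric(ifelse(x[[pc]] == "NS", NA, x[[pc]])))
  }
  x
}

#' Mouse knockout and human expression directions for panel genes
#'
#' Packaged transcription of the knockout evidence: 27 panel genes with a
#' significant (p < 0.05) mouse-knockout effect on lean mass and grip
#' strength (12 decreasing, 15 increasing), with the human
#' protective-allele expression direction for the eight genes where it was
#' reported.
#'
#' @return A tibble with `gene`, `knockout_direction` (+1/-1),
#'   `knockout_significant`, `expression_direction` (+1/-1/NA),
#'   `eqtl_rsid`, `eqtl_allele`.
#' @export
knockout_fixture <- function() {
  readr::read_tsv(pleiosarc_extdata("mouse_knockout_directions.tsv"),
                  comment = "#", progress = FALSE,
                  col_types = readr::cols(
                    gene = "c", knockout_direction = "i",
                    knockout_significant = "l", expression_direction = "i",
                    eqtl_rsid = "c", eqtl_allele = "c"))
}

#' Exercise-responsive panel genes
#'
#' Packaged transcription of the 26 panel genes whose skeletal-muscle mRNA
#' changes significantly after a single bout of resistance exercise
#' (10 upregulated, 16 downregulated).
#'
#' @return A tibble with `gene` and `exercise_response` (`up`/`down`).
#' @export
exercise_fixture <- function() {
  readr::read_tsv(pleiosarc_extdata("exercise_response_genes.tsv"),
                  comment = "#", progress = FALSE,
                  col_types = readr::cols(gene = "c", exercise_response = "c"))
}

#' Combined gene-evidence table for concordance analysis
#'
#' Joins the knockout/expression fixture with the exercise-response fixture
#' into the gene-evidence shape consumed by [concordant()] and
#' [concordance_summary()].
#'
#' @return A tibble with `gene`, `expression_direction`,
#'   `knockout_direction`, `knockout_significant`, `exercise_response`
#'   (`up`/`down`/`none` — `none` for genes absent from the exercise list).
#' @export
gene_evidence_fixture <- function() {
  ko <- knockout_fixture()
  ex <- exercise_fixture()
  genes <- union(ko$gene, ex$gene)
  tibble::tibble(gene = genes) |>
    dplyr::left_join(ko[c("gene", "expression_direction", "knockout_direction",
                          "knockout_significant")], by = "gene") |>
    dplyr::left_join(ex, by = "gene") |>
    dplyr::mutate(
      knockout_significant = dplyr::coalesce(.data$knockout_significant, FALSE),
      exercise_response = dplyr::coalesce(.data$exercise_response, "none")
    )
}
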