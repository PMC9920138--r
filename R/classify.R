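#' Assign nested risk tiers to selected variants
#'
#' Every call starts in the `sarcopenia` tier. It is upgraded to
#' `sarcopenic_obesity` iff its adiposity p-value is below the threshold
#' and the direction is risk-consistent (the risk allele associates with
#' higher body fat), and further to `sarcopenic_diabesity` iff the t2d
#' evidence additionally passes with the risk allele increasing diabetes
#' risk. Direction consistency is read from `beta_fat`/`beta_t2d` when
#' present (betas aligned to the protective allele must be negative, since
#' adiposity and t2d carry benefit direction -1); calls without beta
#' columns — e.g. the packaged published table, which only prints p-values
#' for direction-consistent associations — are treated as consistent
#' whenever a p-value is present. Missing adiposity evidence leaves the
#' call in the sarcopenia tier.
#'
#' @param calls Calls tibble with `p_fat` and `p_t2d` columns (NA = not
#'   significant or missing) and optional `beta_fat`, `beta_t2d`.
#' @param p_threshold Significance threshold (default 0.005, strict `<`).
#' @return `calls` with logical `fat_hit` and `t2d_hit` columns and a
#'   `tier` column in \{`sarcopenia`, `sarcopenic_obesity`,
#'   `sarcopenic_diabesity`\}.
#' @export
assign_tier <- function(calls, p_threshold = 0.005) {
  calls <- tibble::as_tibble(calls)
  n <- nrow(calls)
  pick <- function(name, default) {
    if (name %in% names(calls)) calls[[name]] else rep(default, n)
  }
  p_fat <- pick("p_fat", NA_real_)
  p_t2d <- pick("p_t2d", NA_real_)
  beta_fat <- pick("beta_fat", NA_real_)
  beta_t2d <- pick("beta_t2d", NA_real_)
  # protective-aligned beta < 0 <=> risk allele raises the trait
  cons <- function(beta) is.na(beta) | beta < 0
  fat_hit <- !is.na(p_fat) & p_fat < p_threshold & cons(beta_fat)
  t2d_hit <- !is.na(p_t2d) & p_t2d < p_threshold & cons(beta_t2d)
  calls$fat_hit <- fat_hit
  calls$t2d_hit <- t2d_hit
  calls$tier <- dplyr::case_when(
    fat_hit & t2d_hit ~ "sarcopenic_diabesity",
    fat_hit ~ "sarcopenic_obesity",
    TRUE ~ "sarcopenia"
  )
  calls
}

#' Headline counts over a set of classified calls
#'
#' @param calls Classified calls tibble (from [assign_tier()]); a `gene`
#'   column, when present, defines loci, otherwise each rsid is its own
#'   locus.
#' @return A one-row tibble: `all` (variants), `unique_loci` (distinct gene
#'   labels), `fat_associated`, `t2d_associated`, `diabesity` (both).
#' @export
tier_counts <- function(calls) {
  calls <- tibble::as_tibble(calls)
  loci <- if ("gene" %in% names(calls)) calls$gene else calls$rsid
  tibble::tibble(
    all = nrow(calls),
    unique_loci = dplyr::n_distinct(loci),
    fat_associated = sum(calls$fat_hit),
    t2d_associated = sum(calls$t2d_hit),
    diabesity = sum(calls$tier == "sarcopenic_diabesity")
  )
}

#' Annotate calls with auxiliary-trait associations
#'
#' For each auxiliary trait, aligns that trait's record for each call to
#' the call's protective allele and registers a hit iff p < threshold
#' (strict, matching the "NS means p > 0.005" convention). The stored
#' direction states whether the protective or the risk allele associates
#' with the higher trait value. Records that cannot be aligned to a call's
#' allele pair are skipped with a warning.
#'
#' @param calls Calls tibble (`rsid`, `protective_allele`, `risk_allele`).
#' @param aux_records Named list of association-record tibbles, one per
#'   auxiliary trait.
#' @param p_threshold Hit threshold (default 0.005).
#' @return `calls` with an `aux_hits` list-column (per-call tibble of
#'   `trait`, `p`, `direction`) and attribute `aux_counts`, the per-trait
#'   hit totals.
#' @export
annotate_auxiliary <- function(calls, aux_records, p_threshold = 0.005) {
  calls <- tibble::as_tibble(calls)
  hits <- purrr::imap_dfr(aux_records, function(rec, tr) {
    rec <- tibble::as_tibble(rec)
    m <- dplyr::inner_join(
      rec, calls[c("rsid", "protective_allele", "risk_allele")], by = "rsid")
    alignable <- m$effect_allele == m$protective_allele |
      m$other_allele == m$protective_allele
    if (any(!alignable)) {
      rlang::warn(paste0("skipping unalignable auxiliary record(s) for ",
                         tr, ": ",
                         paste(m$rsid[!alignable], collapse = ", ")))
      m <- m[alignable, , drop = FALSE]
    }
    if (nrow(m) == 0) return(NULL)
    m <- align_to_allele(m, m$protective_allele)
    m <- m[m$p < p_threshold & m$beta != 0, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(rsid = m$rsid, trait = tr, p = m$p,
                   direction = ifelse(m$beta > 0, "protective_raises",
                                      "risk_raises"))
  })
  if (nrow(hits) == 0) {
    calls$aux_hits <- purrr::map(seq_len(nrow(calls)), ~ tibble::tibble(
      trait = character(), p = numeric(), direction = character()))
    attr(calls, "aux_counts") <-
      stats::setNames(integer(length(aux_records)), names(aux_records))
    return(calls)
  }
  calls$aux_hits <- purrr::map(calls$rsid, function(rs) {
    hits[hits$rsid == rs, c("trait", "p", "direction")]
  })
  counts <- table(factor(hits$trait, levels = names(aux_records)))
  attr(calls, "aux_counts") <- stats::setNames(as.integer(counts),
                                               names(aux_records))
  calls
}
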