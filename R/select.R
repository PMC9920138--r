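#' Build the genome-wide discovery list
#'
#' Takes per-trait association records and returns the union of variants
#' reaching each source trait's own discovery threshold. Only traits in a
#' sarcopenia-defining category (`lean_mass`, `strength`, `walking_pace`)
#' contribute; duplicates across sources are collapsed by variant identity
#' (rsid + unordered allele pair).
#'
#' @param per_trait_records Named list of association-record tibbles; names
#'   must match `trait_specs$name`.
#' @param trait_specs Trait-spec tibble with per-trait `discovery_threshold`.
#' @return A tibble of distinct variants (`rsid`, `allele_a`, `allele_b`,
#'   `discovery_p`, `discovery_trait`) with attribute `per_trait_counts`,
#'   the number of distinct variants each source contributed.
#' @export
build_discovery_list <- function(per_trait_records, trait_specs) {
  trait_specs <- validate_trait_specs(trait_specs)
  sarc <- trait_specs$name[trait_specs$category %in%
                             c("lean_mass", "strength", "walking_pace")]
  sources <- intersect(names(per_trait_records), sarc)
  hits <- purrr::map_dfr(sources, function(tr) {
    thr <- trait_specs$discovery_threshold[trait_specs$name == tr]
    rec <- tibble::as_tibble(per_trait_records[[tr]])
    rec <- rec[rec$p < thr, , drop = FALSE]
    if (nrow(rec) == 0) return(NULL)
    tibble::tibble(
      rsid = rec$rsid,
      allele_a = pmin(rec$effect_allele, rec$other_allele),
      allele_b = pmax(rec$effect_allele, rec$other_allele),
      discovery_p = rec$p,
      discovery_trait = tr
    )
  })
  if (nrow(hits) == 0) {
    rlang::warn("no variant passed any discovery threshold")
    out <- tibble::tibble(rsid = character(), allele_a = character(),
                          allele_b = character(), discovery_p = numeric(),
                          discovery_trait = character())
    attr(out, "per_trait_counts") <- stats::setNames(integer(0), character(0))
    return(out)
  }
  counts <- hits |>
    dplyr::distinct(.data$discovery_trait, .data$rsid, .data$allele_a,
                    .data$allele_b) |>
    dplyr::count(.data$discovery_trait, name = "n_variants")
  out <- hits |>
    dplyr::arrange(.data$discovery_p, .data$discovery_trait) |>
    dplyr::distinct(.data$rsid, .data$allele_a, .data$allele_b,
                    .keep_all = TRUE)
  attr(out, "per_trait_counts") <-
    stats::setNames(counts$n_variants, counts$discovery_trait)
  out
}

#' Collapse one variant's records within a trait category
#'
#' When several phenotypes proxy one category (e.g. maximal, relative, left
#' and right handgrip strength all proxy `strength`), the category evidence
#' for a variant is the record with the smallest p-value, aligned to the
#' requested reference allele. Ties are broken by lexicographic trait name.
#'
#' @param records Association-record tibble for one variant and one
#'   category; must carry a `trait` column.
#' @param reference_allele Allele the returned evidence is expressed against.
#' @return A one-row tibble (`trait`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`, `n`).
#' @export
collapse_category <- function(records, reference_allele) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    rlang::abort("no record available for this category")
  }
  aligned <- align_to_allele(records, reference_allele)
  aligned |>
    dplyr::arrange(.data$p, .data$trait) |>
    dplyr::slice(1)
}

#' Harmonize per-trait evidence to per-variant, per-category evidence
#'
#' Stacks all traits' records, aligns every record for a variant to one
#' canonical reference allele (the lexicographically smaller of the two),
#' and collapses each trait category to its minimum-p record. Variants
#' whose allele pairs disagree across sources are dropped with a warning;
#' strand-ambiguous (A/T, C/G) variants are kept but listed in a warning.
#'
#' @param per_trait_records Named list of association-record tibbles.
#' @param trait_specs Trait-spec tibble.
#' @param variants Optional variant tibble (e.g. a discovery list) to
#'   restrict harmonization to; matched by rsid + unordered allele pair.
#' @return A long tibble with one row per variant x category: `rsid`,
#'   `allele_a`, `allele_b`, `reference_allele`, `category`, `trait`,
#'   `beta`, `se`, `p` (beta expressed per copy of `reference_allele`).
#' @export
harmonize_evidence <- function(per_trait_records, trait_specs,
                               variants = NULL) {
  trait_specs <- validate_trait_specs(trait_specs)
  stacked <- purrr::imap_dfr(per_trait_records, function(rec, tr) {
    if (!tr %in% trait_specs$name) return(NULL)
    rec <- tibble::as_tibble(rec)
    rec$trait <- tr
    rec$category <- trait_specs$category[trait_specs$name == tr]
    rec
  })
  if (nrow(stacked) == 0) {
    rlang::warn("no records to harmonize")
    return(tibble::tibble(rsid = character(), allele_a = character(),
                          allele_b = character(),
                          reference_allele = character(),
                          category = character(), trait = character(),
                          beta = numeric(), se = numeric(), p = numeric()))
  }
  stacked$allele_a <- pmin(stacked$effect_allele, stacked$other_allele)
  stacked$allele_b <- pmax(stacked$effect_allele, stacked$other_allele)

  # one allele pair per rsid across sources
  pairs <- dplyr::distinct(stacked, .data$rsid, .data$allele_a, .data$allele_b)
  clash <- pairs$rsid[duplicated(pairs$rsid)]
  if (length(clash) > 0) {
    rlang::warn(paste0("dropping variant(s) with inconsistent allele pairs: ",
                       paste(unique(clash), collapse = ", ")))
    stacked <- stacked[!stacked$rsid %in% clash, , drop = FALSE]
  }
  pal <- palindromic_variants(stacked)
  if (length(pal) > 0) {
    rlang::warn(paste0("strand-ambiguous (palindromic) variant(s), matched ",
                       "by rsid and allele set without strand flipping: ",
                       paste(utils::head(pal, 10), collapse = ", "),
                       if (length(pal) > 10) " ..." else ""))
  }
  if (!is.null(variants)) {
    keep <- paste(variants$rsid, pmin(variants$allele_a, variants$allele_b),
                  pmax(variants$allele_a, variants$allele_b))
    stacked <- stacked[paste(stacked$rsid, stacked$allele_a,
                             stacked$allele_b) %in% keep, , drop = FALSE]
  }
  aligned <- align_to_allele(stacked, stacked$allele_a)
  aligned$reference_allele <- aligned$allele_a
  aligned |>
    dplyr::group_by(.data$rsid, .data$category) |>
    dplyr::arrange(.data$p, .data$trait, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("rsid", "allele_a", "allele_b", "reference_allele",
                  "category", "trait", "beta", "se", "p")
}

#' Select pleiotropic sarcopenia variants
#'
#' Implements the replication stage: a discovery-list variant is selected
#' iff its collapsed evidence in all three sarcopenia categories
#' (`lean_mass`, `strength`, `walking_pace`) has p below the replication
#' threshold and the effect directions are consistent — the signs of the
#' aligned betas, multiplied by each category's benefit direction, all
#' agree. The allele whose effects all point in the benefit direction is
#' reported as the protective allele. Adiposity and t2d evidence, where
#' present in the harmonized table, is carried along aligned to the
#' protective allele for downstream tier classification.
#'
#' @param discovery Discovery-list tibble from [build_discovery_list()].
#' @param harmonized Long evidence tibble from [harmonize_evidence()].
#' @param trait_specs Trait-spec tibble.
#' @param replication_threshold Replication p-value threshold (default
#'   0.005), applied to all three sarcopenia categories.
#' @return A calls tibble, one row per selected variant: `rsid`,
#'   `allele_a`, `allele_b`, `protective_allele`, `risk_allele`,
#'   per-category evidence aligned to the protective allele (`p_grip`,
#'   `beta_grip`, `p_lean`, `beta_lean`, `p_walk`, `beta_walk`, and
#'   `p_fat`/`beta_fat`, `p_t2d`/`beta_t2d` when available),
#'   `discovery_p` and `discovery_trait`. Attribute `exclusions` records
#'   dropped variants and reasons.
#' @export
select_pleiotropic <- function(discovery, harmonized, trait_specs,
                               replication_threshold = 0.005) {
  trait_specs <- validate_trait_specs(trait_specs)
  bdir <- stats::setNames(trait_specs$benefit_direction, trait_specs$category)
  bdir <- bdir[!duplicated(names(bdir))]
  sarc <- c("lean_mass", "strength", "walking_pace")

  ev <- harmonized[harmonized$rsid %in% discovery$rsid, , drop = FALSE]
  wide <- ev |>
    dplyr::mutate(benefit = unname(bdir[.data$category])) |>
    tidyr::nest(.by = "rsid")

  exclusions <- list()
  calls <- purrr::pmap_dfr(wide, function(rsid, data) {
    d <- data
    miss <- setdiff(sarc, d$category)
    if (length(miss) > 0) {
      exclusions[[rsid]] <<- paste0("missing category evidence: ",
                                    paste(miss, collapse = ", "))
      return(NULL)
    }
    s <- d[match(sarc, d$category), ]
    if (any(s$p >= replication_threshold)) {
      exclusions[[rsid]] <<- "replication p above threshold"
      return(NULL)
    }
    if (any(s$beta == 0)) {
      exclusions[[rsid]] <<- "zero beta: direction undefined"
      return(NULL)
    }
    orient <- sign(s$beta) * s$benefit  # +1: reference allele protective
    if (length(unique(orient)) != 1) {
      exclusions[[rsid]] <<- "inconsistent effect directions"
      return(NULL)
    }
    ref <- d$reference_allele[1]
    other <- ifelse(d$allele_a[1] == ref, d$allele_b[1], d$allele_a[1])
    protective <- if (orient[1] > 0) ref else other
    risk <- if (orient[1] > 0) other else ref
    flip <- if (protective == ref) 1 else -1
    grab <- function(cat, what) {
      i <- match(cat, d$category)
      if (is.na(i)) return(NA_real_)
      if (what == "p") d$p[i] else flip * d$beta[i]
    }
    tibble::tibble(
      rsid = rsid, allele_a = d$allele_a[1], allele_b = d$allele_b[1],
      protective_allele = protective, risk_allele = risk,
      p_grip = grab("strength", "p"), beta_grip = grab("strength", "b"),
      p_lean = grab("lean_mass", "p"), beta_lean = grab("lean_mass", "b"),
      p_walk = grab("walking_pace", "p"), beta_walk = grab("walking_pace", "b"),
      p_fat = grab("adiposity", "p"), beta_fat = grab("adiposity", "b"),
      p_t2d = grab("t2d", "p"), beta_t2d = grab("t2d", "b")
    )
  })
  if (nrow(calls) > 0) {
    calls <- dplyr::left_join(
      calls, discovery[c("rsid", "discovery_p", "discovery_trait")],
      by = "rsid")
  }
  attr(calls, "exclusions") <- exclusions
  calls
}
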