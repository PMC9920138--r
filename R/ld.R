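#' Pairwise linkage disequilibrium (r-squared) between two panel variants
#'
#' Computes composite (unphased) LD as the squared Pearson correlation of
#' the two dosage vectors over pairwise-complete samples. A constant dosage
#' vector on the shared samples leaves the correlation undefined; such
#' pairs are reported with `r2 = NA` (pruning treats them as 0 and logs
#' them).
#'
#' @param panel A `genotype_panel`.
#' @param variant_i,variant_j rsids of the two variants.
#' @return A one-row tibble: `variant_i`, `variant_j`, `r2`, `n_used`.
#' @export
r_squared <- function(panel, variant_i, variant_j) {
  i <- match(variant_i, panel$variants$rsid)
  j <- match(variant_j, panel$variants$rsid)
  if (is.na(i) || is.na(j)) {
    rlang::abort("both variants must be present in the panel")
  }
  x <- panel$dosages[, i]
  y <- panel$dosages[, j]
  ok <- !is.na(x) & !is.na(y)
  n_used <- sum(ok)
  if (n_used < 2) rlang::abort("fewer than 2 pairwise-complete samples")
  x <- x[ok]; y <- y[ok]
  r2 <- if (stats::var(x) == 0 || stats::var(y) == 0) {
    NA_real_
  } else {
    stats::cor(x, y)^2
  }
  tibble::tibble(variant_i = variant_i, variant_j = variant_j,
                 r2 = r2, n_used = as.integer(n_used))
}

#' @noRd
pairwise_r2 <- function(panel, rsids) {
  idx <- match(rsids, panel$variants$rsid)
  d <- panel$dosages[, idx, drop = FALSE]
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  r^2
}

#' Greedily prune a candidate set to LD-independent variants
#'
#' Iterates the candidates best-first and retains a candidate iff its
#' r-squared with every already-retained, panel-covered candidate is at or
#' below the threshold. By default candidates are ranked by ascending
#' minimum p across the three sarcopenia categories (strongest signal
#' kept); pass `rank_by = NULL` to keep the input order. Candidates absent
#' from the panel pass through with a warning. Undefined LD (constant
#' dosage) counts as 0 and is logged.
#'
#' @param candidates Calls tibble (needs `rsid`; for the default ranking
#'   also `p_grip`, `p_lean`, `p_walk`).
#' @param panel A `genotype_panel`.
#' @param r2_threshold Maximum r-squared between retained variants
#'   (default 0.2).
#' @param rank_by Optional numeric vector (ascending rank key) overriding
#'   the default min-p ranking; `NULL` keeps input order.
#' @return The retained subset of `candidates`, rank order preserved, with
#'   attribute `pruned`: a tibble of removed variants and the retained
#'   variant each one clashed with.
#' @export
greedy_prune <- function(candidates, panel, r2_threshold = 0.2,
                         rank_by = "min_p") {
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0) {
    attr(candidates, "pruned") <- tibble::tibble(
      rsid = character(), clashed_with = character(), r2 = numeric())
    return(candidates)
  }
  key <- if (is.null(rank_by)) {
    seq_len(nrow(candidates))
  } else if (is.numeric(rank_by)) {
    rank_by
  } else {
    pmin(candidates$p_grip, candidates$p_lean, candidates$p_walk,
         na.rm = TRUE)
  }
  ord <- order(key, candidates$rsid)
  cand <- candidates[ord, , drop = FALSE]

  in_panel <- cand$rsid %in% panel$variants$rsid
  if (any(!in_panel)) {
    rlang::warn(paste0("candidate(s) not covered by the panel retained ",
                       "without LD check: ",
                       paste(cand$rsid[!in_panel], collapse = ", ")))
  }
  covered <- cand$rsid[in_panel]
  r2m <- if (length(covered) >= 2) pairwise_r2(panel, covered) else NULL
  if (!is.null(r2m) && anyNA(r2m)) {
    rlang::warn("undefined LD for constant dosage vector(s); treated as r2 = 0")
    r2m[is.na(r2m)] <- 0
  }

  keep <- logical(nrow(cand))
  pruned <- list()
  kept_cov <- character(0)
  for (k in seq_len(nrow(cand))) {
    if (!in_panel[k]) { keep[k] <- TRUE; next }
    rs <- cand$rsid[k]
    if (length(kept_cov) == 0) {
      keep[k] <- TRUE; kept_cov <- rs; next
    }
    r2s <- r2m[rs, kept_cov]
    if (all(r2s <= r2_threshold)) {
      keep[k] <- TRUE
      kept_cov <- c(kept_cov, rs)
    } else {
      worst <- which.max(r2s)
      pruned[[rs]] <- tibble::tibble(
        rsid = rs, clashed_with = kept_cov[worst],
        r2 = as.numeric(r2s[worst]))
    }
  }
  out <- cand[keep, , drop = FALSE]
  attr(out, "pruned") <- if (length(pruned)) dplyr::bind_rows(pruned) else
    tibble::tibble(rsid = character(), clashed_with = character(),
                   r2 = numeric())
  out
}

#' Write a pairwise LD table for a variant set
#'
#' @param panel A `genotype_panel`.
#' @param rsids Variants to tabulate (all unordered pairs).
#' @param path Optional TSV output path.
#' @return Tibble with `variant_i`, `variant_j`, `r2`, `n_used`.
#' @export
ld_table <- function(panel, rsids, path = NULL) {
  rsids <- intersect(rsids, panel$variants$rsid)
  if (length(rsids) < 2) {
    out <- tibble::tibble(variant_i = character(), variant_j = character(),
                          r2 = numeric(), n_used = integer())
  } else {
    pairs <- utils::combn(rsids, 2)
    out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      r_squared(panel, pairs[1, k], pairs[2, k])
    })
  }
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}
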