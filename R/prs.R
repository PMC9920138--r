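#' Unweighted polygenic risk-allele score
#'
#' Counts risk alleles per individual over a variant set: each variant
#' contributes 0, 1 or 2 copies of its designated risk allele (homozygous
#' non-risk, heterozygous, homozygous risk). Missing genotypes contribute 0
#' and are reported per sample so downstream users can see how complete
#' each score is.
#'
#' @param panel A `genotype_panel`.
#' @param risk_alleles Tibble mapping variants to risk alleles (`rsid`,
#'   `risk_allele`); every listed variant must be in the panel with the
#'   risk allele among its two alleles.
#' @return Tibble with `sample_id`, `score` (integer) and `n_missing`
#'   (missing genotypes among the scored variants).
#' @export
risk_score <- function(panel, risk_alleles) {
  risk_alleles <- tibble::as_tibble(risk_alleles)
  i <- match(risk_alleles$rsid, panel$variants$rsid)
  if (anyNA(i)) {
    rlang::abort(paste0("variant(s) not in panel: ",
                        paste(risk_alleles$rsid[is.na(i)], collapse = ", ")))
  }
  v <- panel$variants[i, ]
  ok <- risk_alleles$risk_allele == v$allele_a |
    risk_alleles$risk_allele == v$allele_b
  if (any(!ok)) {
    rlang::abort(paste0("risk allele not in the variant's allele pair: ",
                        paste(risk_alleles$rsid[!ok], collapse = ", ")))
  }
  d <- panel$dosages[, i, drop = FALSE]
  flip <- risk_alleles$risk_allele != v$counted_allele
  if (any(flip)) {
    d[, flip] <- 2L - d[, flip, drop = FALSE]
  }
  n_missing <- rowSums(is.na(d))
  d[is.na(d)] <- 0L
  tibble::tibble(sample_id = panel$sample_ids,
                 score = as.integer(rowSums(d)),
                 n_missing = as.integer(n_missing))
}

#' Stratify individuals into ordered risk bands
#'
#' Sorts samples ascending by (score, sample_id) and splits them into
#' `n_bands` consecutive groups whose sizes differ by at most one, the
#' remainder going to the lowest bands first (503 samples in 5 bands gives
#' 101/101/101/100/100). Each band reports its observed minimum and
#' maximum score and its size; labels run from `low` (fewest risk alleles)
#' to `high`.
#'
#' @param scores Tibble from [risk_score()] (`sample_id`, `score`).
#' @param n_bands Number of bands (default 5).
#' @param trait_label Label carried on the resulting table (e.g.
#'   `"sarcopenia"`).
#' @param n_snps Number of variants behind the score (bounds the score
#'   range at `2 * n_snps`); inferred as `max(score)/2`-safe upper bound
#'   only if supplied.
#' @return A `risk_band_table`: tibble with `band`, `min_alleles`,
#'   `max_alleles`, `n_individuals`, plus attributes `trait_label`,
#'   `n_snps` and `assignments` (per-sample band membership).
#' @export
stratify <- function(scores, n_bands = 5, trait_label = "sarcopenia",
                     n_snps = NULL) {
  scores <- tibble::as_tibble(scores)
  n <- nrow(scores)
  if (n < n_bands) rlang::abort("fewer samples than bands")
  labels <- if (n_bands == 5) {
    c("low", "below_average", "average", "above_average", "high")
  } else {
    paste0("band_", seq_len(n_bands))
  }
  ord <- order(scores$score, scores$sample_id)
  base <- n %/% n_bands
  rem <- n %% n_bands
  sizes <- rep(base, n_bands) + c(rep(1L, rem), rep(0L, n_bands - rem))
  band_idx <- rep(seq_len(n_bands), sizes)

  assignments <- tibble::tibble(
    sample_id = scores$sample_id[ord],
    score = scores$score[ord],
    band = labels[band_idx]
  )
  bands <- assignments |>
    dplyr::group_by(band = factor(.data$band, levels = labels)) |>
    dplyr::summarise(min_alleles = min(.data$score),
                     max_alleles = max(.data$score),
                     n_individuals = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(band = as.character(.data$band))
  if (!is.null(n_snps) && max(bands$max_alleles) > 2 * n_snps) {
    rlang::abort("scores exceed 2 * n_snps")
  }
  structure(bands,
            class = c("risk_band_table", class(bands)),
            trait_label = trait_label,
            n_snps = n_snps,
            assignments = assignments)
}

#' @export
print.risk_band_table <- function(x, ...) {
  cat(sprintf("Risk-band table: %s (%s SNPs)\n", attr(x, "trait_label"),
              ifelse(is.null(attr(x, "n_snps")), "?", attr(x, "n_snps"))))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a risk-band table
#'
#' @param x A `risk_band_table`.
#' @param ... Unused.
#' @return One row per band: `trait_label`, `band`, `min_alleles`,
#'   `max_alleles`, `n_individuals`.
#' @method tidy risk_band_table
#' @export
tidy.risk_band_table <- function(x, ...) {
  tibble::tibble(trait_label = attr(x, "trait_label"),
                 band = x$band, min_alleles = x$min_alleles,
                 max_alleles = x$max_alleles,
                 n_individuals = x$n_individuals)
}

#' One-row summary of a risk-band table
#'
#' @param x A `risk_band_table`.
#' @param ... Unused.
#' @return A one-row tibble: `trait_label`, `n_snps`, `n_bands`,
#'   `n_individuals`, `score_min`, `score_max`.
#' @method glance risk_band_table
#' @export
glance.risk_band_table <- function(x, ...) {
  tibble::tibble(
    trait_label = attr(x, "trait_label"),
    n_snps = ifelse(is.null(attr(x, "n_snps")), NA_integer_,
                    as.integer(attr(x, "n_snps"))),
    n_bands = nrow(x),
    n_individuals = sum(x$n_individuals),
    score_min = min(x$min_alleles),
    score_max = max(x$max_alleles)
  )
}

#' Plot the risk-allele score distribution behind a band table
#'
#' Histogram of per-sample risk-allele counts coloured by band.
#'
#' @param object A `risk_band_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_band_table
#' @export
autoplot.risk_band_table <- function(object, ...) {
  a <- attr(object, "assignments")
  a$band <- factor(a$band, levels = object$band)
  ggplot2::ggplot(a, ggplot2::aes(x = .data$score, fill = .data$band)) +
    ggplot2::geom_histogram(binwidth = 1, colour = "grey30") +
    ggplot2::labs(x = "risk-allele count", y = "individuals",
                  fill = "risk band",
                  title = paste0("Unweighted polygenic score: ",
                                 attr(object, "trait_label"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
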