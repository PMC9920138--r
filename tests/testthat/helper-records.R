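# Builders for small association-record tibbles used across tests.

make_records <- function(n = 1, rsid = sprintf("rs%05d", seq_len(n)),
                         effect_allele = "A", other_allele = "G",
                         beta = 0.1, se = 0.01, p = 1e-10, n_gwas = 100000L,
                         chrom = NA_character_, pos = NA_integer_) {
  tibble::tibble(
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = rep_len(effect_allele, n),
    other_allele = rep_len(other_allele, n),
    beta = rep_len(beta, n), se = rep_len(se, n), p = rep_len(p, n),
    n = rep_len(as.integer(n_gwas), n)
  )
}

random_records <- function(n, prefix = "rs", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2,
                  byrow = TRUE)
  k <- sample.int(4, n, replace = TRUE)
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ea <- ifelse(swap, pairs[k, 2], pairs[k, 1])
  oa <- ifelse(swap, pairs[k, 1], pairs[k, 2])
  tibble::tibble(
    rsid = sprintf("%s%06d", prefix, seq_len(n)),
    chrom = sample(as.character(1:22), n, replace = TRUE),
    pos = sample.int(1e8, n),
    effect_allele = ea, other_allele = oa,
    beta = stats::rnorm(n, 0, 0.05),
    se = stats::runif(n, 0.001, 0.05),
    p = stats::runif(n),
    n = sample.int(500000L, n)
  )
}

# A tiny deterministic panel built by hand: dosages given as a matrix.
toy_panel <- function(dosages, counted = NULL) {
  m <- ncol(dosages)
  variants <- tibble::tibble(
    rsid = sprintf("rs%05d", seq_len(m)),
    chrom = "1", pos = seq_len(m) * 100L,
    allele_a = rep("A", m), allele_b = rep("G", m),
    counted_allele = if (is.null(counted)) rep("G", m) else counted
  )
  genotype_panel(sprintf("S%03d", seq_len(nrow(dosages))), variants, dosages)
}

# Pearson r^2 computed from explicit sums (independent of stats::cor).
r2_from_definition <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  num <- n * sxy - sx * sy
  den <- (n * sxx - sx^2) * (n * syy - sy^2)
  num^2 / den
}
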