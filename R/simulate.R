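#' Simulation configuration
#'
#' Bundles the parameters of the synthetic genotype panel and the synthetic
#' multi-trait GWAS. Defaults describe the study conditions the pipeline is
#' designed for: a reference panel of 503 European-ancestry individuals,
#' common variants (MAF 0.05-0.5) in blocks of 10 with exchangeable
#' within-block haplotype correlation, GWAS sample sizes near 450,000, and
#' standardized per-allele effects of 0.04 for planted signals. Of the
#' planted pleiotropic variants, a fraction `prop_fat` (default 55/78) is
#' additionally loaded on adiposity and a fraction `prop_t2d` of those
#' (default 21/55) on type-2 diabetes, mirroring the nested tier structure
#' the classifier expects.
#'
#' @param n_samples Panel size (individuals).
#' @param n_variants Number of variants.
#' @param maf_range Interval in (0, 0.5] from which variant MAFs are drawn.
#' @param ld_block_size Variants per LD block.
#' @param ld_rho Within-block latent haplotype correlation, in [0, 1).
#' @param n_causal_pleiotropic Number of planted direction-consistent
#'   pleiotropic variants (loaded on all three sarcopenia categories);
#'   defaults to 1% of `n_variants` (20 under the default panel size).
#' @param n_causal_single_trait Number of planted single-trait variants;
#'   defaults to 1% of `n_variants`.
#' @param effect_size Standardized per-allele effect of planted signals.
#' @param gwas_n Per-trait GWAS sample size.
#' @param prop_fat Fraction of pleiotropic variants also loaded on adiposity.
#' @param prop_t2d Fraction of adiposity-loaded variants also loaded on t2d.
#' @param missing_rate Per-entry genotype missingness probability.
#' @param trait_specs Trait-spec tibble (see [default_trait_specs()]).
#' @param seed Integer seed; every simulation draw derives from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 503L,
                              n_variants = 2000L,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 10L,
                              ld_rho = 0,
                              n_causal_pleiotropic = NULL,
                              n_causal_single_trait = NULL,
                              effect_size = 0.04,
                              gwas_n = 450000L,
                              prop_fat = 55 / 78,
                              prop_t2d = 21 / 55,
                              missing_rate = 0,
                              trait_specs = default_trait_specs(),
                              seed = 1L) {
  if (is.null(n_causal_pleiotropic)) {
    n_causal_pleiotropic <- round(0.01 * n_variants)
  }
  if (is.null(n_causal_single_trait)) {
    n_causal_single_trait <- round(0.01 * n_variants)
  }
  cfg <- list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range), ld_block_size = as.integer(ld_block_size),
    ld_rho = as.numeric(ld_rho),
    n_causal_pleiotropic = as.integer(n_causal_pleiotropic),
    n_causal_single_trait = as.integer(n_causal_single_trait),
    effect_size = as.numeric(effect_size), gwas_n = as.integer(gwas_n),
    prop_fat = as.numeric(prop_fat), prop_t2d = as.numeric(prop_t2d),
    missing_rate = as.numeric(missing_rate),
    trait_specs = validate_trait_specs(trait_specs),
    seed = as.integer(seed)
  )
  if (cfg$n_variants < 1) rlang::abort("n_variants must be positive")
  if (cfg$n_samples < 1) rlang::abort("n_samples must be positive")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) rlang::abort("ld_rho must lie in [0, 1)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    rlang::abort("maf_range must be an interval within (0, 0.5]")
  }
  if (cfg$n_causal_pleiotropic + cfg$n_causal_single_trait > cfg$n_variants) {
    rlang::abort("more causal variants requested than variants simulated")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    rlang::abort("missing_rate must lie in [0, 1)")
  }
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override the [simulation_config()] defaults; a `traits:`
#' block, if present, replaces the default trait specs.
#'
#' @param path YAML file path.
#' @return A `simulation_config` object.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  traits <- y$traits
  y$traits <- NULL
  args <- y[names(y) %in% names(formals(simulation_config))]
  if (!is.null(traits)) args$trait_specs <- read_trait_specs_list(traits)
  do.call(simulation_config, args)
}

#' @noRd
read_trait_specs_list <- function(traits) {
  specs <- purrr::map_dfr(traits, function(t) {
    tibble::tibble(
      name = as.character(t$name), category = as.character(t$category),
      benefit_direction = as.numeric(t$benefit_direction),
      discovery_threshold = as.numeric(t$discovery_threshold),
      replication_threshold = as.numeric(t$replication_threshold),
      n = as.integer(t$n)
    )
  })
  validate_trait_specs(specs)
}

#' Construct a genotype panel object
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param variants Tibble with one row per variant: `rsid`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `counted_allele` (the allele dosages count).
#' @param dosages Integer matrix, samples x variants, entries in
#'   \{0, 1, 2, NA\}.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(sample_ids, variants, dosages) {
  variants <- tibble::as_tibble(variants)
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2)) {
    rlang::abort("dosage entries must be 0, 1, 2 or NA")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$rsid
  structure(list(sample_ids = sample_ids, variants = variants,
                 dosages = dosages),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants; missing %.3f%%\n",
              length(x$sample_ids), nrow(x$variants),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Counted-allele frequencies of a genotype panel
#'
#' @param panel A `genotype_panel`.
#' @return Tibble with `rsid`, `freq` (counted-allele frequency over
#'   non-missing genotypes) and `n_called`.
#' @export
panel_frequencies <- function(panel) {
  n_called <- colSums(!is.na(panel$dosages))
  freq <- colSums(panel$dosages, na.rm = TRUE) / (2 * n_called)
  tibble::tibble(rsid = panel$variants$rsid, freq = as.numeric(freq),
                 n_called = as.integer(n_called))
}

#' Simulate a genotype reference panel with block LD
#'
#' Haplotypes are generated from a latent Gaussian with exchangeable
#' within-block correlation `ld_rho`: per individual and haplotype, one
#' block-level factor plus independent noise is thresholded at each
#' variant's MAF quantile to give an allele indicator, and the two
#' haplotypes are summed to a dosage in \{0, 1, 2\}. This yields a known
#' block-diagonal LD ground truth and Hardy-Weinberg genotype proportions.
#' Variants within a block share one MAF (drawn per block from `maf_range`),
#' as tightly linked real variants do; with strongly different thresholds a
#' high latent correlation would not translate into high dosage r-squared.
#'
#' @param config A [simulation_config()].
#' @return A `genotype_panel`; the attribute `maf` records the target MAFs.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  block <- ((seq_len(m) - 1L) %/% config$ld_block_size) + 1L
  maf_block <- stats::runif(max(block), config$maf_range[1],
                            config$maf_range[2])
  maf <- maf_block[block]
  rho <- config$ld_rho
  thresh <- stats::qnorm(maf)

  hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0) {
      nb <- max(block)
      u <- matrix(stats::rnorm(n * nb), n, nb)
      z <- sqrt(rho) * u[, block, drop = FALSE] + sqrt(1 - rho) * z
    }
    # threshold latent value at the MAF quantile -> allele indicator
    sweep(z, 2, thresh, "<") * 1L
  }
  dos <- hap() + hap()
  if (config$missing_rate > 0) {
    dos[stats::runif(length(dos)) < config$missing_rate] <- NA_integer_
  }

  pairs <- c("A/G", "C/T", "A/C", "G/T")[sample.int(4, m, replace = TRUE)]
  alleles <- strsplit(pairs, "/", fixed = TRUE)
  variants <- tibble::tibble(
    rsid = sprintf("rs%06d", seq_len(m)),
    chrom = as.character(block),
    pos = as.integer(seq_len(m) * 1000L),
    allele_a = purrr::map_chr(alleles, 1),
    allele_b = purrr::map_chr(alleles, 2),
    counted_allele = purrr::map_chr(alleles, 2)
  )
  panel <- genotype_panel(sprintf("S%04d", seq_len(n)), variants, dos)
  attr(panel, "maf") <- maf
  attr(panel, "block") <- block
  panel
}

#' Planted causal structure for a simulated panel
#'
#' Deterministically (from the config seed) assigns `n_causal_pleiotropic`
#' variants loaded on all three sarcopenia categories with a common
#' protective allele, of which a `prop_fat` share is also loaded on
#' adiposity and a `prop_t2d` share of those on t2d; `n_causal_single_trait`
#' further variants are loaded on one random sarcopenia category each.
#'
#' @param panel A `genotype_panel` from [simulate_panel()].
#' @param config The matching [simulation_config()].
#' @return Tibble with `rsid`, `kind` (`pleiotropic`/`single_trait`),
#'   `protective_allele` and logical loading columns `on_lean`,
#'   `on_strength`, `on_walk`, `on_fat`, `on_t2d`.
#' @export
planted_truth <- function(panel, config) {
  set.seed(config$seed + 1000L)
  m <- nrow(panel$variants)
  k_p <- config$n_causal_pleiotropic
  k_s <- config$n_causal_single_trait
  idx <- sample.int(m, k_p + k_s)
  idx_p <- idx[seq_len(k_p)]
  idx_s <- idx[k_p + seq_len(k_s)]
  n_fat <- round(config$prop_fat * k_p)
  n_t2d <- round(config$prop_t2d * n_fat)
  sarc <- c("lean", "strength", "walk")
  single_cat <- if (k_s > 0) sample(sarc, k_s, replace = TRUE) else character(0)
  prot_is_counted <- stats::runif(k_p + k_s) < 0.5
  v <- panel$variants[idx, ]
  tibble::tibble(
    rsid = v$rsid,
    kind = rep(c("pleiotropic", "single_trait"), c(k_p, k_s)),
    protective_allele = ifelse(prot_is_counted, v$counted_allele,
                               ifelse(v$counted_allele == v$allele_a,
                                      v$allele_b, v$allele_a)),
    on_lean = c(rep(TRUE, k_p), single_cat == "lean"),
    on_strength = c(rep(TRUE, k_p), single_cat == "strength"),
    on_walk = c(rep(TRUE, k_p), single_cat == "walk"),
    on_fat = c(seq_len(k_p) <= n_fat, rep(FALSE, k_s)),
    on_t2d = c(seq_len(k_p) <= n_t2d, rep(FALSE, k_s))
  )
}

#' Simulate multi-trait GWAS summary statistics from a panel
#'
#' For each trait in the config's trait specs and each polymorphic panel
#' variant, the true standardized per-allele effect (aligned to the planted
#' protective allele) is `benefit_direction * effect_size` where the
#' variant is loaded on the trait's category and 0 otherwise. The Wald
#' machinery is then simulated directly: `se = 1 / sqrt(2 * gwas_n * f *
#' (1 - f))` with `f` the panel counted-allele frequency, the observed beta
#' is drawn from Normal(true beta, se^2), and the p-value is the two-sided
#' normal tail of beta/se. Binary-trait (t2d) effects are generated on the
#' same standardized scale and labeled log-odds. Monomorphic variants are
#' skipped with a warning.
#'
#' @param panel A `genotype_panel`.
#' @param config The matching [simulation_config()].
#' @return A named list (one association-record tibble per trait) with the
#'   [planted_truth()] table attached as attribute `truth`.
#' @export
simulate_sumstats <- function(panel, config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- planted_truth(panel, config)
  set.seed(config$seed + 2000L)
  fr <- panel_frequencies(panel)
  mono <- fr$freq <= 0 | fr$freq >= 1 | is.na(fr$freq)
  if (any(mono)) {
    rlang::warn(sprintf("skipping %d monomorphic variant(s)", sum(mono)))
  }
  v <- panel$variants[!mono, ]
  f <- fr$freq[!mono]
  se <- 1 / sqrt(2 * config$gwas_n * f * (1 - f))

  tr <- match(v$rsid, truth$rsid)
  prot <- truth$protective_allele[tr]              # NA for null variants
  # sign of the counted allele relative to the protective allele
  prot_sign <- ifelse(is.na(prot), 0, ifelse(prot == v$counted_allele, 1, -1))
  loading <- function(category) {
    on <- switch(category,
      lean_mass = truth$on_lean, strength = truth$on_strength,
      walking_pace = truth$on_walk, adiposity = truth$on_fat,
      t2d = truth$on_t2d, rep(FALSE, nrow(truth)))
    out <- on[tr]
    out[is.na(out)] <- FALSE
    out
  }

  specs <- config$trait_specs
  records <- purrr::map(seq_len(nrow(specs)), function(i) {
    bdir <- specs$benefit_direction[i]
    beta_true <- ifelse(loading(specs$category[i]),
                        prot_sign * bdir * config$effect_size, 0)
    beta <- stats::rnorm(length(se), beta_true, se)
    tibble::tibble(
      rsid = v$rsid, chrom = v$chrom, pos = v$pos,
      effect_allele = v$counted_allele,
      other_allele = ifelse(v$counted_allele == v$allele_a,
                            v$allele_b, v$allele_a),
      beta = beta, se = se,
      p = 2 * stats::pnorm(-abs(beta / se)),
      n = config$gwas_n
    )
  })
  names(records) <- specs$name
  attr(records, "truth") <- truth
  records
}

#' Write a genotype panel as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 with GT fields; the panel's `allele_a` is REF,
#' `allele_b` is ALT, and dosages count the counted allele. Missing
#' genotypes are written as `./.`.
#'
#' @param panel A `genotype_panel`.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  # dosage of ALT (= allele_b) regardless of which allele is counted
  alt_dos <- t(panel$dosages)
  flip <- v$counted_allele != v$allele_b
  alt_dos[flip, ] <- 2L - alt_dos[flip, , drop = FALSE]
  gt <- matrix(c("0/0", "0/1", "1/1")[alt_dos + 1L], nrow(v),
               length(panel$sample_ids))
  gt[is.na(alt_dos)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$rsid, v$allele_a, v$allele_b, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, if (nrow(v)) body), path)
  invisible(path)
}

#' Read a genotype panel from a VCF file
#'
#' Parses GT fields with `vcfR` and counts ALT alleles; the counted allele
#' of the resulting panel is ALT.
#'
#' @param path Path to a VCF file.
#' @return A `genotype_panel`.
#' @export
read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_integer_,
           lengths(regmatches(g, gregexpr("1", g))))
  }
  dos <- t(apply(gt, 1, count_alt))
  if (nrow(gt) == 1) dos <- matrix(dos, nrow = 1)
  variants <- tibble::tibble(
    rsid = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    allele_a = fix$REF, allele_b = fix$ALT, counted_allele = fix$ALT
  )
  genotype_panel(colnames(gt), variants, t(dos))
}

#' Write panel dosages as TSV
#'
#' First columns describe the variants (`rsid`, `chrom`, `pos`, `allele_a`,
#' `allele_b`, `counted_allele`), followed by one integer column per sample.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(panel, path) {
  out <- cbind(panel$variants,
               tibble::as_tibble(t(panel$dosages), .name_repair = "minimal"))
  names(out) <- c(names(panel$variants), panel$sample_ids)
  readr::write_tsv(tibble::as_tibble(out), path, na = ".")
  invisible(path)
}

#' Read panel dosages from TSV written by [write_dosage_tsv()]
#'
#' @param path Input path.
#' @return A `genotype_panel`.
#' @export
read_dosage_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    rsid = "c", chrom = "c", pos = "i", allele_a = "c", allele_b = "c",
    counted_allele = "c", .default = "i"), na = ".", progress = FALSE)
  meta <- c("rsid", "chrom", "pos", "allele_a", "allele_b", "counted_allele")
  samples <- setdiff(names(x), meta)
  dos <- t(as.matrix(x[samples]))
  genotype_panel(samples, x[meta], dos)
}
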