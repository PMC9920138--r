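test_that("panel simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_samples = 50, n_variants = 40, seed = 11)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)
  s1 <- simulate_sumstats(p1, cfg)
  s2 <- simulate_sumstats(p2, cfg)
  expect_identical(s1, s2)
})

test_that("panel allele frequencies converge to configured MAFs", {
  cfg <- simulation_config(n_samples = 2000, n_variants = 200, seed = 3)
  panel <- simulate_panel(cfg)
  target <- attr(panel, "maf")
  fhat <- panel_frequencies(panel)$freq
  tol <- 3 * sqrt(target * (1 - target) / (2 * cfg$n_samples))
  expect_gte(mean(abs(fhat - target) < tol), 0.95)
})

test_that("ld_rho = 0 panels have near-zero LD and HWE genotype proportions", {
  cfg <- simulation_config(n_samples = 2000, n_variants = 50, ld_rho = 0,
                           seed = 5)
  panel <- simulate_panel(cfg)
  r2 <- stats::cor(panel$dosages)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.02)

  # HWE chi-square rejects near the nominal 5% rate
  f <- panel_frequencies(panel)$freq
  n <- cfg$n_samples
  pvals <- vapply(seq_len(ncol(panel$dosages)), function(j) {
    obs <- tabulate(panel$dosages[, j] + 1L, 3L)
    expc <- n * c((1 - f[j])^2, 2 * f[j] * (1 - f[j]), f[j]^2)
    stat <- sum((obs - expc)^2 / expc)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("within-block r2 dominates between-block r2 at high ld_rho", {
  cfg <- simulation_config(n_samples = 1000, n_variants = 40,
                           ld_block_size = 10, ld_rho = 0.9, seed = 6)
  panel <- simulate_panel(cfg)
  block <- attr(panel, "block")
  r2 <- stats::cor(panel$dosages)^2
  same <- outer(block, block, "==") & upper.tri(r2)
  diff <- !outer(block, block, "==") & upper.tri(r2)
  expect_gt(mean(r2[same]), 10 * mean(r2[diff]))
  expect_gt(mean(r2[same]), 0.3)
})

test_that("standard errors shrink with sample size and allele frequency", {
  panel <- simulate_panel(simulation_config(n_samples = 400, n_variants = 30,
                                            seed = 8))
  cfg_small <- simulation_config(n_samples = 400, n_variants = 30,
                                 gwas_n = 1e4, seed = 8)
  cfg_big <- simulation_config(n_samples = 400, n_variants = 30,
                               gwas_n = 4e5, seed = 8)
  ss_small <- simulate_sumstats(panel, cfg_small)[[1]]
  ss_big <- simulate_sumstats(panel, cfg_big)[[1]]
  expect_true(all(ss_big$se < ss_small$se))

  f <- panel_frequencies(panel)$freq
  ord <- order(f)
  below_half <- f[ord] < 0.5
  se_sorted <- ss_big$se[ord][below_half]
  expect_true(all(diff(se_sorted) <= 0))
})

test_that("null variants are calibrated: p < 0.005 at the nominal rate", {
  cfg <- simulation_config(n_samples = 503, n_variants = 10000,
                           n_causal_pleiotropic = 0,
                           n_causal_single_trait = 0, gwas_n = 1e5, seed = 9)
  panel <- simulate_panel(cfg)
  ss <- simulate_sumstats(panel, cfg)
  frac <- mean(ss$handgrip$p < 0.005)
  mc_se <- sqrt(0.005 * 0.995 / cfg$n_variants)
  expect_lt(abs(frac - 0.005), 3 * mc_se)
})

test_that("empirical discovery power matches the closed-form normal formula", {
  cfg <- simulation_config(n_samples = 503, n_variants = 400,
                           maf_range = c(0.3, 0.3), ld_block_size = 1,
                           n_causal_pleiotropic = 400,
                           n_causal_single_trait = 0,
                           effect_size = 0.0125, gwas_n = 450000, seed = 10)
  panel <- simulate_panel(cfg)
  ss <- simulate_sumstats(panel, cfg)$handgrip
  z <- stats::qnorm(1 - 5e-8 / 2)
  mu <- cfg$effect_size / ss$se
  predicted <- mean(stats::pnorm(mu - z) + stats::pnorm(-mu - z))
  empirical <- mean(ss$p < 5e-8)
  mc_se <- sqrt(predicted * (1 - predicted) / nrow(ss))
  expect_lt(abs(empirical - predicted), 3 * mc_se)
})

test_that("monomorphic variants are skipped with a warning", {
  dos <- cbind(c(0L, 1L, 2L, 1L), rep(2L, 4))
  panel <- toy_panel(dos)
  cfg <- simulation_config(n_samples = 4, n_variants = 2,
                           n_causal_pleiotropic = 0,
                           n_causal_single_trait = 0, seed = 2)
  expect_warning(ss <- simulate_sumstats(panel, cfg), "monomorphic")
  expect_equal(ss$handgrip$rsid, "rs00001")
})

test_that("planted truth respects the configured counts and nesting", {
  cfg <- simulation_config(n_variants = 500, n_causal_pleiotropic = 20,
                           n_causal_single_trait = 15, seed = 12)
  panel <- simulate_panel(cfg)
  truth <- planted_truth(panel, cfg)
  expect_equal(sum(truth$kind == "pleiotropic"), 20)
  expect_equal(sum(truth$kind == "single_trait"), 15)
  expect_equal(sum(truth$on_fat), round(cfg$prop_fat * 20))
  expect_equal(sum(truth$on_t2d), round(cfg$prop_t2d * round(cfg$prop_fat * 20)))
  expect_true(all(truth$on_t2d <= truth$on_fat))       # nested loadings
  single <- truth[truth$kind == "single_trait", ]
  expect_true(all(rowSums(single[c("on_lean", "on_strength", "on_walk")]) == 1))
})

test_that("VCF and dosage-TSV round-trips preserve the panel", {
  cfg <- simulation_config(n_samples = 20, n_variants = 15,
                           missing_rate = 0.05, seed = 13)
  panel <- simulate_panel(cfg)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(panel, vcf)
  back <- read_panel_vcf(vcf)
  expect_identical(unname(back$dosages), unname(panel$dosages))
  expect_equal(back$variants$rsid, panel$variants$rsid)
  expect_equal(back$sample_ids, panel$sample_ids)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(panel, tsv)
  back2 <- read_dosage_tsv(tsv)
  expect_identical(unname(back2$dosages), unname(panel$dosages))
  expect_equal(back2$variants, panel$variants)
})

test_that("degenerate configurations are refused", {
  expect_error(simulation_config(n_variants = 0), "n_variants")
  expect_error(simulation_config(ld_rho = 1), "ld_rho")
  expect_error(simulation_config(n_variants = 10, n_causal_pleiotropic = 20),
               "causal")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
})
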