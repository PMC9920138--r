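# Five-trait spec with one trait per category plus split grip phenotypes,
# used to exercise category collapsing.
specs_with_grips <- function() {
  dplyr::bind_rows(
    default_trait_specs(),
    tibble::tibble(name = c("grip_left", "grip_right"),
                   category = "strength", benefit_direction = 1,
                   discovery_threshold = 5e-8,
                   replication_threshold = 0.005, n = 359704L)
  )
}

test_that("discovery list is a union with per-trait thresholds and dedup", {
  specs <- default_trait_specs()
  shared <- make_records(1, rsid = "rs_shared", p = 1e-12)
  recs <- list(
    lean_mass = dplyr::bind_rows(shared, make_records(1, rsid = "rs_lean",
                                                      p = 1e-10)),
    handgrip = dplyr::bind_rows(shared, make_records(1, rsid = "rs_grip",
                                                     p = 1e-9)),
    walking_pace = make_records(1, rsid = "rs_weak", p = 1e-7)  # misses 5e-8
  )
  disc <- build_discovery_list(recs, specs)
  expect_setequal(disc$rsid, c("rs_shared", "rs_lean", "rs_grip"))
  expect_equal(sum(disc$rsid == "rs_shared"), 1)

  # lean mass uses its stricter 5e-9 threshold
  recs2 <- list(lean_mass = make_records(1, rsid = "rs_border", p = 1e-8))
  expect_warning(d2 <- build_discovery_list(recs2, specs), "no variant")
  expect_equal(nrow(d2), 0)

  # adiposity and t2d sources never seed discovery
  recs3 <- list(body_fat = make_records(1, rsid = "rs_fat", p = 1e-30))
  expect_warning(d3 <- build_discovery_list(recs3, specs), "no variant")
  expect_equal(nrow(d3), 0)
})

test_that("category collapse returns the aligned minimum-p record", {
  recs <- dplyr::bind_rows(
    make_records(1, rsid = "rs1", beta = 0.2, p = 0.01),
    make_records(1, rsid = "rs1", beta = -0.3, p = 0.001)
  )
  recs$trait <- c("grip_left", "grip_right")
  best <- collapse_category(recs, "A")
  expect_equal(best$trait, "grip_right")
  expect_equal(best$beta, -0.3)

  single <- collapse_category(recs[1, ], "G")  # identity up to alignment
  expect_equal(single$beta, -0.2)
  expect_error(collapse_category(recs[0, ], "A"), "no record")
})

test_that("category collapse matches an exhaustive scan on random sets", {
  set.seed(21)
  for (rep in 1:20) {
    recs <- random_records(5)
    recs$rsid <- "rs1"
    recs$effect_allele <- sample(c("A", "G"), 5, replace = TRUE)
    recs$other_allele <- ifelse(recs$effect_allele == "A", "G", "A")
    recs$trait <- sample(letters[1:5])
    got <- collapse_category(recs, "G")
    # oracle: align each record by hand, scan for the minimum
    manual_beta <- ifelse(recs$effect_allele == "G", recs$beta, -recs$beta)
    best <- order(recs$p, recs$trait)[1]
    expect_equal(got$p, recs$p[best])
    expect_equal(got$beta, manual_beta[best])
    expect_equal(got$trait, recs$trait[best])
  }
})

test_that("harmonization collapses grips by min p and canonicalizes alleles", {
  specs <- specs_with_grips()
  recs <- list(
    grip_left = make_records(1, rsid = "rs1", effect_allele = "G",
                             other_allele = "A", beta = 0.5, p = 0.01),
    grip_right = make_records(1, rsid = "rs1", effect_allele = "A",
                              other_allele = "G", beta = 0.4, p = 0.001)
  )
  h <- harmonize_evidence(recs, specs)
  expect_equal(nrow(h), 1)
  expect_equal(h$trait, "grip_right")
  expect_equal(h$reference_allele, "A")  # lexicographically smaller
  expect_equal(h$beta, 0.4)
})

test_that("selection requires all three categories under threshold with consistent directions", {
  specs <- default_trait_specs()
  mk <- function(rsid, b_lean, b_grip, b_walk, p = 1e-4, p_disc = 1e-10) {
    list(
      lean_mass = make_records(1, rsid = rsid, beta = b_lean, p = p_disc),
      handgrip = make_records(1, rsid = rsid, beta = b_grip, p = p),
      walking_pace = make_records(1, rsid = rsid, beta = b_walk, p = p)
    )
  }
  merge_recs <- function(...) {
    lists <- list(...)
    nms <- names(lists[[1]])
    stats::setNames(lapply(nms, function(nm) {
      dplyr::bind_rows(lapply(lists, `[[`, nm))
    }), nms)
  }
  recs <- merge_recs(
    mk("rs_good", 0.1, 0.1, 0.1),       # consistent, protective = effect allele
    mk("rs_flip", -0.1, -0.1, -0.1),    # consistent the other way
    mk("rs_bad", 0.1, 0.1, -0.1),       # inconsistent
    mk("rs_weak", 0.1, 0.1, 0.1, p = 0.01),  # fails replication
    mk("rs_zero", 0.1, 0, 0.1)          # undefined direction
  )
  disc <- build_discovery_list(recs, specs)
  h <- harmonize_evidence(recs, specs, variants = disc)
  sel <- select_pleiotropic(disc, h, specs)
  expect_setequal(sel$rsid, c("rs_good", "rs_flip"))
  expect_equal(sel$protective_allele[sel$rsid == "rs_good"], "A")
  expect_equal(sel$protective_allele[sel$rsid == "rs_flip"], "G")
  expect_true(all(c(sel$p_grip, sel$p_lean, sel$p_walk) < 0.005))
  # betas are re-expressed per protective allele: all in the benefit direction
  expect_true(all(c(sel$beta_grip, sel$beta_lean, sel$beta_walk) > 0))
  excl <- attr(sel, "exclusions")
  expect_match(excl$rs_bad, "inconsistent")
  expect_match(excl$rs_zero, "zero beta")
  expect_match(excl$rs_weak, "above threshold")
})

test_that("selection is monotone in the replication threshold", {
  set.seed(31)
  specs <- default_trait_specs()
  cfg <- simulation_config(n_samples = 300, n_variants = 300,
                           n_causal_pleiotropic = 15,
                           n_causal_single_trait = 10,
                           effect_size = 0.03, gwas_n = 200000, seed = 31)
  panel <- simulate_panel(cfg)
  recs <- simulate_sumstats(panel, cfg)
  disc <- build_discovery_list(recs, specs)
  h <- harmonize_evidence(recs, specs, variants = disc)
  tight <- select_pleiotropic(disc, h, specs, replication_threshold = 0.005)
  loose <- select_pleiotropic(disc, h, specs, replication_threshold = 0.05)
  expect_true(all(tight$rsid %in% loose$rsid))
})

test_that("selection is invariant to the incoming allele orientation", {
  specs <- default_trait_specs()
  cfg <- simulation_config(n_samples = 300, n_variants = 200,
                           n_causal_pleiotropic = 10,
                           n_causal_single_trait = 5, seed = 33)
  panel <- simulate_panel(cfg)
  recs <- simulate_sumstats(panel, cfg)
  flip_all <- function(r) {
    tmp <- r$effect_allele
    r$effect_allele <- r$other_allele
    r$other_allele <- tmp
    r$beta <- -r$beta
    r
  }
  run <- function(rr) {
    disc <- build_discovery_list(rr, specs)
    h <- harmonize_evidence(rr, specs, variants = disc)
    select_pleiotropic(disc, h, specs)
  }
  a <- run(recs)
  b <- run(purrr::map(recs, flip_all))
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("planted pleiotropic variants are recovered without false directions", {
  specs <- default_trait_specs()
  cfg <- simulation_config(n_samples = 503, n_variants = 500,
                           n_causal_pleiotropic = 10,
                           n_causal_single_trait = 10,
                           effect_size = 0.04, gwas_n = 450000, seed = 35)
  panel <- simulate_panel(cfg)
  recs <- simulate_sumstats(panel, cfg)
  truth <- attr(recs, "truth")
  planted <- truth$rsid[truth$kind == "pleiotropic"]
  disc <- build_discovery_list(recs, specs)
  h <- harmonize_evidence(recs, specs, variants = disc)
  sel <- select_pleiotropic(disc, h, specs)
  expect_gte(mean(planted %in% sel$rsid), 0.9)
  expect_true(all(sel$rsid %in% planted))
  # protective-allele calls match the planted protective alleles
  hit <- truth[match(sel$rsid, truth$rsid), ]
  expect_equal(sel$protective_allele, hit$protective_allele)
})
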