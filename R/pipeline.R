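#' End-to-end pleiotropy scan
#'
#' Chains the selection stages on in-memory inputs: build the genome-wide
#' discovery list, harmonize and collapse per-category evidence, select
#' direction-consistent pleiotropic variants at the replication threshold,
#' prune to LD-independent variants on the panel, and classify tiers.
#'
#' @param per_trait_records Named list of association-record tibbles.
#' @param panel A `genotype_panel` (LD reference); `NULL` skips pruning.
#' @param trait_specs Trait-spec tibble.
#' @param replication_threshold Replication p threshold (default 0.005).
#' @param r2_threshold LD pruning threshold (default 0.2).
#' @return A `pleio_scan` object: classified calls plus stage counters.
#'   Use [tidy()] for the calls, [glance()] for the count flow.
#' @export
scan_pleiotropy <- function(per_trait_records, panel = NULL,
                            trait_specs = default_trait_specs(),
                            replication_threshold = 0.005,
                            r2_threshold = 0.2) {
  trait_specs <- validate_trait_specs(trait_specs)
  discovery <- build_discovery_list(per_trait_records, trait_specs)
  harmonized <- harmonize_evidence(per_trait_records, trait_specs,
                                   variants = discovery)
  selected <- select_pleiotropic(discovery, harmonized, trait_specs,
                                 replication_threshold)
  pruned <- if (!is.null(panel) && nrow(selected) > 0) {
    greedy_prune(selected, panel, r2_threshold)
  } else {
    selected
  }
  calls <- assign_tier(pruned, p_threshold = replication_threshold)
  structure(
    list(
      calls = calls,
      counts = tibble::tibble(
        discovered = nrow(discovery),
        selected = nrow(selected),
        independent = nrow(pruned),
        fat_associated = sum(calls$fat_hit),
        diabesity = sum(calls$tier == "sarcopenic_diabesity")
      ),
      discovery = discovery,
      exclusions = attr(selected, "exclusions"),
      pruned_away = attr(pruned, "pruned"),
      replication_threshold = replication_threshold,
      r2_threshold = r2_threshold
    ),
    class = "pleio_scan"
  )
}

#' @export
print.pleio_scan <- function(x, ...) {
  cat("<pleio_scan>\n")
  cat(sprintf("  discovery list: %d variants\n", x$counts$discovered))
  cat(sprintf("  selected (p < %g, consistent directions): %d\n",
              x$replication_threshold, x$counts$selected))
  cat(sprintf("  LD-independent (r2 <= %g): %d\n",
              x$r2_threshold, x$counts$independent))
  cat(sprintf("  body-fat associated: %d; diabesity: %d\n",
              x$counts$fat_associated, x$counts$diabesity))
  invisible(x)
}

#' Tidy a pleiotropy scan
#'
#' @param x A `pleio_scan`.
#' @param ... Unused.
#' @return The classified calls tibble, one row per retained variant.
#' @method tidy pleio_scan
#' @export
tidy.pleio_scan <- function(x, ...) x$calls

#' One-row summary of a pleiotropy scan
#'
#' @param x A `pleio_scan`.
#' @param ... Unused.
#' @return A one-row tibble with the stage count flow (`discovered`,
#'   `selected`, `independent`, `fat_associated`, `diabesity`) and the
#'   thresholds used.
#' @method glance pleio_scan
#' @export
glance.pleio_scan <- function(x, ...) {
  dplyr::bind_cols(x$counts,
                   tibble::tibble(
                     replication_threshold = x$replication_threshold,
                     r2_threshold = x$r2_threshold))
}

#' Plot the per-category significance of scanned variants
#'
#' One point per retained variant and sarcopenia category at -log10 p,
#' coloured by assigned tier.
#'
#' @param object A `pleio_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pleio_scan
#' @export
autoplot.pleio_scan <- function(object, ...) {
  calls <- object$calls
  long <- tidyr::pivot_longer(
    calls[c("rsid", "tier", "p_grip", "p_lean", "p_walk")],
    cols = c("p_grip", "p_lean", "p_walk"),
    names_to = "category", values_to = "p")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category,
                                     y = -log10(.data$p),
                                     colour = .data$tier)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)), colour = "tier") +
    ggplot2::theme_minimal()
}

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate panel and summary statistics from
#'   `sim`), `"files"` (read them from `sumstats_paths`/`panel_path`) or
#'   `"fixture"` (classify the packaged published variant table; no
#'   selection or pruning).
#' @param trait_specs Trait-spec tibble.
#' @param sim A [simulation_config()] (simulate mode).
#' @param sumstats_paths Named list of per-trait summary-statistic TSV
#'   paths (files mode).
#' @param panel_path Panel path, `.vcf` or dosage `.tsv` (files mode).
#' @param replication_threshold,ld_r2,n_bands Pipeline thresholds.
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files", "fixture"),
                            trait_specs = default_trait_specs(),
                            sim = NULL, sumstats_paths = NULL,
                            panel_path = NULL,
                            replication_threshold = 0.005, ld_r2 = 0.2,
                            n_bands = 5, seed = 1L) {
  mode <- match.arg(mode)
  if (!(replication_threshold > 0 && replication_threshold <= 1)) {
    rlang::abort("replication_threshold must lie in (0, 1]")
  }
  if (!(ld_r2 > 0 && ld_r2 <= 1)) rlang::abort("ld_r2 must lie in (0, 1]")
  if (n_bands < 2) rlang::abort("n_bands must be >= 2")
  if (mode == "simulate" && is.null(sim)) {
    sim <- simulation_config(trait_specs = trait_specs, seed = seed)
  }
  if (mode == "files") {
    for (p in c(unlist(sumstats_paths), panel_path)) {
      if (!is.null(p) && !file.exists(p)) {
        rlang::abort(paste0("referenced path does not exist: ", p))
      }
    }
  }
  structure(list(mode = mode, trait_specs = validate_trait_specs(trait_specs),
                 sim = sim, sumstats_paths = sumstats_paths,
                 panel_path = panel_path,
                 replication_threshold = replication_threshold,
                 ld_r2 = ld_r2, n_bands = as.integer(n_bands),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline and write a reproducible run directory
#'
#' Executes the configured stages and writes, under `out_dir`: the
#' classified calls (`classified_calls.tsv`), headline counts
#' (`tier_counts.json`), per-tier risk-band tables and per-sample scores
#' (simulate/files modes), the gene-evidence concordance summary
#' (`concordance.json`) and a run manifest (`manifest.json`) echoing the
#' configuration, seed, package version and per-stage row counts. The
#' manifest is written even when a stage fails, with the failing stage
#' named, and the error is then re-raised.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `calls`, `tier_counts`, `bands`,
#'   `concordance` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "pleiosarc",
    version = as.character(utils::packageVersion("pleiosarc")),
    seed = config$seed, mode = config$mode,
    replication_threshold = config$replication_threshold,
    ld_r2 = config$ld_r2, n_bands = config$n_bands,
    traits = config$trait_specs$name,
    stages = list(), failed_stage = NA
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest()
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "ok")
    out
  }

  if (config$mode == "fixture") {
    calls <- stage("classify", assign_tier(table2_fixture(),
                                           config$replication_threshold))
    manifest$stages$classify$rows <- nrow(calls)
    scan <- NULL
  } else {
    if (config$mode == "simulate") {
      panel <- stage("simulate_panel", simulate_panel(config$sim))
      sumstats <- stage("simulate_sumstats",
                        simulate_sumstats(panel, config$sim))
    } else {
      panel <- stage("read_panel", {
        if (grepl("\\.vcf$", config$panel_path)) {
          read_panel_vcf(config$panel_path)
        } else {
          read_dosage_tsv(config$panel_path)
        }
      })
      sumstats <- stage("read_sumstats",
                        purrr::map(config$sumstats_paths, read_sumstats))
    }
    manifest$stages$input <- list(
      status = "ok", samples = length(panel$sample_ids),
      variants = nrow(panel$variants),
      records = sum(purrr::map_int(sumstats, nrow)))
    scan <- stage("scan", scan_pleiotropy(
      sumstats, panel, config$trait_specs,
      config$replication_threshold, config$ld_r2))
    calls <- scan$calls
    manifest$stages$scan <- c(manifest$stages$scan,
                              as.list(glance(scan)[1, 1:5]))
  }

  stage("write_calls", {
    readr::write_tsv(
      dplyr::select(calls, -dplyr::matches("_text$")),
      file.path(out_dir, "classified_calls.tsv"))
  })
  counts <- stage("tier_counts", tier_counts(calls))
  jsonlite::write_json(as.list(counts), file.path(out_dir, "tier_counts.json"),
                       auto_unbox = TRUE, digits = NA)

  bands <- NULL
  if (config$mode != "fixture" && nrow(calls) >= config$n_bands) {
    bands <- stage("prs", {
      subsets <- list(
        sarcopenia = calls,
        sarcopenic_obesity = calls[calls$fat_hit, , drop = FALSE],
        sarcopenic_diabesity =
          calls[calls$tier == "sarcopenic_diabesity", , drop = FALSE]
      )
      purrr::imap(subsets, function(sub, label) {
        if (nrow(sub) == 0) return(NULL)
        sc <- risk_score(panel, sub[c("rsid", "risk_allele")])
        readr::write_tsv(sc, file.path(out_dir,
                                       paste0("scores_", label, ".tsv")))
        bt <- stratify(sc, config$n_bands, trait_label = label,
                       n_snps = nrow(sub))
        jsonlite::write_json(tidy(bt),
                             file.path(out_dir, paste0("bands_", label,
                                                       ".json")),
                             auto_unbox = TRUE, digits = NA)
        bt
      })
    })
  }

  concordance <- stage("concordance",
                       concordance_summary(gene_evidence_fixture()))
  jsonlite::write_json(as.list(concordance),
                       file.path(out_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA)

  write_manifest()
  invisible(list(calls = calls, scan = scan, tier_counts = counts,
                 bands = bands, concordance = concordance,
                 manifest = manifest))
}
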