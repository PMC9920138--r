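#' Trait categories recognised by the selection pipeline
#'
#' The three sarcopenia-defining categories (`lean_mass`, `strength`,
#' `walking_pace`), the two tier-upgrading categories (`adiposity`, `t2d`)
#' and `auxiliary` for everything else (tiredness, falls, diet, ...).
#'
#' @export
trait_categories <- c("lean_mass", "strength", "walking_pace",
                      "adiposity", "t2d", "auxiliary")

#' Default trait specifications
#'
#' One row per GWAS trait consumed by the pipeline. `benefit_direction` is
#' the sign of a per-allele effect that protects against sarcopenia: +1 for
#' lean mass, strength and walking pace (more is better), -1 for body-fat
#' percentage and type-2 diabetes (more is worse). Discovery thresholds are
#' genome-wide (5e-8; 5e-9 for the large appendicular-lean-mass GWAS) and the
#' replication threshold is the less stringent 0.005 used for cross-trait
#' matching. Sample sizes follow the UK Biobank source studies.
#'
#' @return A tibble with columns `name`, `category`, `benefit_direction`,
#'   `discovery_threshold`, `replication_threshold`, `n`.
#' @export
default_trait_specs <- function() {
  tibble::tribble(
    ~name,           ~category,      ~benefit_direction, ~discovery_threshold, ~replication_threshold, ~n,
    "lean_mass",     "lean_mass",    1,  5e-9, 0.005, 450243L,
    "handgrip",      "strength",     1,  5e-8, 0.005, 359704L,
    "walking_pace",  "walking_pace", 1,  5e-8, 0.005, 450967L,
    "body_fat",      "adiposity",   -1,  5e-8, 0.005, 354628L,
    "t2d",           "t2d",         -1,  5e-8, 0.005, 408959L
  )
}

#' Validate a trait-specification table
#'
#' @param specs A data frame with one row per trait.
#' @return The validated specs as a tibble (invisibly usable in pipes).
#' @export
validate_trait_specs <- function(specs) {
  specs <- tibble::as_tibble(specs)
  required <- c("name", "category", "benefit_direction",
                "discovery_threshold", "replication_threshold", "n")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0) {
    rlang::abort(paste0("trait specs missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(specs$name)) rlang::abort("duplicate trait names")
  if (!all(specs$category %in% trait_categories)) {
    rlang::abort(paste0("unknown trait category; must be one of: ",
                        paste(trait_categories, collapse = ", ")))
  }
  if (!all(specs$benefit_direction %in% c(-1, 1))) {
    rlang::abort("benefit_direction must be +1 or -1")
  }
  bad_dir <- specs$category %in% c("adiposity", "t2d") & specs$benefit_direction != -1
  if (any(bad_dir)) {
    rlang::abort("adiposity and t2d traits must carry benefit_direction -1")
  }
  thr <- c(specs$discovery_threshold, specs$replication_threshold)
  if (!all(thr > 0 & thr < 1)) rlang::abort("thresholds must lie in (0, 1)")
  if (!all(specs$replication_threshold >= specs$discovery_threshold)) {
    rlang::abort("replication_threshold must be >= discovery_threshold")
  }
  specs
}

#' Read trait specifications from a YAML file
#'
#' The file holds a top-level `traits:` list with one entry per trait
#' (fields `name`, `category`, `benefit_direction`, `discovery_threshold`,
#' `replication_threshold`, `n`).
#'
#' @param path Path to the YAML file.
#' @return A validated trait-spec tibble.
#' @export
read_trait_specs <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  y <- yaml::read_yaml(path)
  traits <- if (!is.null(y$traits)) y$traits else y
  specs <- purrr::map_dfr(traits, function(t) {
    tibble::tibble(
      name = as.character(t$name),
      category = as.character(t$category),
      benefit_direction = as.numeric(t$benefit_direction),
      discovery_threshold = as.numeric(t$discovery_threshold),
      replication_threshold = as.numeric(t$replication_threshold),
      n = as.integer(t$n)
    )
  })
  validate_trait_specs(specs)
}

#' Write trait specifications to YAML
#'
#' @param specs Trait-spec tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_specs <- function(specs, path) {
  specs <- validate_trait_specs(specs)
  yaml::write_yaml(list(traits = purrr::transpose(as.list(specs))), path)
  invisible(path)
}
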