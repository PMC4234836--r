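# End-to-end orchestration: each run_* stage reads/writes plain TSV files
# in an output directory and records a manifest with the fully resolved
# configuration and seed, so any run is reproducible from its manifest.

write_manifest <- function(out_dir, stage, params) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("autozyg")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              params = params)
  yaml::write_yaml(man, file.path(out_dir, paste0("manifest_", stage, ".yaml")))
}

resolve_config <- function(config, defaults = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(defaults, as.list(config))
}

#' Simulate a herd dataset and write it to disk
#'
#' Writes `pedigree.tsv`, `genotypes.tsv` + `genotypes.map.tsv`,
#' `phenotypes.tsv`, `truth.tsv` and a manifest into `out_dir`. The files
#' are valid inputs to [run_inbreed()], [run_depression()] and
#' [run_gwas()] without edits.
#'
#' @param config A [sim_config], a list of `sim_config` arguments, or the
#'   path of a YAML file holding them. `seed` is required.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of files written.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- if (inherits(config, "sim_config")) config else {
    do.call(sim_config, resolve_config(config))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  herd <- simulate_herd(cfg)
  ped_out <- herd$pedigree
  readr::write_tsv(tibble::as_tibble(ped_out), file.path(out_dir, "pedigree.tsv"))
  write_geno_tsv(herd$genotypes, file.path(out_dir, "genotypes.tsv"),
                 file.path(out_dir, "genotypes.map.tsv"))
  phen <- dplyr::rename(herd$phenotypes, cow_id = "cow")
  readr::write_tsv(phen, file.path(out_dir, "phenotypes.tsv"))
  truth <- herd$truth$ibd
  if (!is.null(herd$truth$qtl_status)) {
    truth <- dplyr::left_join(truth, herd$truth$qtl_status, by = "animal")
  }
  readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
  qtl_cfg <- if (is.null(cfg$qtl)) NULL else as.list(as.data.frame(cfg$qtl))
  params <- cfg[!vapply(cfg, is.function, logical(1))]
  params$qtl <- qtl_cfg
  params$vc <- as.list(cfg$vc)
  params$fixed_effect_sds <- as.list(cfg$fixed_effect_sds)
  params$forced_matings <- as.list(cfg$forced_matings)
  write_manifest(out_dir, "simulate", params)
  files <- file.path(out_dir, c("pedigree.tsv", "genotypes.tsv",
                                "genotypes.map.tsv", "phenotypes.tsv",
                                "truth.tsv", "manifest_simulate.yaml"))
  invisible(files)
}

read_stage_inputs <- function(dir, need_geno = TRUE, need_phen = FALSE) {
  ped <- read_pedigree(file.path(dir, "pedigree.tsv"))
  g <- if (need_geno) {
    read_geno_tsv(file.path(dir, "genotypes.tsv"),
                  file.path(dir, "genotypes.map.tsv"))
  } else NULL
  phen <- if (need_phen) {
    readr::read_tsv(file.path(dir, "phenotypes.tsv"), show_col_types = FALSE,
                    progress = FALSE)
  } else NULL
  list(ped = ped, g = g, phen = phen)
}

#' Compute inbreeding measures for a dataset on disk
#'
#' Reads the pedigree and genotypes from `dir`, writes per-animal measures
#' (`measures.tsv`), a mean/SD summary per measure (`measures_summary.tsv`)
#' and the between-measure correlation matrix (`correlations.tsv`).
#'
#' @param dir Directory holding `pedigree.tsv`, `genotypes.tsv`,
#'   `genotypes.map.tsv` (as written by [run_simulate()]).
#' @param out_dir Output directory (default `dir`).
#' @param n_grid Minimum ROH lengths in SNPs.
#' @return Invisibly, the measures tibble.
#' @export
run_inbreed <- function(dir, out_dir = dir, n_grid = c(1L, seq(5L, 100L, 5L))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- read_stage_inputs(dir)
  meas <- inbreeding_measures(inp$ped, inp$g, n_grid = n_grid)
  readr::write_tsv(meas, file.path(out_dir, "measures.tsv"))
  num <- meas[vapply(meas, is.numeric, logical(1))]
  summ <- tibble::tibble(measure = names(num),
                         mean = vapply(num, mean, numeric(1), na.rm = TRUE),
                         sd = vapply(num, stats::sd, numeric(1), na.rm = TRUE))
  readr::write_tsv(summ, file.path(out_dir, "measures_summary.tsv"))
  cors <- measure_correlations(meas)
  cor_df <- tibble::as_tibble(cors, rownames = "measure")
  readr::write_tsv(cor_df, file.path(out_dir, "correlations.tsv"))
  write_manifest(out_dir, "inbreed", list(dir = dir, n_grid = n_grid))
  invisible(meas)
}

#' Fit an inbreeding-depression regression for a dataset on disk
#'
#' @param dir Directory with `pedigree.tsv`, `phenotypes.tsv` and (for
#'   genomic measures) genotype files.
#' @param out_dir Output directory (default `dir`).
#' @param measure,joint_with,quadratic,n_roh Passed to
#'   [fit_inbreeding_depression()].
#' @param trait Trait to analyse when several are present.
#' @return Invisibly, the `ibd_fit`.
#' @export
run_depression <- function(dir, out_dir = dir, measure = "pedigree",
                           joint_with = NULL, quadratic = FALSE, n_roh = 50,
                           trait = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- read_stage_inputs(dir, need_geno = measure != "pedigree" ||
                             !is.null(joint_with), need_phen = TRUE)
  fit <- fit_inbreeding_depression(inp$phen, inp$ped, g = inp$g,
                                   measure = measure, joint_with = joint_with,
                                   quadratic = quadratic, n_roh = n_roh,
                                   trait = trait)
  write_fit(fit, file.path(out_dir, "depression_fit.tsv"))
  readr::write_tsv(glance(fit), file.path(out_dir, "depression_vc.tsv"))
  write_manifest(out_dir, "depression",
                 list(dir = dir, measure = measure,
                      joint_with = joint_with, quadratic = quadratic,
                      n_roh = n_roh, trait = trait))
  invisible(fit)
}

#' Run the ROH genome scan for a dataset on disk
#'
#' Writes the per-position scan table (`gwas_scan.tsv`), clustered region
#' summaries (`gwas_regions.tsv`) and the FDR line (`gwas_fdr.tsv`).
#'
#' @param dir Directory with pedigree, genotype and phenotype files.
#' @param out_dir Output directory (default `dir`).
#' @param cfg A [gwas_config].
#' @param trait_polarity Trait polarity for region direction labels.
#' @param trait Trait to analyse when several are present.
#' @return Invisibly, the `roh_scan`.
#' @export
run_gwas <- function(dir, out_dir = dir, cfg = gwas_config(),
                     trait_polarity = "higher_better", trait = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- read_stage_inputs(dir, need_phen = TRUE)
  scan <- roh_gwas_scan(inp$phen, inp$ped, inp$g, cfg = cfg, trait = trait)
  readr::write_tsv(tibble::as_tibble(scan), file.path(out_dir, "gwas_scan.tsv"))
  regions <- cluster_significant(scan, cfg, trait_polarity = trait_polarity)
  readr::write_tsv(summarize_regions(regions, scan),
                   file.path(out_dir, "gwas_regions.tsv"))
  readr::write_tsv(scan_fdr(scan, cfg), file.path(out_dir, "gwas_fdr.tsv"))
  write_manifest(out_dir, "gwas",
                 list(dir = dir, n_roh = cfg$n_roh,
                      p_threshold = cfg$p_threshold,
                      min_carriers = cfg$min_carriers,
                      indicator_mode = cfg$indicator_mode,
                      trait_polarity = trait_polarity, trait = trait))
  invisible(scan)
}
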