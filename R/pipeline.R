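# Orchestration: YAML-configured stage commands
#   simulate -> qc -> structure -> evaluate -> validate
# Each command is idempotent given identical config + seed, echoes the
# resolved config into its output directory and appends structured log lines.

#' Load and validate a pipeline run configuration
#'
#' @param config Path to a YAML file, or an equivalent named list. Sections:
#'   `seed`, `simulate` (fields of [sim_config()]), `qc`
#'   (`min_call_rate, max_missing, min_maf, hwe_alpha, chromosomes`),
#'   `structure` (`max_distance_kb, bin_kb`), `model`
#'   (`target_breed, blend_weight`), `gibbs` (fields of [gibbs_config()]),
#'   `validation` (`step, max_added, n_validation, window_years`). Missing
#'   fields take package defaults.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  assert_that(is.list(cfg), "config must be a YAML file or a list")
  defaults <- list(
    seed = 1L,
    simulate = list(),
    qc = list(min_call_rate = 0.90, max_missing = 0.10, min_maf = 0.01,
              hwe_alpha = 1e-6, chromosomes = 1:30),
    structure = list(max_distance_kb = 500, bin_kb = 1),
    model = list(target_breed = NULL, blend_weight = 0.05),
    gibbs = list(chain_length = 100000, burn_in = 10000, thin = 50),
    validation = list(step = 300, max_added = NULL, n_validation = 50,
                      window_years = 4))
  for (s in names(defaults)) {
    if (is.list(defaults[[s]])) {
      cfg[[s]] <- modifyList(defaults[[s]], cfg[[s]] %||% list())
    } else if (is.null(cfg[[s]])) cfg[[s]] <- defaults[[s]]
  }
  assert_that(cfg$qc$min_call_rate > 0 && cfg$qc$min_call_rate <= 1 &&
                cfg$qc$max_missing >= 0 && cfg$qc$max_missing <= 1 &&
                cfg$qc$min_maf >= 0 && cfg$qc$min_maf < 0.5,
              "QC thresholds outside their domains")
  structure(cfg, class = c("run_config", "list"))
}

pipeline_log <- function(outdir, stage, msg) {
  line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = file.path(outdir, "pipeline.log"),
      append = TRUE)
  invisible(line)
}

echo_config <- function(cfg, outdir, stage) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  pipeline_log(outdir, stage,
               paste0("ssgblup ", as.character(utils::packageVersion("ssgblup")),
                      " seed=", cfg$seed))
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    abort(paste0("missing upstream artifact ", basename(path),
                 "; run ", producer, " first"))
  }
  path
}

#' Pipeline stage commands
#'
#' Five stage commands covering the whole analysis. All read a
#' [read_run_config()] configuration and write plain-text artifacts plus an
#' echoed config and a log into `outdir`.
#'
#' * `cmd_simulate()` writes the simulated dataset (pedigree, phenotype,
#'   dosage and truth CSVs, PLINK PED/MAP, founder frequencies).
#' * `cmd_qc()` applies per-breed animal/SNP quality control, intersects the
#'   surviving marker panels and mean-imputes; writes the QC'd dosage CSV
#'   and per-rule reports.
#' * `cmd_structure()` writes the LD-decay curve, G-matrix PCA scores and
#'   kinship block summary.
#' * `cmd_evaluate()` runs the bivariate Gibbs evaluation on all data;
#'   writes posterior summaries, GEBVs and the retained variance-component
#'   chain.
#' * `cmd_validate()` runs the gradient joint-reference validation
#'   experiment; writes the reliability/bias/inflation report.
#'
#' @param config A [read_run_config()] input (path or list).
#' @param outdir Output directory (created if needed).
#' @return The stage's main result, invisibly.
#' @export
cmd_simulate <- function(config, outdir) {
  cfg <- read_run_config(config)
  sim_args <- cfg$simulate
  sim_args$seed <- sim_args$seed %||% substream_seed(cfg$seed, "sim")
  sc <- do.call(sim_config, sim_args)
  echo_config(cfg, outdir, "simulate")
  ds <- simulate_dataset(sc)
  write_pedigree_csv(ds$pedigree, file.path(outdir, "pedigree.csv"))
  write_phenotype_csv(ds$phenotypes, file.path(outdir, "phenotypes.csv"))
  write_dosage_csv(ds$genotypes, file.path(outdir, "genotypes.csv"))
  write_plink_pedmap(ds$genotypes, ds$map, file.path(outdir, "genotypes.ped"),
                     file.path(outdir, "genotypes.map"))
  readr::write_csv(ds$map, file.path(outdir, "map.csv"))
  readr::write_csv(ds$truth$tbv, file.path(outdir, "truth_tbv.csv"))
  vc <- ds$truth$variance_components
  readr::write_csv(tibble(parameter = c("sigma_a1", "sigma_a2", "sigma_a12",
                                        "sigma_e1", "sigma_e2", "h2_1",
                                        "h2_2", "genetic_correlation",
                                        "realized_fst"),
                          value = c(vc$sigma_a, vc$sigma_a12, vc$sigma_e,
                                    vc$h2, vc$genetic_correlation,
                                    ds$truth$realized_fst)),
                   file.path(outdir, "truth_parameters.csv"))
  pipeline_log(outdir, "simulate",
               paste0(nrow(ds$pedigree), " animals, ", nrow(ds$map), " SNPs, ",
                      nrow(ds$phenotypes), " records"))
  invisible(ds)
}

#' @rdname cmd_simulate
#' @export
cmd_qc <- function(config, outdir) {
  cfg <- read_run_config(config)
  echo_config(cfg, outdir, "qc")
  geno <- read_dosage_csv(require_artifact(file.path(outdir, "genotypes.csv"),
                                           "cmd_simulate"))
  map <- readr::read_csv(file.path(outdir, "map.csv"),
                         col_types = readr::cols(), progress = FALSE)
  per_breed <- lapply(unique(geno$breed), function(b) {
    g <- subset_genotypes(geno, animals = which(geno$breed == b))
    qa <- qc_animals(g, cfg$qc$min_call_rate)
    qs <- qc_snps(qa$genotypes, map, cfg$qc$max_missing, cfg$qc$min_maf,
                  cfg$qc$hwe_alpha, cfg$qc$chromosomes)
    list(geno = qs$genotypes, map = qs$map, animal_report = qa$report,
         snp_report = qs$report, breed = b)
  })
  xs <- intersect_snps(per_breed[[1]]$geno, per_breed[[1]]$map,
                       per_breed[[2]]$geno, per_breed[[2]]$map)
  merged <- genotypes(rbind(xs$genotypes_a$dosage, xs$genotypes_b$dosage),
                      c(xs$genotypes_a$breed, xs$genotypes_b$breed))
  imp <- impute_mean(merged)
  write_dosage_csv(imp, file.path(outdir, "genotypes_qc.csv"))
  readr::write_csv(xs$map, file.path(outdir, "map_qc.csv"))
  readr::write_tsv(dplyr::bind_rows(lapply(per_breed, `[[`, "animal_report")),
                   file.path(outdir, "qc_animals.tsv"))
  readr::write_tsv(dplyr::bind_rows(lapply(per_breed, function(x)
    dplyr::mutate(x$snp_report, breed = x$breed))),
    file.path(outdir, "qc_snps.tsv"))
  pipeline_log(outdir, "qc",
               paste0(nrow(imp$dosage), " animals x ", ncol(imp$dosage),
                      " SNPs after QC and intersection"))
  invisible(list(genotypes = imp, map = xs$map))
}

#' @rdname cmd_simulate
#' @export
cmd_structure <- function(config, outdir) {
  cfg <- read_run_config(config)
  echo_config(cfg, outdir, "structure")
  geno <- read_dosage_csv(require_artifact(
    file.path(outdir, "genotypes_qc.csv"), "cmd_qc"))
  map <- readr::read_csv(file.path(outdir, "map_qc.csv"),
                         col_types = readr::cols(), progress = FALSE)
  # LD uses hard genotype calls; imputed fractional cells are rounded
  geno_ld <- genotypes(round(geno$dosage), geno$breed)
  ld <- ld_decay(geno_ld, map, cfg$structure$max_distance_kb,
                 cfg$structure$bin_kb)
  readr::write_tsv(ld, file.path(outdir, "ld_decay.tsv"))
  G <- vanraden_g(geno$dosage)
  pca <- grm_pca(G)
  readr::write_tsv(tidy(pca, n_components = 3) |>
                     tidyr::pivot_wider(names_from = "component",
                                        values_from = "score",
                                        names_prefix = "PC"),
                   file.path(outdir, "pca.tsv"))
  readr::write_tsv(kinship_blocks(G, geno$breed),
                   file.path(outdir, "kinship_blocks.tsv"))
  pipeline_log(outdir, "structure", "LD, PCA and kinship summaries written")
  invisible(list(ld = ld, pca = pca))
}

#' @rdname cmd_simulate
#' @export
cmd_evaluate <- function(config, outdir) {
  cfg <- read_run_config(config)
  echo_config(cfg, outdir, "evaluate")
  ped <- read_pedigree_csv(require_artifact(file.path(outdir, "pedigree.csv"),
                                            "cmd_simulate"))
  phen <- read_phenotype_csv(require_artifact(
    file.path(outdir, "phenotypes.csv"), "cmd_simulate"))
  geno <- read_dosage_csv(require_artifact(
    file.path(outdir, "genotypes_qc.csv"), "cmd_qc"))
  rel <- build_relationships(ped, geno, cfg$model$blend_weight)
  design <- build_design(phen, ped$animal)
  gc_args <- cfg$gibbs
  gc_args$seed <- gc_args$seed %||% substream_seed(cfg$seed, "gibbs")
  fit <- gibbs_sample(design, rel$H_inv, do.call(gibbs_config, gc_args))
  readr::write_csv(tidy(fit), file.path(outdir, "posterior_summary.csv"))
  readr::write_csv(fit$gebv, file.path(outdir, "gebv.csv"))
  chain <- as_tibble(fit$vc_chain) |>
    dplyr::mutate(iteration = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter",
                        values_to = "value")
  readr::write_tsv(chain, file.path(outdir, "vc_chain.tsv"))
  bad <- dplyr::filter(tidy(fit), abs(.data$geweke_z) > 3)
  if (nrow(bad) > 0) {
    pipeline_log(outdir, "evaluate",
                 paste0("WARNING convergence: |Geweke z| > 3 for ",
                        paste(bad$parameter, collapse = ", ")))
    warn(paste0("Geweke |z| > 3 for: ", paste(bad$parameter, collapse = ", ")))
  }
  pipeline_log(outdir, "evaluate",
               paste0(fit$retained, " retained samples"))
  invisible(fit)
}

#' @rdname cmd_simulate
#' @export
cmd_validate <- function(config, outdir) {
  cfg <- read_run_config(config)
  echo_config(cfg, outdir, "validate")
  ped <- read_pedigree_csv(require_artifact(file.path(outdir, "pedigree.csv"),
                                            "cmd_simulate"))
  phen <- read_phenotype_csv(file.path(outdir, "phenotypes.csv"))
  geno <- read_dosage_csv(require_artifact(
    file.path(outdir, "genotypes_qc.csv"), "cmd_qc"))
  breeds <- unique(ped$breed)
  target <- cfg$model$target_breed %||% breeds[1]
  other <- setdiff(breeds, target)
  gids <- rownames(geno$dosage)
  target_g <- gids[geno$breed[gids] == target]
  pool <- gids[geno$breed[gids] == other]
  grid <- gradient_groups(pool, target_g, step = cfg$validation$step,
                          max_added = cfg$validation$max_added,
                          seed = substream_seed(cfg$seed, "grouping"))
  vids <- select_validation(target_g, ped, cfg$validation$n_validation,
                            cfg$validation$window_years)
  gc_args <- cfg$gibbs
  gc_args$seed <- gc_args$seed %||% substream_seed(cfg$seed, "gibbs")
  report <- run_validation(list(pedigree = ped, genotypes = geno,
                                phenotypes = phen),
                           target, grid, vids,
                           do.call(gibbs_config, gc_args),
                           cfg$model$blend_weight)
  readr::write_csv(report, file.path(outdir, "validation_report.csv"))
  readr::write_csv(attr(report, "vc"),
                   file.path(outdir, "scenario_variance_components.csv"))
  pipeline_log(outdir, "validate",
               paste0(nrow(grid), " scenarios x ", length(vids),
                      " validation animals"))
  invisible(report)
}
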