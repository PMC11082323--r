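#' Nested gradient reference groups
#'
#' Random nested subsets of the other-breed genotyped pool of sizes
#' `0, step, 2 step, ..., max_added`, each extending the previous so that
#' scenario curves differ only by the animals added. The scenario reference
#' set is the union of `base_ids` with the subset.
#'
#' @param pool_ids Other-breed genotyped animal ids to sample from.
#' @param base_ids Target-breed genotyped animal ids always included.
#' @param step Increment size (default 300).
#' @param max_added Largest added count (must not exceed the pool).
#' @param seed Integer seed for the random (nested) draw.
#' @param nested Draw nested subsets (default) or independent redraws per
#'   scenario.
#' @return A tibble `scenario, n_reference, n_base, n_added, added` where
#'   `added` is a list-column of added ids.
#' @examples
#' gradient_groups(paste0("c", 1:10), paste0("b", 1:4), step = 5,
#'                 max_added = 10, seed = 1)
#' @export
gradient_groups <- function(pool_ids, base_ids, step = 300, max_added = NULL,
                            seed = 1L, nested = TRUE) {
  max_added <- max_added %||% (length(pool_ids) %/% step * step)
  assert_that(step >= 1, "step must be positive")
  assert_that(max_added <= length(pool_ids),
              paste0("pool too small: ", length(pool_ids), " available, ",
                     max_added, " requested"))
  sizes <- seq(0, max_added, by = step)
  with_seed(seed, {
    perm <- sample(pool_ids, max_added)
    purrr::map_dfr(seq_along(sizes), function(k) {
      add <- if (nested) {
        perm[seq_len(sizes[k])]
      } else if (sizes[k] > 0) {
        sample(pool_ids, sizes[k])
      } else character(0)
      tibble(scenario = k,
             n_reference = length(base_ids) + sizes[k],
             n_base = length(base_ids),
             n_added = sizes[k],
             added = list(add))
    })
  })
}

#' Select the validation group of young genotyped animals
#'
#' Among the genotyped target-breed animals born within `window_years` of
#' the latest birth year, the `n` youngest are selected, ties broken by
#' identifier order.
#'
#' @param genotyped_target_ids Candidate animal ids.
#' @param pedigree Pedigree tibble supplying `birth_year`.
#' @param n Validation group size (default 50).
#' @param window_years Birth-year window counted back from the latest birth
#'   year (default 4, i.e. years `max - 3 ... max`).
#' @return Character vector of `n` validation ids.
#' @export
select_validation <- function(genotyped_target_ids, pedigree, n = 50,
                              window_years = 4) {
  sub <- pedigree[pedigree$animal %in% genotyped_target_ids, , drop = FALSE]
  assert_that(nrow(sub) > 0 && !anyNA(sub$birth_year),
              "birth years required for validation selection")
  ymax <- max(sub$birth_year)
  elig <- sub[sub$birth_year > ymax - window_years, , drop = FALSE]
  if (nrow(elig) < n) {
    abort(paste0("only ", nrow(elig), " animals born in the last ",
                 window_years, " years; ", n, " requested (short by ",
                 n - nrow(elig), ")"))
  }
  elig <- elig[order(-elig$birth_year, elig$animal), , drop = FALSE]
  sort(elig$animal[seq_len(n)])
}

#' Prediction reliability of GEBVs
#'
#' Pearson correlation `R` between the full-data proxy breeding values
#' (`TBV*`, the GEBVs computed with the validation phenotypes included) and
#' the reduced-run GEBVs, plus its square. `R2` is reported as an unsigned
#' square; `R` carries the sign.
#'
#' @param tbv_star,gebv_reduced Aligned numeric vectors (length >= 3).
#' @return A tibble `R, R2` (both `NA` when either vector is degenerate).
#' @export
reliability <- function(tbv_star, gebv_reduced) {
  assert_that(length(tbv_star) == length(gebv_reduced) &&
                length(tbv_star) >= 3, "need >= 3 aligned pairs")
  if (isTRUE(all.equal(var(tbv_star), 0)) ||
      isTRUE(all.equal(var(gebv_reduced), 0))) {
    return(tibble(R = NA_real_, R2 = NA_real_))
  }
  r <- cor(tbv_star, gebv_reduced)
  tibble(R = r, R2 = r^2)
}

#' Bias and inflation of GEBVs
#'
#' Ordinary least squares of `TBV*` on the reduced-run GEBV:
#' `TBV* = b0 + b1 GEBV`. `b1 < 1` flags inflated (over-dispersed)
#' predictions, `b0` the estimation bias.
#'
#' @inheritParams reliability
#' @return A tibble `b0, b1`.
#' @export
bias_inflation <- function(tbv_star, gebv_reduced) {
  v <- var(gebv_reduced)
  assert_that(isTRUE(v > 0), "zero variance in GEBV: regression undefined")
  b1 <- cov(tbv_star, gebv_reduced) / v
  b0 <- mean(tbv_star) - b1 * mean(gebv_reduced)
  tibble(b0 = b0, b1 = b1)
}

#' Run one joint-reference scenario (full and reduced evaluations)
#'
#' Builds the scenario's genotype pool (target-breed genotyped animals plus
#' the scenario's added other-breed animals), constructs H-inverse once, and
#' runs the bivariate Gibbs evaluation twice: a full run with every
#' phenotype, and a reduced run with the validation animals' phenotype
#' records masked (their genotypes and pedigree links are retained). Fixed
#' -effect levels present only in the masked records are dropped from the
#' reduced design with a warning.
#'
#' @param data A dataset list (`pedigree, genotypes, phenotypes`) as from
#'   [simulate_dataset()].
#' @param target_breed Breed under evaluation.
#' @param added_ids Other-breed genotyped animals joining the reference.
#' @param validation_ids Target-breed animals whose phenotypes are masked in
#'   the reduced run.
#' @param config A [gibbs_config()].
#' @param blend_weight Passed to [blend_g()].
#' @return A list `full` and `reduced` ([gibbs_sample()] fits), plus
#'   `animal_ids` and the scenario bookkeeping.
#' @export
run_scenario <- function(data, target_breed, added_ids, validation_ids,
                         config = gibbs_config(), blend_weight = 0.05) {
  ped <- data$pedigree
  geno <- data$genotypes
  phen <- data$phenotypes
  breeds <- unique(ped$breed)
  other <- setdiff(breeds, target_breed)
  assert_that(length(other) == 1, "exactly two breeds expected")
  gids <- rownames(geno$dosage)
  target_g <- gids[geno$breed[gids] == target_breed]
  assert_that(all(validation_ids %in% target_g),
              "validation animals must be genotyped target-breed animals")

  keep_g <- c(target_g, intersect(gids, added_ids))
  geno_s <- subset_genotypes(geno, animals = keep_g)
  # markers monomorphic within this scenario's genotype pool carry no
  # genomic information for it and would break the VanRaden denominator
  p <- coded_freq(geno_s$dosage)
  geno_s <- subset_genotypes(geno_s, snps = which(p > 0 & p < 1))
  rel <- build_relationships(ped, geno_s, blend_weight = blend_weight)

  use_phen <- phen[phen$breed == target_breed |
                     phen$animal %in% added_ids, , drop = FALSE]
  design_full <- build_design(use_phen, ped$animal,
                              traits = c(target_breed, other))
  fit_full <- gibbs_sample(design_full, rel$H_inv, config)

  red_phen <- use_phen[!use_phen$animal %in% validation_ids, , drop = FALSE]
  dropped <- check_dropped_levels(use_phen, red_phen, target_breed)
  design_red <- build_design(red_phen, ped$animal,
                             traits = c(target_breed, other))
  fit_red <- gibbs_sample(design_red, rel$H_inv, config)

  list(full = fit_full, reduced = fit_red,
       animal_ids = ped$animal, target_genotyped = target_g,
       validation_ids = validation_ids, added_ids = added_ids,
       dropped_levels = dropped)
}

check_dropped_levels <- function(full, reduced, target_breed) {
  dropped <- list()
  for (f in intersect(c("farm", "year_class", "season", "parity"),
                      names(full))) {
    lost <- setdiff(unique(full[[f]][full$breed == target_breed]),
                    unique(reduced[[f]][reduced$breed == target_breed]))
    if (length(lost)) {
      warn(paste0("fixed-effect level(s) only in masked records dropped: ",
                  f, " = ", paste(lost, collapse = ", ")))
      dropped[[f]] <- lost
    }
  }
  dropped
}

#' Joint-reference-population validation experiment
#'
#' Runs every scenario of a [gradient_groups()] grid through
#' [run_scenario()] and reports reliability, bias and inflation for the
#' target breed, over the total genotyped target-breed population and over
#' the validation subset (the paper-style two column blocks).
#'
#' @param data Dataset list (`pedigree, genotypes, phenotypes`).
#' @param target_breed Breed under evaluation.
#' @param grid Output of [gradient_groups()].
#' @param validation_ids From [select_validation()].
#' @param config A [gibbs_config()] (per-scenario seeds derive from it).
#' @param blend_weight Passed to [blend_g()].
#' @return A tibble of class `validation_report`:
#'   `scenario_size, breed, trait, population, R, R2, b0, b1`, plus a
#'   `vc` attribute with per-scenario posterior variance components.
#' @export
run_validation <- function(data, target_breed, grid, validation_ids,
                           config = gibbs_config(), blend_weight = 0.05) {
  trait <- unique(data$phenotypes$trait)[1]
  vc_rows <- list()
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    cfg_k <- config
    cfg_k$seed <- substream_seed(config$seed, paste0("scenario", k))
    sc <- run_scenario(data, target_breed, grid$added[[k]], validation_ids,
                       cfg_k, blend_weight)
    full_g <- sc$full$gebv[sc$full$gebv$trait == target_breed, ]
    red_g <- sc$reduced$gebv[sc$reduced$gebv$trait == target_breed, ]
    tbv_star <- setNames(full_g$gebv, full_g$animal)
    gebv_red <- setNames(red_g$gebv, red_g$animal)
    vc_rows[[k]] <<- dplyr::bind_cols(
      tibble(scenario_size = grid$n_reference[k], run = c("full", "reduced")),
      dplyr::bind_rows(vc_means(sc$full), vc_means(sc$reduced)))
    purrr::map_dfr(
      list(total = sc$target_genotyped, validation = sc$validation_ids),
      function(ids) {
        rel <- reliability(tbv_star[ids], gebv_red[ids])
        bi <- tryCatch(bias_inflation(tbv_star[ids], gebv_red[ids]),
                       error = function(e) tibble(b0 = NA_real_, b1 = NA_real_))
        dplyr::bind_cols(rel, bi)
      }, .id = "population") |>
      dplyr::mutate(scenario_size = grid$n_reference[k],
                    breed = target_breed, trait = trait, .before = 1)
  })
  out <- rows[, c("scenario_size", "breed", "trait", "population",
                  "R", "R2", "b0", "b1")]
  attr(out, "vc") <- dplyr::bind_rows(vc_rows)
  class(out) <- c("validation_report", class(out))
  out
}

vc_means <- function(fit) {
  m <- colMeans(fit$vc_chain)
  tibble(sigma_a1 = m[["sigma_a1"]], sigma_a12 = m[["sigma_a12"]],
         sigma_a2 = m[["sigma_a2"]], sigma_e1 = m[["sigma_e1"]],
         sigma_e2 = m[["sigma_e2"]],
         h2_1 = heritability(m[["sigma_a1"]], m[["sigma_e1"]]),
         h2_2 = heritability(m[["sigma_a2"]], m[["sigma_e2"]]))
}
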