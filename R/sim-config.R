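#' Simulation configuration for a two-breed study
#'
#' Bundles every knob of the two-breed gene-drop simulator. Defaults describe
#' a desk-scale study: two breeds of 500 animals over 3 generations, 3
#' chromosomes of 1,000 SNPs each, founder divergence Fst = 0.10 (enough to
#' give near-zero cross-breed genomic kinship), heritabilities 0.30/0.25 with
#' genetic correlation 0.5, and per-breed trait scales mirroring the large
#' scale gap between a dual-purpose mountain breed and a specialised dairy
#' breed (305-day milk yield means ~4,126 vs ~10,117 kg, phenotypic SD ~1,406
#' vs ~2,045 kg).
#'
#' @param n_animals_per_breed Total animals per breed, split evenly across
#'   generations.
#' @param n_generations Number of discrete generations (1 = founders only).
#' @param n_snps Total SNPs, split evenly across chromosomes.
#' @param n_chromosomes Number of autosomes.
#' @param chrom_length_morgans Genetic length of each chromosome (Morgans).
#' @param chrom_length_bp Physical length of each chromosome (bp).
#' @param fst Balding-Nichols divergence between the two breeds, in `[0, 1)`.
#' @param founder_ld_morgans Decay scale (Morgans) of ancestral linkage
#'   disequilibrium among founder haplotypes; adjacent-site latent
#'   correlation is `exp(-d / scale)`. `0` draws founder sites
#'   independently (no ancestral LD).
#' @param ancestral_freq_range Range `(low, high)` in (0,1) for the uniform
#'   ancestral allele frequency.
#' @param h2 Length-2 heritability per breed-trait, each in `[0, 1)`.
#' @param genetic_correlation Correlation of marker effects across the two
#'   breed-traits, in `[-1, 1]`.
#' @param trait_means Length-2 per-breed trait means (trait units).
#' @param residual_scales Length-2 per-breed residual standard deviations.
#' @param breeds Length-2 breed labels.
#' @param trait_name Biological trait label; each breed's expression is its
#'   own breed-trait in the bivariate model.
#' @param n_farms Number of farm levels.
#' @param year_class_width Calving years are grouped into classes of this
#'   width (years).
#' @param season_rule Named list per breed mapping month (1-12) to a season
#'   label; defaults encode two climate-specific groupings (a short-autumn
#'   continental rule and a standard 3-month rule).
#' @param max_parity Parity levels 1..max_parity (records per cow capped at
#'   `max_records`).
#' @param max_records Maximum lactation records simulated per cow.
#' @param fixed_effect_sd Named fractions of the phenotypic SD used as the SD
#'   of farm / year-class / season / parity level effects.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_animals_per_breed = 60, n_snps = 150, seed = 1)
#' @export
sim_config <- function(n_animals_per_breed = 500,
                       n_generations = 3,
                       n_snps = 3000,
                       n_chromosomes = 3,
                       chrom_length_morgans = 1,
                       chrom_length_bp = 1e8,
                       fst = 0.10,
                       founder_ld_morgans = 0.05,
                       ancestral_freq_range = c(0.1, 0.9),
                       h2 = c(0.30, 0.25),
                       genetic_correlation = 0.5,
                       trait_means = c(4126, 10117),
                       residual_scales = c(1176, 1771),
                       breeds = c("XB", "CH"),
                       trait_name = "305dMY",
                       n_farms = 20,
                       year_class_width = 2,
                       season_rule = NULL,
                       max_parity = 6,
                       max_records = 3,
                       fixed_effect_sd = c(farm = 0.10, year_class = 0.05,
                                           season = 0.03, parity = 0.05),
                       seed = 1L) {
  assert_that(is_count(n_animals_per_breed) && is_count(n_generations) &&
                is_count(n_snps) && is_count(n_chromosomes),
              "counts must be integers >= 1")
  assert_that(is.numeric(fst) && fst >= 0 && fst < 1, "fst must lie in [0, 1)")
  assert_that(length(ancestral_freq_range) == 2 &&
                all(ancestral_freq_range > 0 & ancestral_freq_range < 1) &&
                ancestral_freq_range[1] <= ancestral_freq_range[2],
              "ancestral_freq_range must be (low, high) within (0, 1)")
  assert_that(length(h2) == 2 && all(h2 >= 0 & h2 < 1),
              "h2 must be two values in [0, 1)")
  assert_that(abs(genetic_correlation) <= 1,
              "genetic_correlation must lie in [-1, 1]")
  assert_that(length(breeds) == 2 && !anyDuplicated(breeds),
              "exactly two distinct breed labels required")
  assert_that(all(residual_scales > 0) || all(h2 == 0),
              "residual_scales must be positive")
  if (is.null(season_rule)) {
    season_rule <- list(
      # short-autumn continental rule: Apr-May spring, Jun-Aug summer,
      # Sep autumn, the rest winter
      c("W", "W", "W", "Sp", "Sp", "Su", "Su", "Su", "A", "W", "W", "W"),
      # standard three-month rule
      c("W", "W", "Sp", "Sp", "Sp", "Su", "Su", "Su", "A", "A", "A", "W"))
    names(season_rule) <- breeds
  }
  structure(list(
    n_animals_per_breed = as.integer(n_animals_per_breed),
    n_generations = as.integer(n_generations),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_morgans = chrom_length_morgans,
    chrom_length_bp = chrom_length_bp,
    fst = fst,
    founder_ld_morgans = founder_ld_morgans,
    ancestral_freq_range = ancestral_freq_range,
    h2 = setNames(h2, breeds),
    genetic_correlation = genetic_correlation,
    trait_means = setNames(trait_means, breeds),
    residual_scales = setNames(residual_scales, breeds),
    breeds = breeds,
    trait_name = trait_name,
    n_farms = as.integer(n_farms),
    year_class_width = year_class_width,
    season_rule = season_rule,
    max_parity = as.integer(max_parity),
    max_records = as.integer(max_records),
    fixed_effect_sd = fixed_effect_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", paste(x$breeds, collapse = " + "),
      ": ", x$n_animals_per_breed, " animals/breed, ",
      x$n_generations, " generations, ",
      x$n_snps, " SNPs on ", x$n_chromosomes, " chromosomes\n", sep = "")
  cat("fst ", x$fst, ", h2 ", paste(x$h2, collapse = "/"),
      ", r_g ", x$genetic_correlation, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
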