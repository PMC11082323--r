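#' Simulate lactation phenotypes and the accompanying truth record
#'
#' True breeding values are built from marker effects shared across the two
#' breed-traits: per-SNP effect pairs are drawn bivariate normal with the
#' configured genetic correlation, multiplied onto centred dosages, then each
#' breed-trait column is rescaled to its target additive variance
#' `h2 / (1 - h2) * residual_scale^2`. Every animal carries both breed-trait
#' breeding values but is phenotyped only for its own breed's trait; records
#' (one per parity) add breed mean, farm, year-class, season and parity level
#' effects plus an independent residual. Residuals are independent across
#' breeds (no cross-breed residual covariance, the breeds being reared
#' separately).
#'
#' @param pedigree Pedigree tibble from [simulate_pedigree()].
#' @param geno [genotypes()] for all pedigree animals.
#' @param config A [sim_config()].
#' @param seed Integer seed (default: derived from `config$seed`).
#' @return A list with elements
#'   * `phenotypes`: tibble `animal, breed, trait, value, farm, year_class,
#'     season, parity`;
#'   * `truth`: list with `tbv` (tibble `animal, breed_trait, tbv`),
#'     `variance_components` (true genetic/residual (co)variances),
#'     `realized_fst`, and the per-level fixed-effect values used.
#' @export
simulate_phenotypes <- function(pedigree, geno, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "genotypes"))
  assert_that(all(config$h2 < 1), "h2 = 1 not allowed: residual variance must be positive")
  if (is.null(seed)) seed <- substream_seed(config$seed, "phenotypes")
  breeds <- config$breeds
  founder <- pedigree$sire == "0" & pedigree$dam == "0"
  assert_that(all(breeds %in% pedigree$breed[founder]),
              "genotyped founders must cover both breeds")
  dos <- geno$dosage[pedigree$animal, , drop = FALSE]
  m <- ncol(dos)
  n <- nrow(dos)
  rg <- config$genetic_correlation
  sigma_a <- config$h2 / (1 - config$h2) * config$residual_scales^2
  sigma_e <- config$residual_scales^2
  sd_p <- sqrt(sigma_a + sigma_e)

  with_seed(seed, {
    # correlated marker effect pairs
    z1 <- rnorm(m); z2 <- rnorm(m)
    alpha <- cbind(z1, rg * z1 + sqrt(1 - rg^2) * z2)
    Mc <- sweep(dos, 2, colMeans(dos))
    tbv_raw <- Mc %*% alpha
    tbv <- matrix(0, n, 2, dimnames = list(pedigree$animal, breeds))
    for (k in 1:2) {
      own <- pedigree$breed == breeds[k]
      v <- var(tbv_raw[own, k])
      if (sigma_a[k] > 0 && v > 0) {
        tbv[, k] <- tbv_raw[, k] * sqrt(sigma_a[k] / v)
      }
    }

    # per-level fixed effect values, per breed
    effects <- lapply(seq_along(breeds), function(k) {
      f <- config$fixed_effect_sd
      seasons <- unique(config$season_rule[[breeds[k]]])
      list(farm = rnorm(config$n_farms, 0, f[["farm"]] * sd_p[k]),
           season = setNames(rnorm(length(seasons), 0, f[["season"]] * sd_p[k]),
                             seasons),
           parity = rnorm(config$max_parity, 0, f[["parity"]] * sd_p[k]))
    })
    names(effects) <- breeds

    years <- pedigree$birth_year
    recs <- purrr::map_dfr(seq_len(n), function(i) {
      b <- pedigree$breed[i]
      k <- match(b, breeds)
      n_rec <- sample.int(min(config$max_records, config$max_parity), 1L)
      parity <- seq_len(n_rec)
      calving_year <- years[i] + 1L + parity
      month <- sample.int(12L, n_rec, replace = TRUE)
      season <- config$season_rule[[b]][month]
      farm <- sample.int(config$n_farms, n_rec, replace = TRUE)
      tibble(animal = pedigree$animal[i], breed = b,
             trait = config$trait_name,
             farm = farm, year_class = calving_year, season = season,
             parity = pmin(parity, config$max_parity),
             .tbv = tbv[i, k], .k = k)
    })
    # group calving years into classes of configured width
    y0 <- min(recs$year_class)
    recs$year_class <- sprintf("Y%02d", (recs$year_class - y0) %/%
                                 config$year_class_width + 1L)
    # year-class effects drawn per breed after classes are known
    yc_levels <- sort(unique(recs$year_class))
    yc_eff <- lapply(seq_along(breeds), function(k) {
      setNames(rnorm(length(yc_levels),
                     0, config$fixed_effect_sd[["year_class"]] * sd_p[k]),
               yc_levels)
    })
    names(yc_eff) <- breeds

    k <- recs$.k
    value <- config$trait_means[k] + recs$.tbv +
      purrr::map_dbl(seq_len(nrow(recs)), function(r) {
        e <- effects[[recs$breed[r]]]
        e$farm[recs$farm[r]] + yc_eff[[recs$breed[r]]][recs$year_class[r]] +
          e$season[[recs$season[r]]] + e$parity[recs$parity[r]]
      }) +
      rnorm(nrow(recs), 0, config$residual_scales[k])
    phen <- recs |>
      dplyr::mutate(value = value, farm = sprintf("F%02d", .data$farm),
                    parity = as.integer(.data$parity)) |>
      dplyr::select("animal", "breed", "trait", "value", "farm",
                    "year_class", "season", "parity")

    tbv_long <- tibble(animal = rep(pedigree$animal, 2),
                       breed_trait = rep(breeds, each = n),
                       tbv = c(tbv[, 1], tbv[, 2]))
    gcov <- if (all(sigma_a > 0)) rg * sqrt(prod(sigma_a)) else 0
    truth <- list(
      tbv = tbv_long,
      variance_components = list(
        sigma_a = setNames(as.numeric(sigma_a), breeds),
        sigma_a12 = gcov,
        sigma_e = setNames(as.numeric(sigma_e), breeds),
        h2 = setNames(as.numeric(config$h2), breeds),
        genetic_correlation = rg),
      realized_fst = hudson_fst(geno, breeds),
      fixed_effects = list(per_breed = effects, year_class = yc_eff))
    list(phenotypes = phen, truth = truth)
  })
}

#' Simulate a complete two-breed study
#'
#' One-call wrapper chaining [simulate_founder_frequencies()],
#' [simulate_pedigree()], [simulate_snp_map()], [drop_genotypes()] and
#' [simulate_phenotypes()], each on a named substream of `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list `pedigree, genotypes, map, founder_freqs, phenotypes,
#'   truth, config`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_animals_per_breed = 40, n_snps = 120,
#'                                   seed = 7))
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ff <- simulate_founder_frequencies(
    config$n_snps, config$fst, config$ancestral_freq_range, config$breeds,
    seed = substream_seed(config$seed, "founders"))
  ped <- simulate_pedigree(config)
  map <- simulate_snp_map(config$n_snps, config$n_chromosomes,
                          config$chrom_length_bp)
  geno <- drop_genotypes(ped, ff, map,
                         chrom_length_morgans = config$chrom_length_morgans,
                         founder_ld_morgans = config$founder_ld_morgans,
                         seed = substream_seed(config$seed, "genedrop"))
  phe <- simulate_phenotypes(ped, geno, config)
  list(pedigree = ped, genotypes = geno, map = map, founder_freqs = ff,
       phenotypes = phe$phenotypes, truth = phe$truth, config = config)
}
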