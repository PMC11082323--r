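test_that("founder frequencies follow the Balding-Nichols divergence model", {
  # degenerate case: no divergence means identical breed frequencies
  ff0 <- simulate_founder_frequencies(50, fst = 0, seed = 3)
  expect_identical(ff0$XB, ff0$p_ancestral)
  expect_identical(ff0$CH, ff0$p_ancestral)

  # seeded determinism, and frequencies stay inside (0, 1)
  a <- simulate_founder_frequencies(200, fst = 0.2, seed = 9)
  b <- simulate_founder_frequencies(200, fst = 0.2, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$XB > 0 & a$XB < 1 & a$CH > 0 & a$CH < 1))

  # population-level Hudson Fst over SNPs recovers the nominal value
  est <- vapply(1:10, function(s) {
    ff <- simulate_founder_frequencies(5000, fst = 0.1, seed = s)
    p1 <- ff$XB; p2 <- ff$CH
    sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
  }, numeric(1))
  expect_true(all(abs(est - 0.1) < 0.02))

  expect_error(simulate_founder_frequencies(10, fst = 1), "fst")
  expect_error(simulate_founder_frequencies(10, fst = -0.1), "fst")
})

test_that("simulated pedigrees are acyclic with the configured generation sizes", {
  cfg1 <- sim_config(n_animals_per_breed = 25, n_generations = 1, seed = 5)
  ped1 <- simulate_pedigree(cfg1)
  expect_true(all(ped1$sire == "0" & ped1$dam == "0"))

  cfg <- sim_config(n_animals_per_breed = 100, n_generations = 3, seed = 5)
  ped <- simulate_pedigree(cfg)
  # generation counts from an exhaustive ancestor walk: depth = 1 + max
  # parental depth
  depth <- setNames(rep(NA_integer_, nrow(ped)), ped$animal)
  walk <- function(a) {
    if (!is.na(depth[[a]])) return(depth[[a]])
    r <- which(ped$animal == a)
    dep <- if (ped$sire[r] == "0") 1L else {
      1L + max(walk(ped$sire[r]), walk(ped$dam[r]))
    }
    depth[[a]] <<- dep
    dep
  }
  for (a in ped$animal) walk(a)
  for (b in c("XB", "CH")) {
    expect_equal(as.integer(table(depth[ped$animal[ped$breed == b]])),
                 c(34L, 33L, 33L))
  }
  # parents always precede offspring, so no animal is its own ancestor
  pos <- setNames(seq_len(nrow(ped)), ped$animal)
  nonf <- ped$sire != "0"
  expect_true(all(pos[ped$sire[nonf]] < pos[ped$animal[nonf]]))
  expect_true(all(pos[ped$dam[nonf]] < pos[ped$animal[nonf]]))
})

test_that("gene drop transmits unrecombined gametes at zero map length", {
  # direct gamete check: with no crossovers the gamete is one whole parental
  # haplotype
  h1 <- rep(1L, 40); h2 <- rep(0L, 40)
  for (k in 1:10) {
    g <- ssgblup:::make_gamete(h1, h2, list(1:40), list(seq(0, 0, length.out = 40)),
                               chrom_len = 0)
    expect_true(all(g == h1) || all(g == h2))
  }

  # fixed founder allele propagates: frequency 1 gives dosage 2 everywhere
  ped <- tibble::tibble(animal = c("f1", "f2", "c1"),
                        sire = c("0", "0", "f1"), dam = c("0", "0", "f2"),
                        breed = "XB")
  map <- snp_map(paste0("s", 1:12), chrom = 1, pos_bp = seq(1000, 12000, 1000))
  ff <- tibble::tibble(XB = rep(1, 12))
  g <- drop_genotypes(ped, ff, map, chrom_length_morgans = 0, seed = 2)
  expect_true(all(g$dosage == 2))

  # one known parent is rejected
  bad <- tibble::tibble(animal = c("f1", "c1"), sire = c("0", "f1"),
                        dam = c("0", "0"), breed = "XB")
  expect_error(drop_genotypes(bad, ff, map, seed = 1), "one known parent")
})

test_that("gene drop produces distance-dependent linkage disequilibrium", {
  # 500 founders; tight cluster of SNPs vs far-apart SNPs on a 1-Morgan
  # chromosome
  n <- 500
  ped <- tibble::tibble(animal = sprintf("f%03d", 1:n), sire = "0",
                        dam = "0", breed = "XB")
  map <- snp_map(sprintf("s%02d", 1:22), chrom = 1,
                 pos_bp = c(round(seq(1e6, 1.001e6, length.out = 11)),
                            round(seq(5e7, 9.9e7, length.out = 11))))
  ff <- tibble::tibble(XB = rep(0.5, 22))
  g <- drop_genotypes(ped, ff, map, chrom_length_morgans = 1,
                      founder_ld_morgans = 0.05, seed = 31)
  d <- g$dosage
  near <- mean(vapply(1:10, function(j) ld_r2(d[, j], d[, j + 1]), numeric(1)))
  far_pairs <- utils::combn(12:22, 2)
  far <- mean(apply(far_pairs, 2, function(p) ld_r2(d[, p[1]], d[, p[2]])))
  expect_gt(near, far)
  expect_gt(near, 0.5)   # tightly linked cluster keeps high r2
  expect_lt(far, 0.05)   # 50+ cM pairs are effectively unlinked
})

test_that("phenotype simulation honours heritability and genetic correlation", {
  base <- sim_config(n_animals_per_breed = 30, n_generations = 1, n_snps = 60,
                     n_chromosomes = 1, seed = 7)

  # h2 = 0 collapses the breeding values of that trait
  cfg0 <- base; cfg0$h2[] <- c(0, 0.3)
  ds0 <- simulate_dataset(cfg0)
  tbv1 <- ds0$truth$tbv$tbv[ds0$truth$tbv$breed_trait == "XB"]
  expect_equal(var(tbv1), 0)

  # perfect genetic correlation makes the trait pair collinear
  cfg1 <- base; cfg1$genetic_correlation <- 1
  ds1 <- simulate_dataset(cfg1)
  wide <- tidyr::pivot_wider(ds1$truth$tbv, names_from = "breed_trait",
                             values_from = "tbv")
  expect_gt(abs(cor(wide$XB, wide$CH)), 1 - 1e-10)

  # h2 = 1 is rejected: residual variance must stay positive
  cfgbad <- base; cfgbad$h2[] <- c(1, 0.3)
  expect_error(simulate_dataset(cfgbad), "residual variance")
})

test_that("with fixed effects silenced, phenotypic variance is twice the
          genetic variance at h2 = 0.5", {
  cfg <- sim_config(n_animals_per_breed = 2000, n_generations = 1,
                    n_snps = 300, n_chromosomes = 1, h2 = c(0.5, 0.5),
                    fixed_effect_sd = c(farm = 0, year_class = 0,
                                        season = 0, parity = 0),
                    max_records = 1, seed = 17)
  ds <- simulate_dataset(cfg)
  for (b in c("XB", "CH")) {
    ph <- ds$phenotypes[ds$phenotypes$breed == b, ]
    tb <- ds$truth$tbv[ds$truth$tbv$breed_trait == b &
                         ds$truth$tbv$animal %in% ph$animal, ]
    expect_lt(abs(var(ph$value) / (2 * var(tb$tbv)) - 1), 0.10)
    # realized-heritability invariant: phenotype regressed on TBV has slope 1
    slope <- cov(ph$value, tb$tbv[match(ph$animal, tb$animal)]) /
      var(tb$tbv[match(ph$animal, tb$animal)])
    expect_lt(abs(slope - 1), 0.1)
  }
})

test_that("the full simulated dataset is reproducible and shows breed structure", {
  cfg <- sim_config(n_animals_per_breed = 40, n_snps = 150, n_chromosomes = 1,
                    seed = 12)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$pedigree, d2$pedigree)
  expect_identical(d1$genotypes$dosage, d2$genotypes$dosage)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$truth$tbv, d2$truth$tbv)

  # cross-breed kinship: with ancestral-frequency centring the between-breed
  # block mean sits nearer zero than the within-breed means
  G <- vanraden_g(d1$genotypes, freqs = d1$founder_freqs$p_ancestral)
  kb <- kinship_blocks(G, d1$genotypes$breed)
  between <- kb$mean_kinship[kb$group_a != kb$group_b]
  within <- kb$mean_kinship[kb$group_a == kb$group_b]
  expect_true(all(abs(between) < abs(within)))

  expect_true(d1$truth$realized_fst > 0 && d1$truth$realized_fst < 1)
})
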