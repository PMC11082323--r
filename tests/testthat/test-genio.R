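test_that("dosage CSV round-trips losslessly, missing token included", {
  d <- matrix(c(0, 1, 2, NA, 2, 0, 1, 1, 0, 2, NA, 1), 3, 4)
  g <- make_geno(d, breed = c("XB", "XB", "CH"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dosage_csv(g, path)
  g2 <- read_dosage_csv(path)
  expect_identical(unname(g2$dosage), unname(d))
  expect_identical(g2$breed, g$breed)
  expect_identical(rownames(g2$dosage), rownames(g$dosage))
})

test_that("PED/MAP round-trips and enforces the missing and biallelic rules", {
  d <- matrix(c(0, 1, 2, 1, NA, 2, 0, 0, 1, 2, 2, NA), 3, 4)
  g <- make_geno(d, breed = c("XB", "CH", "CH"))
  map <- snp_map(colnames(g$dosage), chrom = c(1, 1, 2, 2),
                 pos_bp = c(100, 200, 100, 300))
  ped_p <- withr::local_tempfile(fileext = ".ped")
  map_p <- withr::local_tempfile(fileext = ".map")
  write_plink_pedmap(g, map, ped_p, map_p)
  back <- read_plink_pedmap(ped_p, map_p, coded = map$allele_coded)
  expect_identical(unname(back$genotypes$dosage), unname(d))
  expect_identical(back$map$chrom, map$chrom)
  expect_identical(back$map$pos_bp, map$pos_bp)
  # "0 0" encodes a missing genotype
  expect_true(is.na(back$genotypes$dosage[2, 2]))

  # a third allele at any SNP is rejected, naming the SNP
  lines <- readLines(ped_p)
  lines[1] <- sub("^(\\S+ \\S+ \\S+ \\S+ \\S+ \\S+) \\S \\S",
                  "\\1 C A", lines[1])
  bad_p <- withr::local_tempfile(fileext = ".ped")
  writeLines(lines, bad_p)
  expect_error(read_plink_pedmap(bad_p, map_p), "biallelic")

  # duplicated animal ids are rejected
  dup_p <- withr::local_tempfile(fileext = ".ped")
  writeLines(c(readLines(ped_p), readLines(ped_p)[1]), dup_p)
  expect_error(read_plink_pedmap(dup_p, map_p), "duplicated")
})

test_that("simulator-written files reparse to the manifest dimensions", {
  ds <- shared_dataset()
  ped_p <- withr::local_tempfile(fileext = ".ped")
  map_p <- withr::local_tempfile(fileext = ".map")
  write_plink_pedmap(ds$genotypes, ds$map, ped_p, map_p)
  back <- read_plink_pedmap(ped_p, map_p, coded = ds$map$allele_coded)
  expect_identical(dim(back$genotypes$dosage), dim(ds$genotypes$dosage))
  expect_equal(back$genotypes$dosage, ds$genotypes$dosage,
               ignore_attr = FALSE, tolerance = 0)
})

test_that("animal call-rate filtering matches exhaustive per-animal counts", {
  set.seed(88)
  d <- matrix(sample(0:2, 20 * 50, replace = TRUE), 20, 50)
  # three animals pushed under 90% call rate (11% missing between them)
  for (i in c(3, 9, 14)) d[i, sample(50, 6)] <- NA
  # one animal at exactly the threshold: 5/50 = 10% missing -> call rate 0.90
  d[5, 1:5] <- NA
  g <- make_geno(d)
  res <- qc_animals(g, min_call_rate = 0.90)
  oracle_removed <- which(rowMeans(!is.na(d)) < 0.90)
  expect_identical(which(res$report$removed), oracle_removed)
  expect_identical(length(oracle_removed), 3L)
  expect_identical(nrow(res$genotypes$dosage), 17L)
  # at-threshold animal retained, complete animal retained
  expect_false(res$report$removed[5])
  expect_false(res$report$removed[1])
})

test_that("SNP filters replicate an independent rule-by-rule oracle", {
  # exact Hardy-Weinberg proportions score p = 1
  d_hwe <- matrix(c(rep(0, 25), rep(1, 50), rep(2, 25)), ncol = 1)
  g_hwe <- make_geno(d_hwe)
  m_hwe <- snp_map("s01", 1, 100)
  r <- qc_snps(g_hwe, m_hwe)
  expect_false(r$report$removed[1])
  expect_equal(ssgblup:::hwe_pvalue(d_hwe[, 1]), 1)

  # rare allele: MAF 0.005 fails the 0.01 floor
  d_maf <- matrix(c(1, rep(0, 99)), ncol = 1)
  r2 <- qc_snps(make_geno(d_maf), snp_map("s01", 1, 100))
  expect_true(r2$report$fail_maf[1])

  # 200-SNP panel with seeded violations vs a brute-force filter
  set.seed(41)
  n <- 80; m <- 200
  p_true <- runif(m, 0.05, 0.95)
  d <- sapply(p_true, function(p) rbinom(n, 2, p))
  viol_chrom <- 1:12
  viol_miss <- 13:24
  viol_maf <- 25:36
  viol_hwe <- 37:48
  for (j in viol_miss) d[sample(n, 10), j] <- NA      # 12.5% missing
  for (j in viol_maf) d[, j] <- rbinom(n, 2, 0.003)
  for (j in viol_hwe) d[, j] <- sample(c(0, 2), n, replace = TRUE)  # no hets
  g <- make_geno(d)
  map <- snp_map(colnames(g$dosage),
                 chrom = ifelse(seq_len(m) %in% viol_chrom, 31L, 1L),
                 pos_bp = seq_len(m) * 100)
  res <- qc_snps(g, map, max_missing = 0.10, min_maf = 0.01,
                 hwe_alpha = 1e-6, chromosomes = 1:30)
  oracle <- vapply(seq_len(m), function(j) {
    x <- d[, j]
    pj <- mean(x, na.rm = TRUE) / 2
    maf <- min(pj, 1 - pj)
    keep <- map$chrom[j] %in% 1:30 &&
      mean(is.na(x)) < 0.10 &&
      maf > 0.01 &&
      ssgblup:::hwe_pvalue(x) > 1e-6
    !keep
  }, logical(1))
  expect_identical(res$report$removed, oracle)
  expect_true(all(viol_chrom %in% which(oracle)))
  expect_identical(ncol(res$genotypes$dosage), sum(!oracle))

  # idempotence: filtering the survivors again removes nothing
  res2 <- qc_snps(res$genotypes, res$map, max_missing = 0.10, min_maf = 0.01,
                  hwe_alpha = 1e-6, chromosomes = 1:30)
  expect_identical(res2$map$snp_id, res$map$snp_id)
})

test_that("marker-panel intersection behaves as a set intersection", {
  geno_for <- function(ids, n_animals, breed, prefix) {
    genotypes(matrix(1, n_animals, length(ids),
                     dimnames = list(sprintf("%s%02d", prefix,
                                             seq_len(n_animals)), ids)),
              breed)
  }
  map_a <- snp_map(sprintf("m%03d", 1:120), 1, seq_len(120) * 10)
  g_a <- geno_for(map_a$snp_id, 10, "XB", "a")
  map_b <- snp_map(sprintf("m%03d", 6:120), 1, (6:120) * 10)
  g_b <- geno_for(map_b$snp_id, 8, "CH", "b")

  out <- intersect_snps(g_a, map_a, g_b, map_b)
  expect_identical(out$map$snp_id, intersect(map_a$snp_id, map_b$snp_id))
  expect_identical(ncol(out$genotypes_a$dosage), 115L)
  expect_identical(colnames(out$genotypes_a$dosage),
                   colnames(out$genotypes_b$dosage))

  # identical maps keep everything; disjoint maps error
  same <- intersect_snps(g_a, map_a, g_a, map_a)
  expect_identical(nrow(same$map), 120L)
  map_c <- snp_map(sprintf("x%03d", 1:5), 1, 1:5 * 10)
  g_c <- geno_for(map_c$snp_id, 4, "CH", "c")
  expect_error(intersect_snps(g_a, map_a, g_c, map_c), "shared")

  # two panels of 120 and 115 sharing exactly 100 ids
  map_d <- snp_map(c(sprintf("m%03d", 1:100), sprintf("z%03d", 1:15)), 1,
                   seq_len(115) * 10)
  g_d <- geno_for(map_d$snp_id, 6, "CH", "d")
  out2 <- intersect_snps(g_a, map_a, g_d, map_d)
  expect_identical(nrow(out2$map), 100L)
})

test_that("mean imputation fills 2 p-hat within breed", {
  # p = 0.5 with one missing cell imputes exactly 1
  d <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2)
  g <- make_geno(d)
  imp <- impute_mean(g)
  expect_equal(imp$dosage[3, 1], 1)

  # complete matrix unchanged
  d2 <- matrix(c(0, 1, 2, 2), 2, 2)
  g2 <- make_geno(d2)
  expect_identical(impute_mean(g2)$dosage, g2$dosage)

  # random masking: imputed values equal the within-breed 2 p-hat oracle
  set.seed(14)
  full <- matrix(rbinom(40 * 30, 2, 0.4), 40, 30)
  masked <- full
  holes <- sample(length(full), 0.1 * length(full))
  masked[holes] <- NA
  breed <- rep(c("XB", "CH"), each = 20)
  gm <- make_geno(masked, breed = breed)
  im <- impute_mean(gm)
  for (cell in holes) {
    i <- (cell - 1) %% 40 + 1
    j <- (cell - 1) %/% 40 + 1
    same_breed <- which(breed == breed[i])
    expect_equal(im$dosage[i, j],
                 mean(masked[same_breed, j], na.rm = TRUE))
  }

  # entirely missing SNP within a breed errors
  bad <- full
  bad[1:20, 3] <- NA
  expect_error(impute_mean(make_geno(bad, breed = breed)),
               "entirely missing")
})

test_that("phenotype screening applies closed per-breed bounds", {
  rules <- default_screening_rules()
  phen <- tibble::tibble(
    animal = sprintf("a%02d", 1:4), breed = "CH", trait = "305dMY",
    value = c(3999, 4000, 15000, 15001),
    farm = "F01", year_class = "Y01", season = "W", parity = 1L)
  out <- screen_phenotypes(phen, rules)
  expect_identical(out$phenotypes$value, c(4000, 15000))
  expect_identical(out$report$n_removed, 2L)

  # unknown (breed, trait) combinations are rejected
  phen_bad <- dplyr::mutate(phen, trait = "unheard-of")
  expect_error(screen_phenotypes(phen_bad, rules), "no screening rule")

  # 1,000 synthetic records vs brute-force bound check
  set.seed(6)
  many <- tibble::tibble(
    animal = sprintf("x%04d", 1:1000),
    breed = sample(c("XB", "CH"), 1000, replace = TRUE),
    trait = "305dMY",
    value = runif(1000, 0, 20000),
    farm = "F01", year_class = "Y01", season = "W", parity = 1L)
  res <- screen_phenotypes(many, rules)
  keep_oracle <- ifelse(many$breed == "XB",
                        many$value >= 2000 & many$value <= 13000,
                        many$value >= 4000 & many$value <= 15000)
  expect_identical(res$phenotypes$animal, many$animal[keep_oracle])
})

test_that("somatic cell count transforms to score on the log2 scale", {
  expect_equal(scc_to_scs(100), 3)
  expect_equal(scc_to_scs(400), 5)
  # at the screening ceiling of 25,000 the score reaches ~10.97
  expect_lt(abs(scc_to_scs(25000) - 10.9658), 1e-3)
  expect_error(scc_to_scs(0), "positive")
})
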