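#' Remove animals with low genotyping call rate
#'
#' @param geno A [genotypes()] object.
#' @param min_call_rate Minimum fraction of non-missing genotypes an animal
#'   must reach to be retained (default 0.90; an animal at exactly the
#'   threshold is retained).
#' @return A list `genotypes` (filtered) and `report`: a tibble with one row
#'   per animal (`animal, breed, call_rate, removed`).
#' @export
qc_animals <- function(geno, min_call_rate = 0.90) {
  stopifnot(inherits(geno, "genotypes"))
  assert_that(nrow(geno$dosage) > 0, "empty genotype matrix")
  cr <- rowMeans(!is.na(geno$dosage))
  removed <- cr < min_call_rate
  assert_that(!all(removed), "quality control removed every animal")
  report <- tibble(animal = rownames(geno$dosage),
                   breed = unname(geno$breed[rownames(geno$dosage)]),
                   call_rate = unname(cr), removed = unname(removed))
  list(genotypes = subset_genotypes(geno, animals = which(!removed)),
       report = report)
}

# 1-df chi-square test of Hardy-Weinberg proportions from dosages
hwe_pvalue <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0) return(NA_real_)
  counts <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((counts - expd)^2 / expd)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' SNP quality control
#'
#' A SNP is retained iff its chromosome is in `chromosomes`, its missing
#' fraction is below `max_missing`, its minor allele frequency exceeds
#' `min_maf`, and its Hardy-Weinberg 1-df chi-square p-value exceeds
#' `hwe_alpha` within every breed present (the HWE test is breed-wise, since
#' pooling diverged breeds induces a Wahlund excess of homozygotes).
#'
#' @param geno A [genotypes()] object.
#' @param map Matching [snp_map()].
#' @param max_missing Maximum missing fraction (exclusive bound).
#' @param min_maf Minimum minor allele frequency (exclusive bound).
#' @param hwe_alpha HWE p-value threshold (exclusive bound).
#' @param chromosomes Retained chromosome set (default 1-30, the chip's
#'   autosome numbering).
#' @param hwe_exact Use the exact HWE test (mid-p-free enumeration of
#'   heterozygote counts) instead of the chi-square approximation.
#' @return A list `genotypes`, `map` (both filtered) and `report`, a tibble
#'   with one row per SNP and per-rule logicals
#'   (`fail_chrom, fail_missing, fail_maf, fail_hwe, removed`).
#' @export
qc_snps <- function(geno, map, max_missing = 0.10, min_maf = 0.01,
                    hwe_alpha = 1e-6, chromosomes = 1:30,
                    hwe_exact = FALSE) {
  stopifnot(inherits(geno, "genotypes"))
  assert_that(identical(map$snp_id, colnames(geno$dosage)),
              "map rows must align with genotype columns")
  d <- geno$dosage
  missf <- colMeans(is.na(d))
  p <- coded_freq(d)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  breeds <- unique(geno$breed)
  hwe_fun <- if (hwe_exact) hwe_exact_pvalue else hwe_pvalue
  hwe_p <- sapply(seq_len(ncol(d)), function(j) {
    ps <- vapply(breeds, function(b) {
      pv <- hwe_fun(d[geno$breed == b, j])
      if (is.na(pv)) 1 else pv
    }, numeric(1))
    min(ps)
  })
  report <- tibble(
    snp_id = map$snp_id,
    fail_chrom = !(map$chrom %in% chromosomes),
    fail_missing = unname(missf >= max_missing),
    fail_maf = unname(maf <= min_maf),
    fail_hwe = unname(hwe_p <= hwe_alpha))
  report$removed <- report$fail_chrom | report$fail_missing |
    report$fail_maf | report$fail_hwe
  keep <- which(!report$removed)
  if (!length(keep)) warn("SNP quality control removed every SNP")
  list(genotypes = subset_genotypes(geno, snps = keep),
       map = map[keep, , drop = FALSE],
       report = report)
}

# Exact test of HWE (Wigginton-style enumeration of heterozygote counts)
hwe_exact_pvalue <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0) return(NA_real_)
  n_ab <- sum(d == 1)
  n_b <- 2 * sum(d == 2) + n_ab
  n_a <- 2 * n - n_b
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hets == n_ab] * (1 + 1e-12)])
}

#' Intersect the marker sets of two post-QC panels
#'
#' @param geno_a,geno_b [genotypes()] objects (for example, one per breed).
#' @param map_a,map_b Their [snp_map()]s.
#' @return A list `genotypes_a`, `genotypes_b`, `map` restricted and
#'   column-aligned to the shared SNP ids (in `map_a` order).
#' @export
intersect_snps <- function(geno_a, map_a, geno_b, map_b) {
  shared <- intersect(map_a$snp_id, map_b$snp_id)
  assert_that(length(shared) > 0, "no SNPs shared between the two panels")
  list(genotypes_a = subset_genotypes(geno_a, snps = shared),
       genotypes_b = subset_genotypes(geno_b, snps = shared),
       map = map_a[match(shared, map_a$snp_id), , drop = FALSE])
}

#' Mean-impute missing dosages within breed
#'
#' Each missing cell is replaced by twice the coded-allele frequency computed
#' from the non-missing entries of that SNP within the animal's breed.
#'
#' @param geno A [genotypes()] object.
#' @return A `genotypes`-like object with no missing values; imputed cells
#'   are fractional, so the dosage matrix is returned in a plain list (class
#'   `genotypes_imputed`) with the same `dosage`/`breed` fields.
#' @export
impute_mean <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  d <- geno$dosage
  if (!anyNA(d)) return(geno)
  for (b in unique(geno$breed)) {
    rows <- which(geno$breed == b)
    sub <- d[rows, , drop = FALSE]
    nmiss <- colSums(is.na(sub))
    bad <- nmiss == length(rows)
    if (any(bad)) {
      abort(paste0("SNP entirely missing within breed ", b, ": ",
                   paste(head(colnames(d)[bad], 5), collapse = ", ")))
    }
    jj <- which(nmiss > 0)
    for (j in jj) {
      mu <- mean(sub[, j], na.rm = TRUE)
      sub[is.na(sub[, j]), j] <- mu
    }
    d[rows, ] <- sub
  }
  structure(list(dosage = d, breed = geno$breed),
            class = c("genotypes_imputed", "genotypes"))
}

#' Screen phenotype records against per-breed trait bounds
#'
#' Records with values outside the closed interval `[lower, upper]` for
#' their (breed, trait) are removed; values exactly at a bound are retained.
#'
#' @param phen Phenotype tibble (`animal, breed, trait, value, ...`).
#' @param rules Tibble with columns `breed, trait, lower, upper` covering
#'   every (breed, trait) present in `phen`.
#' @return A list `phenotypes` (survivors) and `report` (per-rule counts:
#'   `breed, trait, n_in, n_removed, n_retained`).
#' @export
screen_phenotypes <- function(phen, rules) {
  need <- dplyr::distinct(phen, .data$breed, .data$trait)
  have <- dplyr::distinct(rules, .data$breed, .data$trait)
  miss <- dplyr::anti_join(need, have, by = c("breed", "trait"))
  if (nrow(miss) > 0) {
    abort(paste0("no screening rule for: ",
                 paste(miss$breed, miss$trait, sep = "/", collapse = ", ")))
  }
  joined <- dplyr::left_join(phen, rules, by = c("breed", "trait"))
  keep <- joined$value >= joined$lower & joined$value <= joined$upper
  report <- joined |>
    dplyr::mutate(.keep_rec = keep) |>
    dplyr::group_by(.data$breed, .data$trait) |>
    dplyr::summarise(n_in = dplyr::n(),
                     n_removed = sum(!.data$.keep_rec),
                     n_retained = sum(.data$.keep_rec), .groups = "drop")
  list(phenotypes = phen[keep, , drop = FALSE], report = report)
}

#' Default phenotype screening bounds
#'
#' Screening bounds for milk traits in the two-breed study: 305-day milk
#' yield 2,000-13,000 kg for the first (dual-purpose) breed and
#' 4,000-15,000 kg for the second (dairy) breed; fat and protein percentage
#' 2-7 for both; somatic cell count 0-25,000 (1,000 cells/mL). Bounds are
#' configuration, not constants; edit the returned tibble to taste.
#'
#' @param breeds Two breed labels.
#' @return A tibble `breed, trait, lower, upper`.
#' @export
default_screening_rules <- function(breeds = c("XB", "CH")) {
  tibble(
    breed = rep(breeds, each = 4),
    trait = rep(c("305dMY", "MFP", "MPP", "SCC"), 2),
    lower = c(2000, 2, 2, 0, 4000, 2, 2, 0),
    upper = c(13000, 7, 7, 25000, 15000, 7, 7, 25000))
}

#' Convert somatic cell count to somatic cell score
#'
#' `SCS = log2(SCC / 100) + 3` with SCC in 1,000 cells/mL, the standard
#' dairy-recording transform (SCC of 100,000 cells/mL maps to score 3).
#'
#' @param scc Somatic cell count (1,000 cells/mL), strictly positive.
#' @return Somatic cell score.
#' @examples
#' scc_to_scs(c(100, 400))
#' @export
scc_to_scs <- function(scc) {
  assert_that(all(scc > 0), "SCC must be strictly positive")
  log2(scc / 100) + 3
}
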