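#' Simulate diverged founder allele frequencies for two breeds
#'
#' Draws an ancestral allele frequency per SNP uniformly on `freq_range`, then
#' each breed's frequency from the Balding-Nichols distribution
#' `Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst)`. With `fst = 0` both
#' breeds inherit the ancestral frequency unchanged.
#'
#' @param n_snps Number of SNPs.
#' @param fst Divergence parameter in `[0, 1)`.
#' @param freq_range Range for the uniform ancestral frequency, within (0,1).
#' @param breeds Two breed labels naming the output columns.
#' @param seed Integer seed.
#' @return A tibble with columns `snp` (index), `p_ancestral`, and one
#'   frequency column per breed, all values in (0, 1).
#' @examples
#' simulate_founder_frequencies(5, fst = 0.1, seed = 1)
#' @export
simulate_founder_frequencies <- function(n_snps, fst,
                                         freq_range = c(0.1, 0.9),
                                         breeds = c("XB", "CH"),
                                         seed = 1L) {
  assert_that(is.numeric(fst) && length(fst) == 1 && fst >= 0 && fst < 1,
              "fst must lie in [0, 1)")
  assert_that(is_count(n_snps), "n_snps must be a positive integer")
  with_seed(seed, {
    p <- runif(n_snps, freq_range[1], freq_range[2])
    draw <- function() {
      if (fst == 0) return(p)
      q <- rbeta(n_snps, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
      pmin(pmax(q, 1e-6), 1 - 1e-6)
    }
    out <- tibble(snp = seq_len(n_snps), p_ancestral = p)
    for (b in breeds) out[[b]] <- draw()
    out
  })
}

#' Hudson's Fst estimator from genotype dosages
#'
#' Ratio-of-means Hudson estimator over SNPs, computed from realized allele
#' frequencies of two groups of diploid genotypes.
#'
#' @param geno A [genotypes()] object covering both breeds.
#' @param breeds Optional two breed labels to compare (default: the two
#'   present).
#' @return A single Fst estimate.
#' @export
hudson_fst <- function(geno, breeds = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  if (is.null(breeds)) breeds <- unique(geno$breed)
  assert_that(length(breeds) == 2, "exactly two breeds required")
  d1 <- geno$dosage[geno$breed == breeds[1], , drop = FALSE]
  d2 <- geno$dosage[geno$breed == breeds[2], , drop = FALSE]
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(d1))
  n2 <- 2 * colSums(!is.na(d2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
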