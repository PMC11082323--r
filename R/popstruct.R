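#' Pairwise linkage disequilibrium r-squared
#'
#' Composite (dosage-correlation) estimator: the squared Pearson correlation
#' of the two dosage vectors, pairwise-deleting missing entries. This is the
#' unphased-genotype LD estimator; it does not require haplotypes.
#'
#' @param dosage_a,dosage_b Numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @examples
#' ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2))
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  assert_that(length(dosage_a) == length(dosage_b),
              "dosage vectors must have equal length")
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  va <- var(dosage_a[ok]); vb <- var(dosage_b[ok])
  assert_that(isTRUE(va > 0) && isTRUE(vb > 0),
              "zero-variance dosage vector: monomorphic SNPs must be filtered before LD")
  min(cor(dosage_a[ok], dosage_b[ok])^2, 1)
}

#' Binned LD decay curve
#'
#' Computes r-squared for every within-chromosome SNP pair up to
#' `max_distance_kb` apart and averages it in distance bins of `bin_kb`.
#' Monomorphic SNPs are skipped; missing dosages are pairwise-deleted
#' (through [stats::cor()] with `use = "pairwise.complete.obs"`).
#'
#' @param geno A [genotypes()] object.
#' @param map Matching [snp_map()], sorted by (chromosome, position).
#' @param max_distance_kb Maximum pair distance (kb).
#' @param bin_kb Bin width (kb, default 1).
#' @param group Optional subset: breed label(s) whose animals are used.
#' @return A tibble of class `ld_decay` with columns
#'   `bin_start_kb, bin_end_kb, mean_r2, n_pairs` (empty bins kept with
#'   `n_pairs = 0`).
#' @export
ld_decay <- function(geno, map, max_distance_kb = 500, bin_kb = 1,
                     group = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  assert_that(identical(map$snp_id, colnames(geno$dosage)),
              "map rows must align with genotype columns")
  d <- geno$dosage
  if (!is.null(group)) d <- d[geno$breed %in% group, , drop = FALSE]
  ord <- order(map$chrom, map$pos_bp)
  assert_that(identical(ord, seq_len(nrow(map))),
              "map must be sorted by (chromosome, position)")
  n_bins <- ceiling(max_distance_kb / bin_kb)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    sub <- d[, idx, drop = FALSE]
    v <- apply(sub, 2, var, na.rm = TRUE)
    poly <- which(!is.na(v) & v > 0)
    if (length(poly) < 2) next
    sub <- sub[, poly, drop = FALSE]
    pos <- map$pos_bp[idx][poly]
    r2 <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))^2
    dist_kb <- abs(outer(pos, pos, "-")) / 1000
    ut <- upper.tri(dist_kb)
    sel <- ut & dist_kb <= max_distance_kb & !is.na(r2)
    bin <- pmin(floor(dist_kb[sel] / bin_kb) + 1L, n_bins)
    if (!length(bin)) next
    sums <- sums + unname(vapply(seq_len(n_bins), function(b)
      sum(r2[sel][bin == b]), numeric(1)))
    counts <- counts + unname(vapply(seq_len(n_bins), function(b)
      sum(bin == b), integer(1)))
  }
  out <- tibble(bin_start_kb = (seq_len(n_bins) - 1) * bin_kb,
                bin_end_kb = seq_len(n_bins) * bin_kb,
                mean_r2 = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
                n_pairs = counts)
  class(out) <- c("ld_decay", class(out))
  out
}

#' Principal components of a genomic relationship matrix
#'
#' Uncentred eigendecomposition of G (G already encodes centring through its
#' allele-frequency construction). Components are ordered by eigenvalue; the
#' percentage of variance is each eigenvalue's share of the trace.
#'
#' @param G Symmetric genomic relationship matrix with animal dimnames.
#' @param tol Relative symmetry tolerance.
#' @return An object of class `grm_pca`: list with `eigenvalues`
#'   (descending), `vectors` (orthonormal columns), `pct_variance`.
#' @export
grm_pca <- function(G, tol = 1e-8) {
  check_symmetric(G, tol, "G")
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  structure(list(eigenvalues = ee$values,
                 vectors = ee$vectors,
                 animal = rownames(G) %||% as.character(seq_len(nrow(G))),
                 pct_variance = ee$values / sum(ee$values) * 100),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  cat("<grm_pca> ", length(x$eigenvalues), " components; PC1-3 explain ",
      paste(sprintf("%.2f%%", head(x$pct_variance, 3)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn grm_pca Per-animal scores as a tibble
#'   (`animal, component, score, pct_variance`).
#' @param x A `grm_pca` object.
#' @param n_components Number of leading components to return.
#' @param ... Unused.
#' @export
tidy.grm_pca <- function(x, n_components = 3, ...) {
  k <- min(n_components, length(x$eigenvalues))
  purrr::map_dfr(seq_len(k), function(j) {
    tibble(animal = x$animal, component = j,
           score = x$vectors[, j] * sqrt(max(x$eigenvalues[j], 0)),
           pct_variance = x$pct_variance[j])
  })
}

#' @describeIn grm_pca One-row summary (trace, leading shares).
#' @export
glance.grm_pca <- function(x, ...) {
  tibble(n = length(x$eigenvalues),
         trace = sum(x$eigenvalues),
         pc1_pct = x$pct_variance[1],
         pc2_pct = x$pct_variance[2] %||% NA_real_,
         pc3_pct = x$pct_variance[3] %||% NA_real_)
}

#' Mean kinship within and between groups
#'
#' Block means of a relationship matrix under a grouping of the animals.
#' Within-group means exclude the diagonal; a singleton group's within-mean
#' is reported missing.
#'
#' @param G Relationship matrix with animal dimnames.
#' @param group_of Named character vector animal -> group label (or a vector
#'   aligned with the rows of `G`).
#' @return A tibble `group_a, group_b, mean_kinship, n_pairs` covering every
#'   unordered group pair.
#' @export
kinship_blocks <- function(G, group_of) {
  n <- nrow(G)
  ids <- rownames(G) %||% as.character(seq_len(n))
  g <- if (!is.null(names(group_of))) group_of[ids] else group_of
  assert_that(!anyNA(g) && length(g) == n, "group_of must cover every animal")
  labs <- sort(unique(g))
  purrr::map_dfr(seq_along(labs), function(i) {
    purrr::map_dfr(seq(i, length(labs)), function(j) {
      ri <- which(g == labs[i]); rj <- which(g == labs[j])
      block <- G[ri, rj, drop = FALSE]
      if (i == j) {
        np <- length(ri) * (length(ri) - 1)
        mk <- if (length(ri) > 1) {
          (sum(block) - sum(diag(block))) / np
        } else NA_real_
      } else {
        np <- length(ri) * length(rj)
        mk <- mean(block)
      }
      tibble(group_a = labs[i], group_b = labs[j],
             mean_kinship = mk, n_pairs = as.integer(np))
    })
  })
}
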