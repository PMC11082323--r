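# Pedigree and genomic relationship algebra: A, F, A-inverse (Henderson's
# rules with inbreeding), A22, VanRaden G, blending, and the combined H
# matrix of single-step GBLUP in both explicit and inverse form.

# Validate a pedigree and return integer parent indices in topological order.
# sire/dam "0" (or NA) = unknown. Errors on cycles or half-known parents when
# require_both = TRUE.
ped_index <- function(ped) {
  n <- nrow(ped)
  id <- as.character(ped$animal)
  assert_that(!anyDuplicated(id), "duplicated animal id in pedigree")
  look <- setNames(seq_len(n), id)
  code <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "0"
    out <- ifelse(x == "0", 0L, unname(look[x]))
    assert_that(!anyNA(out), "parent id absent from pedigree")
    out
  }
  s <- code(ped$sire); d <- code(ped$dam)
  # topological order (Kahn); cycle -> error
  ord <- integer(0)
  indeg_done <- logical(n)
  remaining <- seq_len(n)
  while (length(remaining)) {
    sr <- s[remaining]; dr <- d[remaining]
    sok <- sr == 0L | indeg_done[pmax(sr, 1L)]
    dok <- dr == 0L | indeg_done[pmax(dr, 1L)]
    ready <- remaining[sok & dok]
    if (!length(ready)) abort("pedigree contains a cycle")
    indeg_done[ready] <- TRUE
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  perm <- order(match(seq_len(n), ord))   # new position of each original row
  new_of <- integer(n); new_of[ord] <- seq_len(n)
  list(order = ord,
       id = id[ord],
       sire = ifelse(s[ord] == 0L, 0L, new_of[pmax(s[ord], 1L)] * (s[ord] > 0L)),
       dam = ifelse(d[ord] == 0L, 0L, new_of[pmax(d[ord], 1L)] * (d[ord] > 0L)))
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' The classic recursion: `a(i,i) = 1 + a(s,d)/2` and
#' `a(i,j) = (a(j,s) + a(j,d))/2` for `j` prior to `i`, with unknown parents
#' contributing zero. Rows/columns are returned in the pedigree's own order.
#'
#' @param ped Pedigree tibble with columns `animal, sire, dam` (unknown
#'   parent `"0"` or `NA`); any topological order is accepted, cycles error.
#' @return Dense symmetric matrix with animal dimnames;
#'   `diag(A) = 1 + F`.
#' @examples
#' ped <- tibble::tibble(animal = c("s", "d", "o"),
#'                       sire = c("0", "0", "s"), dam = c("0", "0", "d"))
#' a_matrix(ped)
#' @export
a_matrix <- function(ped) {
  px <- ped_index(ped)
  n <- length(px$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- px$sire[i]; d <- px$dam[i]
    if (i > 1) {
      prior <- seq_len(i - 1L)
      as_ <- if (s > 0) A[prior, s] else numeric(i - 1L)
      ad_ <- if (d > 0) A[prior, d] else numeric(i - 1L)
      A[prior, i] <- A[i, prior] <- (as_ + ad_) / 2
    }
    A[i, i] <- 1 + (if (s > 0 && d > 0) A[s, d] / 2 else 0)
  }
  # back to input order
  inv <- order(px$order)
  A <- A[inv, inv, drop = FALSE]
  dimnames(A) <- list(as.character(ped$animal), as.character(ped$animal))
  A
}

#' Inbreeding coefficients
#'
#' `F_i = a(sire, dam) / 2`, computed through the tabular relationship
#' matrix.
#'
#' @inheritParams a_matrix
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  A <- a_matrix(ped)
  setNames(diag(A) - 1, rownames(A))
}

#' Inverse of the pedigree relationship matrix (Henderson's rules)
#'
#' Assembles A-inverse directly from the pedigree using Henderson's rules
#' with inbreeding-adjusted Mendelian-sampling variances:
#' `d_i = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, `1` with none.
#'
#' @inheritParams a_matrix
#' @return Dense symmetric matrix, same ordering as `ped`.
#' @export
a_inverse <- function(ped) {
  px <- ped_index(ped)
  n <- length(px$id)
  Fcoef <- unname(inbreeding(ped))[px$order]
  Ainv <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- px$sire[i]; d <- px$dam[i]
    di <- if (s > 0 && d > 0) {
      0.5 - 0.25 * (Fcoef[s] + Fcoef[d])
    } else if (s > 0 || d > 0) {
      0.75 - 0.25 * Fcoef[max(s, d)]
    } else 1
    al <- 1 / di
    Ainv[i, i] <- Ainv[i, i] + al
    for (p in c(s, d)[c(s, d) > 0]) {
      Ainv[i, p] <- Ainv[i, p] - al / 2
      Ainv[p, i] <- Ainv[p, i] - al / 2
    }
    pp <- c(s, d)[c(s, d) > 0]
    for (p1 in pp) for (p2 in pp) {
      Ainv[p1, p2] <- Ainv[p1, p2] + al / 4
    }
  }
  inv <- order(px$order)
  Ainv <- Ainv[inv, inv, drop = FALSE]
  dimnames(Ainv) <- list(as.character(ped$animal), as.character(ped$animal))
  Ainv
}

#' VanRaden genomic relationship matrix
#'
#' `G = M M' / (2 sum_k p_k (1 - p_k))`, where `M` is the dosage matrix with
#' column `k` centred by `2 p_k` and `p_k` the coded-allele frequency.
#'
#' @param geno A [genotypes()] object (or imputed variant) with no missing
#'   dosages, or a plain dosage matrix.
#' @param freqs Optional coded-allele frequencies; default: observed
#'   frequencies of the supplied (combined-breed) pool. Monomorphic SNPs
#'   (`p` of 0 or 1) error and must be removed by QC first.
#' @return Dense symmetric G with animal dimnames.
#' @export
vanraden_g <- function(geno, freqs = NULL) {
  d <- if (inherits(geno, "genotypes")) geno$dosage else geno
  assert_that(!anyNA(d), "missing dosages: impute before building G")
  p <- freqs %||% (colMeans(d) / 2)
  assert_that(length(p) == ncol(d), "one frequency per SNP required")
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    abort(paste0("monomorphic SNPs must be removed before building G: ",
                 paste(head(colnames(d)[mono], 5), collapse = ", ")))
  }
  M <- sweep(d, 2, 2 * p)
  G <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  (G + t(G)) / 2
}

#' Blend G with the pedigree relationships of the genotyped animals
#'
#' `G_blend = (1 - weight) G + weight A22`. A small weight guarantees an
#' invertible genomic matrix when markers are fewer than animals or G is
#' otherwise near-singular.
#'
#' @param G_raw VanRaden G over the genotyped animals.
#' @param A22 Pedigree relationship sub-block for the same animals, same
#'   order.
#' @param weight Blending weight in `[0, 1)` (default 0.05).
#' @return The blended matrix.
#' @export
blend_g <- function(G_raw, A22, weight = 0.05) {
  assert_that(weight >= 0 && weight < 1, "weight must lie in [0, 1)")
  assert_that(all(dim(G_raw) == dim(A22)), "G and A22 shapes differ")
  (1 - weight) * G_raw + weight * A22
}

#' Inverse of the single-step H matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`: the pedigree inverse plus the
#' genomic correction on the genotyped block.
#'
#' @param A_inv Inverse pedigree relationship matrix (all animals, with
#'   dimnames).
#' @param G_blend Invertible (blended) genomic matrix over the genotyped
#'   animals, dimnames matching `genotyped_ids`.
#' @param A22 Pedigree relationship sub-block of the genotyped animals.
#' @param genotyped_ids Animal ids of the genotyped block.
#' @return Dense symmetric H-inverse in the ordering of `A_inv`.
#' @export
h_inverse <- function(A_inv, G_blend, A22, genotyped_ids) {
  ids <- rownames(A_inv)
  assert_that(all(genotyped_ids %in% ids),
              "genotyped ids must appear in the pedigree")
  if (!length(genotyped_ids)) return(A_inv)
  Ginv <- tryCatch(solve(G_blend), error = function(e) {
    abort("G is singular; use a blending weight > 0 (see blend_g)")
  })
  A22inv <- solve(A22)
  H <- A_inv
  gi <- match(genotyped_ids, ids)
  H[gi, gi] <- H[gi, gi] + (Ginv + t(Ginv)) / 2 - (A22inv + t(A22inv)) / 2
  (H + t(H)) / 2
}

#' Explicit single-step H matrix
#'
#' Block assembly of the combined relationship matrix: the non-genotyped
#' block is `A11 - A12 A22^-1 A21 + A12 A22^-1 G A22^-1 A21`, the
#' off-diagonal `A12 A22^-1 G`, and the genotyped block `G` itself.
#'
#' @param A Full pedigree relationship matrix (with dimnames).
#' @param G_blend Genomic matrix over the genotyped animals.
#' @param genotyped_ids Animal ids of the genotyped block.
#' @return Dense symmetric H in the ordering of `A`.
#' @export
h_matrix_explicit <- function(A, G_blend, genotyped_ids) {
  ids <- rownames(A)
  if (!length(genotyped_ids)) return(A)
  gi <- match(genotyped_ids, ids)
  ni <- setdiff(seq_len(nrow(A)), gi)
  A22 <- A[gi, gi, drop = FALSE]
  A22inv <- tryCatch(solve(A22), error = function(e) {
    abort("A22 is singular")
  })
  H <- A
  if (length(ni)) {
    A12 <- A[ni, gi, drop = FALSE]
    P <- A12 %*% A22inv
    H[ni, ni] <- A[ni, ni, drop = FALSE] - P %*% t(A12) +
      P %*% G_blend %*% t(P)
    H[ni, gi] <- P %*% G_blend
    H[gi, ni] <- t(H[ni, gi])
  }
  H[gi, gi] <- G_blend
  (H + t(H)) / 2
}

#' Build the full relationship set for an analysis
#'
#' Convenience wrapper: tabular A, inbreeding, Henderson A-inverse, A22,
#' VanRaden G from the genotyped pool (combined-breed frequencies by
#' default), blending and H-inverse, all on one declared animal ordering
#' (the pedigree's).
#'
#' @param ped Pedigree tibble.
#' @param geno [genotypes()] (no missing dosages) for a subset of pedigree
#'   animals.
#' @param blend_weight Weight passed to [blend_g()].
#' @param freqs Optional allele frequencies for [vanraden_g()].
#' @return List `A, F, A_inv, A22, G_raw, G_blend, H_inv, genotyped_ids`.
#' @export
build_relationships <- function(ped, geno, blend_weight = 0.05, freqs = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  gids <- rownames(geno$dosage)
  assert_that(all(gids %in% ped$animal),
              "all genotyped animals must appear in the pedigree")
  A <- a_matrix(ped)
  Ainv <- a_inverse(ped)
  A22 <- A[gids, gids, drop = FALSE]
  G <- vanraden_g(geno, freqs)
  Gb <- blend_g(G, A22, blend_weight)
  Hinv <- h_inverse(Ainv, Gb, A22, gids)
  list(A = A, F = diag(A) - 1, A_inv = Ainv, A22 = A22,
       G_raw = G, G_blend = Gb, H_inv = Hinv, genotyped_ids = gids)
}
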