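#' Evenly spaced SNP map for the simulator
#'
#' @param n_snps Total SNPs, split as evenly as possible over chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Physical chromosome length in bp.
#' @return A [snp_map()] tibble with evenly spaced positions.
#' @export
simulate_snp_map <- function(n_snps, n_chromosomes = 1, chrom_length_bp = 1e8) {
  per <- rep(n_snps %/% n_chromosomes, n_chromosomes)
  if (n_snps %% n_chromosomes > 0) {
    per[seq_len(n_snps %% n_chromosomes)] <- per[seq_len(n_snps %% n_chromosomes)] + 1L
  }
  purrr::map_dfr(seq_len(n_chromosomes), function(ch) {
    k <- per[ch]
    pos <- unique(as.integer(round(seq(1e4, chrom_length_bp, length.out = k))))
    assert_that(length(pos) == k, "chromosome too short for requested SNP count")
    snp_map(sprintf("snp%d_%05d", ch, seq_len(k)), chrom = ch, pos_bp = pos)
  })
}

# Latent AR(1) Gaussian copula haplotypes: exact Bernoulli(p_j) marginals,
# between-site correlation decaying as exp(-d / scale) on the latent scale.
# scale = 0 gives independent sites. Returns n_hap x m 0/1 matrix.
draw_founder_haplotypes <- function(n_hap, p, gen_pos, chrom, scale) {
  m <- length(p)
  thr <- stats::qnorm(p)
  z <- matrix(rnorm(n_hap * m), n_hap, m)
  if (scale > 0 && m > 1) {
    for (j in 2:m) {
      if (chrom[j] != chrom[j - 1]) next
      rho <- exp(-(gen_pos[j] - gen_pos[j - 1]) / scale)
      z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
  }
  (z < matrix(thr, n_hap, m, byrow = TRUE)) + 0L
}

# One gamete from parental haplotypes h1, h2 (vectors over all SNPs), with
# Haldane crossovers (Poisson count per chromosome, uniform positions, no
# interference).
make_gamete <- function(h1, h2, chrom_index, gen_pos, chrom_len) {
  out <- integer(length(h1))
  for (ci in seq_along(chrom_index)) {
    idx <- chrom_index[[ci]]
    nco <- rpois(1, chrom_len[ci])
    start <- sample.int(2L, 1L) - 1L
    if (nco == 0L) {
      seg <- rep(0L, length(idx))
    } else {
      bp <- sort(runif(nco, 0, chrom_len[ci]))
      seg <- findInterval(gen_pos[[ci]], bp)
    }
    use2 <- (start + seg) %% 2L == 1L
    out[idx] <- ifelse(use2, h2[idx], h1[idx])
  }
  out
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn from the breed-specific allele frequencies
#' (with optional ancestral LD, see [sim_config()]); every descendant
#' inherits one recombined gamete from each parent, with Haldane crossovers
#' (Poisson number per chromosome, uniform positions, no interference).
#' Genetic positions are physical positions rescaled so each chromosome spans
#' `chrom_length_morgans`.
#'
#' @param pedigree Pedigree tibble (`animal, sire, dam, breed`) with parents
#'   preceding offspring; every animal has either two known parents or none.
#' @param founder_freqs Output of [simulate_founder_frequencies()] (or any
#'   tibble with one frequency column per breed), rows aligned with `map`.
#' @param map A [snp_map()] tibble, positions strictly increasing within
#'   chromosome.
#' @param chrom_length_morgans Genetic length of each chromosome.
#' @param founder_ld_morgans Ancestral LD decay scale for founders (0 =
#'   independent sites).
#' @param seed Integer seed.
#' @return A [genotypes()] object with dosages in `{0, 1, 2}` (no missing).
#' @export
drop_genotypes <- function(pedigree, founder_freqs, map,
                           chrom_length_morgans = 1,
                           founder_ld_morgans = 0,
                           seed = 1L) {
  m <- nrow(map)
  breeds <- intersect(names(founder_freqs), unique(pedigree$breed))
  assert_that(length(breeds) >= 1, "founder_freqs lacks breed columns")
  assert_that(all(pedigree$breed %in% breeds),
              "every pedigree breed needs a founder frequency column")
  ok <- tapply(map$pos_bp, map$chrom, function(p) all(diff(p) > 0))
  assert_that(all(unlist(ok)), "map positions must be strictly increasing within chromosome")
  one_parent <- xor(pedigree$sire == "0", pedigree$dam == "0")
  if (any(one_parent)) {
    abort(paste0("animals with exactly one known parent are not supported: ",
                 paste(head(pedigree$animal[one_parent], 5), collapse = ", ")))
  }

  chroms <- unique(map$chrom)
  chrom_index <- lapply(chroms, function(ch) which(map$chrom == ch))
  # rescale physical positions to [0, L] Morgans per chromosome
  gen_pos <- lapply(chrom_index, function(idx) {
    p <- map$pos_bp[idx]
    if (length(p) == 1) return(chrom_length_morgans / 2)
    (p - p[1]) / (p[length(p)] - p[1]) * chrom_length_morgans
  })
  chrom_len <- rep(chrom_length_morgans, length(chroms))
  gen_pos_flat <- numeric(m)
  chrom_flat <- map$chrom
  for (ci in seq_along(chroms)) gen_pos_flat[chrom_index[[ci]]] <- gen_pos[[ci]]

  n <- nrow(pedigree)
  row_of <- setNames(seq_len(n), pedigree$animal)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)

  with_seed(seed, {
    founder <- pedigree$sire == "0" & pedigree$dam == "0"
    for (b in breeds) {
      fi <- which(founder & pedigree$breed == b)
      if (!length(fi)) next
      hap <- draw_founder_haplotypes(2L * length(fi), founder_freqs[[b]],
                                     gen_pos_flat, chrom_flat,
                                     founder_ld_morgans)
      H1[fi, ] <- hap[seq_along(fi), , drop = FALSE]
      H2[fi, ] <- hap[length(fi) + seq_along(fi), , drop = FALSE]
    }
    for (i in which(!founder)) {
      si <- row_of[[pedigree$sire[i]]]
      di <- row_of[[pedigree$dam[i]]]
      assert_that(si < i && di < i, "pedigree must list parents before offspring")
      H1[i, ] <- make_gamete(H1[si, ], H2[si, ], chrom_index, gen_pos, chrom_len)
      H2[i, ] <- make_gamete(H1[di, ], H2[di, ], chrom_index, gen_pos, chrom_len)
    }
  })

  dos <- H1 + H2
  dimnames(dos) <- list(pedigree$animal, map$snp_id)
  genotypes(dos, setNames(pedigree$breed, pedigree$animal))
}
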