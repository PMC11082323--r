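#' Genotype container
#'
#' A lightweight container pairing an animals-by-SNPs dosage matrix (counted
#' copies of the coded allele: 0, 1, 2 or `NA` for missing) with the breed of
#' each animal. Row names are animal identifiers, column names SNP identifiers.
#'
#' @param dosage Numeric matrix, animals in rows and SNPs in columns, values
#'   in `{0, 1, 2, NA}`. Must have row and column names.
#' @param breed Character vector of breed labels, one per animal (recycled if
#'   length one).
#' @param fractional Allow fractional dosages in `[0, 2]` (as produced by
#'   mean imputation); default `FALSE` restricts to the coded set.
#' @return An object of class `genotypes` with elements `dosage` and `breed`
#'   (a character vector named by animal).
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("a1", "a2"), c("s1", "s2")))
#' genotypes(d, breed = c("XB", "CH"))
#' @export
genotypes <- function(dosage, breed, fractional = FALSE) {
  assert_that(is.matrix(dosage), "dosage must be a matrix")
  assert_that(!is.null(rownames(dosage)) &&
                (ncol(dosage) == 0L || !is.null(colnames(dosage))),
              "dosage must have animal row names and SNP column names")
  assert_that(!anyDuplicated(rownames(dosage)), "duplicated animal id in dosage")
  ok <- if (fractional) {
    (dosage >= 0 & dosage <= 2) | is.na(dosage)
  } else {
    dosage %in% c(0, 1, 2) | is.na(dosage)
  }
  assert_that(all(ok), "dosage values must be 0, 1, 2 or NA")
  if (length(breed) == 1L) breed <- rep(breed, nrow(dosage))
  assert_that(length(breed) == nrow(dosage),
              "breed must have one label per animal")
  structure(list(dosage = dosage,
                 breed = setNames(as.character(breed), rownames(dosage))),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("<genotypes> ", nrow(x$dosage), " animals x ", ncol(x$dosage), " SNPs\n",
      sep = "")
  tb <- table(x$breed)
  cat("breeds: ", paste0(names(tb), " (", tb, ")", collapse = ", "), "\n", sep = "")
  nm <- sum(is.na(x$dosage))
  cat("missing dosages: ", nm, " (",
      format(100 * nm / length(x$dosage), digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosage)

#' Subset a genotype container
#'
#' @param x A [genotypes()] object.
#' @param animals Animal ids or row indices to keep (default all).
#' @param snps SNP ids or column indices to keep (default all).
#' @return A `genotypes` object restricted to the selection.
#' @export
subset_genotypes <- function(x, animals = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotypes"))
  d <- x$dosage
  if (!is.null(animals)) d <- d[animals, , drop = FALSE]
  if (!is.null(snps)) d <- d[, snps, drop = FALSE]
  genotypes(d, x$breed[rownames(d)],
            fractional = !all(d %in% c(0, 1, 2) | is.na(d)))
}

# coded-allele frequency per SNP from non-missing dosages
coded_freq <- function(dosage) colMeans(dosage, na.rm = TRUE) / 2

#' SNP map constructor
#'
#' @param snp_id Character SNP identifiers.
#' @param chrom Integer chromosome.
#' @param pos_bp 1-based physical position in base pairs (strictly positive).
#' @param allele_coded,allele_other Allele labels; the dosage counts copies of
#'   `allele_coded`.
#' @return A tibble with class `snp_map` columns
#'   `snp_id, chrom, pos_bp, allele_coded, allele_other`.
#' @export
snp_map <- function(snp_id, chrom, pos_bp, allele_coded = "B", allele_other = "A") {
  assert_that(all(pos_bp > 0), "positions must be strictly positive")
  assert_that(!anyDuplicated(snp_id), "duplicated snp_id in map")
  tibble(snp_id = as.character(snp_id),
         chrom = as.integer(chrom),
         pos_bp = as.integer(pos_bp),
         allele_coded = rep_len(as.character(allele_coded), length(snp_id)),
         allele_other = rep_len(as.character(allele_other), length(snp_id)))
}
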