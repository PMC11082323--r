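#' Read genotypes from PLINK PED/MAP text files
#'
#' Parses the whitespace-delimited PED dialect (FID, IID, sire, dam, sex,
#' phenotype, then two allele columns per SNP; `0` = missing allele) together
#' with a 4-column MAP (chromosome, SNP id, genetic position, bp position).
#' Dosages count copies of the coded allele. Unless `coded` supplies the
#' coded allele per SNP, the minor allele is used (lexicographic tie-break),
#' the usual A1 convention.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param breed_of Optional named character vector animal -> breed; defaults
#'   to the PED family id column.
#' @param coded Optional character vector (length = SNPs) of coded alleles.
#' @return A list with `genotypes` (a [genotypes()] object) and `map` (a
#'   [snp_map()] tibble including the inferred allele columns).
#' @export
read_plink_pedmap <- function(ped_path, map_path, breed_of = NULL, coded = NULL) {
  mp <- readr::read_table(map_path,
                          col_names = c("chrom", "snp_id", "pos_cm", "pos_bp"),
                          col_types = "icdi", progress = FALSE)
  lines <- readr::read_lines(ped_path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(mp)
  widths <- lengths(toks)
  assert_that(all(widths == 6 + 2 * m),
              sprintf("PED rows must have %d fields (6 + 2 x %d SNPs)", 6 + 2 * m, m))
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  fid <- tok[, 1]; iid <- tok[, 2]
  assert_that(!anyDuplicated(iid),
              paste0("duplicated animal id in PED: ",
                     paste(unique(iid[duplicated(iid)])[1], collapse = ", ")))
  a1 <- tok[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(m), drop = FALSE]
  half_missing <- xor(a1 == "0", a2 == "0")
  assert_that(!any(half_missing), "half-missing genotype (one allele 0) in PED")

  dos <- matrix(NA_real_, nrow(tok), m,
                dimnames = list(iid, mp$snp_id))
  allele_coded <- character(m)
  allele_other <- character(m)
  for (j in seq_len(m)) {
    obs1 <- a1[, j]; obs2 <- a2[, j]
    present <- obs1 != "0"
    alleles <- sort(unique(c(obs1[present], obs2[present])))
    if (length(alleles) > 2) {
      abort(paste0("SNP ", mp$snp_id[j], " is not biallelic: alleles ",
                   paste(alleles, collapse = "/")))
    }
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, NA_character_)
    if (!is.null(coded)) {
      cj <- coded[j]
      assert_that(is.na(alleles[2]) || cj %in% alleles,
                  paste0("coded allele for ", mp$snp_id[j], " not observed"))
    } else {
      cnt1 <- sum(obs1[present] == alleles[1]) + sum(obs2[present] == alleles[1])
      tot <- 2 * sum(present)
      # minor allele coded; lexicographic tie-break (alleles is sorted)
      cj <- if (!is.na(alleles[2]) && cnt1 > tot - cnt1) alleles[2] else alleles[1]
    }
    allele_coded[j] <- cj
    allele_other[j] <- setdiff(alleles, cj)[1] %||% NA_character_
    dos[present, j] <- (obs1[present] == cj) + (obs2[present] == cj)
  }
  breed <- if (is.null(breed_of)) setNames(fid, iid) else breed_of[iid]
  map <- snp_map(mp$snp_id, mp$chrom, mp$pos_bp, allele_coded, allele_other)
  list(genotypes = genotypes(dos, breed), map = map)
}

#' Write genotypes to PLINK PED/MAP text files
#'
#' Inverse of [read_plink_pedmap()]: dosage `d` becomes `d` copies of the
#' coded allele and `2 - d` of the other; missing dosage becomes `0 0`.
#'
#' @param geno A [genotypes()] object.
#' @param map A [snp_map()] aligned with the columns of `geno`.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_pedmap <- function(geno, map, ped_path, map_path) {
  stopifnot(inherits(geno, "genotypes"))
  assert_that(identical(map$snp_id, colnames(geno$dosage)),
              "map rows must align with genotype columns")
  d <- geno$dosage
  m <- ncol(d)
  cells <- matrix("0 0", nrow(d), m)
  for (j in seq_len(m)) {
    g <- d[, j]
    ac <- map$allele_coded[j]; ao <- map$allele_other[j]
    cells[, j] <- dplyr::case_when(
      is.na(g) ~ "0 0",
      g == 0 ~ paste(ao, ao),
      g == 1 ~ paste(ao, ac),
      g == 2 ~ paste(ac, ac))
  }
  lead <- paste(geno$breed, rownames(d), "0", "0", "0", "-9")
  readr::write_lines(paste(lead, apply(cells, 1, paste, collapse = " ")),
                     ped_path)
  readr::write_lines(sprintf("%d\t%s\t%g\t%d", map$chrom, map$snp_id,
                             0, map$pos_bp), map_path)
  invisible(c(ped_path, map_path))
}

#' Read / write a dosage-matrix CSV
#'
#' Plain dialect: header `animal,breed,<snp ids...>`, one animal per row,
#' dosages 0/1/2 with `NA` for missing.
#'
#' @param path File path.
#' @return `read_dosage_csv()`: a [genotypes()] object.
#' @export
read_dosage_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    animal = readr::col_character(), breed = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  assert_that(!anyDuplicated(df$animal), "duplicated animal id in dosage CSV")
  d <- as.matrix(df[, setdiff(names(df), c("animal", "breed")), drop = FALSE])
  rownames(d) <- df$animal
  genotypes(d, setNames(df$breed, df$animal),
            fractional = !all(d %in% c(0, 1, 2) | is.na(d)))
}

#' @param geno A [genotypes()] object.
#' @rdname read_dosage_csv
#' @export
write_dosage_csv <- function(geno, path) {
  stopifnot(inherits(geno, "genotypes"))
  df <- dplyr::bind_cols(
    tibble(animal = rownames(geno$dosage),
           breed = unname(geno$breed[rownames(geno$dosage)])),
    as_tibble(geno$dosage))
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

#' Read / write pedigree and phenotype CSV files
#'
#' Pedigree columns `animal, sire, dam, breed, birth_year` (unknown parent
#' `0`); phenotype columns `animal, breed, trait, value, farm, year_class,
#' season, parity`.
#'
#' @param path File path.
#' @param ped,phen Tibbles to write.
#' @return The read tibble, or (for writers) the path invisibly.
#' @export
read_pedigree_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    animal = readr::col_character(), sire = readr::col_character(),
    dam = readr::col_character(), breed = readr::col_character(),
    birth_year = readr::col_integer(), .default = readr::col_guess()),
    progress = FALSE)
}

#' @rdname read_pedigree_csv
#' @export
write_pedigree_csv <- function(ped, path) {
  readr::write_csv(ped, path)
  invisible(path)
}

#' @rdname read_pedigree_csv
#' @export
read_phenotype_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    animal = readr::col_character(), breed = readr::col_character(),
    trait = readr::col_character(), value = readr::col_double(),
    farm = readr::col_character(), year_class = readr::col_character(),
    season = readr::col_character(), parity = readr::col_integer()),
    progress = FALSE)
}

#' @rdname read_pedigree_csv
#' @export
write_phenotype_csv <- function(phen, path) {
  readr::write_csv(phen, path)
  invisible(path)
}
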