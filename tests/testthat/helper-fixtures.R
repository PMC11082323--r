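# Shared fixtures and small independent oracles, all built in code.

# small genotype container with controllable values
make_geno <- function(d, breed = "XB") {
  if (is.null(rownames(d))) rownames(d) <- sprintf("a%02d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("s%02d", seq_len(ncol(d)))
  genotypes(d, breed)
}

# five-animal pedigree: two founders, two full sibs, one full-sib mating
full_sib_mating_ped <- function() {
  tibble::tibble(animal = c("s", "d", "k1", "k2", "o"),
                 sire = c("0", "0", "s", "s", "k1"),
                 dam = c("0", "0", "d", "d", "k2"))
}

# random acyclic pedigree over n animals (generations of size ~n/3)
random_pedigree <- function(n, seed) {
  withr::with_seed(seed, {
    gen <- sort(rep_len(1:3, n))
    sire <- dam <- rep("0", n)
    ids <- sprintf("p%03d", seq_len(n))
    for (i in which(gen > 1)) {
      prev <- which(gen == gen[i] - 1)
      pick <- sample(prev, 2)
      sire[i] <- ids[pick[1]]; dam[i] <- ids[pick[2]]
    }
    tibble::tibble(animal = ids, sire = sire, dam = dam)
  })
}

# independent tabular oracle for A: recursive kinship coefficients with
# memoisation (A[i,j] = 2 * phi(i,j); phi(i,i) = (1 + phi(s,d)) / 2)
kinship_oracle <- function(ped) {
  id <- as.character(ped$animal)
  s <- match(as.character(ped$sire), id, nomatch = 0L)
  d <- match(as.character(ped$dam), id, nomatch = 0L)
  n <- length(id)
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      (1 + phi(s[i], d[i])) / 2
    } else if (i > j) {
      (phi(s[i], j) + phi(d[i], j)) / 2
    } else {
      (phi(s[j], i) + phi(d[j], i)) / 2
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# batch-means Monte-Carlo standard error of a chain mean
mcse_batch <- function(x, n_batch = 20) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(b) {
    mean(x[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# one cached desk-tiny simulated dataset, QC'd, shared across test files
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_animals_per_breed = 60, n_snps = 240,
                        n_chromosomes = 2, seed = 421)
      ds <- simulate_dataset(cfg)
      qs <- qc_snps(ds$genotypes, ds$map)
      ds$genotypes <- qs$genotypes
      ds$map <- qs$map
      cache <<- ds
    }
    cache
  }
})
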