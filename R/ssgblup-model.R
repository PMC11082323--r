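#' Build design matrices for the bivariate breed-trait animal model
#'
#' Each breed's expression of the trait is its own model trait. Fixed-effect
#' factors are dummy-coded with the first observed level as reference, per
#' trait, giving a full-rank X (per-trait intercept plus `levels - 1` dummies
#' per factor); factors with a single observed level contribute only to the
#' intercept. Z maps each record to the breeding value of the record's
#' animal for the record's trait.
#'
#' @param phen Phenotype tibble (`animal, breed, trait, value`, plus the
#'   fixed-effect columns).
#' @param animal_ids Character vector fixing the animal ordering of the
#'   relationship matrices; every record's animal must appear here.
#' @param traits Trait labels in model order; default: breeds present, in
#'   first-appearance order. A record's model trait is its breed.
#' @param fixed Fixed-effect factor columns (default
#'   `farm, year_class, season, parity`); only columns present in `phen` are
#'   used.
#' @return A list of class `mme_design`: `y`, dense `X`, integer vectors
#'   `animal` and `trait` (0-based, for the sampler), `animal_ids`,
#'   `traits`, and a `columns` tibble (`trait, term`).
#' @export
build_design <- function(phen, animal_ids,
                         traits = NULL,
                         fixed = c("farm", "year_class", "season", "parity")) {
  unknown <- setdiff(unique(phen$animal), animal_ids)
  if (length(unknown)) {
    abort(paste0("records reference animals absent from the pedigree: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  traits <- traits %||% unique(phen$breed)
  assert_that(length(traits) == 2, "the bivariate model needs exactly two traits")
  assert_that(all(phen$breed %in% traits), "record breed outside the trait pair")
  fixed <- intersect(fixed, names(phen))
  ord <- order(match(phen$breed, traits))
  phen <- phen[ord, , drop = FALSE]

  blocks <- lapply(traits, function(tr) {
    sub <- phen[phen$breed == tr, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    cols <- list(`(Intercept)` = rep(1, nrow(sub)))
    for (f in fixed) {
      lev <- unique(as.character(sub[[f]]))
      lev <- sort(lev)
      for (l in lev[-1]) {
        cols[[paste0(f, l)]] <- as.numeric(as.character(sub[[f]]) == l)
      }
    }
    do.call(cbind, cols)
  })
  p_per <- vapply(blocks, function(b) if (is.null(b)) 0L else ncol(b), integer(1))
  n_rec <- nrow(phen)
  X <- matrix(0, n_rec, sum(p_per))
  terms <- character(0); term_trait <- character(0)
  off_col <- 0L; off_row <- 0L
  for (k in seq_along(traits)) {
    if (p_per[k] > 0) {
      nr <- nrow(blocks[[k]])
      X[off_row + seq_len(nr), off_col + seq_len(p_per[k])] <- blocks[[k]]
      terms <- c(terms, colnames(blocks[[k]]))
      term_trait <- c(term_trait, rep(traits[k], p_per[k]))
      off_row <- off_row + nr
      off_col <- off_col + p_per[k]
    }
  }
  colnames(X) <- paste(term_trait, terms, sep = ":")
  structure(list(
    y = phen$value,
    X = X,
    animal = match(phen$animal, animal_ids) - 1L,
    trait = match(phen$breed, traits) - 1L,
    animal_ids = animal_ids,
    traits = traits,
    records = phen,
    columns = tibble(trait = term_trait, term = terms)),
    class = "mme_design")
}

#' Solve the bivariate mixed-model equations at fixed variances
#'
#' Direct (dense) solve of Henderson's mixed-model equations for the
#' two-trait animal model with genetic covariance `G0 (x) H` and
#' trait-diagonal residuals. Returns BLUE fixed effects and GEBVs for every
#' animal in the relationship matrix, both traits.
#'
#' @param design An [build_design()] result.
#' @param H_inv Inverse relationship matrix over `design$animal_ids`.
#' @param G0 2x2 genetic (co)variance matrix (positive definite).
#' @param sigma_e Length-2 residual variances.
#' @return An object of class `mme_fit`: tibbles `beta`
#'   (`trait, term, estimate`) and `gebv` (`animal, trait, gebv`).
#' @export
solve_mme <- function(design, H_inv, G0, sigma_e) {
  stopifnot(inherits(design, "mme_design"))
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  assert_that(all(ev > 0) && all(sigma_e > 0),
              "variance components must be positive definite")
  n <- length(design$animal_ids)
  p <- ncol(design$X)
  rinv <- 1 / sigma_e[design$trait + 1L]
  X <- design$X
  zcol <- design$trait * n + design$animal + 1L   # 1..2n

  XtRX <- crossprod(X, X * rinv)
  XtRy <- crossprod(X, design$y * rinv)
  zr <- rowsum(cbind(X * rinv, design$y * rinv, rinv), group = zcol)
  zidx <- as.integer(rownames(zr))
  XtRZ <- matrix(0, p, 2 * n)
  XtRZ[, zidx] <- t(zr[, seq_len(p), drop = FALSE])
  ZtRy <- numeric(2 * n); ZtRy[zidx] <- zr[, p + 1L]
  ZtRZ <- numeric(2 * n); ZtRZ[zidx] <- zr[, p + 2L]

  G0inv <- solve(G0)
  K <- kronecker(G0inv, H_inv)
  diag_idx <- seq_len(2 * n)
  K[cbind(diag_idx, diag_idx)] <- diag(K) + ZtRZ

  C <- rbind(cbind(XtRX, XtRZ), cbind(t(XtRZ), K))
  rhs <- c(XtRy, ZtRy)
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    abort(paste0("singular mixed-model coefficient matrix (rank ",
                 qr(C)$rank, " of ", nrow(C), ")"))
  })
  beta <- sol[seq_len(p)]
  avec <- if (p > 0) sol[-seq_len(p)] else sol
  structure(list(
    beta = tibble(trait = design$columns$trait, term = design$columns$term,
                  estimate = unname(beta)),
    gebv = tibble(animal = rep(design$animal_ids, 2),
                  trait = rep(design$traits, each = n),
                  gebv = unname(avec)),
    G0 = G0, sigma_e = sigma_e, design = design),
    class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat("<mme_fit> ", nrow(x$beta), " fixed-effect solutions, ",
      nrow(x$gebv), " breeding values (",
      length(unique(x$gebv$animal)), " animals x 2 traits)\n", sep = "")
  invisible(x)
}

#' @export
tidy.mme_fit <- function(x, ...) x$beta

#' @export
glance.mme_fit <- function(x, ...) {
  tibble(n_records = length(x$design$y),
         n_animals = length(x$design$animal_ids),
         n_fixed = nrow(x$beta),
         sigma_a1 = x$G0[1, 1], sigma_a12 = x$G0[1, 2], sigma_a2 = x$G0[2, 2],
         sigma_e1 = x$sigma_e[1], sigma_e2 = x$sigma_e[2])
}
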