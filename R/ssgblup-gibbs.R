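#' Gibbs chain settings
#'
#' Defaults follow the routine evaluation protocol: 100,000 total iterations,
#' 10,000 burn-in, thinning interval 50, hence `(100000 - 10000) / 50 = 1800`
#' retained samples. Priors are weakly informative: inverted-Wishart
#' (`nu_g = 4`) for the 2x2 genetic matrix with scale defaulting to 30% of
#' each trait's phenotypic variance on the diagonal, and scaled inverse
#' chi-square (`nu_e = 4`) per residual with scale defaulting to 50% of the
#' phenotypic variance.
#'
#' @param chain_length Total iterations.
#' @param burn_in Discarded leading iterations (must be `< chain_length`).
#' @param thin Thinning interval (>= 1).
#' @param seed Integer seed.
#' @param nu_g,S_g Inverted-Wishart degrees of freedom and 2x2 scale for the
#'   genetic matrix (`S_g = NULL`: derived from the data at fit time).
#' @param nu_e,s_e Scaled inverse chi-square degrees of freedom and per-trait
#'   scales for the residual variances (`s_e = NULL`: derived at fit time).
#' @param block_animal Update each animal's two trait effects jointly
#'   (2x2 blocked draw) instead of the default single-site scan; improves
#'   mixing of the genetic correlation.
#' @return A list of class `gibbs_config`.
#' @export
gibbs_config <- function(chain_length = 100000, burn_in = 10000, thin = 50,
                         seed = 1L, nu_g = 4, S_g = NULL, nu_e = 4,
                         s_e = NULL, block_animal = FALSE) {
  assert_that(is_count(chain_length) && is_count(thin) &&
                burn_in >= 0 && burn_in == floor(burn_in),
              "chain_length/thin must be positive integers, burn_in >= 0")
  assert_that(burn_in < chain_length, "burn_in must be smaller than chain_length")
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), nu_g = nu_g, S_g = S_g,
                 nu_e = nu_e, s_e = s_e,
                 block_animal = isTRUE(block_animal)),
            class = "gibbs_config")
}

#' Retained-sample count implied by chain settings
#'
#' `floor((chain_length - burn_in) / thin)`.
#'
#' @param config A [gibbs_config()].
#' @return Integer count of retained samples.
#' @export
retained_samples <- function(config) {
  (config$chain_length - config$burn_in) %/% config$thin
}

#' Gibbs sampler for the bivariate single-step animal model
#'
#' Systematic-scan single-site Gibbs sampling of fixed effects, breeding
#' values for every animal and both traits (animals without records on a
#' trait are linked in through H and the genetic correlation), the 2x2
#' genetic (co)variance matrix (inverted-Wishart full conditional with the
#' `a' H^-1 a` quadratic form) and per-trait residual variances (scaled
#' inverse chi-square on observed records). Residual covariance across the
#' two breed-traits is structurally zero: the breeds are phenotyped in
#' disjoint herds.
#'
#' @param design A [build_design()] result.
#' @param H_inv Inverse relationship matrix over `design$animal_ids`.
#' @param config A [gibbs_config()].
#' @param fix_at Optional list `list(G0 = 2x2, sigma_e = length-2)`; when
#'   given, variance components stay fixed (the sampler then targets the
#'   exact BLUP/BLUE posterior, used for cross-checks against
#'   [solve_mme()]).
#' @return An object of class `gibbs_fit`: `vc_chain` (retained draws,
#'   columns `sigma_a1, sigma_a12, sigma_a2, sigma_e1, sigma_e2`),
#'   `beta_chain`, `gebv` tibble (posterior mean and SD per animal x trait),
#'   `retained`, `config`, `traits`.
#' @export
gibbs_sample <- function(design, H_inv, config = gibbs_config(),
                         fix_at = NULL) {
  stopifnot(inherits(design, "mme_design"), inherits(config, "gibbs_config"))
  n <- length(design$animal_ids)
  assert_that(all(dim(H_inv) == n), "H_inv must match the animal ordering")

  varp <- vapply(0:1, function(t) {
    v <- var(design$y[design$trait == t])
    if (is.na(v) || v <= 0) 1 else v
  }, numeric(1))
  S_g <- config$S_g %||% diag(0.3 * varp)
  s_e <- config$s_e %||% (0.5 * varp)
  update_vc <- is.null(fix_at)
  G0_init <- if (update_vc) diag(0.3 * varp) else fix_at$G0
  se_init <- if (update_vc) 0.5 * varp else fix_at$sigma_e

  res <- with_seed(config$seed, {
    .gibbs_bivariate_cpp(design$y, design$X, design$animal, design$trait,
                         H_inv, config$chain_length, config$burn_in,
                         config$thin, config$nu_g, S_g, config$nu_e, s_e,
                         update_vc, G0_init, se_init,
                         isTRUE(config$block_animal))
  })
  if (res$pd_failures > 0) {
    warn(paste0("genetic covariance re-jittered in ", res$pd_failures,
                " iterations to restore positive definiteness"))
  }
  vc <- res$vc_chain
  colnames(vc) <- c("sigma_a1", "sigma_a12", "sigma_a2",
                    "sigma_e1", "sigma_e2")
  beta <- res$beta_chain
  colnames(beta) <- colnames(design$X)
  gebv <- tibble(animal = rep(design$animal_ids, 2),
                 trait = rep(design$traits, each = n),
                 gebv = c(res$a_mean[, 1], res$a_mean[, 2]),
                 gebv_sd = c(res$a_sd[, 1], res$a_sd[, 2]))
  structure(list(vc_chain = vc, beta_chain = beta, gebv = gebv,
                 retained = res$retained, config = config,
                 traits = design$traits, fixed_vc = !update_vc),
            class = "gibbs_fit")
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat("<gibbs_fit> ", x$retained, " retained samples (chain ",
      x$config$chain_length, ", burn-in ", x$config$burn_in, ", thin ",
      x$config$thin, ")\n", sep = "")
  print(tidy(x), n = 8)
  invisible(x)
}

#' @describeIn gibbs_sample Posterior summaries per variance parameter plus
#'   derived heritabilities and genetic correlation
#'   (`parameter, mean, sd, geweke_z`).
#' @param x A `gibbs_fit`.
#' @param ... Unused.
#' @export
tidy.gibbs_fit <- function(x, ...) {
  vc <- as_tibble(x$vc_chain)
  der <- tibble(
    h2_1 = vc$sigma_a1 / (vc$sigma_a1 + vc$sigma_e1),
    h2_2 = vc$sigma_a2 / (vc$sigma_a2 + vc$sigma_e2),
    r_g = vc$sigma_a12 / sqrt(pmax(vc$sigma_a1 * vc$sigma_a2, 1e-300)))
  all <- dplyr::bind_cols(vc, der)
  purrr::map_dfr(names(all), function(p) {
    v <- all[[p]]
    tibble(parameter = p, mean = mean(v), sd = sd(v),
           geweke_z = tryCatch(geweke_z(v), error = function(e) NA_real_))
  })
}

#' @describeIn gibbs_sample One-row chain summary.
#' @export
glance.gibbs_fit <- function(x, ...) {
  td <- tidy(x)
  tibble(retained = x$retained,
         chain_length = x$config$chain_length,
         burn_in = x$config$burn_in, thin = x$config$thin,
         max_abs_geweke = max(abs(td$geweke_z), na.rm = TRUE),
         h2_1 = td$mean[td$parameter == "h2_1"],
         h2_2 = td$mean[td$parameter == "h2_2"],
         r_g = td$mean[td$parameter == "r_g"])
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`.
#'
#' @param sigma2_a Additive genetic variance (>= 0).
#' @param sigma2_e Residual variance (> 0).
#' @return Heritability in `[0, 1)`. Vectorized.
#' @examples
#' heritability(238.44, 1429.4)   # 0.143
#' @export
heritability <- function(sigma2_a, sigma2_e) {
  assert_that(all(sigma2_a >= 0), "sigma2_a must be non-negative")
  assert_that(all(sigma2_e > 0), "sigma2_e must be positive")
  sigma2_a / (sigma2_a + sigma2_e)
}

#' Standard error of heritability from posterior draws
#'
#' The headline estimate is the empirical posterior SD of the per-draw
#' heritability `sigma2_a / sigma2_p`. `"delta"` is the textbook first-order
#' propagation `SE^2 = h^4 (Var(sa)/sa^2 + Var(sp)/sp^2 - 2 Cov/(sa sp))`
#' evaluated at the posterior means. `"delta_published"` evaluates the
#' variant that circulates in the evaluation literature,
#' `SE^2 = (sa/sp) (Var(sa)/sa^2 + Var(sp)/sp^2 - Cov/(sa sp))`, which
#' carries neither the squared-heritability factor nor the factor 2 on the
#' covariance term; it is offered for comparability only and is not
#' equivalent to the other two.
#'
#' @param sigma2_a_draws,sigma2_p_draws Aligned posterior draws of the
#'   additive and total phenotypic variance (at least 2).
#' @param method `"empirical"` (default), `"delta"`, or `"delta_published"`.
#' @return The standard error.
#' @export
heritability_se <- function(sigma2_a_draws, sigma2_p_draws,
                            method = c("empirical", "delta",
                                       "delta_published")) {
  method <- match.arg(method)
  assert_that(length(sigma2_a_draws) >= 2 &&
                length(sigma2_a_draws) == length(sigma2_p_draws),
              "need at least two aligned draws")
  if (method == "empirical") {
    return(sd(sigma2_a_draws / sigma2_p_draws))
  }
  sa <- mean(sigma2_a_draws); sp <- mean(sigma2_p_draws)
  va <- var(sigma2_a_draws); vp <- var(sigma2_p_draws)
  cv <- cov(sigma2_a_draws, sigma2_p_draws)
  se2 <- if (method == "delta") {
    (sa / sp)^2 * (va / sa^2 + vp / sp^2 - 2 * cv / (sa * sp))
  } else {
    (sa / sp) * (va / sa^2 + vp / sp^2 - cv / (sa * sp))
  }
  sqrt(max(se2, 0))
}

# spectral density at frequency zero via an AIC-selected AR fit
spectrum0_ar <- function(x) {
  v <- var(x)
  if (is.na(v) || v == 0) return(0)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(length(x) - 1, 20)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `first` fraction of the chain with the
#' mean of the last `last` fraction:
#' `z = (mean_first - mean_last) / sqrt(se1^2 + se2^2)`, with segment
#' variances estimated by the spectral density at frequency zero (AR fit).
#' Under convergence z is approximately standard normal.
#'
#' @param chain Numeric vector (one parameter's retained samples) or a
#'   matrix/data frame with one parameter per column.
#' @param first,last Fractions of the chain used for the two segments.
#' @return A z value per parameter (`NA` when a segment is degenerate).
#' @export
geweke_z <- function(chain, first = 0.10, last = 0.50) {
  if (is.matrix(chain) || is.data.frame(chain)) {
    return(vapply(as.data.frame(chain), geweke_z, numeric(1),
                  first = first, last = last))
  }
  n <- length(chain)
  assert_that(n >= 20, "need at least 20 retained samples")
  x1 <- chain[seq_len(max(floor(first * n), 2))]
  x2 <- chain[seq(n - max(floor(last * n), 2) + 1, n)]
  s1 <- spectrum0_ar(x1); s2 <- spectrum0_ar(x2)
  if (s1 <= 0 || s2 <= 0) return(NA_real_)
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}
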