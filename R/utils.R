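# internal helpers shared across modules

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

# Deterministic per-stage seed derived from one global seed, so that e.g.
# changing the scenario grid does not perturb the simulated data.
# Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_symmetric <- function(M, tol = 1e-8, name = "matrix") {
  assert_that(is.matrix(M) && nrow(M) == ncol(M),
              paste0(name, " must be a square matrix"))
  d <- max(abs(M - t(M)))
  s <- max(abs(M), 1)
  assert_that(d / s <= tol, paste0(name, " is not symmetric (max rel. asymmetry ",
                                   format(d / s), ")"))
  invisible(TRUE)
}
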