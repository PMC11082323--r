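#' Simulate two disjoint breed pedigrees with discrete generations
#'
#' Animals are split as evenly as possible across `n_generations` per breed.
#' Generation 1 animals are founders (both parents unknown, coded `"0"`);
#' each later animal draws a sire among the previous generation's males and a
#' dam among its females, within breed. Sexes alternate within generation so
#' both are always represented. Birth years advance by two years per
#' generation from 2000.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns
#'   `animal, sire, dam, breed, birth_year, sex, generation`, parents always
#'   preceding offspring.
#' @examples
#' ped <- simulate_pedigree(sim_config(n_animals_per_breed = 30, seed = 2))
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_animals_per_breed
  g <- config$n_generations
  counts <- rep(n %/% g, g)
  if (n %% g > 0) counts[seq_len(n %% g)] <- counts[seq_len(n %% g)] + 1L
  with_seed(substream_seed(config$seed, "pedigree"), {
    purrr::map_dfr(config$breeds, function(b) {
      ids <- sprintf("%s%05d", b, seq_len(n))
      gen <- rep(seq_len(g), counts)
      sex <- unlist(lapply(counts, function(k) rep_len(c("M", "F"), k)))
      sire <- dam <- rep("0", n)
      for (gi in seq_len(g)[-1]) {
        prev <- which(gen == gi - 1L)
        males <- ids[prev[sex[prev] == "M"]]
        females <- ids[prev[sex[prev] == "F"]]
        assert_that(length(males) >= 1 && length(females) >= 1,
                    "previous generation must contain both sexes")
        cur <- which(gen == gi)
        sire[cur] <- sample(males, length(cur), replace = TRUE)
        dam[cur] <- sample(females, length(cur), replace = TRUE)
      }
      tibble(animal = ids, sire = sire, dam = dam, breed = b,
             birth_year = 2000L + 2L * (gen - 1L), sex = sex,
             generation = gen)
    })
  })
}
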