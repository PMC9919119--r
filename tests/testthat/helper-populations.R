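# Deterministic micro-population builders for unit tests.

# A plant population of n identical individuals. Effect genes are given as
# length-2 count vectors; the load genome as two allele-code vectors
# (0/1 = neutral A/B, +2 = detrimental flag), recycled to `genes` genes.
make_plants <- function(n = 1, res = c(0, 0), tol = c(0, 0), selfg = c(0, 0),
                        hap1 = 0L, hap2 = 0L, genes = 100L, selfer = FALSE) {
  if (n == 0) {
    return(defmate:::new_plant_pop(
      res = matrix(integer(0), 0, 2), tol = matrix(integer(0), 0, 2),
      selfg = matrix(integer(0), 0, 2), g1 = matrix(integer(0), 0, genes),
      g2 = matrix(integer(0), 0, genes), selfer = logical(0)
    ))
  }
  defmate:::new_plant_pop(
    res = matrix(rep(res, each = n), nrow = n),
    tol = matrix(rep(tol, each = n), nrow = n),
    selfg = matrix(rep(selfg, each = n), nrow = n),
    g1 = matrix(rep_len(hap1, genes), nrow = n, ncol = genes, byrow = TRUE),
    g2 = matrix(rep_len(hap2, genes), nrow = n, ncol = genes, byrow = TRUE),
    selfer = rep(selfer, n)
  )
}

make_herbivores <- function(n = 1, anti = c(0, 0), female = NULL) {
  if (is.null(female)) female <- rep(c(TRUE, FALSE), length.out = n)
  defmate:::new_herbivore_pop(
    anti = matrix(rep(anti, each = n), nrow = n),
    female = female
  )
}

# Minimal defense_sim wrapper around hand-made trajectories, for summary
# statistics tests.
fake_run <- function(freqs, trait = "resistance",
                     selfing_mode = "heritable", status = "completed") {
  p <- validate_params(default_params())
  p$selfing_mode <- selfing_mode
  n <- length(freqs)
  rec <- data.frame(
    generation = 0:(n - 1),
    freq_resistance = 0, freq_tolerance = 0, freq_selfing = 0,
    freq_antiresistance = 0, selfer_fraction = 0,
    mean_het = 0.5, mean_load = 0, n_plants = 10, n_herbivores = 10,
    mean_fitness = 1, attack_rate = 0.5
  )
  col <- switch(trait,
    resistance = "freq_resistance", tolerance = "freq_tolerance",
    selfing = if (selfing_mode == "non_heritable") "selfer_fraction" else "freq_selfing",
    antiresistance = "freq_antiresistance")
  rec[[col]] <- freqs
  structure(list(params = p, seed = 1L, records = rec, status = status),
            class = "defense_sim")
}

# small fast parameter set for engine-level tests
fast_params <- function(...) {
  p <- default_params()
  p$K_plants <- 120L
  p$K_herbivores <- 120L
  p$generations <- 30L
  over <- list(...)
  for (k in names(over)) p[[k]] <- over[[k]]
  p
}
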