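# Next-generation construction for plants (hermaphroditic, mixed mating)
# and herbivores (dioecious).

#' Per-plant selfing probability
#'
#' Under heritable selfing the probability of a seed being selfed is the
#' selfing-allele dosage of the mother: (count over both genes)/4. Under
#' non-heritable selfing each plant is either a complete selfer or a
#' complete outcrosser according to its (non-genetic, maternally copied)
#' selfer tag. With selfing disabled all seeds are outcrossed.
#'
#' @param pop A plant population.
#' @param mode One of `"heritable"`, `"non_heritable"`, `"none"`.
#' @return Numeric vector of selfing probabilities in \[0, 1\].
#' @export
selfing_probability <- function(pop, mode) {
  switch(mode,
    heritable = rowSums(pop$selfg) / 4,
    non_heritable = as.numeric(pop$selfer),
    none = rep(0, pop_size(pop)),
    stop("unknown selfing mode: ", mode)
  )
}

# vectorized effect-gene gametes: transmitted effect-allele indicator per
# gene is Bernoulli(count/2), independent across genes and offspring
.effect_offspring <- function(mat, mi, fi) {
  M <- length(mi)
  mg <- matrix(stats::rbinom(M * 2L, 1L, as.vector(mat[mi, , drop = FALSE]) / 2),
               nrow = M)
  pg <- matrix(stats::rbinom(M * 2L, 1L, as.vector(mat[fi, , drop = FALSE]) / 2),
               nrow = M)
  mg + pg
}

# Build a batch of plant offspring (before viability culling).
# mi/fi are mother/father indices into `plants` (fi == mi for selfed seeds).
build_plant_offspring <- function(plants, mi, fi, p) {
  off_load <- offspring_load_cpp(plants$g1, plants$g2, mi, fi, p$mu)
  pop <- new_plant_pop(
    res = .effect_offspring(plants$res, mi, fi),
    tol = .effect_offspring(plants$tol, mi, fi),
    selfg = .effect_offspring(plants$selfg, mi, fi),
    g1 = off_load$g1, g2 = off_load$g2,
    selfer = plants$selfer[mi]  # maternal copy; FALSE everywhere unless non-heritable
  )
  list(pop = pop, lethal = off_load$lethal)
}

#' Produce the next plant generation
#'
#' Each plant draws a Poisson seed number with mean `w0` times its fitness
#' factor. Each seed is selfed with the mother's selfing probability,
#' otherwise outcrossed with a pollen parent drawn uniformly from all plants
#' (pollen production is not fitness-weighted and selfers do export pollen).
#' Offspring are built by gamete formation, load-genome mutation and fusion;
#' seeds homozygous for a detrimental allele at any load gene die at birth.
#' Viable seeds are subsampled uniformly to the plant carrying capacity
#' (fewer are all kept), so populations can shrink under inbreeding
#' depression; fewer than 2 survivors is extinction.
#'
#' @param plants Current plant population.
#' @param damage 0/1 damage vector from [resolve_attacks()].
#' @param p A `defmate_params`.
#' @param fitness Optional precomputed fitness factors (else computed here).
#' @return A list with `plants` (new population, or `NULL`) and `extinct`.
#' @export
next_plant_generation <- function(plants, damage, p, fitness = NULL) {
  N <- pop_size(plants)
  if (N == 0) return(list(plants = NULL, extinct = TRUE))
  if (is.null(fitness)) fitness <- plant_fitness(plants, damage, p)
  seeds <- realize_seeds(p, fitness)
  S <- sum(seeds)
  if (S < 2) return(list(plants = NULL, extinct = TRUE))

  mothers <- rep.int(seq_len(N), seeds)
  sp <- selfing_probability(plants, p$selfing_mode)
  selfed <- stats::rbinom(S, 1L, sp[mothers]) == 1L
  fathers <- ifelse(selfed, mothers, sample.int(N, S, replace = TRUE))

  # Process the seed pool in a uniformly random order and keep the first
  # K viable seeds: identical in distribution to building every seed,
  # culling lethals, then subsampling survivors uniformly to K.
  ord <- sample.int(S)
  K <- p$K_plants
  kept <- NULL
  got <- 0L
  pos <- 1L
  chunk0 <- as.integer(min(S, ceiling(K * 1.15) + 16L))
  while (got < K && pos <= S) {
    take <- ord[pos:min(S, pos + chunk0 - 1L)]
    pos <- pos + length(take)
    off <- build_plant_offspring(plants, mothers[take], fathers[take], p)
    viable <- which(!off$lethal)
    if (length(viable) > 0) {
      need <- K - got
      if (length(viable) > need) viable <- viable[seq_len(need)]
      kept <- pop_bind(kept, pop_subset(off$pop, viable))
      got <- got + length(viable)
    }
    chunk0 <- as.integer(min(max(64L, K - got + 32L), 4L * K))
  }
  if (got < 2L) return(list(plants = NULL, extinct = TRUE))
  list(plants = kept, extinct = FALSE)
}

.empty_herbivores <- function() {
  new_herbivore_pop(matrix(integer(0), 0, 2), logical(0))
}

#' Produce the next herbivore generation
#'
#' Each female draws a Poisson offspring number with mean
#' `herbivore_base_fecundity` times her fitness factor; fathers are drawn
#' among males with probability proportional to their fitness factors;
#' offspring sex is equiprobable; the brood is subsampled to the herbivore
#' carrying capacity. A missing sex, or all-zero male fitness, empties the
#' next generation — herbivore extinction is a recorded state, not an error.
#'
#' @param herbivores Current herbivore population.
#' @param p A `defmate_params`.
#' @param fitness Fitness factors from [herbivore_fitness_factor()], one per
#'   herbivore (computed from investment and fed flag if omitted).
#' @return The next herbivore population (possibly empty).
#' @export
next_herbivore_generation <- function(herbivores, p, fitness = NULL) {
  Nh <- pop_size(herbivores)
  if (Nh == 0) return(.empty_herbivores())
  if (is.null(fitness)) {
    fitness <- herbivore_fitness_factor(p, investment(herbivores, "antiresistance"),
                                        herbivores$fed)
  }
  females <- which(herbivores$female)
  males <- which(!herbivores$female)
  if (length(females) == 0 || length(males) == 0) return(.empty_herbivores())
  wm <- fitness[males]
  if (sum(wm) <= 0) return(.empty_herbivores())

  noff <- stats::rpois(length(females), p$herbivore_base_fecundity * fitness[females])
  S <- sum(noff)
  if (S == 0) return(.empty_herbivores())
  mi <- rep.int(females, noff)
  if (S > p$K_herbivores) mi <- mi[sample.int(S, p$K_herbivores)]
  M <- length(mi)
  fi <- males[sample.int(length(males), M, replace = TRUE, prob = wm)]
  new_herbivore_pop(anti = .effect_offspring(herbivores$anti, mi, fi),
                    female = stats::rbinom(M, 1L, 0.5) == 1L)
}
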