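# Gene-for-gene plant-herbivore encounters.
#
# Rules: (1) a plant without resistance alleles is fully susceptible;
# (2) one resistance allele at a gene arms that gene and confers full
# protection; (3) one anti-resistance allele at the matching herbivore gene
# disarms it. An attack succeeds iff no armed plant gene is left uncountered.

#' Gene-for-gene attack outcome
#'
#' Decides whether a herbivore genotype overcomes a plant genotype. Gene `g`
#' of the plant is armed iff it carries at least one resistance allele; an
#' armed gene is disarmed iff the herbivore carries at least one
#' anti-resistance allele at the same gene. The attack succeeds iff every
#' armed gene is disarmed.
#'
#' Accepts either a length-2 count vector per side (one encounter) or
#' matrices with two columns (vectorized over rows, recycled to a common
#' number of encounters).
#'
#' @param plant_R Per-gene resistance allele counts (values 0, 1, 2).
#' @param herb_A Per-gene anti-resistance allele counts (values 0, 1, 2).
#' @return Logical vector: `TRUE` where the attack succeeds.
#' @export
#' @examples
#' attack_success(c(0, 0), c(0, 0))  # susceptible plant: TRUE
#' attack_success(c(1, 0), c(0, 0))  # armed, uncountered: FALSE
#' attack_success(c(1, 0), c(1, 0))  # armed but disarmed: TRUE
attack_success <- function(plant_R, herb_A) {
  if (is.null(dim(plant_R))) plant_R <- matrix(plant_R, nrow = 1)
  if (is.null(dim(herb_A))) herb_A <- matrix(herb_A, nrow = 1)
  stopifnot(ncol(plant_R) == 2, ncol(herb_A) == 2,
            all(plant_R %in% 0:2), all(herb_A %in% 0:2))
  nr <- max(nrow(plant_R), nrow(herb_A))
  if (nrow(plant_R) == 1 && nr > 1) plant_R <- plant_R[rep(1, nr), , drop = FALSE]
  if (nrow(herb_A) == 1 && nr > 1) herb_A <- herb_A[rep(1, nr), , drop = FALSE]
  blocked <- (plant_R >= 1) & (herb_A == 0)
  rowSums(blocked) == 0
}

#' Resolve one generation of herbivore attacks
#'
#' Each herbivore is assigned one plant uniformly at random (with
#' replacement: several herbivores may land on the same plant). A plant's
#' damage is 1 iff at least one assigned herbivore succeeds; damage
#' saturates at 1. Each herbivore's fed flag is its own success.
#'
#' @param plants A plant population.
#' @param herbivores A herbivore population (may be empty: no damage).
#' @return A list with `damage` (0/1 per plant), `target` (plant index per
#'   herbivore) and `fed` (logical per herbivore).
#' @export
resolve_attacks <- function(plants, herbivores) {
  N <- pop_size(plants)
  if (N == 0) stop("plant population is extinct")
  Nh <- pop_size(herbivores)
  if (Nh == 0) {
    return(list(damage = rep(0L, N), target = integer(0), fed = logical(0)))
  }
  target <- sample.int(N, Nh, replace = TRUE)
  fed <- attack_success(plants$res[target, , drop = FALSE], herbivores$anti)
  damage <- rep(0L, N)
  damage[unique(target[fed])] <- 1L
  list(damage = damage, target = target, fed = fed)
}

#' Herbivore fitness factor
#'
#' Herbivores pay the anti-resistance cost `c_a * a^l` and, when their attack
#' failed, lose a configurable proportion of fitness
#' (`herbivore_failure_cost`, default 0.75) rather than dying outright.
#'
#' @param p A `defmate_params`.
#' @param a Anti-resistance investment(s) in \[0, 1\].
#' @param fed Logical: did the attack succeed.
#' @return Non-negative fitness factor(s), floored at 0.
#' @export
herbivore_fitness_factor <- function(p, a, fed) {
  pmax(0, (1 - p$c_a * a^p$l) * (1 - p$herbivore_failure_cost * (1 - fed)))
}
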