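# Genotype representation
#
# Populations are stored column-wise for speed. Plants:
#   res, tol, selfg : N x 2 integer matrices of effect-allele counts per gene
#                     (two unlinked diallelic genes per effect, counts 0..2)
#   g1, g2          : N x n_genome_genes integer matrices, one per haplotype,
#                     load-genome allele codes: bit 1 (value 1) = neutral
#                     class B, bit 2 (value 2) = detrimental flag; a gene is
#                     heterozygous when the two composite codes differ, and
#                     lethal when both alleles carry the detrimental bit
#   selfer          : logical N, maternally transmitted selfer tag
#                     (meaningful only under non-heritable selfing)
# Herbivores:
#   anti            : N x 2 effect-allele counts (anti-resistance)
#   female          : logical N (sex, fixed at birth)
#   fed             : logical N (feeding outcome of the current generation)

.DETRIMENTAL <- 2L

new_plant_pop <- function(res, tol, selfg, g1, g2, selfer) {
  structure(list(res = res, tol = tol, selfg = selfg,
                 g1 = g1, g2 = g2, selfer = selfer),
            class = "defmate_plants")
}

new_herbivore_pop <- function(anti, female, fed = rep(FALSE, nrow(anti))) {
  structure(list(anti = anti, female = female, fed = fed),
            class = "defmate_herbivores")
}

pop_size <- function(pop) {
  m <- if (inherits(pop, "defmate_herbivores")) pop$anti else pop$res
  if (is.null(m)) 0L else nrow(m)
}

pop_subset <- function(pop, idx) {
  if (inherits(pop, "defmate_herbivores")) {
    new_herbivore_pop(pop$anti[idx, , drop = FALSE], pop$female[idx],
                      pop$fed[idx])
  } else {
    new_plant_pop(pop$res[idx, , drop = FALSE], pop$tol[idx, , drop = FALSE],
                  pop$selfg[idx, , drop = FALSE], pop$g1[idx, , drop = FALSE],
                  pop$g2[idx, , drop = FALSE], pop$selfer[idx])
  }
}

pop_bind <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  new_plant_pop(rbind(a$res, b$res), rbind(a$tol, b$tol),
                rbind(a$selfg, b$selfg), rbind(a$g1, b$g1),
                rbind(a$g2, b$g2), c(a$selfer, b$selfer))
}

#' Resource investment of each individual in an effect
#'
#' Investment in resistance, tolerance, selfing (plants) or anti-resistance
#' (herbivores) is the proportion of effect alleles carried over the four
#' allele slots of the two genes controlling the effect: (count gene 1 +
#' count gene 2) / 4, one of 0, 0.25, 0.5, 0.75, 1. A single retained
#' resistance allele (investment 0.25) already confers full protection under
#' the gene-for-gene rules, which is why 0.25 is the predicted optimal
#' resistance investment when resistance is costly.
#'
#' @param pop A plant or herbivore population.
#' @param effect One of `"resistance"`, `"tolerance"`, `"selfing"`
#'   (plants) or `"antiresistance"` (herbivores).
#' @return Numeric vector of investments, one per individual.
#' @export
investment <- function(pop, effect) {
  m <- switch(effect,
    resistance = pop$res,
    tolerance = pop$tol,
    selfing = pop$selfg,
    antiresistance = pop$anti,
    stop("unknown effect: ", effect)
  )
  if (is.null(m)) stop("effect '", effect, "' not carried by this genotype")
  rowSums(m) / 4
}

#' Individual genomic heterozygosity
#'
#' Fraction of the load-genome genes whose two alleles differ in composite
#' state (neutral class or detrimental flag). Ranges 0-1 by definition; under
#' random mating at diallelic equilibrium the realized population mean tends
#' to 0.5, and to 0 under full selfing.
#'
#' @param pop A plant population.
#' @return Numeric vector in \[0, 1\], one value per individual.
#' @export
heterozygosity <- function(pop) {
  rowMeans(pop$g1 != pop$g2)
}

#' Count detrimental alleles and flag lethal genotypes
#'
#' Counts detrimental-flagged alleles over all load-genome slots of each
#' individual, and flags a genotype as lethal when any gene carries the
#' detrimental flag on both alleles (lethal recessives: homozygotes have
#' fitness zero and are culled at birth in the simulator).
#'
#' @param pop A plant population.
#' @return A data.frame with columns `count` (integer) and `lethal` (logical).
#' @export
count_detrimental <- function(pop) {
  d1 <- pop$g1 >= .DETRIMENTAL
  d2 <- pop$g2 >= .DETRIMENTAL
  data.frame(count = as.integer(rowSums(d1) + rowSums(d2)),
             lethal = rowSums(d1 & d2) > 0)
}

#' Form one gamete by independent assortment
#'
#' All genes (the two genes of each effect and every load-genome gene) are
#' unlinked: one allele is chosen uniformly at random per gene, independently
#' across genes. For the diallelic effect genes the transmitted allele is the
#' effect allele with probability count/2.
#'
#' @param pop A plant or herbivore population.
#' @param i Index of the parent within `pop`.
#' @return An object of class `defmate_gamete`: a list with `kind`
#'   (`"plant"` or `"herbivore"`), `eff` (named list of 0/1 effect-allele
#'   indicators, one per gene) and, for plants, `load` (integer vector of
#'   load-genome allele codes).
#' @export
make_gamete <- function(pop, i = 1L) {
  if (inherits(pop, "defmate_herbivores")) {
    eff <- list(antiresistance = stats::rbinom(2, 1, pop$anti[i, ] / 2))
    return(structure(list(kind = "herbivore", eff = eff, load = NULL),
                     class = "defmate_gamete"))
  }
  eff <- list(
    resistance = stats::rbinom(2, 1, pop$res[i, ] / 2),
    tolerance  = stats::rbinom(2, 1, pop$tol[i, ] / 2),
    selfing    = stats::rbinom(2, 1, pop$selfg[i, ] / 2)
  )
  n <- ncol(pop$g1)
  pick <- stats::runif(n) < 0.5
  load <- ifelse(pick, pop$g1[i, ], pop$g2[i, ])
  structure(list(kind = "plant", eff = eff, load = as.integer(load)),
            class = "defmate_gamete")
}

#' Mutate the load genome of a gamete
#'
#' Each load-genome allele independently acquires the detrimental flag with
#' probability `mu` per generation (idempotent on already-detrimental
#' alleles). Effect genes never mutate: lost effect alleles can only persist
#' cryptically in the population and resurge by segregation.
#'
#' @param gam A `defmate_gamete` from [make_gamete()].
#' @param mu Per-allele mutation rate in \[0, 1\].
#' @return The gamete with mutated load genome.
#' @export
mutate_gamete <- function(gam, mu) {
  stopifnot(mu >= 0, mu <= 1)
  if (is.null(gam$load) || mu == 0) return(gam)
  hit <- stats::runif(length(gam$load)) < mu
  gam$load[hit] <- bitwOr(gam$load[hit], .DETRIMENTAL)
  gam
}

#' Fuse two gametes into a diploid genotype
#'
#' Builds a one-individual population from a maternal and a paternal gamete;
#' derived quantities (heterozygosity, detrimental count, lethality,
#' investments) are pure functions of the stored state and can be read with
#' [heterozygosity()], [count_detrimental()] and [investment()].
#'
#' @param maternal,paternal Two `defmate_gamete` objects of the same kind.
#' @param selfer Selfer tag for the offspring (non-heritable selfing only).
#' @return A one-individual population of the matching kind.
#' @export
fuse <- function(maternal, paternal, selfer = FALSE) {
  stopifnot(identical(maternal$kind, paternal$kind))
  if (maternal$kind == "herbivore") {
    anti <- matrix(maternal$eff$antiresistance + paternal$eff$antiresistance,
                   nrow = 1)
    return(new_herbivore_pop(anti, female = stats::runif(1) < 0.5))
  }
  new_plant_pop(
    res = matrix(maternal$eff$resistance + paternal$eff$resistance, nrow = 1),
    tol = matrix(maternal$eff$tolerance + paternal$eff$tolerance, nrow = 1),
    selfg = matrix(maternal$eff$selfing + paternal$eff$selfing, nrow = 1),
    g1 = matrix(maternal$load, nrow = 1),
    g2 = matrix(paternal$load, nrow = 1),
    selfer = selfer
  )
}

#' Initialize the plant and herbivore populations
#'
#' Draws `K_plants` plants and `K_herbivores` herbivores. Effect alleles are
#' drawn independently per allele slot at the configured initial frequencies;
#' load-genome neutral classes are drawn at `init_genome_het` (the frequency
#' of the B class, so the expected initial heterozygosity is 2p(1-p)); no
#' detrimental alleles exist at the start; herbivore sexes alternate to an
#' even split; selfer tags are drawn at `init_selfer_fraction` when the
#' selfing mode is non-heritable.
#'
#' @param p A validated `defmate_params`.
#' @return A list with elements `plants` and `herbivores`.
#' @export
init_population <- function(p) {
  p <- validate_params(p)
  N <- p$K_plants
  n <- p$n_genome_genes
  eff_init <- function(N, freq) {
    matrix(stats::rbinom(N * 2L, 2L, freq), nrow = N, ncol = 2L)
  }
  res <- eff_init(N, p$init_freq_resistance)
  tol <- eff_init(N, p$init_freq_tolerance)
  selfg <- eff_init(N, p$init_freq_selfing)
  g1 <- matrix(stats::rbinom(N * n, 1L, p$init_genome_het), nrow = N, ncol = n)
  g2 <- matrix(stats::rbinom(N * n, 1L, p$init_genome_het), nrow = N, ncol = n)
  selfer <- if (p$selfing_mode == "non_heritable") {
    stats::runif(N) < p$init_selfer_fraction
  } else {
    rep(FALSE, N)
  }
  plants <- new_plant_pop(res, tol, selfg, g1, g2, selfer)

  Nh <- p$K_herbivores
  herbivores <- if (Nh > 0) {
    new_herbivore_pop(eff_init(Nh, p$init_freq_antiresistance),
                      female = rep(c(TRUE, FALSE), length.out = Nh))
  } else {
    new_herbivore_pop(matrix(integer(0), 0, 2), logical(0))
  }
  list(plants = plants, herbivores = herbivores)
}
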