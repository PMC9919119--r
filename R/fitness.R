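# Individual fitness under the multiplicative and additive allocation models.
#
# Terms (all powered by the linearity exponent l):
#   RC = c_r * r^l          cost of resistance
#   TC = c_t * t^l          cost of tolerance
#   HD = c_h * d^l          cost of herbivory damage (d binary)
#   TB = b_t * d^l * t^l    benefit of tolerance (inducible: zero without damage)
#   O1 = (h_i / H)^k        overdominance, multiplicative (ratio to reference H)
#   O2 = k * (H - h_i)      overdominance penalty, additive (sign-corrected:
#                           above-reference heterozygosity raises fitness;
#                           the verbatim k*(h_i - H) sits behind
#                           o2_sign_verbatim)
#   D  = (u_i * s)^l        dominance load: detrimental alleles times s
#   I  = 0 when any load gene is detrimental-homozygous (lethal), else 1

fitness_factor_core <- function(model, c_r, c_t, c_h, b_t, k, H, s, l,
                                o2_verbatim, r, t, d, h_i, u_i, lethal) {
  RC <- c_r * r^l
  TC <- c_t * t^l
  HD <- c_h * d^l
  TB <- b_t * d^l * t^l
  D <- (u_i * s)^l
  I <- ifelse(lethal, 0, 1)
  if (model == "multiplicative") {
    O1 <- (h_i / H)^k
    F <- pmax(0, 1 - RC) * pmax(0, 1 - TC) * pmax(0, 1 - HD + TB) *
      O1 * pmax(0, 1 - D) * I
  } else {
    O2 <- if (o2_verbatim) k * (h_i - H) else k * (H - h_i)
    F <- pmax(0, 1 - RC - TC - HD + TB - O2 - D) * I
  }
  F
}

#' Individual fitness factor
#'
#' Evaluates the fitness factor of one or more individuals under the
#' multiplicative or additive allocation model. Under the multiplicative
#' model every parenthesized factor is floored at zero and the overdominance
#' ratio `(h_i/H)^k` can exceed one (individuals more heterozygous than the
#' reference gain fitness); a fully homozygous genome (`h_i = 0`) cancels
#' the whole multiplicative fitness. Under the additive model the single sum
#' is floored at zero. Lethal genotypes (a detrimental-homozygous load gene)
#' have fitness zero under either model.
#'
#' All of `r`, `t`, `d`, `h_i`, `u_i`, `lethal` are recycled to a common
#' length, so the function evaluates whole populations at once.
#'
#' @param p A `defmate_params` (uses `model`, costs/benefits, `k`, `H`, `s`,
#'   `l` and `o2_sign_verbatim`).
#' @param r,t Investments in resistance and tolerance (proportions).
#' @param d Herbivory damage, 0 or 1.
#' @param h_i Individual genomic heterozygosity.
#' @param u_i Individual count of detrimental alleles.
#' @param lethal Logical, detrimental-homozygous at some load gene.
#' @return Non-negative numeric vector of fitness factors (may exceed 1 under
#'   the multiplicative model when `h_i > H`).
#' @export
#' @examples
#' p <- default_params()
#' fitness_factor(p, r = 0, t = 0, d = 0, h_i = p$H, u_i = 0)  # 1: neutral
#' fitness_factor(p, r = 0.25, t = 0, d = 0, h_i = p$H, u_i = 0)  # 1 - c_r/4
fitness_factor <- function(p, r, t, d, h_i, u_i, lethal = FALSE) {
  fitness_factor_core(p$model, p$c_r, p$c_t, p$c_h, p$b_t, p$k, p$H, p$s,
                      p$l, p$o2_sign_verbatim, r, t, d, h_i, u_i, lethal)
}

# fitness factors for a whole plant population given the damage vector
plant_fitness <- function(plants, damage, p) {
  cd <- count_detrimental(plants)
  fitness_factor(p,
                 r = investment(plants, "resistance"),
                 t = investment(plants, "tolerance"),
                 d = damage,
                 h_i = heterozygosity(plants),
                 u_i = cd$count,
                 lethal = cd$lethal)
}

#' Realize integer seed counts from a fitness factor
#'
#' Seed numbers are Poisson with mean `w0 * F`: the Poisson base fitness
#' (mean `w0`) thinned by the fitness factor is again Poisson, and the same
#' form extends to factors above one.
#'
#' @param p A `defmate_params` (uses `w0`).
#' @param F Non-negative fitness factor(s).
#' @return Integer vector of seed counts, one per element of `F`.
#' @export
realize_seeds <- function(p, F) {
  stopifnot(all(F >= 0))
  stats::rpois(length(F), p$w0 * F)
}
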