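# Closed-form companions to the simulator: scenario fitness maxima, the
# optimal tolerance investment, curvature classification, mutation-load
# equilibria, and fitness-surface grids.

#' Optimal tolerance investment under herbivory
#'
#' Exact maximizer of the damaged, resistance-free multiplicative fitness
#' `(1 - c_t t)(1 - c_h + b_t t)` at `l = 1`, `d = 1`:
#' `t = (1/2) (1/c_t - (1 - c_h)/b_t)`, clipped to \[0, 1\] (the interior
#' optimum is taken only when it falls inside the unit interval).
#'
#' @param c_t Maximum tolerance cost (> 0).
#' @param c_h Maximum herbivory cost.
#' @param b_t Maximum tolerance benefit (> 0).
#' @return Optimal tolerance investment in \[0, 1\].
#' @export
#' @examples
#' optimal_tolerance(0.4, 0.75, 0.25)  # 0.75 at the default costs
optimal_tolerance <- function(c_t, c_h, b_t) {
  if (any(c_t <= 0) || any(b_t <= 0)) {
    stop("c_t and b_t must be positive for the tolerance optimum")
  }
  t <- 0.5 * (1 / c_t - (1 - c_h) / b_t)
  pmin(1, pmax(0, t))
}

#' Scenario fitness maxima and the fitness ratio
#'
#' Evaluates the two fitness-maximizing scenarios of the model, stated at
#' `d = 1` and `l = 1` for the tolerance part:
#'
#' * resistance scenario: resistance persists at the minimum investment
#'   `r* = 0.25` (one retained allele over four slots), cancelling herbivory
#'   damage and with it any tolerance benefit, so tolerance is lost and
#'   `w_RS = 1 - c_r (r*)^l` under either model;
#' * non-resistance scenario: damage is taken and tolerance pays; under the
#'   multiplicative model the maximum is the exact product
#'   `(1 - c_t t_h)(1 - c_h + b_t t_h)` at `t_h =` [optimal_tolerance()],
#'   while the additive maximum is `1 - c_t t - c_h + b_t t` at `t = 1` when
#'   `b_t > c_t` and `t = 0` otherwise.
#'
#' The ratio `f_r = w_NRS / w_RS` decides the favored scenario: resistance
#' for `f_r < 1`, non-resistance for `f_r > 1`. Neither scenario predicts a
#' mixed strategy — the double trade-off between cost duplication and the
#' inducibility of tolerance excludes it at this level; mixed strategies in
#' the simulations arise from segregation and random mating around these
#' optima.
#'
#' @param p A `defmate_params`.
#' @param form `"exact"` (default) for the product-form multiplicative
#'   non-resistance maximum, or `"printed"` for the linear form
#'   `1 - t_h (b_t - c_t) - c_h` kept for comparison.
#' @return An object of class `defmate_scenario`: list with `w_RS`, `w_NRS`,
#'   `t_opt`, `f_r` and `favored`.
#' @export
scenario_predictions <- function(p, form = c("exact", "printed")) {
  form <- match.arg(form)
  r_star <- 0.25
  w_rs <- 1 - p$c_r * r_star^p$l
  if (p$model == "multiplicative") {
    t_opt <- optimal_tolerance(p$c_t, p$c_h, p$b_t)
    w_nrs <- if (form == "exact") {
      (1 - p$c_t * t_opt) * (1 - p$c_h + p$b_t * t_opt)
    } else {
      1 - t_opt * (p$b_t - p$c_t) - p$c_h
    }
  } else {
    t_opt <- if (p$b_t > p$c_t) 1 else 0
    w_nrs <- 1 - p$c_t * t_opt - p$c_h + p$b_t * t_opt
  }
  f_r <- w_nrs / w_rs
  structure(list(
    model = p$model, w_RS = w_rs, w_NRS = w_nrs, t_opt = t_opt, f_r = f_r,
    favored = if (f_r > 1) "non_resistance" else "resistance"
  ), class = "defmate_scenario")
}

#' @export
print.defmate_scenario <- function(x, ...) {
  cat(sprintf("Scenario predictions (%s model)\n", x$model))
  cat(sprintf("  resistance scenario max fitness factor  w_RS  = %.4f\n", x$w_RS))
  cat(sprintf("  non-resistance scenario max             w_NRS = %.4f (t_opt = %.3f)\n",
              x$w_NRS, x$t_opt))
  cat(sprintf("  fitness ratio f_r = %.4f -> favored: %s\n", x$f_r, x$favored))
  invisible(x)
}

#' Curvature class of a powered fitness term
#'
#' A term `k a^l` is convex in `a` when the base coefficient is positive and
#' `l > 1`, concave when positive and `l < 1`; the classes flip for a
#' negative coefficient; `l = 1` is linear. Concavity of costs (benefits
#' accumulating faster than costs) widens the window for mixed defense
#' strategies; convexity narrows it.
#'
#' @param base_sign `"positive"` or `"negative"`.
#' @param l Linearity exponent (> 0).
#' @return One of `"convex"`, `"concave"`, `"linear"`.
#' @export
curvature_class <- function(base_sign = c("positive", "negative"), l) {
  base_sign <- match.arg(base_sign)
  stopifnot(l > 0)
  if (l == 1) return("linear")
  pos_convex <- l > 1
  if (base_sign == "negative") pos_convex <- !pos_convex
  if (pos_convex) "convex" else "concave"
}

#' Mutation-load equilibria
#'
#' Expected number of detrimental (lethal-recessive) alleles carried per
#' individual at mutation-selection balance, per mating regime:
#'
#' * outcrossing: per-locus equilibrium frequency `q* = sqrt(mu)` (the exact
#'   fixpoint of the lethal-recessive recursion, see
#'   [load_equilibrium_recursion()]), giving `2 n sqrt(mu)` carried alleles;
#' * selfing: each new lethal is exposed as a homozygote and purged within
#'   about one selfed generation, so the standing load equals the diploid
#'   genomic mutation rate `U = 2 n mu`.
#'
#' At the default `mu = 0.00245` and `n = 100` these are ~9.9 and 0.49.
#'
#' @param mu Per-allele mutation rate in (0, 1) (0 allowed, giving 0).
#' @param n_genes Number of load-genome genes.
#' @param regime `"outcrossing"` or `"selfing"`.
#' @return Expected detrimental alleles per individual.
#' @export
load_equilibrium <- function(mu, n_genes = 100,
                             regime = c("outcrossing", "selfing")) {
  regime <- match.arg(regime)
  stopifnot(mu >= 0, mu < 1)
  if (regime == "outcrossing") 2 * n_genes * sqrt(mu) else 2 * n_genes * mu
}

#' Deterministic per-locus recursion for the outcrossing load equilibrium
#'
#' Iterates the one-locus lethal-recessive recursion under random mating to
#' its fixpoint: selection removes `aa` homozygotes, taking the allele
#' frequency from `q` to `q/(1+q)`, then mutation adds `mu` on the normal
#' alleles, giving `q' = (q + mu)/(1 + q)`. The fixpoint solves
#' `q^2 = mu` exactly, which is the independent check behind the closed form
#' in [load_equilibrium()].
#'
#' @param mu Per-allele mutation rate.
#' @param n_genes Number of load genes.
#' @param tol Convergence tolerance on `q`.
#' @param max_iter Iteration cap.
#' @return Expected carried detrimental alleles per individual, `2 n q*`.
#' @export
load_equilibrium_recursion <- function(mu, n_genes = 100, tol = 1e-12,
                                       max_iter = 100000L) {
  q <- 0
  for (i in seq_len(max_iter)) {
    q_new <- (q * (1 - q) / (1 - q^2)) + mu * (1 - q / (1 + q))
    if (abs(q_new - q) < tol) {
      q <- q_new
      break
    }
    q <- q_new
  }
  2 * n_genes * q
}

#' Fitness-surface grid over two swept inputs
#'
#' Evaluates the fitness factor over the Cartesian product of two swept
#' inputs from `c_r`, `c_t`, `r`, `t`, `d`, `l`, holding everything else at
#' the values in `p` and `fixed`. When the tolerance cost `c_t` is swept the
#' tolerance benefit is linked as `b_t = 1 - c_t`, so the cost axis probes
#' the cost-benefit balance at once.
#'
#' @param p A `defmate_params`.
#' @param axes Named list of exactly two numeric vectors; names among
#'   `c_r`, `c_t`, `r`, `t`, `d`, `l`.
#' @param fixed Named list of fixed inputs overriding the defaults
#'   `r = 0, t = 0, d = 0, h_i = p$H, u_i = 0`.
#' @return A long-format data.frame: the two axis columns, all effective
#'   inputs (`c_r`, `c_t`, `b_t`, `l`, `r`, `t`, `d`, `h_i`, `u_i`) and the
#'   fitness factor `F`.
#' @export
fitness_surface_grid <- function(p, axes, fixed = list()) {
  allowed <- c("c_r", "c_t", "r", "t", "d", "l")
  if (length(axes) != 2 || is.null(names(axes)) ||
      !all(names(axes) %in% allowed)) {
    stop("axes must be a named list of two vectors over {",
         paste(allowed, collapse = ", "), "}")
  }
  if (!all(names(fixed) %in% c(allowed, "h_i", "u_i", "b_t"))) {
    stop("unknown name in fixed: ",
         paste(setdiff(names(fixed), c(allowed, "h_i", "u_i", "b_t")),
               collapse = ", "))
  }
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  val <- function(name, default) {
    if (name %in% names(grid)) return(grid[[name]])
    if (name %in% names(fixed)) return(rep(fixed[[name]], nrow(grid)))
    rep(default, nrow(grid))
  }
  c_r <- val("c_r", p$c_r)
  c_t <- val("c_t", p$c_t)
  b_t <- if ("c_t" %in% names(grid)) 1 - c_t else val("b_t", p$b_t)
  l <- val("l", p$l)
  r <- val("r", 0)
  t <- val("t", 0)
  d <- val("d", 0)
  h_i <- val("h_i", p$H)
  u_i <- val("u_i", 0)
  F <- fitness_factor_core(p$model, c_r, c_t, p$c_h, b_t, p$k, p$H, p$s, l,
                           p$o2_sign_verbatim, r, t, d, h_i, u_i, FALSE)
  out <- data.frame(c_r = c_r, c_t = c_t, b_t = b_t, l = l, r = r, t = t,
                    d = d, h_i = h_i, u_i = u_i, F = F)
  cbind(grid, out[setdiff(names(out), names(grid))])
}
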