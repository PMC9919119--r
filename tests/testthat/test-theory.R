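test_that("optimal tolerance investment matches the grid-search argmax", {
  expect_equal(optimal_tolerance(0.4, 0.75, 0.25), 0.75)
  expect_equal(optimal_tolerance(0.9, 0.1, 0.1), 0)   # interior optimum < 0
  expect_equal(optimal_tolerance(0.5, 1.0, 0.5), 1)   # boundary
  expect_error(optimal_tolerance(0, 0.5, 0.2), "positive")

  set.seed(81)
  tgrid <- seq(0, 1, by = 1e-4)
  for (i in 1:300) {
    c_t <- runif(1, 0.05, 1); c_h <- runif(1); b_t <- runif(1, 0.05, 1)
    w <- (1 - c_t * tgrid) * (1 - c_h + b_t * tgrid)
    expect_lt(abs(optimal_tolerance(c_t, c_h, b_t) - tgrid[which.max(w)]),
              1e-3 + 1e-8)
  }
})

test_that("scenario predictions reproduce the default-parameter analysis", {
  p <- default_params()
  sc <- scenario_predictions(p)
  expect_equal(sc$w_RS, 0.9625)
  expect_equal(sc$t_opt, 0.75)
  expect_equal(sc$w_NRS, 0.7 * 0.4375)  # (1 - 0.4*0.75)(1 - 0.75 + 0.25*0.75)
  expect_equal(sc$f_r, 0.30625 / 0.9625)
  expect_equal(sc$favored, "resistance")

  pa <- p; pa$model <- "additive"
  sca <- scenario_predictions(pa)
  expect_equal(sca$t_opt, 0)  # b_t < c_t: no tolerance pays additively
  expect_equal(sca$w_NRS, 0.25)
  expect_equal(sca$f_r, 0.25 / 0.9625)

  pf <- p; pf$c_r <- 0
  expect_equal(scenario_predictions(pf)$w_RS, 1)
  expect_equal(scenario_predictions(pf)$favored, "resistance")

  # printed linear form kept for comparison differs from the exact product
  expect_false(isTRUE(all.equal(
    scenario_predictions(p, form = "printed")$w_NRS, sc$w_NRS)))
})

test_that("perturbing c_r across the f_r = 1 point flips the favored scenario", {
  p <- default_params()
  p$c_h <- 0.9; p$c_t <- 0.1; p$b_t <- 0.9
  # w_NRS = 0.9; w_RS = 1 - 0.25 c_r crosses at c_r = 0.4
  p$c_r <- 0.38
  expect_equal(scenario_predictions(p)$favored, "resistance")
  p$c_r <- 0.42
  expect_equal(scenario_predictions(p)$favored, "non_resistance")
})

test_that("curvature classification follows the sign and exponent", {
  expect_equal(curvature_class("positive", 5.0), "convex")
  expect_equal(curvature_class("positive", 0.2), "concave")
  expect_equal(curvature_class("negative", 5.0), "concave")
  expect_equal(curvature_class("negative", 0.2), "convex")
  expect_equal(curvature_class("positive", 1), "linear")
  expect_equal(curvature_class("negative", 1), "linear")
})

test_that("load equilibria match the per-locus recursion fixpoint", {
  expect_equal(load_equilibrium(0.0025, 100, "outcrossing"), 10)
  expect_equal(load_equilibrium(0.00245, 100, "selfing"), 0.49)
  expect_equal(load_equilibrium(0, 100, "outcrossing"), 0)
  expect_equal(load_equilibrium(0, 100, "selfing"), 0)
  for (mu in c(1e-4, 5e-4, 1e-3, 2.45e-3, 1e-2)) {
    closed <- load_equilibrium(mu, 100, "outcrossing")
    rec <- load_equilibrium_recursion(mu, 100)
    expect_lt(abs(closed - rec) / closed, 0.01)
  }
})

test_that("fitness-surface grids expose the cost-benefit structure", {
  p <- default_params()
  # no herbivory: fitness falls along both cost axes at positive investments
  g <- fitness_surface_grid(p, axes = list(c_r = seq(0, 1, 0.25),
                                           c_t = seq(0, 0.9, 0.3)),
                            fixed = list(r = 0.5, t = 0.5, d = 0))
  expect_equal(g$b_t, 1 - g$c_t)  # linked benefit convention
  for (ct in unique(g$c_t)) {
    F <- g$F[g$c_t == ct][order(g$c_r[g$c_t == ct])]
    expect_true(all(diff(F) <= 1e-12))
  }
  for (cr in unique(g$c_r)) {
    F <- g$F[g$c_r == cr][order(g$c_t[g$c_r == cr])]
    expect_true(all(diff(F) <= 1e-12))
  }

  # under damage at l = 1 (additive model), the tolerance payoff has the
  # sign of b_t - c_t exactly
  pa <- p; pa$model <- "additive"
  g2 <- fitness_surface_grid(pa, axes = list(t = c(0, 1),
                                             c_t = seq(0.1, 0.9, 0.1)),
                             fixed = list(d = 1, r = 0))
  for (ct in unique(g2$c_t)) {
    diffF <- g2$F[g2$t == 1 & g2$c_t == ct] - g2$F[g2$t == 0 & g2$c_t == ct]
    expect_equal(sign(diffF), sign((1 - ct) - ct))
  }

  # a single-cell grid agrees with a direct fitness evaluation
  g3 <- fitness_surface_grid(p, axes = list(r = 0.25, t = 0.5),
                             fixed = list(d = 1))
  expect_equal(nrow(g3), 1L)
  expect_equal(g3$F, fitness_factor(p, 0.25, 0.5, 1, p$H, 0))

  expect_error(fitness_surface_grid(p, axes = list(q = 1, r = 0)), "axes")
})
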