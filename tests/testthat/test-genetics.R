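test_that("investment is the effect-allele dosage over four slots", {
  expect_equal(investment(make_plants(res = c(0, 0)), "resistance"), 0)
  # one retained allele: the minimum investment that still arms resistance
  expect_equal(investment(make_plants(res = c(1, 0)), "resistance"), 0.25)
  expect_equal(investment(make_plants(res = c(2, 2)), "resistance"), 1)
  # invariant under gene order (unlinked, exchangeable)
  expect_equal(investment(make_plants(tol = c(0, 1)), "tolerance"),
               investment(make_plants(tol = c(1, 0)), "tolerance"))
  expect_equal(investment(make_herbivores(anti = c(2, 1)), "antiresistance"), 0.75)
  expect_error(investment(make_plants(), "virulence"), "unknown effect")
  expect_error(investment(make_herbivores(), "resistance"), "not carried")
})

test_that("heterozygosity is the fraction of composite-state-mismatched genes", {
  expect_equal(heterozygosity(make_plants(hap1 = 0L, hap2 = 0L)), 0)
  expect_equal(heterozygosity(make_plants(hap1 = 0L, hap2 = 1L)), 1)
  # half the genes heterozygous, including via the detrimental flag alone
  half <- make_plants(hap1 = 0L, hap2 = rep(c(0L, 2L), 50))
  expect_equal(heterozygosity(half), 0.5)
})

test_that("detrimental counting and lethality detection", {
  cd <- count_detrimental(make_plants())
  expect_equal(cd$count, 0L)
  expect_false(cd$lethal)

  # 10 genes with one detrimental allele each: count 10, not lethal
  hap <- rep(0L, 100); hap[1:10] <- 2L
  cd <- count_detrimental(make_plants(hap1 = hap, hap2 = 0L))
  expect_equal(cd$count, 10L)
  expect_false(cd$lethal)

  # one gene detrimental on both alleles: lethal
  h1 <- rep(0L, 100); h1[7] <- 2L
  h2 <- rep(1L, 100); h2[7] <- 3L
  cd <- count_detrimental(make_plants(hap1 = h1, hap2 = h2))
  expect_equal(cd$count, 2L)
  expect_true(cd$lethal)
})

test_that("gametes from homozygous parents copy the parental haplotype", {
  hap <- rep(c(0L, 1L), 50)
  pop <- make_plants(res = c(2, 0), tol = c(0, 2), selfg = c(0, 0),
                     hap1 = hap, hap2 = hap)
  g <- make_gamete(pop, 1)
  expect_equal(g$eff$resistance, c(1, 0))
  expect_equal(g$eff$tolerance, c(0, 1))
  expect_equal(g$eff$selfing, c(0, 0))
  expect_equal(g$load, hap)
})

test_that("segregation from heterozygotes is fair (binomial oracle)", {
  set.seed(11)
  pop <- make_plants(res = c(1, 0))
  n <- 4000
  trans <- vapply(seq_len(n), function(i) make_gamete(pop, 1)$eff$resistance[1], 0)
  # Binomial(n, 1/2): 3 sigma band around 0.5
  expect_lt(abs(mean(trans) - 0.5), 3 * sqrt(0.25 / n))

  # same for a heterozygous load gene, through the batch kernel
  # (mother heterozygous at gene 1, father fully homozygous)
  h1 <- rep(0L, 100); h1[1] <- 1L
  pop2 <- defmate:::new_plant_pop(
    res = matrix(0L, 2, 2), tol = matrix(0L, 2, 2), selfg = matrix(0L, 2, 2),
    g1 = rbind(h1, rep(0L, 100)), g2 = rbind(rep(0L, 100), rep(0L, 100)),
    selfer = c(FALSE, FALSE)
  )
  off <- defmate:::offspring_load_cpp(pop2$g1, pop2$g2, rep(1L, n), rep(2L, n), 0)
  expect_lt(abs(mean(off$g1[, 1]) - 0.5), 3 * sqrt(0.25 / n))
  expect_true(all(off$g2[, 1] == 0))  # father homozygous at that gene
})

test_that("two gametes drawn from the same RNG state are identical", {
  pop <- make_plants(res = c(1, 1), hap1 = 0L, hap2 = 1L)
  set.seed(99); g1 <- make_gamete(pop, 1)
  set.seed(99); g2 <- make_gamete(pop, 1)
  expect_identical(g1, g2)
})

test_that("gamete mutation hits load alleles at rate mu and is idempotent", {
  pop <- make_plants()
  g <- make_gamete(pop, 1)
  expect_identical(mutate_gamete(g, 0), g)
  expect_true(all(mutate_gamete(g, 1)$load >= 2))
  # already-detrimental alleles stay detrimental
  gd <- g; gd$load <- rep(2L, 100)
  expect_identical(mutate_gamete(gd, 1)$load, gd$load)

  # Poisson oracle on the per-gamete path: 1000 gametes x 100 alleles
  set.seed(21)
  mu <- 0.00245
  hits <- sum(vapply(1:1000, function(i) sum(mutate_gamete(g, mu)$load >= 2), 0))
  lambda <- 1000 * 100 * mu
  expect_lt(abs(hits - lambda), 3 * sqrt(lambda))
})

test_that("batch-kernel mutation matches the per-allele Bernoulli rate", {
  set.seed(22)
  pop <- make_plants(n = 2)
  mu <- 0.00245
  reps <- 2000
  off <- defmate:::offspring_load_cpp(pop$g1, pop$g2, rep(1L, reps), rep(2L, reps), mu)
  hits <- sum(off$load)
  lambda <- reps * 200 * mu
  expect_lt(abs(hits - lambda), 3 * sqrt(lambda))
  # derived summaries agree with recomputation from the returned matrices
  expect_equal(off$het, rowMeans(off$g1 != off$g2))
  expect_equal(off$load, as.integer(rowSums(off$g1 >= 2) + rowSums(off$g2 >= 2)))
  expect_equal(off$lethal, rowSums(off$g1 >= 2 & off$g2 >= 2) > 0)
})

test_that("fusion derives heterozygosity and lethality from the gametes", {
  pop <- make_plants()
  a <- make_gamete(pop, 1)
  expect_equal(heterozygosity(fuse(a, a)), 0)

  b <- a; b$load <- rep(1L, 100)  # all-B gamete vs all-A gamete
  expect_equal(heterozygosity(fuse(a, b)), 1)

  d <- a; d$load[5] <- 2L
  e <- a; e$load[5] <- 2L
  expect_true(count_detrimental(fuse(d, e))$lethal)
  expect_false(count_detrimental(fuse(d, a))$lethal)
})

test_that("initial populations match the configured frequencies", {
  set.seed(31)
  p <- fast_params(K_plants = 10000L, K_herbivores = 50L,
                   init_freq_resistance = 0)
  pops <- init_population(p)
  expect_true(all(investment(pops$plants, "resistance") == 0))
  expect_equal(pop_size_plants <- nrow(pops$plants$res), 10000L)

  p$init_freq_resistance <- 0.5
  pops <- init_population(p)
  N <- 10000
  # mean allele frequency over 4N slots: 3 sigma binomial band
  expect_lt(abs(mean(investment(pops$plants, "resistance")) - 0.5),
            3 * sqrt(0.25 / (4 * N)))
  # expected initial heterozygosity 2pq = 0.5 at p = 0.5
  expect_lt(abs(mean(heterozygosity(pops$plants)) - 0.5), 0.01)
  # no detrimental alleles at the start
  expect_equal(sum(count_detrimental(pops$plants)$count), 0L)
  # herbivore sexes alternate to an even split
  expect_equal(sum(pops$herbivores$female), 25L)
})
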