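test_that("persistence is the grand mean over generations and replicates", {
  expect_equal(persistence(fake_run(rep(0.5, 10)), "resistance"), 0.5)
  expect_equal(persistence(fake_run(c(0, 0.5, 1)), "resistance"), 0.5)
  two <- list(fake_run(rep(0.2, 8)), fake_run(rep(0.6, 8)))
  expect_equal(persistence(two, "resistance"), 0.4)
  # replicate order does not matter
  expect_equal(persistence(rev(two), "resistance"), 0.4)
  # bounded by the per-replicate means
  expect_gte(persistence(two, "resistance"), 0.2)
  expect_lte(persistence(two, "resistance"), 0.6)
  expect_error(persistence(two, "vigor"), "unknown trait")
})

test_that("extinct replicates are padded with their terminal frequency", {
  long <- fake_run(rep(0.0, 10))
  short <- fake_run(c(0.2, 0.4), status = "plant_extinction")
  # padded short series: 0.2, then 0.4 nine times -> mean 0.38
  expect_equal(persistence(list(long, short), "resistance"),
               mean(c(rep(0, 10), 0.2, rep(0.4, 9))))
})

test_that("selfing series follow the mating-system representation", {
  her <- fake_run(rep(0.8, 5), trait = "selfing", selfing_mode = "heritable")
  expect_equal(persistence(her, "selfing"), 0.8)
  non <- fake_run(rep(0.3, 5), trait = "selfing", selfing_mode = "non_heritable")
  expect_equal(persistence(non, "selfing"), 0.3)  # reads the selfer fraction
})

test_that("outcome classification applies final-window thresholds and flags", {
  runs <- list(fake_run(c(rep(0.5, 90), rep(1, 10)), trait = "tolerance"))
  cls <- classify_outcome(runs)
  tol <- cls$traits[cls$traits$trait == "tolerance", ]
  expect_equal(tol$state, "fixed")

  # resistance 0.25 and tolerance 0.6 in the final window: mixed defense
  r <- fake_run(rep(0.25, 20), trait = "resistance")
  r$records$freq_tolerance <- 0.6
  cls <- classify_outcome(r)
  st <- setNames(cls$traits$state, cls$traits$trait)
  expect_equal(unname(st[c("resistance", "tolerance")]),
               c("polymorphic", "polymorphic"))
  expect_true(cls$mixed_defense)

  # everything lost: no flags, and fixed/lost are mutually exclusive
  alllost <- fake_run(rep(0.01, 20))
  alllost$records$freq_tolerance <- 0.01
  alllost$records$freq_selfing <- 0.01
  alllost$records$freq_antiresistance <- 0.01
  cls <- classify_outcome(alllost)
  expect_true(all(cls$traits$state == "lost"))
  expect_false(cls$mixed_defense)
  expect_false(cls$mixed_mating)

  poly <- fake_run(rep(0.5, 20), trait = "selfing")
  expect_true(classify_outcome(poly)$mixed_mating)
})

test_that("run CSVs round-trip the records, parameters and status", {
  dir <- withr::local_tempdir()
  p <- fast_params(generations = 10L, model = "additive", c_t = 0.35)
  sim <- run_simulation(p, seed = 91)
  f <- file.path(dir, "run.csv")
  write_run_csv(sim, f)
  back <- read_run_csv(f)
  expect_equal(back$records, sim$records)
  expect_equal(back$params$c_t, 0.35)
  expect_equal(back$params$model, "additive")
  expect_equal(back$seed, sim$seed)
  expect_equal(back$status, sim$status)
  # header row plus one data row per generation including generation 0
  expect_equal(sum(!grepl("^#", readLines(f))), 12L)
})

test_that("replicate groups summarize to one row per trait", {
  p <- fast_params(generations = 12L)
  runs <- lapply(1:2, function(j) run_simulation(p, seed = 900 + j))
  tab <- summarize_runs(runs)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$trait,
                  c("resistance", "tolerance", "selfing", "antiresistance"))
  expect_true(all(tab$persistence >= 0 & tab$persistence <= 1))

  dir <- withr::local_tempdir()
  files <- write_outputs(runs, dir)
  expect_true(all(file.exists(files)))
  expect_true(file.exists(file.path(dir, "summary.csv")))
})

test_that("sweep directories summarize to one row per cell and trait", {
  dir <- withr::local_tempdir()
  p <- fast_params(generations = 8L)
  grid <- expand.grid(c_t = c(0.2, 0.8), model = c("multiplicative", "additive"),
                      stringsAsFactors = FALSE)
  run_sweep(grid, p, reps = 2, out_dir = dir)
  out <- file.path(dir, "summary.csv")
  res <- summarize_sweep(dir, out)
  expect_equal(nrow(res), 4 * 4)  # 4 cells x 4 traits
  expect_true(file.exists(out))
  expect_setequal(unique(res$c_t), c(0.2, 0.8))
})
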