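# Per-generation loop, replicates, and factorial sweeps.

.record_cols <- c(
  "generation", "freq_resistance", "freq_tolerance", "freq_selfing",
  "freq_antiresistance", "selfer_fraction", "mean_het", "mean_load",
  "n_plants", "n_herbivores", "mean_fitness", "attack_rate"
)

.make_record <- function(gen, plants, herbivores, Fp, fed) {
  N <- pop_size(plants)
  Nh <- pop_size(herbivores)
  c(
    generation = gen,
    freq_resistance = sum(plants$res) / (4 * N),
    freq_tolerance = sum(plants$tol) / (4 * N),
    freq_selfing = sum(plants$selfg) / (4 * N),
    freq_antiresistance = if (Nh > 0) sum(herbivores$anti) / (4 * Nh) else NA_real_,
    selfer_fraction = mean(plants$selfer),
    mean_het = mean(heterozygosity(plants)),
    mean_load = mean(count_detrimental(plants)$count),
    n_plants = N,
    n_herbivores = Nh,
    mean_fitness = mean(Fp),
    attack_rate = if (Nh > 0) mean(fed) else NA_real_
  )
}

#' Run one simulation
#'
#' Executes the per-generation loop: resolve herbivore attacks, compute
#' plant fitness and seed numbers, build the next plant generation (with
#' lethal culling and capacity regulation), build the next herbivore
#' generation, and append a per-generation record. Damage is computed before
#' reproduction, so tolerance benefits are inducible within the same
#' generation. Herbivore extinction does not halt the run (plants continue
#' without damage); plant extinction does.
#'
#' @param p A `defmate_params`.
#' @param seed RNG seed for this run (defaults to `p$seed`). Two runs with
#'   identical parameters and seed produce identical results.
#' @return An object of class `defense_sim`: a list with `params`, `seed`,
#'   `records` (data.frame, one row per generation starting at generation 0)
#'   and `status` (one of `"completed"`, `"plant_extinction"`,
#'   `"herbivore_extinction_continued"`).
#' @seealso [run_sweep()], [persistence()], [classify_outcome()]
#' @export
#' @examples
#' p <- default_params()
#' p$K_plants <- 60L; p$K_herbivores <- 60L; p$generations <- 20L
#' sim <- run_simulation(p, seed = 7)
#' summary(sim)
run_simulation <- function(p, seed = p$seed) {
  p <- validate_params(p)
  set.seed(seed)
  pops <- init_population(p)
  plants <- pops$plants
  herbivores <- pops$herbivores
  G <- p$generations
  rec <- matrix(NA_real_, nrow = G + 1L, ncol = length(.record_cols),
                dimnames = list(NULL, .record_cols))
  status <- "completed"
  herb_gone <- pop_size(herbivores) == 0
  nrec <- 0L
  for (gen in 0:G) {
    atk <- resolve_attacks(plants, herbivores)
    Fp <- plant_fitness(plants, atk$damage, p)
    nrec <- nrec + 1L
    rec[nrec, ] <- .make_record(gen, plants, herbivores, Fp, atk$fed)
    if (gen == G) break
    nx <- next_plant_generation(plants, atk$damage, p, fitness = Fp)
    if (nx$extinct) {
      status <- "plant_extinction"
      break
    }
    if (pop_size(herbivores) > 0) {
      Fh <- herbivore_fitness_factor(p, investment(herbivores, "antiresistance"),
                                     atk$fed)
      herbivores <- next_herbivore_generation(herbivores, p, fitness = Fh)
      if (pop_size(herbivores) == 0) herb_gone <- TRUE
    }
    plants <- nx$plants
  }
  if (status == "completed" && herb_gone && p$K_herbivores > 0) {
    status <- "herbivore_extinction_continued"
  }
  records <- as.data.frame(rec[seq_len(nrec), , drop = FALSE])
  structure(list(params = p, seed = as.integer(seed), records = records,
                 status = status),
            class = "defense_sim")
}

#' Run a factorial parameter sweep
#'
#' Runs every row of `grid` (a data.frame whose columns are parameter names
#' overriding `p`) for `reps` replicates each, with a derived seed per
#' (cell, replicate) from [replicate_seed()]. Results are written to disk as
#' they complete (one CSV per run, see [write_run_csv()]); an interrupted
#' sweep rerun with the same arguments completes only the missing cells.
#'
#' @param grid data.frame of parameter overrides, one row per cell. Use
#'   `expand.grid()` for Cartesian products.
#' @param p Base parameters.
#' @param reps Number of replicates per cell (default `p$replicates`).
#' @param out_dir Output directory (created if needed).
#' @param overwrite Re-run cells whose output files already exist.
#' @param quiet Suppress per-run progress messages on standard error.
#' @return Invisibly, a data.frame indexing the produced files: cell,
#'   replicate, seed, file, status, plus the grid columns.
#' @export
run_sweep <- function(grid, p = default_params(), reps = p$replicates,
                      out_dir, overwrite = FALSE, quiet = TRUE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- p
    for (col in names(grid)) cell[[col]] <- grid[[col]][i]
    cell <- validate_params(cell)
    for (j in seq_len(reps)) {
      file <- file.path(out_dir, sprintf("run_cell%03d_rep%02d.csv", i, j))
      seed <- replicate_seed(p$seed, j, cell = i)
      status <- NA_character_
      if (overwrite || !file.exists(file)) {
        res <- tryCatch(run_simulation(cell, seed = seed), error = identity)
        if (inherits(res, "error")) {
          message(sprintf("sweep cell %d rep %d failed: %s", i, j,
                          conditionMessage(res)))
          next
        }
        write_run_csv(res, file)
        status <- res$status
        if (!quiet) {
          message(sprintf("cell %d rep %d -> %s (%s)", i, j, file, status))
        }
      } else {
        status <- "skipped_existing"
      }
      idx[[length(idx) + 1L]] <- cbind(
        data.frame(cell = i, replicate = j, seed = seed, file = file,
                   status = status, stringsAsFactors = FALSE),
        grid[i, , drop = FALSE], row.names = NULL)
    }
  }
  invisible(do.call(rbind, idx))
}

#' @export
print.defense_sim <- function(x, ...) {
  r <- x$records
  n <- nrow(r)
  cat(sprintf("defense_sim: %d generation(s), status '%s', seed %d\n",
              n - 1L, x$status, x$seed))
  cat(sprintf("  model %s, selfing %s, l = %g\n",
              x$params$model, x$params$selfing_mode, x$params$l))
  last <- r[n, ]
  cat(sprintf("  final: resistance %.3f, tolerance %.3f, selfing %.3f, selfer fraction %.3f\n",
              last$freq_resistance, last$freq_tolerance, last$freq_selfing,
              last$selfer_fraction))
  cat(sprintf("  final: mean het %.3f, mean load %.2f, %d plants, %d herbivores\n",
              last$mean_het, last$mean_load, last$n_plants, last$n_herbivores))
  invisible(x)
}

#' Summarize a simulation run
#'
#' Reports whole-run (persistence-style) and final-window means of the
#' tracked frequencies plus population sizes and status.
#'
#' @param object A `defense_sim`.
#' @param window Final-window fraction for the "final" means (default 0.1).
#' @param ... Unused.
#' @export
summary.defense_sim <- function(object, window = 0.1, ...) {
  r <- object$records
  n <- nrow(r)
  fw <- max(1L, ceiling(n * window))
  fin <- r[(n - fw + 1L):n, , drop = FALSE]
  traits <- c("freq_resistance", "freq_tolerance", "freq_selfing",
              "freq_antiresistance", "selfer_fraction", "mean_het", "mean_load")
  out <- data.frame(
    quantity = traits,
    overall_mean = vapply(traits, function(tr) mean(r[[tr]], na.rm = TRUE), 0),
    final_window_mean = vapply(traits, function(tr) mean(fin[[tr]], na.rm = TRUE), 0),
    row.names = NULL
  )
  structure(list(table = out, status = object$status,
                 generations = n - 1L, seed = object$seed),
            class = "summary.defense_sim")
}

#' @export
print.summary.defense_sim <- function(x, ...) {
  cat(sprintf("defense_sim summary: %d generations, status '%s', seed %d\n",
              x$generations, x$status, x$seed))
  tbl <- x$table
  tbl$overall_mean <- round(tbl$overall_mean, 4)
  tbl$final_window_mean <- round(tbl$final_window_mean, 4)
  print(tbl, row.names = FALSE)
  invisible(x)
}

#' Plot allele-frequency trajectories of a run
#'
#' Draws the resistance, tolerance, selfing (allele frequency or selfer
#' fraction, depending on the selfing mode) and herbivore anti-resistance
#' trajectories over generations.
#'
#' @param x A `defense_sim`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.defense_sim <- function(x, ...) {
  r <- x$records
  selfing <- if (x$params$selfing_mode == "non_heritable") {
    r$selfer_fraction
  } else {
    r$freq_selfing
  }
  y <- cbind(resistance = r$freq_resistance, tolerance = r$freq_tolerance,
             selfing = selfing, `anti-resistance` = r$freq_antiresistance)
  graphics::matplot(r$generation, y, type = "l", lty = 1,
                    col = c("forestgreen", "steelblue", "purple", "firebrick"),
                    xlab = "generation", ylab = "frequency", ylim = c(0, 1), ...)
  graphics::legend("topright", colnames(y), lty = 1, bty = "n",
                   col = c("forestgreen", "steelblue", "purple", "firebrick"))
  invisible(x)
}

#' @export
as.data.frame.defense_sim <- function(x, ...) x$records
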