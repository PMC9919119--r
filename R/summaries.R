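# Persistence statistic, outcome classification, and tidy CSV output.

.trait_column <- function(run, trait) {
  switch(trait,
    resistance = "freq_resistance",
    tolerance = "freq_tolerance",
    selfing = if (!is.null(run$params) && run$params$selfing_mode == "non_heritable")
      "selfer_fraction" else "freq_selfing",
    antiresistance = "freq_antiresistance",
    stop("unknown trait: ", trait)
  )
}

# per-replicate series, padded with the terminal value to a common length
.trait_series <- function(runs, trait, pad_to = NULL) {
  series <- lapply(runs, function(run) {
    run$records[[.trait_column(run, trait)]]
  })
  len <- if (is.null(pad_to)) max(vapply(series, length, 0L)) else pad_to
  lapply(series, function(s) {
    if (length(s) < len) c(s, rep(s[length(s)], len - length(s))) else s
  })
}

#' Persistence of a trait across replicates
#'
#' The persistence of a trait allele is its frequency averaged over all
#' simulated generations and all replicates (grand mean). Extinct replicates
#' are padded with their terminal frequency to the length of the longest
#' series so cells remain comparable.
#'
#' @param runs A `defense_sim` or list of replicate `defense_sim` objects.
#' @param trait One of `"resistance"`, `"tolerance"`, `"selfing"`,
#'   `"antiresistance"`. For non-heritable selfing runs, `"selfing"` reads
#'   the selfer fraction; otherwise the selfing allele frequency.
#' @return Persistence in \[0, 1\].
#' @export
persistence <- function(runs, trait) {
  if (inherits(runs, "defense_sim")) runs <- list(runs)
  series <- .trait_series(runs, trait)
  mean(unlist(series), na.rm = TRUE)
}

#' Classify the outcome of a set of replicate runs
#'
#' Applies final-window mean thresholds per trait: `fixed` when the mean
#' frequency over the last `window` fraction of generations (pooled over
#' replicates) exceeds the upper threshold, `lost` below the lower one,
#' `polymorphic` otherwise. Derived flags: `mixed_defense` when resistance
#' and tolerance are both still present (not lost), and `mixed_mating` when
#' selfing is polymorphic.
#'
#' @param runs A `defense_sim` or list of replicate runs.
#' @param thresholds Length-2 numeric: `c(fixed, lost)` thresholds
#'   (default 0.95 and 0.05).
#' @param window Final-window fraction of generations (default 0.1).
#' @return A list with `traits` (data.frame: trait, final_mean, state),
#'   `mixed_defense` and `mixed_mating`.
#' @export
classify_outcome <- function(runs, thresholds = c(fixed = 0.95, lost = 0.05),
                             window = 0.1) {
  if (inherits(runs, "defense_sim")) runs <- list(runs)
  traits <- c("resistance", "tolerance", "selfing", "antiresistance")
  final_mean <- vapply(traits, function(tr) {
    series <- .trait_series(runs, tr)
    vals <- unlist(lapply(series, function(s) {
      fw <- max(1L, ceiling(length(s) * window))
      s[(length(s) - fw + 1L):length(s)]
    }))
    mean(vals, na.rm = TRUE)
  }, 0)
  final_mean <- unname(final_mean)
  state <- ifelse(is.na(final_mean), NA_character_,
           ifelse(final_mean > thresholds[[1]], "fixed",
           ifelse(final_mean < thresholds[[2]], "lost", "polymorphic")))
  tab <- data.frame(trait = traits, final_mean = final_mean, state = state,
                    row.names = NULL)
  present <- function(tr) !is.na(state[traits == tr]) && state[traits == tr] != "lost"
  list(
    traits = tab,
    mixed_defense = present("resistance") && present("tolerance"),
    mixed_mating = identical(state[traits == "selfing"], "polymorphic")
  )
}

#' Write one run to CSV
#'
#' One row per generation (including generation 0), columns the
#' per-generation record fields, preceded by `#`-prefixed header lines
#' carrying the parameter echo, the seed and the termination status.
#' [read_run_csv()] reproduces the in-memory object exactly.
#'
#' @param run A `defense_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.character(v)) return(v)
    format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }
  for (k in names(run$params)) {
    writeLines(sprintf("# %s = %s", k, fmt(run$params[[k]])), con)
  }
  writeLines(sprintf("# seed = %d", run$seed), con)
  writeLines(sprintf("# status = %s", run$status), con)
  utils::write.csv(run$records, con, row.names = FALSE)
  invisible(path)
}

#' Read a run CSV back into a `defense_sim`
#'
#' @param path Path written by [write_run_csv()].
#' @return A `defense_sim` object.
#' @export
read_run_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  meta <- sub("^#\\s*", "", lines[hdr])
  kv <- strsplit(meta, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  p <- default_params()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% c("seed_run", "status")) next
    if (k %in% names(p)) {
      proto <- p[[k]]
      p[[k]] <- if (is.logical(proto)) vals[i] == "true"
        else if (is.character(proto)) vals[i]
        else as.numeric(vals[i])
    }
  }
  seed <- as.integer(vals[keys == "seed"][length(vals[keys == "seed"])])
  status <- vals[keys == "status"][1]
  records <- utils::read.csv(textConnection(lines[-hdr]))
  structure(list(params = validate_params(p), seed = seed,
                 records = records, status = status),
            class = "defense_sim")
}

#' Summarize replicate groups of runs into a tidy table
#'
#' One row per trait: the persistence over the runs, the final-window state
#' from [classify_outcome()], and the derived mixed-strategy flags.
#'
#' @param runs A `defense_sim` or list of replicate runs.
#' @param thresholds,window Passed to [classify_outcome()].
#' @return data.frame with columns trait, persistence, state,
#'   mixed_defense, mixed_mating.
#' @export
summarize_runs <- function(runs, thresholds = c(fixed = 0.95, lost = 0.05),
                           window = 0.1) {
  if (inherits(runs, "defense_sim")) runs <- list(runs)
  cls <- classify_outcome(runs, thresholds, window)
  traits <- cls$traits$trait
  data.frame(
    trait = traits,
    persistence = vapply(traits, function(tr) persistence(runs, tr), 0),
    state = cls$traits$state,
    mixed_defense = cls$mixed_defense,
    mixed_mating = cls$mixed_mating,
    row.names = NULL
  )
}

#' Write per-run and summary CSVs for a set of runs
#'
#' Writes each run with [write_run_csv()] (files `run_01.csv`, ...) plus a
#' `summary.csv` with one row per trait from [summarize_runs()].
#'
#' @param runs A `defense_sim` or list of runs (replicates of one cell).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(runs, out_dir) {
  if (inherits(runs, "defense_sim")) runs <- list(runs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(runs)) {
    f <- file.path(out_dir, sprintf("run_%02d.csv", i))
    write_run_csv(runs[[i]], f)
    files <- c(files, f)
  }
  sf <- file.path(out_dir, "summary.csv")
  utils::write.csv(summarize_runs(runs), sf, row.names = FALSE)
  invisible(c(files, sf))
}

#' Summarize a sweep output directory
#'
#' Reads the per-run CSVs written by [run_sweep()], groups them by sweep
#' cell, and writes a tidy summary CSV with one row per cell and trait
#' (parameters echoed, persistence, outcome state, mixed-strategy flags).
#'
#' @param in_dir Directory of `run_cellXXX_repYY.csv` files.
#' @param out_file Output CSV path.
#' @return Invisibly, the summary data.frame.
#' @export
summarize_sweep <- function(in_dir, out_file) {
  files <- list.files(in_dir, pattern = "^run_cell\\d+_rep\\d+\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no run files found in ", in_dir)
  cells <- sub("^run_(cell\\d+)_rep\\d+\\.csv$", "\\1", basename(files))
  out <- list()
  for (cell in unique(cells)) {
    runs <- lapply(files[cells == cell], read_run_csv)
    tab <- summarize_runs(runs)
    p <- runs[[1]]$params
    tab <- cbind(data.frame(cell = cell, model = p$model,
                            selfing_mode = p$selfing_mode, c_r = p$c_r,
                            c_t = p$c_t, b_t = p$b_t, l = p$l,
                            stringsAsFactors = FALSE),
                 tab)
    out[[cell]] <- tab
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  utils::write.csv(res, out_file, row.names = FALSE)
  invisible(res)
}
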