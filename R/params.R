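#' Default simulation parameters
#'
#' Returns the full parameter set of the model with its default values: the
#' fitness-equation constants (base fitness, cost/benefit maxima, the
#' overdominance shape `k` and reference heterozygosity `H`, the per-allele
#' selection coefficient `s` and the non-linearity exponent `l`) plus the
#' structural parameters of a run (population sizes, genome size, mutation
#' rate, run length, replicate count, initial allele frequencies, herbivore
#' demography and the RNG seed).
#'
#' The per-allele load-genome mutation rate `mu` defaults to 0.00245 so that
#' the diploid genomic rate is U = 2 * 100 * mu = 0.49, the value at which the
#' selfing-regime mutation-load equilibrium sits at ~0.49 alleles per
#' individual and the outcrossing equilibrium at 2 * 100 * sqrt(mu) ~ 9.9
#' (see [load_equilibrium()]).
#'
#' @return An object of class `defmate_params`: a named list of parameters.
#' @seealso [load_config()], [validate_params()], [write_config()]
#' @export
#' @examples
#' p <- default_params()
#' p$c_r   # maximum resistance cost
#' 2 * p$n_genome_genes * p$mu   # diploid genomic mutation rate U
default_params <- function() {
  p <- list(
    # fitness-equation constants
    w0  = 25.0,   # base fitness: expected seeds of an unimpaired plant
    c_r = 0.15,   # maximum cost of resistance (proportion)
    c_t = 0.4,    # maximum cost of tolerance (proportion)
    c_h = 0.75,   # maximum cost of herbivory (proportion)
    b_t = 0.25,   # maximum benefit of tolerance (proportion)
    c_a = 0.4,    # maximum anti-resistance cost in herbivores (proportion)
    k   = 0.3,    # overdominance shape parameter
    H   = 0.25,   # reference population heterozygosity (constant)
    s   = 0.005,  # selection coefficient per detrimental allele
    l   = 1.0,    # linearity/shape exponent, allowed range [0.2, 5]
    model = "multiplicative",
    selfing_mode = "none",
    o2_sign_verbatim = FALSE,
    # structural parameters
    mu = 0.00245,            # per-allele load mutation rate per generation
    n_genome_genes = 100L,   # load-genome size
    K_plants = 500L,
    K_herbivores = 500L,
    generations = 15000L,
    replicates = 3L,
    init_freq_resistance = 0.5,
    init_freq_tolerance = 0.5,
    init_freq_selfing = 0.5,
    init_freq_antiresistance = 0.5,
    init_selfer_fraction = 0.5,
    init_genome_het = 0.5,   # initial frequency of the B neutral class
    herbivore_base_fecundity = 25.0,
    herbivore_failure_cost = 0.75,
    seed = 1L
  )
  class(p) <- "defmate_params"
  p
}

.defmate_models <- c("multiplicative", "additive")
.defmate_selfing_modes <- c("heritable", "non_heritable", "none")

# fields constrained to [0,1]
.defmate_prop_fields <- c(
  "c_r", "c_t", "c_h", "b_t", "c_a", "k", "H", "s", "mu",
  "init_freq_resistance", "init_freq_tolerance", "init_freq_selfing",
  "init_freq_antiresistance", "init_selfer_fraction", "init_genome_het",
  "herbivore_failure_cost"
)

#' Validate a parameter set
#'
#' Checks every model invariant (proportions in \[0,1\], `l` in \[0.2, 5\],
#' positive base fitness, plant carrying capacity of at least 2, valid
#' enumeration members) and returns the parameters unchanged if all hold.
#' All violations are reported together, each naming the offending key.
#'
#' @param p A `defmate_params` object or plain named list of parameters.
#' @return `p`, invisibly unchanged, with class `defmate_params`.
#' @export
validate_params <- function(p) {
  defaults <- default_params()
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  full <- defaults
  full[names(p)] <- p
  p <- full
  class(p) <- "defmate_params"

  errs <- character(0)
  bad <- function(msg) errs <<- c(errs, msg)

  for (f in .defmate_prop_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad(sprintf("%s must be a proportion in [0, 1] (got %s)", f,
                  paste(format(v), collapse = ",")))
    }
  }
  if (!is.numeric(p$l) || p$l < 0.2 || p$l > 5.0) {
    bad(sprintf("l must lie in [0.2, 5.0] (got %s)", format(p$l)))
  }
  if (!is.numeric(p$w0) || p$w0 <= 0) bad("w0 must be > 0")
  if (!is.numeric(p$herbivore_base_fecundity) || p$herbivore_base_fecundity < 0) {
    bad("herbivore_base_fecundity must be >= 0")
  }
  if (!is.numeric(p$K_plants) || p$K_plants < 2) {
    bad(sprintf("K_plants must be >= 2 (got %s)", format(p$K_plants)))
  }
  if (!is.numeric(p$K_herbivores) || p$K_herbivores < 0) {
    bad("K_herbivores must be >= 0 (use 0 to disable herbivory)")
  }
  if (!is.numeric(p$n_genome_genes) || p$n_genome_genes < 1) {
    bad("n_genome_genes must be >= 1")
  }
  if (!is.numeric(p$generations) || p$generations < 0) {
    bad("generations must be >= 0")
  }
  if (!is.numeric(p$replicates) || p$replicates < 1) {
    bad("replicates must be >= 1")
  }
  if (!is.character(p$model) || !(p$model %in% .defmate_models)) {
    bad(sprintf("model must be one of {%s} (got %s)",
                paste(.defmate_models, collapse = ", "), format(p$model)))
  }
  if (!is.character(p$selfing_mode) || !(p$selfing_mode %in% .defmate_selfing_modes)) {
    bad(sprintf("selfing_mode must be one of {%s} (got %s)",
                paste(.defmate_selfing_modes, collapse = ", "),
                format(p$selfing_mode)))
  }
  if (!is.logical(p$o2_sign_verbatim) || length(p$o2_sign_verbatim) != 1) {
    bad("o2_sign_verbatim must be TRUE or FALSE")
  }
  if (!is.numeric(p$seed) || length(p$seed) != 1 || is.na(p$seed)) {
    bad("seed must be a single integer")
  }
  if (length(errs) > 0) {
    stop("invalid parameters:\n  - ", paste(errs, collapse = "\n  - "))
  }
  for (f in c("n_genome_genes", "K_plants", "K_herbivores", "generations",
              "replicates", "seed")) {
    p[[f]] <- as.integer(p[[f]])
  }
  p
}

#' Load parameters from a plain-text configuration file
#'
#' Reads a section-less `key = value` configuration file (lower-case
#' snake-case keys, `#` comments, booleans as `true`/`false`). Keys not
#' present in the file keep their defaults; unknown keys are rejected. The
#' result is validated before being returned, so every error names the
#' offending key.
#'
#' @param path Path to the configuration file.
#' @return A validated `defmate_params` object.
#' @seealso [write_config()] for the inverse; the two round-trip exactly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- default_params()
  defaults <- p
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("cannot parse config line (expected 'key = value'): ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    if (!(key %in% names(defaults))) stop("unknown configuration key: ", key)
    proto <- defaults[[key]]
    parsed <- if (is.logical(proto)) {
      if (!tolower(val) %in% c("true", "false")) {
        stop("key ", key, " expects true/false, got: ", val)
      }
      tolower(val) == "true"
    } else if (is.character(proto)) {
      val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("key ", key, " expects a number, got: ", val)
      num
    }
    p[[key]] <- parsed
  }
  validate_params(p)
}

#' Write parameters to a configuration file
#'
#' Emits every parameter as a `key = value` line in the same dialect that
#' [load_config()] reads, so that a written file reloads to an identical
#' parameter set.
#'
#' @param p A `defmate_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  p <- validate_params(p)
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.character(v)) return(v)
    format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }
  lines <- vapply(names(p), function(k) paste(k, "=", fmt(p[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' Derive the RNG seed of one replicate
#'
#' Documented splitting rule for replicate streams: each replicate of a run
#' (and each cell of a sweep) gets its own seed derived deterministically
#' from the base seed, kept below 2^31 - 1.
#'
#' @param seed Base integer seed.
#' @param replicate Replicate index (1-based).
#' @param cell Optional sweep-cell index (1-based), default 0 for single runs.
#' @return A single integer seed.
#' @export
replicate_seed <- function(seed, replicate, cell = 0L) {
  base <- abs(as.numeric(seed)) %% 1e6
  as.integer((base * 1013 + cell * 8191 + replicate * 127) %% 2147483647)
}

#' @export
print.defmate_params <- function(x, ...) {
  cat("Model parameters (defmate)\n")
  cat(sprintf("  model: %s | selfing: %s | l = %g\n", x$model, x$selfing_mode, x$l))
  cat(sprintf("  w0 = %g, c_r = %g, c_t = %g, c_h = %g, b_t = %g, c_a = %g\n",
              x$w0, x$c_r, x$c_t, x$c_h, x$b_t, x$c_a))
  cat(sprintf("  inbreeding: k = %g, H = %g, s = %g, mu = %g (U = %g over %d genes)\n",
              x$k, x$H, x$s, x$mu, 2 * x$n_genome_genes * x$mu, x$n_genome_genes))
  cat(sprintf("  populations: %d plants, %d herbivores; %d generations x %d replicates; seed %d\n",
              x$K_plants, x$K_herbivores, x$generations, x$replicates, x$seed))
  invisible(x)
}
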