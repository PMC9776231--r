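# Conformer-population estimation from per-conformation energies.
#
# Each conformer (one structural model of the system) is represented by the
# conformational energies of its saved snapshots. Populations follow from a
# Metropolis Monte Carlo walk over the pooled conformations: the fraction of
# steps spent in each conformer estimates its equilibrium probability. An
# exact Boltzmann-weighted oracle over all conformations is provided for
# cross-checking, along with relative free energies of the conformers.

#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041

#' Bundle per-conformation energies by conformer
#'
#' @param x a named list of numeric vectors (one per conformer, energies in
#'   kcal/mol), or a data.frame with columns `conformer` and `energy`.
#' @return named list of class `conformer_energy_set`.
#' @export
conformer_energy_set <- function(x) {
  if (is.data.frame(x)) {
    cols <- names(x)
    ec <- intersect(c("energy", "energy_kcal_mol", "E"), cols)[1L]
    cc <- intersect(c("conformer", "conformer_label", "label"), cols)[1L]
    if (is.na(ec) || is.na(cc))
      stop("data.frame input needs columns 'conformer' and 'energy'")
    x <- split(as.numeric(x[[ec]]), as.character(x[[cc]]))
  }
  if (!is.list(x) || !length(x)) stop("need at least one conformer")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("conformers must be named")
  for (nm in names(x)) {
    e <- x[[nm]]
    if (!is.numeric(e) || !length(e))
      stop("conformer '", nm, "' has no energies")
    if (!all(is.finite(e)))
      stop("non-finite energy in conformer '", nm, "'")
    x[[nm]] <- as.numeric(e)
  }
  structure(x, class = "conformer_energy_set")
}

#' Read a conformer energy table
#'
#' Expects delimited text (comma or whitespace) with a header naming a
#' conformer-label column and an energy column in kcal/mol, e.g.
#' `conformer_label,energy_kcal_mol`.
#'
#' @param path path to the table.
#' @return a `conformer_energy_set`.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- sub("^conformer_label$", "conformer", names(df))
  names(df) <- sub("^energy_kcal_mol$", "energy", names(df))
  conformer_energy_set(df)
}

#' Monte Carlo walk configuration
#'
#' @param temperature absolute temperature in K (default 298).
#' @param steps number of Monte Carlo steps (default one million).
#' @param seed RNG seed.
#' @return list of class `population_config`.
#' @export
population_config <- function(temperature = 298, steps = 1e6, seed = 1L) {
  if (temperature <= 0) stop("temperature must be positive")
  if (steps < 1) stop("steps must be >= 1")
  structure(list(temperature = temperature, steps = as.double(steps),
                 seed = as.integer(seed)), class = "population_config")
}

#' Conformer populations by Metropolis Monte Carlo
#'
#' Runs a random walk over the pooled conformations: starting from a
#' uniformly random conformation, each step proposes a uniformly random
#' conformation of a uniformly random other conformer and accepts the move
#' when the Boltzmann factor `exp(-(E_j - E_i)/kT)` exceeds a uniform(0,1)
#' draw (factors above 1 are always accepted). The conformer occupied after
#' each step is counted, so the visit counts sum to the number of steps and
#' `P_n = N_n / N_total`. Standard errors come from batch means (10 batches),
#' appropriate for the autocorrelated chain. The walk is deterministic for a
#' given seed.
#'
#' Note that the other-conformer proposal is symmetric when all conformers
#' carry equal numbers of conformations (the usual design, e.g. 500 saved
#' conformations for each of seven conformers); only then is the walk's
#' stationary distribution the Boltzmann measure that
#' [exact_populations()] integrates.
#'
#' @param energies a `conformer_energy_set` (or coercible input).
#' @param config a `population_config`.
#' @return list of class `population_estimate` with elements `conformer`,
#'   `visits`, `n_total`, `probability`, `stderr`, `temperature`.
#' @export
mc_populations <- function(energies, config = population_config()) {
  energies <- conformer_energy_set(energies)
  stopifnot(inherits(config, "population_config"))
  labels <- names(energies)
  k <- length(labels)
  if (k == 1L) {
    message("single conformer: population is 1 by definition")
    return(structure(list(conformer = labels, visits = config$steps,
                          n_total = config$steps, probability = 1,
                          stderr = 0, temperature = config$temperature),
                     class = "population_estimate"))
  }
  counts <- vapply(energies, length, 0L)
  offsets <- c(0L, cumsum(counts))[seq_len(k)]
  energy <- unlist(energies, use.names = FALSE)
  inv_kt <- 1 / (KB_KCAL * config$temperature)
  n_batches <- 10L
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  batches <- mc_walk_cpp(energy, offsets, counts, config$steps, inv_kt,
                         n_batches)
  visits <- colSums(batches)
  n_total <- sum(visits)
  prob <- visits / n_total
  batch_p <- sweep(batches, 1L, rowSums(batches), `/`)
  se <- apply(batch_p, 2L, stats::sd) / sqrt(n_batches)
  structure(list(conformer = labels, visits = as.numeric(visits),
                 n_total = n_total, probability = as.numeric(prob),
                 stderr = as.numeric(se), temperature = config$temperature),
            class = "population_estimate")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("Conformer populations (T =", x$temperature, "K, N_total =",
      format(x$n_total, big.mark = ","), "steps)\n")
  df <- data.frame(conformer = x$conformer, N_n = x$visits,
                   P_n = round(x$probability, 4),
                   stderr = signif(x$stderr, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Exact Boltzmann populations of conformers
#'
#' The stationary target of the Monte Carlo walk for equal-count conformer
#' sets, integrated exactly: each conformation receives weight
#' `exp(-(E - E_min)/kT)` (energies shifted by the minimum so the sums cannot
#' overflow), and a conformer's population is its share of the total weight.
#'
#' @param energies a `conformer_energy_set` (or coercible input).
#' @param temperature absolute temperature in K (default 298).
#' @return named numeric vector of probabilities summing to 1.
#' @export
exact_populations <- function(energies, temperature = 298) {
  energies <- conformer_energy_set(energies)
  if (temperature <= 0) stop("temperature must be positive")
  kt <- KB_KCAL * temperature
  emin <- min(unlist(energies, use.names = FALSE))
  w <- vapply(energies, function(e) sum(exp(-(e - emin) / kt)), 0)
  w / sum(w)
}

#' Relative free energies of conformers from their populations
#'
#' `dG_n = -kT log(P_n / P_max)`, so the most populated conformer sits at
#' zero and all others are non-negative. Zero populations are reported as
#' `Inf` with attribute `unbounded` flagging them rather than an error.
#'
#' @param populations named numeric vector of probabilities (or a
#'   `population_estimate`).
#' @param temperature absolute temperature in K (default 298).
#' @return named numeric vector of free energies in kcal/mol, attribute
#'   `unbounded` marking conformers with zero population.
#' @export
relative_free_energies <- function(populations, temperature = 298) {
  if (inherits(populations, "population_estimate")) {
    p <- populations$probability
    names(p) <- populations$conformer
    populations <- p
  }
  if (any(populations < 0)) stop("populations must be non-negative")
  pmax_ <- max(populations)
  if (pmax_ <= 0) stop("all populations are zero")
  kt <- KB_KCAL * temperature
  dg <- -kt * log(populations / pmax_)
  attr(dg, "unbounded") <- populations == 0
  dg
}
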