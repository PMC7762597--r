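#' Simulation run configuration
#'
#' Collects every knob of a single simulation. Physical defaults are the
#' study conditions: N = 100 beads, channel width D = 3 and length L = 600,
#' contact energies eps(P1,P1) = -1 with everything else athermal, reduced
#' temperature T = 1, orientation dead band delta = 0.01, and an annealed
#' burn-in of 1e5 elementary attempts.
#'
#' Time is counted in elementary attempts t_E (one attempted
#' micromodification, accepted or not); one MC cycle is N attempts. The
#' default recording cadence of 1e3 t_E matches coarse trajectory records; a
#' cadence of 1 records every elementary step for fine (single-event)
#' analyses.
#'
#' @param N chain length (even).
#' @param D,L channel width and length (lattice units), see
#'   [channel_geometry].
#' @param energy an [energy_model].
#' @param n_equil burn-in length in elementary attempts, run under the
#'   hyperbolic annealing schedule (see [anneal_temperature]) and never
#'   recorded.
#' @param n_attempts production length in elementary attempts.
#' @param record_every observable recording cadence in t_E.
#' @param bead_every cadence for recording per-bead x positions (0 = off);
#'   needed for bead autocorrelation curves.
#' @param snapshot_every cadence for full 3D snapshots (0 = off).
#' @param record_thermo logical; compute entropy/energy/free-energy and
#'   gyration radii at each record? Turning it off speeds up long runs whose
#'   only purpose is displacement statistics.
#' @param delta dead band (lattice units) of the mutual orientation
#'   parameter M.
#' @param anneal_c,anneal_K hyperbolic annealing parameters; `anneal_K`
#'   defaults to `n_equil / 10`.
#' @param weight Metropolis acceptance weight: `"U"` uses the internal
#'   contact energy alone (canonical sampling of `exp(-U/T)`); `"A"` uses
#'   the Helmholtz free energy `A = U - T*S` with the phantom-chain SCM
#'   entropy (free-energy dynamics, stationary on `exp(-A/T)`). See the
#'   methods vignette for the choice between them.
#' @param seed optional RNG seed stored with the config.
#' @return An object of class `run_config`.
#' @export
run_config <- function(N = 100, D = 3, L = 600, energy = energy_model(),
                       n_equil = 1e5, n_attempts = 2e6, record_every = 1e3,
                       bead_every = 0, snapshot_every = 0,
                       record_thermo = TRUE, delta = 0.01,
                       anneal_c = 4, anneal_K = NULL, weight = c("U", "A"),
                       seed = NULL) {
  weight <- match.arg(weight)
  if (N < 2 || N %% 2 != 0)
    stop("N must be an even integer >= 2 (the chain has two equal halves)")
  geom <- channel_geometry(D, L)
  if (!inherits(energy, "energy_model")) stop("energy must be an energy_model")
  if (n_attempts < 1) stop("n_attempts must be >= 1")
  if (record_every < 1) stop("record_every must be >= 1")
  if (n_equil < 0) stop("n_equil must be >= 0")
  if (delta < 0) stop("delta must be >= 0")
  if (is.null(anneal_K)) anneal_K <- n_equil / 10
  structure(list(N = as.integer(N), geom = geom, energy = energy,
                 n_equil = n_equil, n_attempts = n_attempts,
                 record_every = record_every, bead_every = bead_every,
                 snapshot_every = snapshot_every,
                 record_thermo = record_thermo, delta = delta,
                 anneal_c = anneal_c, anneal_K = anneal_K, weight = weight,
                 seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("<run_config> N = %d, D = %d, L = %d, T = %g\n",
                     "  equilibration %g + production %g attempts, record every %g t_E\n"),
              x$N, x$geom$D, x$geom$L, x$energy$T,
              x$n_equil, x$n_attempts, x$record_every))
  invisible(x)
}

.config_keys <- c("N", "D", "L", "eps_P1P1", "eps_P2P2", "eps_P1P2",
                  "eps_PS", "eps_SS", "T", "n_equil", "n_attempts",
                  "record_every", "bead_every", "snapshot_every",
                  "record_thermo", "delta", "anneal_c", "anneal_K",
                  "weight", "seed", "analysis")

#' Read a run configuration from a YAML file
#'
#' An empty file (or empty mapping) yields the full default configuration.
#' Unknown keys are rejected with an error naming them. The optional
#' `analysis` mapping (e.g. autocorrelation lag grid, fit windows, histogram
#' bins) is passed through untouched in the `analysis` field of the result.
#'
#' @param path path to a YAML file.
#' @return A [run_config]; any analysis settings are attached as
#'   `$analysis`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  # quote bare mapping keys so YAML-1.1 boolean tokens like "N" stay keys
  txt <- sub("^(\\s*)([A-Za-z_][A-Za-z0-9_.]*)(\\s*):", "\\1\"\\2\"\\3:", txt)
  raw <- yaml::yaml.load(paste(txt, collapse = "\n"))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping")
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  grab <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  energy <- energy_model(eps_P1P1 = grab("eps_P1P1", -1),
                         eps_P2P2 = grab("eps_P2P2", 0),
                         eps_P1P2 = grab("eps_P1P2", 0),
                         eps_PS = grab("eps_PS", 0),
                         eps_SS = grab("eps_SS", 0),
                         T = grab("T", 1))
  cfg <- run_config(N = grab("N", 100), D = grab("D", 3), L = grab("L", 600),
                    energy = energy,
                    n_equil = grab("n_equil", 1e5),
                    n_attempts = grab("n_attempts", 2e6),
                    record_every = grab("record_every", 1e3),
                    bead_every = grab("bead_every", 0),
                    snapshot_every = grab("snapshot_every", 0),
                    record_thermo = grab("record_thermo", TRUE),
                    delta = grab("delta", 0.01),
                    anneal_c = grab("anneal_c", 4),
                    anneal_K = grab("anneal_K", NULL),
                    weight = grab("weight", "U"),
                    seed = grab("seed", NULL))
  cfg$analysis <- grab("analysis", list())
  cfg
}
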