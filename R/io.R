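# Observable tables are plain tab-delimited text with a fixed leading
# column order; snapshots use the XYZ convention with the element column
# carrying the block label.

.obs_required <- c("t_E", "x_cm", "x_P1", "x_P2", "Rg_P1", "Rg_P2",
                   "S", "U", "A", "M")

#' Write a trajectory observable table
#'
#' Tab-delimited with a header; the first ten columns are always
#' `t_E, x_cm, x_P1, x_P2, Rg_P1, Rg_P2, S, U, A, M`, any extra columns
#' follow. Values round-trip losslessly at 12+ significant digits.
#'
#' @param obs data frame of trajectory rows (an `mc_trajectory`'s `$obs`).
#' @param path output file.
#' @export
write_observables <- function(obs, path) {
  obs <- .obs_frame(obs)
  missing_cols <- setdiff(.obs_required, names(obs))
  if (length(missing_cols) > 0)
    stop("observable table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  obs <- obs[, c(.obs_required, setdiff(names(obs), .obs_required))]
  out <- as.data.frame(lapply(obs, function(col) {
    if (is.numeric(col)) format(col, digits = 15, trim = TRUE) else col
  }), stringsAsFactors = FALSE)
  names(out) <- names(obs)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory observable table
#'
#' Validates the schema: all required columns must be present (an error
#' names the first missing one) and M must be in \{-1, 0, 1\}.
#'
#' @param path file written by [write_observables].
#' @return data frame.
#' @export
read_observables <- function(path) {
  obs <- read.delim(path, check.names = FALSE)
  missing_cols <- setdiff(.obs_required, names(obs))
  if (length(missing_cols) > 0)
    stop("observable file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- obs$M[is.finite(obs$M)]
  if (any(!m %in% c(-1, 0, 1)))
    stop("column M must only contain -1, 0, or 1")
  obs
}

#' Write chain snapshots in XYZ format
#'
#' One record per frame: the bead count line, a comment line
#' `t_E=<n> D=<D> L=<L>`, then one line per bead with the block label as the
#' element column and the (unwrapped-x) integer coordinates.
#'
#' @param states list of [chain_state] objects, or an `mc_trajectory` run
#'   with `snapshot_every > 0`.
#' @param path output file.
#' @param geom a [channel_geometry] (taken from the trajectory config when
#'   one is supplied).
#' @param t_E time stamps, one per frame.
#' @param stride keep every `stride`-th frame.
#' @export
write_xyz <- function(states, path, geom = NULL, t_E = NULL, stride = 1) {
  if (inherits(states, "mc_trajectory")) {
    traj <- states
    geom <- traj$config$geom
    states <- snapshot_states(traj)
    t_E <- seq(0, by = traj$config$snapshot_every, length.out = length(states))
  }
  if (is.null(geom)) stop("geom is required")
  keep <- seq(1, length(states), by = stride)
  if (is.null(t_E)) t_E <- rep(NA, length(states))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in keep) {
    st <- states[[f]]
    writeLines(as.character(st$N), con)
    writeLines(sprintf("t_E=%s D=%d L=%d", format(t_E[f]), geom$D, geom$L),
               con)
    writeLines(sprintf("%s %d %d %d", st$labels, st$positions[, 1],
                       st$positions[, 2], st$positions[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ snapshot file
#'
#' @param path file written by [write_xyz].
#' @return list with `states` (list of [chain_state]), `t_E`, `D`, `L`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  states <- list()
  t_E <- numeric(0)
  D <- L <- NA_integer_
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed XYZ: expected a bead count at line ", i)
    meta <- lines[i + 1]
    m <- regmatches(meta, regexec("t_E=(\\S+) D=(\\d+) L=(\\d+)", meta))[[1]]
    if (length(m) == 4) {
      t_E <- c(t_E, suppressWarnings(as.numeric(m[2])))
      D <- as.integer(m[3]); L <- as.integer(m[4])
    } else t_E <- c(t_E, NA_real_)
    rows <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
    pos <- matrix(as.integer(parts[, 2:4]), ncol = 3)
    states[[length(states) + 1]] <- chain_state(pos)
    i <- i + 2 + n
  }
  list(states = states, t_E = t_E, D = D, L = L)
}
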