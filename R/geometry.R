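#' Nanochannel geometry
#'
#' Defines the simulation box: a simple cubic lattice channel of square cross
#' section. The two transverse axes (y, z) are confined between impenetrable
#' walls: allowed coordinates are the integers `1..D`, the walls being the
#' excluded planes `0` and `D+1`. The longitudinal axis x is periodic with
#' period `L`. All lengths are in lattice units (the lattice constant b is 1).
#'
#' Observables are always computed from unwrapped x coordinates; wrapping is
#' applied only for occupancy and contact tests.
#'
#' @param D integer, channel width: the number of allowed transverse lattice
#'   planes per confined axis (>= 1).
#' @param L integer, periodic channel length along x (>= 4).
#' @return An object of class `channel_geometry` with fields `D` and `L`.
#' @examples
#' geom <- channel_geometry(D = 3, L = 600)
#' @export
channel_geometry <- function(D = 3, L = 600) {
  if (length(D) != 1 || D < 1 || D != round(D))
    stop("channel width D must be a single integer >= 1")
  if (length(L) != 1 || L < 4 || L != round(L))
    stop("channel length L must be a single integer >= 4")
  structure(list(D = as.integer(D), L = as.integer(L)),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> width D = %d, length L = %d (periodic in x)\n",
              x$D, x$L))
  invisible(x)
}

#' Chain state
#'
#' An N-bead self-avoiding lattice chain. Positions are integer lattice sites
#' with x unwrapped (unbounded); block labels are a fixed function of the bead
#' index: the first half (`i <= N/2`) is P1, the rest P2. Labels never migrate
#' with moves.
#'
#' @param positions integer matrix with N rows and 3 columns (x, y, z).
#' @return An object of class `chain_state` with fields `positions`, `N`,
#'   and `labels` (character, "P1"/"P2").
#' @examples
#' st <- chain_state(cbind(0:3, 2L, 2L))
#' @export
chain_state <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns (x, y, z)")
  if (any(positions != round(positions))) stop("positions must be integers")
  storage.mode(positions) <- "integer"
  n <- nrow(positions)
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  labels <- ifelse(seq_len(n) <= n %/% 2, "P1", "P2")
  structure(list(positions = positions, N = n, labels = labels),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("<chain_state> N = %d beads (%d P1 + %d P2), x span [%d, %d]\n",
              x$N, sum(x$labels == "P1"), sum(x$labels == "P2"),
              min(x$positions[, 1]), max(x$positions[, 1])))
  invisible(x)
}

# wrap x into 0..L-1
wrap_x <- function(x, L) ((x %% L) + L) %% L

# encode wrapped lattice sites as scalar keys (unique within the channel)
site_key <- function(pos, geom) {
  xw <- wrap_x(pos[, 1], geom$L)
  (xw * (geom$D + 2) + pos[, 2]) * (geom$D + 2) + pos[, 3]
}

part_index <- function(state, part = c("whole", "P1", "P2")) {
  part <- match.arg(part)
  switch(part,
         whole = seq_len(state$N),
         P1 = which(state$labels == "P1"),
         P2 = which(state$labels == "P2"))
}

#' Check the full conformational validity of a chain in a channel
#'
#' True iff (i) consecutive beads are lattice nearest neighbours (unit bond
#' on one axis), (ii) all wrapped positions are distinct (self-avoidance,
#' including across periodic images), and (iii) every bead lies between the
#' channel walls on both confined axes.
#'
#' @param state a [chain_state].
#' @param geom a [channel_geometry].
#' @return logical scalar.
#' @export
is_valid_conformation <- function(state, geom) {
  p <- state$positions
  if (state$N >= 2) {
    d <- diff(p)
    if (any(rowSums(abs(d)) != 1L)) return(FALSE)
  }
  if (any(p[, 2] < 1 | p[, 2] > geom$D | p[, 3] < 1 | p[, 3] > geom$D))
    return(FALSE)
  !anyDuplicated(site_key(p, geom))
}

#' Non-bonded lattice contacts of a chain
#'
#' Every unordered bead pair `(i, j)` with `|i - j| >= 2` whose wrapped
#' positions are lattice nearest neighbours. Bonded pairs (including the
#' junction bond between the two blocks) are excluded: their adjacency is a
#' structural constant of the chain.
#'
#' @inheritParams is_valid_conformation
#' @return integer matrix with columns `i`, `j` (i < j), zero rows if none.
#' @export
nonbonded_contacts <- function(state, geom) {
  p <- state$positions
  n <- state$N
  keys <- site_key(p, geom)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(keys[i]), i, envir = lookup)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    nb <- sweep(offsets, 2, p[i, ], "+")
    nb_keys <- site_key(nb, geom)
    for (k in nb_keys) {
      j <- mget(as.character(k), envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j - i >= 2) out <- rbind(out, c(i, j))
    }
  }
  colnames(out) <- c("i", "j")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Centre of mass of the chain or one block
#'
#' Arithmetic mean of the selected beads' coordinates; x is unwrapped, so the
#' result is meaningful across the periodic boundary.
#'
#' @inheritParams is_valid_conformation
#' @param part `"whole"`, `"P1"`, or `"P2"`.
#' @return numeric length-3 vector (x, y, z).
#' @export
center_of_mass <- function(state, part = c("whole", "P1", "P2")) {
  idx <- part_index(state, part)
  colMeans(state$positions[idx, , drop = FALSE])
}

#' Radius of gyration of the chain or one block
#'
#' Root-mean-square distance of the selected beads from their own centre of
#' mass, in lattice units.
#'
#' @inheritParams center_of_mass
#' @return numeric scalar.
#' @export
radius_of_gyration <- function(state, part = c("whole", "P1", "P2")) {
  idx <- part_index(state, part)
  p <- state$positions[idx, , drop = FALSE]
  cm <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2, cm)^2)))
}

#' Canonical conformation key (quotient by longitudinal translation)
#'
#' Encodes a conformation as a string after translating bead 1 to wrapped
#' x = 0. Transverse coordinates are kept absolute (the walls break
#' transverse translation symmetry). Used to match sampled states against
#' exhaustive enumerations.
#'
#' @inheritParams is_valid_conformation
#' @return character scalar.
#' @export
conformation_key <- function(state, geom) {
  p <- state$positions
  xr <- wrap_x(p[, 1] - p[1, 1], geom$L)
  paste(xr, p[, 2], p[, 3], sep = ",", collapse = ";")
}
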