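# Brute-force references for validating the sampler and the entropy
# estimator on tiny systems. Enumeration is depth-first and deliberately
# guarded: it exists to be exact, not to scale.

#' Exhaustively enumerate self-avoiding walks
#'
#' All valid N-bead conformations, canonicalised by fixing bead 1 at wrapped
#' x = 0 (quotienting the longitudinal translation symmetry only; the walls
#' break transverse translation, and reflections are deliberately not
#' quotiented so that sampled-frequency comparisons stay simple). With
#' `geom = NULL` the walk is unconfined and bead 1 is pinned at the origin.
#'
#' @param N bead count (<= 9).
#' @param geom a [channel_geometry] with cross-section at most 3 x 3, or
#'   NULL for the unconfined lattice.
#' @return An object of class `saw_enumeration`: list with `states` (list
#'   of [chain_state]), `keys` (canonical keys, channel case), `N`, `geom`.
#' @examples
#' length(enumerate_saws(3, NULL)$states)   # 30
#' @export
enumerate_saws <- function(N, geom = NULL) {
  if (N > 9) stop("enumeration guard: N must be <= 9")
  if (!is.null(geom) && geom$D > 3)
    stop("enumeration guard: channel cross-section must be at most 3 x 3")
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  states <- list()
  key_of <- function(pos) {
    if (is.null(geom)) paste(t(pos), collapse = ",")
    else conformation_key(chain_state(pos), geom)
  }
  occ_key <- function(p) {
    if (is.null(geom)) paste(p, collapse = ",")
    else as.character(site_key(matrix(as.integer(p), 1), geom))
  }
  in_bounds <- function(p) {
    is.null(geom) || (p[2] >= 1 && p[2] <= geom$D && p[3] >= 1 && p[3] <= geom$D)
  }
  grow <- function(pos, occupied) {
    i <- nrow(pos)
    if (i == N) {
      states[[length(states) + 1]] <<- chain_state(pos)
      return(invisible())
    }
    for (d in seq_len(6)) {
      nxt <- pos[i, ] + offsets[d, ]
      if (!in_bounds(nxt)) next
      k <- occ_key(nxt)
      if (!is.null(occupied[[k]])) next
      occupied[[k]] <- TRUE
      grow(rbind(pos, nxt), occupied)
      occupied[[k]] <- NULL
    }
  }
  starts <- if (is.null(geom)) list(c(0L, 0L, 0L))
            else {
              g <- expand.grid(y = seq_len(geom$D), z = seq_len(geom$D))
              lapply(seq_len(nrow(g)), function(r) c(0L, g$y[r], g$z[r]))
            }
  for (s in starts) {
    p0 <- matrix(as.integer(s), 1)
    occupied <- list()
    occupied[[occ_key(s)]] <- TRUE
    grow(p0, occupied)
  }
  keys <- vapply(states, function(st) {
    if (is.null(geom)) paste(t(st$positions), collapse = ",")
    else conformation_key(st, geom)
  }, character(1))
  if (anyDuplicated(keys)) stop("internal error: duplicate canonical keys")
  structure(list(states = states, keys = keys, N = N, geom = geom),
            class = "saw_enumeration")
}

#' @export
print.saw_enumeration <- function(x, ...) {
  cat(sprintf("<saw_enumeration> %d conformations of N = %d beads\n",
              length(x$states), x$N))
  invisible(x)
}

#' Exact Boltzmann distribution over an enumeration
#'
#' Normalised weights `exp(-U_c / T)` per enumerated conformation under an
#' energy model. The athermal model gives the uniform distribution.
#'
#' @param enum a [saw_enumeration] (requires a channel geometry).
#' @param energy an [energy_model].
#' @return numeric vector of probabilities (sums to 1), parallel to
#'   `enum$states`.
#' @export
boltzmann_distribution <- function(enum, energy) {
  if (is.null(enum$geom))
    stop("Boltzmann weights need a channel geometry (contacts are wrapped)")
  U <- vapply(enum$states, internal_energy, numeric(1),
              geom = enum$geom, energy = energy)
  w <- exp(-U / energy$T)
  w / sum(w)
}

#' Exact continuation counts along each enumerated conformation
#'
#' For every conformation, the number of valid placements of each successive
#' bead given all prior beads: the exact quantity that the phantom-chain
#' rebuild of [entropy_scm] counts as vacant-neighbour numbers. Computed
#' here independently of the entropy code.
#'
#' @param enum a [saw_enumeration].
#' @return list of integer vectors (length N - 1), parallel to
#'   `enum$states`; each product is >= 1.
#' @export
exact_continuation_counts <- function(enum) {
  geom <- enum$geom
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  okey <- function(p) {
    if (is.null(geom)) paste(p, collapse = ",")
    else as.character(site_key(matrix(as.integer(p), 1), geom))
  }
  lapply(enum$states, function(st) {
    p <- st$positions
    n <- st$N
    seen <- list()
    seen[[okey(p[1, ])]] <- TRUE
    counts <- integer(n - 1)
    for (i in seq_len(n - 1)) {
      w <- 0L
      for (d in seq_len(6)) {
        cand <- p[i, ] + offsets[d, ]
        if (!is.null(geom) &&
            (cand[2] < 1 || cand[2] > geom$D || cand[3] < 1 || cand[3] > geom$D))
          next
        if (is.null(seen[[okey(cand)]])) w <- w + 1L
      }
      counts[i] <- w
      seen[[okey(p[i + 1, ])]] <- TRUE
    }
    counts
  })
}
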