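#' Phantom-chain conformational entropy (statistical counting method)
#'
#' Estimates the conformational entropy of a single chain conformation by the
#' phantom-chain rebuild: the whole chain is removed from the lattice, bead 1
#' is put back, and for each rebuild step `i = 1..N-1` the effective
#' coordination number `omega_i` is counted as the number of neighbour sites
#' of bead `i` that are vacant at that moment - not a wall plane and not
#' occupied by an already-replaced bead. Beads not yet replaced do not block
#' (that is the "phantom" part). The entropy is `S/kB = sum(ln omega_i)`.
#' The site that bead `i+1` actually occupies is always vacant at count time,
#' so every `omega_i >= 1` and the sum is finite.
#'
#' With `parts = TRUE` the rebuild sum is split by index range: step `i`
#' (placing bead `i+1`) belongs to P1 for `i <= N/2 - 1` and to P2 from the
#' junction step `i = N/2` onward.
#'
#' The estimator is relative, not absolute: only fluctuations and gradients
#' of S along a trajectory are physically meaningful.
#'
#' @inheritParams is_valid_conformation
#' @param parts logical; also return per-block sums?
#' @return Scalar `S/kB`, or named vector `c(S, S_P1, S_P2)`.
#' @examples
#' geom <- channel_geometry(D = 9, L = 20)
#' rod <- chain_state(cbind(0:2, 5L, 5L))
#' entropy_scm(rod, geom)   # log(6) + log(5)
#' @export
entropy_scm <- function(state, geom, parts = FALSE) {
  p <- state$positions
  n <- state$N
  half <- n %/% 2
  placed <- new.env(hash = TRUE, size = n)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  S <- S1 <- S2 <- 0
  if (n >= 1) assign(as.character(site_key(p[1, , drop = FALSE], geom)), TRUE,
                     envir = placed)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      nb <- sweep(offsets, 2, p[i, ], "+")
      ok <- nb[, 2] >= 1 & nb[, 2] <= geom$D & nb[, 3] >= 1 & nb[, 3] <= geom$D
      w <- 0L
      keys <- as.character(site_key(nb, geom))
      for (k in which(ok)) {
        if (!exists(keys[k], envir = placed, inherits = FALSE)) w <- w + 1L
      }
      lw <- log(w)
      S <- S + lw
      if (i <= half - 1) S1 <- S1 + lw else S2 <- S2 + lw
      assign(as.character(site_key(p[i + 1, , drop = FALSE], geom)), TRUE,
             envir = placed)
    }
  }
  if (parts) c(S = S, S_P1 = S1, S_P2 = S2) else S
}

#' Helmholtz free energy
#'
#' `A = U - T * S` in units of kB*T, with S in units of kB. The identity
#' holds exactly at every trajectory record; the whole-chain A is computed
#' from whole-chain S and U (it need not equal the sum of the per-block
#' values when cross terms are present).
#'
#' @param U internal energy (kB*T).
#' @param S conformational entropy (kB).
#' @param T reduced temperature.
#' @return numeric, same length as the inputs.
#' @export
helmholtz <- function(U, S, T = 1) U - T * S
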