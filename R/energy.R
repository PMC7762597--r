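#' Contact energy model
#'
#' Pairwise contact energies, in units of kB*T, between the two bead types of
#' the copolymer, plus the (zero) solvent energies and the reduced
#' temperature. The default is the study configuration: the P1 block is
#' self-attracting (`eps_P1P1 = -1`, a poor-solvent block with Flory chi = 2)
#' and the P2 block is athermal (`eps_P2P2 = 0`); mixed contacts carry zero
#' energy so the athermal block stays athermal at the junction.
#'
#' @param eps_P1P1,eps_P2P2,eps_P1P2 contact energies between bead types.
#' @param eps_PS,eps_SS bead-solvent and solvent-solvent energies (zero in
#'   the model; with both zero, solvent terms drop out of energy differences).
#' @param T reduced temperature.
#' @return An object of class `energy_model`: a list with the symmetric 2x2
#'   matrix `eps` (rows/cols P1, P2), `eps_PS`, `eps_SS`, and `T`.
#' @examples
#' energy_model()                       # the default two-block model
#' energy_model(eps_P1P1 = 0)           # fully athermal (symmetric) chain
#' @export
energy_model <- function(eps_P1P1 = -1, eps_P2P2 = 0, eps_P1P2 = 0,
                         eps_PS = 0, eps_SS = 0, T = 1) {
  if (T <= 0) stop("reduced temperature T must be positive")
  eps <- matrix(c(eps_P1P1, eps_P1P2, eps_P1P2, eps_P2P2), 2, 2,
                dimnames = list(c("P1", "P2"), c("P1", "P2")))
  structure(list(eps = eps, eps_PS = eps_PS, eps_SS = eps_SS, T = T),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> contact energies (kB T):\n")
  print(x$eps)
  cat(sprintf("eps_PS = %g, eps_SS = %g, T = %g\n", x$eps_PS, x$eps_SS, x$T))
  invisible(x)
}

#' Flory interaction coefficient of a bead type
#'
#' Lattice Flory chi from the interchange energy
#' `d_eps = eps_PS - (eps_PP + eps_SS) / 2` with the effective coordination
#' number `z - 2` (two of the six cubic-lattice neighbours of an interior
#' bead are taken by its bonded neighbours):
#' `chi = (z - 2) * d_eps / (kB T)`. For the default `eps_P1P1 = -1` this
#' gives chi = 2 (poor solvent); an athermal block gives chi = 0.
#'
#' @param energy an [energy_model].
#' @param bead `"P1"` or `"P2"`.
#' @param z lattice coordination number (6 for the simple cubic lattice).
#' @return numeric scalar.
#' @examples
#' flory_chi(energy_model())          # 2
#' flory_chi(energy_model(), "P2")    # 0
#' @export
flory_chi <- function(energy, bead = c("P1", "P2"), z = 6) {
  bead <- match.arg(bead)
  eps_pp <- energy$eps[bead, bead]
  d_eps <- energy$eps_PS - (eps_pp + energy$eps_SS) / 2
  (z - 2) * d_eps / energy$T
}

#' Internal energy of a conformation
#'
#' Sum of contact energies over all non-bonded lattice contacts
#' (see [nonbonded_contacts]). With `parts = TRUE` the energy is decomposed
#' by block: contacts within P1 or within P2 are assigned to that block and
#' mixed contacts are split equally.
#'
#' @inheritParams is_valid_conformation
#' @param energy an [energy_model].
#' @param parts logical; return the per-block decomposition as well?
#' @return With `parts = FALSE` a scalar (units kB*T); otherwise a named
#'   vector `c(U, U_P1, U_P2)`.
#' @examples
#' geom <- channel_geometry(D = 5, L = 20)
#' sq <- chain_state(cbind(c(0L, 1L, 1L, 0L), c(2L, 2L, 3L, 3L), 3L))
#' internal_energy(sq, geom, energy_model(eps_P1P1 = -1, eps_P2P2 = -1,
#'                                        eps_P1P2 = -1))
#' @export
internal_energy <- function(state, geom, energy, parts = FALSE) {
  ct <- nonbonded_contacts(state, geom)
  if (nrow(ct) == 0) {
    return(if (parts) c(U = 0, U_P1 = 0, U_P2 = 0) else 0)
  }
  li <- state$labels[ct[, 1]]
  lj <- state$labels[ct[, 2]]
  e <- energy$eps[cbind(li, lj)]
  if (!parts) return(sum(e))
  both1 <- li == "P1" & lj == "P1"
  both2 <- li == "P2" & lj == "P2"
  mixed <- !(both1 | both2)
  c(U = sum(e),
    U_P1 = sum(e[both1]) + 0.5 * sum(e[mixed]),
    U_P2 = sum(e[both2]) + 0.5 * sum(e[mixed]))
}
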