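# Small conformations and geometries used across test files; everything is
# built in code.

geom_wide <- function() channel_geometry(D = 9, L = 30)
geom_tight <- function() channel_geometry(D = 3, L = 20)

# straight rod along x at a given transverse position
rod_state <- function(n, y = 5L, z = 5L, x0 = 0L) {
  chain_state(cbind(x0 + 0:(n - 1), y, z))
}

# N = 4 unit square in the xy plane
square_state <- function(y0 = 5L, z0 = 5L) {
  chain_state(cbind(c(0L, 1L, 1L, 0L), c(y0, y0, y0 + 1L, y0 + 1L), z0))
}

# N = 5 hairpin: out along x, one step in y, back along -x
hairpin_state <- function() {
  chain_state(cbind(c(0L, 1L, 2L, 2L, 1L), c(5L, 5L, 5L, 6L, 6L), 5L))
}

all_p1_energy <- function() energy_model(eps_P1P1 = -1, eps_P2P2 = -1,
                                         eps_P1P2 = -1)
athermal_energy <- function() energy_model(eps_P1P1 = 0)
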