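# polychan

Lattice Monte Carlo simulation and analysis of a two-block copolymer
confined in a tight nanochannel.

## The problem

A flexible polymer squeezed into a channel a few monomer diameters wide
behaves very differently from a free coil: conformational entropy is cut
down by the walls, and an *asymmetric* chain — here a diblock whose first
half P1 is self-attracting (poor solvent, compact) while the second half
P2 is athermal (loose) — can couple its internal asymmetry to its
longitudinal motion. The questions this package lets you study are the
ones asked about such systems: how does the mean squared displacement
(autocorrelation function) of the chain's mass centre and of its beads
scale with lag time,

```
g(Δt)  = ⟨(x(t) − x(t+Δt))²⟩  ~  Δt^ν ,
g_B(Δt) = (2/N) Σ_i ⟨(x_B,i(t) − x_B,i(t+Δt))²⟩ ,
```

where ν = 1 is ordinary diffusion, ν < 1 subdiffusion, ν > 1
superdiffusion; how often the two blocks swap their order along the
channel (the mutual orientation parameter `M = sign(x_P1 − x_P2)` with a
dead band δ); and how the free energy `A = U − T·S` — with `S` estimated
per conformation by the phantom-chain statistical counting method,
`S/k_B = Σ ln ω_i` — varies along the channel coordinate, yielding forces
`F = ∂A/∂x` and their impulses.

## The model in brief

* Self-avoiding walk of `N` beads on a simple cubic lattice (`b = 1`);
  square channel with habitable transverse planes `1..D`, impenetrable
  walls at `0` and `D+1`, periodic in x with period `L`.
* Two equal blocks fixed by bead index; default contact energies
  `ε(P1,P1) = −k_BT` (Flory χ = 2), all others zero, reduced temperature
  `T = 1`.
* Metropolis dynamics over the Verdier–Stockmayer moves (kink-jump,
  crankshaft, end moves, reptation), proposed proportionally to their
  object counts; time is counted in elementary attempts `t_E`, one MC
  cycle = `N` attempts; annealed burn-in with a hyperbolic cooling
  schedule.
* The Metropolis weight is configurable: internal energy `U` (default,
  canonical sampling — verified against exhaustive enumeration) or the
  free energy `A = U − T·S` (see the methods vignette).
* The inner loop is compiled (Rcpp); about 3–4 million attempts per
  second per core for `N = 100`, bit-reproducible for a given seed.

## Worked example

```r
library(polychan)

cfg  <- run_config(N = 20, D = 3, L = 200, n_equil = 5e4,
                   n_attempts = 5e6, record_every = 500, seed = 42)
traj <- run_simulation(cfg)
traj
#> <mc_trajectory> N = 20, D = 3: 10001 records over 5e+06 attempts
#> acceptance rates:
#>        kind attempts accepts       rate
#>   kink_jump  2307953  747351 0.32381552
#>  crankshaft  2178547   81101 0.03722711
#>    end_move   256543  121617 0.47406088
#>   reptation   256957   77382 0.30114766

flory_chi(cfg$energy, "P1")
#> [1] 2

# diffusion exponent of the mass centre over lags 500..5000 t_E
fit_exponent(autocorr_g(traj), window = c(5e2, 5e3))
#> <scaling_fit> nu = 0.9444 +/- 0.0047 over dt in [500, 5000] (n = 10, R2 = 0.9998)

# block-order reversals and their period distribution
ev <- detect_swaps(traj)
ev
#> <swap_events> 312 events (hysteresis) over span 5e+06 t_E
dens <- swap_period_density(ev)
round(dens$modes, 2)          # mode locations in log10(t_E)
#> [1] 2.88 3.84 4.45
```

The acceptance rates show the tight channel at work (crankshafts almost
never fit in a 3×3 cross-section); the mass centre diffuses almost
classically (ν ≈ 0.94) at these lags; and the inter-swap periods of this
short chain already spread over two decades with a multi-modal structure.
Mean gyration radii confirm the asymmetry: the self-attracting P1 block is
compact (here ⟨Rg⟩ ≈ 1.19) against the looser athermal P2 (≈ 1.48).

Thermodynamic traces ride along in `traj$obs` (columns `S`, `U`, `A`,
with per-block values), ready for `force_profile()` / `impulse()`.

A command-line front end is installed with the package
(`system.file("cli", "polychan", package = "polychan")`) with subcommands
`simulate`, `msd`, `swaps`, `thermo`, `scaling`, and `enumerate`, reading
a YAML config and writing tab-delimited tables and XYZ snapshots.

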