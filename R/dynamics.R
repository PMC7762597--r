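#' Initial chain conformation
#'
#' The default deterministic layout is a straight rod along the channel axis
#' at the transverse centre of the channel. `how = "grow"` instead grows a
#' biased random self-avoiding walk (useful to decorrelate independent
#' replicas before burn-in); growth restarts on dead ends.
#'
#' @param N chain length.
#' @param geom a [channel_geometry].
#' @param how `"rod"` or `"grow"`.
#' @param max_restarts restart budget for random growth.
#' @return A valid [chain_state].
#' @export
init_chain <- function(N, geom, how = c("rod", "grow"), max_restarts = 1000) {
  how <- match.arg(how)
  if (how == "rod") {
    if (N > geom$L)
      stop("cannot place a rod of ", N, " beads in a periodic channel of length ",
           geom$L)
    yz <- geom$D %/% 2 + 1L
    return(chain_state(cbind(0:(N - 1), yz, yz)))
  }
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (try in seq_len(max_restarts)) {
    pos <- matrix(0L, N, 3)
    pos[1, ] <- c(0L, sample.int(geom$D, 1), sample.int(geom$D, 1))
    occupied <- as.character(site_key(pos[1, , drop = FALSE], geom))
    ok <- TRUE
    for (i in seq_len(N - 1)) {
      cand <- sweep(offsets, 2, pos[i, ], "+")
      keys <- as.character(site_key(cand, geom))
      free <- cand[, 2] >= 1 & cand[, 2] <= geom$D &
        cand[, 3] >= 1 & cand[, 3] <= geom$D & !(keys %in% occupied)
      if (!any(free)) { ok <- FALSE; break }
      # bias forward along +x to avoid trapping in tight channels
      w <- ifelse(cand[, 1] > pos[i, 1], 3, 1) * free
      pick <- sample.int(6, 1, prob = w)
      pos[i + 1, ] <- cand[pick, ]
      occupied <- c(occupied, keys[pick])
    }
    if (ok) return(chain_state(pos))
  }
  stop("random growth failed after ", max_restarts, " restarts")
}

#' Move-kind selection probabilities
#'
#' Each move kind is proposed with frequency proportional to the number of
#' objects it can act on: kink-jumps on the N-2 interior beads, crankshafts
#' on the N-3 adjacent interior bead pairs, end moves on the 2 chain ends,
#' and reptation in its 2 directions.
#'
#' @param N chain length.
#' @return named numeric vector of probabilities summing to 1.
#' @examples
#' move_kind_probs(100)["kink_jump"]  # 98/199
#' @export
move_kind_probs <- function(N) {
  counts <- c(kink_jump = max(N - 2, 0), crankshaft = max(N - 3, 0),
              end_move = 2, reptation = 2)
  counts / sum(counts)
}

#' Metropolis acceptance
#'
#' Accept with probability `min(1, exp(-dU / T))`. Vectorised over `dU`.
#'
#' @param dU energy difference(s) in kB*T.
#' @param T reduced temperature.
#' @return logical vector.
#' @export
metropolis_accept <- function(dU, T = 1) {
  runif(length(dU)) < exp(-pmax(dU, 0) / T)
}

#' Annealing temperature schedule
#'
#' Hyperbolic cooling used during burn-in:
#' `T(k) = T_final * (1 + c * K / (k + K))`, starting at `T_final * (1 + c)`
#' and decaying to `T_final`. With `c = 0` the burn-in is isothermal.
#'
#' @param k attempt index (0-based).
#' @param T_final target temperature.
#' @param c initial relative overheating.
#' @param K decay scale in attempts.
#' @return numeric temperature(s).
#' @export
anneal_temperature <- function(k, T_final = 1, c = 4, K = 1e4) {
  if (c <= 0 || K <= 0) return(rep(T_final, length(k)))
  T_final * (1 + c * K / (k + K))
}

#' Slither the chain by one bead (reptation)
#'
#' Shifts every bead one index along the chain: the bead at the leaving end
#' is removed and a new bead is appended at `new_site`, which must be a
#' lattice neighbour of the growing end. Block labels stay attached to
#' indices, not to physical beads, so P1 and P2 remain contiguous halves.
#'
#' @param state a [chain_state].
#' @param direction `"head"` (bead N end grows) or `"tail"` (bead 1 end
#'   grows).
#' @param new_site integer length-3 vector, the appended bead's position.
#' @return the shifted [chain_state] (not validity-checked).
#' @export
apply_reptation <- function(state, direction = c("head", "tail"), new_site) {
  direction <- match.arg(direction)
  p <- state$positions
  new_site <- as.integer(new_site)
  grow <- if (direction == "head") state$N else 1L
  if (sum(abs(p[grow, ] - new_site)) != 1)
    stop("new_site must be a lattice neighbour of the growing end")
  q <- if (direction == "head") rbind(p[-1, , drop = FALSE], new_site)
       else rbind(new_site, p[-state$N, , drop = FALSE])
  chain_state(q)
}

#' Propose one Verdier-Stockmayer micromodification (reference sampler)
#'
#' Draws a move kind with the [move_kind_probs] frequencies, picks a uniform
#' object of that kind, and works out the proposal geometry: kink-jump as the
#' 90-degree corner flip of one interior bead, crankshaft as the rigid
#' quarter/half turn of a two-bead U-segment about the axis through its
#' flanking beads, end move of an end bead to a uniform neighbour site of its
#' bonded neighbour, and reptation towards a uniform neighbour of the growing
#' end. Geometrically impossible proposals are returned with
#' `feasible = FALSE` (they consume an attempt and are rejected).
#'
#' This is a plain-R reference of the proposal rules used by the compiled
#' engine; it is convenient for inspecting and testing single moves, not for
#' production runs.
#'
#' @param state a valid [chain_state].
#' @param geom a [channel_geometry].
#' @return list with `kind`, `target`, `new_positions` (full proposed
#'   position matrix) and `feasible`.
#' @export
propose_move <- function(state, geom) {
  p <- state$positions
  n <- state$N
  kind <- sample(names(move_kind_probs(n)), 1, prob = move_kind_probs(n))
  infeasible <- function(target)
    list(kind = kind, target = target, new_positions = NULL, feasible = FALSE)
  occupied <- function(site, ignore) {
    keys <- site_key(p[-ignore, , drop = FALSE], geom)
    site_key(matrix(site, 1), geom) %in% keys
  }
  in_walls <- function(site) all(site[2:3] >= 1 & site[2:3] <= geom$D)
  if (kind == "kink_jump") {
    i <- sample(2:(n - 1), 1)
    a <- p[i + 1, ] - p[i - 1, ]
    if (sum(a^2) != 2) return(infeasible(i))
    new <- p[i - 1, ] + p[i + 1, ] - p[i, ]
    if (!in_walls(new) || occupied(new, i)) return(infeasible(i))
    q <- p; q[i, ] <- new
    return(list(kind = kind, target = i, new_positions = q, feasible = TRUE))
  }
  if (kind == "crankshaft") {
    if (n < 4) return(infeasible(NA))
    i <- sample(2:(n - 2), 1)          # beads i, i+1 move
    ax <- p[i + 2, ] - p[i - 1, ]
    if (sum(ax^2) != 1) return(infeasible(i))
    q <- sample(1:3, 1)
    rot90 <- function(v) ax * sum(ax * v) +
      c(ax[2] * v[3] - ax[3] * v[2], ax[3] * v[1] - ax[1] * v[3],
        ax[1] * v[2] - ax[2] * v[1])
    v1 <- p[i, ] - p[i - 1, ]; v2 <- p[i + 1, ] - p[i - 1, ]
    for (k in seq_len(q)) { v1 <- rot90(v1); v2 <- rot90(v2) }
    n1 <- p[i - 1, ] + v1; n2 <- p[i - 1, ] + v2
    if (!in_walls(n1) || !in_walls(n2)) return(infeasible(i))
    if (occupied(n1, c(i, i + 1)) || occupied(n2, c(i, i + 1)))
      return(infeasible(i))
    qp <- p; qp[i, ] <- n1; qp[i + 1, ] <- n2
    return(list(kind = kind, target = i, new_positions = qp, feasible = TRUE))
  }
  if (kind == "end_move") {
    head <- runif(1) < 0.5
    e <- if (head) n else 1L
    a <- if (head) n - 1L else 2L
    dir <- sample(6, 1)
    offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    new <- p[a, ] + offsets[dir, ]
    if (!in_walls(new)) return(infeasible(e))
    if (all(new == p[e, ])) {         # null move
      return(list(kind = kind, target = e, new_positions = p, feasible = TRUE))
    }
    if (occupied(new, e)) return(infeasible(e))
    q <- p; q[e, ] <- new
    return(list(kind = kind, target = e, new_positions = q, feasible = TRUE))
  }
  # reptation
  head <- runif(1) < 0.5
  grow <- if (head) n else 1L
  leave <- if (head) 1L else n
  dir <- sample(6, 1)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  new <- p[grow, ] + offsets[dir, ]
  if (!in_walls(new) || occupied(new, leave) || all(new == p[grow, ]))
    return(infeasible(grow))
  st <- apply_reptation(state, if (head) "head" else "tail", new)
  list(kind = "reptation", target = grow, new_positions = st$positions,
       feasible = TRUE)
}

.engine_call <- function(state, config, n_equil, n_attempts) {
  type0 <- as.integer(state$labels == "P2")
  .run_engine(state$positions[, 1], state$positions[, 2],
              state$positions[, 3], type0,
              config$geom$D, config$geom$L, config$energy$eps,
              config$energy$T, identical(config$weight, "A"),
              n_equil, config$anneal_c, config$anneal_K,
              n_attempts, config$record_every, config$bead_every,
              config$snapshot_every, config$record_thermo, config$delta,
              0)
}

#' A single Monte Carlo micromodification
#'
#' Runs exactly one attempted move on a state (no burn-in, no recording):
#' draw a move kind and object, check geometry and excluded volume, and
#' apply the Metropolis criterion. Convenient for stepping through the
#' dynamics; production runs use [run_simulation].
#'
#' @param state a valid [chain_state].
#' @param config a [run_config] (its geometry, energies, and weight are
#'   used).
#' @param seed optional RNG seed.
#' @return list with `state` (possibly updated), `accepted` (logical;
#'   FALSE also for geometrically impossible proposals), and `dU` (contact
#'   energy change; 0 unless accepted).
#' @export
mc_step <- function(state, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  U0 <- internal_energy(state, config$geom, config$energy)
  cfg <- config
  cfg$n_equil <- 0
  cfg$record_every <- 1
  cfg$bead_every <- 0
  cfg$snapshot_every <- 0
  res <- .engine_call(state, cfg, 0, 1)
  new_state <- chain_state(cbind(res$final_x, res$final_y, res$final_z))
  list(state = new_state, accepted = sum(res$accepts) == 1,
       dU = res$U_final - U0)
}

#' Annealed burn-in
#'
#' Runs `config$n_equil` elementary attempts under the hyperbolic cooling
#' schedule and returns the final state; nothing is recorded.
#'
#' @param state a valid [chain_state].
#' @param config a [run_config].
#' @param seed optional RNG seed (`set.seed` is called if given).
#' @return the equilibrated [chain_state].
#' @export
equilibrate <- function(state, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- .engine_call(state, config, config$n_equil, 0)
  chain_state(cbind(res$final_x, res$final_y, res$final_z))
}

#' Run a full Monte Carlo simulation
#'
#' Initialisation, annealed burn-in, and the production loop in one call.
#' Every `record_every` elementary attempts a trajectory row is recorded
#' with the time stamp `t_E`, unwrapped longitudinal mass centres of the
#' whole chain and both blocks, per-block gyration radii, the thermodynamic
#' state (S, U, A, whole and per block), and the mutual orientation
#' parameter M. Runs are bit-reproducible given `seed`.
#'
#' @param config a [run_config].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param state optional starting [chain_state]; default is the centred rod
#'   of [init_chain].
#' @param validate_every debug option: every so many attempts, recompute the
#'   total energy from scratch inside the engine and abort on any mismatch
#'   with the incrementally updated value (0 = off).
#' @return An object of class `mc_trajectory`: list with `obs` (data frame
#'   of trajectory rows), `acceptance` (per move kind), `bead_x` (integer
#'   matrix of unwrapped bead x positions, if `bead_every > 0`), `snapshots`
#'   (integer array `frames x N x 3`, if `snapshot_every > 0`),
#'   `final_state`, and `config`.
#' @examples
#' cfg <- run_config(N = 20, L = 50, n_equil = 2e3, n_attempts = 2e4,
#'                   record_every = 100)
#' traj <- run_simulation(cfg, seed = 1)
#' head(traj$obs)
#' @export
run_simulation <- function(config, seed = config$seed, state = NULL,
                           validate_every = 0) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- init_chain(config$N, config$geom)
  if (!is_valid_conformation(state, config$geom))
    stop("starting state is not a valid conformation")
  type0 <- as.integer(state$labels == "P2")
  res <- .run_engine(state$positions[, 1], state$positions[, 2],
                     state$positions[, 3], type0,
                     config$geom$D, config$geom$L, config$energy$eps,
                     config$energy$T, identical(config$weight, "A"),
                     config$n_equil, config$anneal_c,
                     config$anneal_K, config$n_attempts, config$record_every,
                     config$bead_every, config$snapshot_every,
                     config$record_thermo, config$delta, validate_every)
  obs <- as.data.frame(res$obs)
  acceptance <- data.frame(
    kind = c("kink_jump", "crankshaft", "end_move", "reptation"),
    attempts = res$attempts, accepts = res$accepts,
    rate = ifelse(res$attempts > 0, res$accepts / res$attempts, NA))
  out <- list(obs = obs, acceptance = acceptance,
              bead_x = res$bead_x, snapshots = res$snapshots,
              final_state = chain_state(cbind(res$final_x, res$final_y,
                                              res$final_z)),
              U_final = res$U_final, config = config, seed = seed)
  class(out) <- "mc_trajectory"
  out
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("<mc_trajectory> N = %d, D = %d: %d records over %g attempts\n",
              x$config$N, x$config$geom$D, nrow(x$obs), x$config$n_attempts))
  cat("acceptance rates:\n")
  print(x$acceptance, row.names = FALSE)
  invisible(x)
}

#' Extract chain states from recorded snapshots
#'
#' @param traj an `mc_trajectory` run with `snapshot_every > 0`.
#' @param frames which frames (default all).
#' @return list of [chain_state] objects.
#' @export
snapshot_states <- function(traj, frames = NULL) {
  if (is.null(traj$snapshots)) stop("trajectory has no snapshots")
  arr <- traj$snapshots
  if (is.null(frames)) frames <- seq_len(dim(arr)[1])
  lapply(frames, function(f) chain_state(cbind(arr[f, , 1], arr[f, , 2],
                                               arr[f, , 3])))
}
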