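#' Mutual orientation parameter M
#'
#' Sign of the longitudinal separation of the two block mass centres with a
#' dead band: `M = +1` if `x_P1 - x_P2 > delta`, `-1` if `< -delta`, else 0.
#' M = +1 means the self-attracting block P1 leads along +x.
#'
#' @param x_P1,x_P2 unwrapped longitudinal block centres (vectorised).
#' @param delta dead band in lattice units.
#' @return integer vector in \{-1, 0, +1\}.
#' @export
orientation_M <- function(x_P1, x_P2, delta = 0.01) {
  d <- x_P1 - x_P2
  ifelse(d > delta, 1L, ifelse(d < -delta, -1L, 0L))
}

#' Mutual orientation parameter from 3D block centres
#'
#' Bulk-phase variant: compares the distances of the two block centres from
#' the whole-chain centre, with threshold `delta / 2`.
#'
#' Note a degeneracy of this definition: for a chain of two *equal-mass*
#' halves the two block centres are exact mirror vectors about the
#' whole-chain centre (`r_P1 = -r_P2`), so the two distances are identical
#' and the comparison returns 0 on every row. It is therefore only
#' informative for unequal masses (or centres computed with different
#' weights); the longitudinal form [orientation_M] is the operative
#' definition in a channel.
#'
#' @param com_P1,com_P2,com_whole n x 3 matrices of unwrapped centres.
#' @param delta dead band in lattice units.
#' @return integer vector in \{-1, 0, +1\}.
#' @export
orientation_M_3d <- function(com_P1, com_P2, com_whole, delta = 0.01) {
  r1 <- sqrt(rowSums((com_P1 - com_whole)^2))
  r2 <- sqrt(rowSums((com_P2 - com_whole)^2))
  d <- r1 - r2
  ifelse(d > delta / 2, 1L, ifelse(d < -delta / 2, -1L, 0L))
}

.obs_frame <- function(traj) {
  if (inherits(traj, "mc_trajectory")) traj$obs else as.data.frame(traj)
}

.uniform_stride <- function(t) {
  dt <- unique(diff(t))
  if (length(dt) != 1)
    stop("trajectory rows must be uniformly sampled in t_E")
  dt
}

#' Logarithmic lag grid
#'
#' Lag times for autocorrelation curves: approximately `per_decade` points
#' per decade from `stride` to `t_max`, snapped to multiples of the sampling
#' stride and deduplicated.
#'
#' @param stride sampling stride in t_E.
#' @param t_max largest lag.
#' @param per_decade grid density.
#' @return numeric vector of lags.
#' @export
log_dt_grid <- function(stride, t_max, per_decade = 20) {
  if (t_max < stride) stop("t_max must be at least one stride")
  n_dec <- log10(t_max / stride)
  raw <- stride * 10^seq(0, n_dec, by = 1 / per_decade)
  unique(pmax(1, round(raw / stride)) * stride)
}

.msd_one <- function(x, k) {
  n <- length(x)
  d <- x[(1 + k):n] - x[1:(n - k)]
  mean(d * d)
}

#' Mass-centre autocorrelation function g
#'
#' Mean squared displacement of the whole-chain centre of mass over lag
#' `dt`, averaged over all overlapping time origins:
#' `g(dt) = <(x(t) - x(t + dt))^2>`. With `use = "3d"` the squared
#' displacements of all three components are summed (in the channel the two
#' transverse components contribute only bounded fluctuations, so the x and
#' 3D variants agree within error at large lags).
#'
#' @param traj an `mc_trajectory` or a data frame with columns `t_E`,
#'   `x_cm` (and `y_cm`, `z_cm` for `use = "3d"`).
#' @param dt lag grid in t_E (multiples of the sampling stride); default a
#'   logarithmic grid up to a tenth of the trajectory span.
#' @param use `"x"` or `"3d"`.
#' @param per_decade grid density when `dt` is defaulted.
#' @return data frame with columns `dt`, `g`, `n_origins`.
#' @export
autocorr_g <- function(traj, dt = NULL, use = c("x", "3d"), per_decade = 20) {
  use <- match.arg(use)
  obs <- .obs_frame(traj)
  stride <- .uniform_stride(obs$t_E)
  span <- obs$t_E[nrow(obs)] - obs$t_E[1]
  if (is.null(dt)) dt <- log_dt_grid(stride, max(stride, span / 10), per_decade)
  if (any(dt %% stride != 0))
    stop("dt values must be multiples of the sampling stride (", stride, ")")
  if (any(dt > span)) stop("dt exceeds the trajectory span")
  ks <- as.integer(dt / stride)
  g <- vapply(ks, function(k) {
    v <- .msd_one(obs$x_cm, k)
    if (use == "3d") v <- v + .msd_one(obs$y_cm, k) + .msd_one(obs$z_cm, k)
    v
  }, numeric(1))
  data.frame(dt = dt, g = g, n_origins = nrow(obs) - ks)
}

#' Mean bead autocorrelation function g_B
#'
#' Per-bead mean squared longitudinal displacement over lag `dt`, averaged
#' over all time origins and over the beads of the selected block:
#' `g_B(dt) = (2/N) * sum_i <(x_i(t) - x_i(t + dt))^2>`. Beads are tracked
#' by monomer slot (index), consistent with the label-continuity rule under
#' reptation.
#'
#' @param bead_x integer/numeric matrix of unwrapped bead x positions, one
#'   row per recorded frame and one column per bead, as returned in
#'   `$bead_x` by [run_simulation]; or an `mc_trajectory` run with
#'   `bead_every > 0`.
#' @param stride sampling stride of the bead frames in t_E (taken from the
#'   trajectory config if one is supplied).
#' @param part `"P1"`, `"P2"`, or `"both"`.
#' @param dt lag grid; defaults as in [autocorr_g].
#' @param per_decade grid density when `dt` is defaulted.
#' @return data frame with columns `dt`, `gB`, `n_origins`.
#' @export
autocorr_gB <- function(bead_x, stride = NULL, part = c("P1", "P2", "both"),
                        dt = NULL, per_decade = 20) {
  part <- match.arg(part)
  if (inherits(bead_x, "mc_trajectory")) {
    if (is.null(bead_x$bead_x)) stop("trajectory has no bead records")
    stride <- bead_x$config$bead_every
    bead_x <- bead_x$bead_x
  }
  if (is.null(stride)) stop("stride must be given for a bare bead matrix")
  n <- nrow(bead_x)
  nb <- ncol(bead_x)
  cols <- switch(part, P1 = seq_len(nb %/% 2),
                 P2 = (nb %/% 2 + 1):nb, both = seq_len(nb))
  X <- bead_x[, cols, drop = FALSE]
  span <- (n - 1) * stride
  if (is.null(dt)) dt <- log_dt_grid(stride, max(stride, span / 10), per_decade)
  if (any(dt %% stride != 0) || any(dt > span))
    stop("dt values must be multiples of the stride and within the span")
  ks <- as.integer(dt / stride)
  gB <- vapply(ks, function(k) {
    d <- X[(1 + k):n, , drop = FALSE] - X[1:(n - k), , drop = FALSE]
    mean(d * d)
  }, numeric(1))
  data.frame(dt = dt, gB = gB, n_origins = n - ks)
}

#' Detect block swap events
#'
#' A swap is a reversal of the blocks' order along the channel. With the
#' default hysteresis definition, an event is recorded each time the series
#' enters the saturated state (`|x_P1 - x_P2| > delta`) of the sign opposite
#' to the previously held saturated state; brief excursions into the dead
#' band without a sign reversal are not events. `method = "crossing"` counts
#' plain sign changes of the (nonzero-sign) difference instead.
#'
#' @param traj an `mc_trajectory` or data frame with columns `t_E`, `x_P1`,
#'   `x_P2`.
#' @param delta dead band.
#' @param method `"hysteresis"` or `"crossing"`.
#' @return An object of class `swap_events`: list with `times` (t_E of each
#'   event), `periods` (differences of consecutive event times), `method`,
#'   and `span` (trajectory extent).
#' @export
detect_swaps <- function(traj, delta = 0.01, method = c("hysteresis", "crossing")) {
  method <- match.arg(method)
  obs <- .obs_frame(traj)
  d <- obs$x_P1 - obs$x_P2
  t <- obs$t_E
  s <- ifelse(d > delta, 1L, ifelse(d < -delta, -1L, 0L))
  times <- numeric(0)
  if (method == "hysteresis") {
    held <- 0L
    for (r in seq_along(s)) {
      if (s[r] != 0L) {
        if (held != 0L && s[r] != held) times <- c(times, t[r])
        held <- s[r]
      }
    }
  } else {
    sgn <- sign(d)
    nz <- which(sgn != 0)
    if (length(nz) > 1) {
      flips <- nz[-1][sgn[nz[-1]] != sgn[nz[-length(nz)]]]
      times <- t[flips]
    }
  }
  structure(list(times = times, periods = diff(times), method = method,
                 span = t[length(t)] - t[1]),
            class = "swap_events")
}

#' @export
print.swap_events <- function(x, ...) {
  cat(sprintf("<swap_events> %d events (%s) over span %g t_E\n",
              length(x$times), x$method, x$span))
  invisible(x)
}

#' Probability density of inter-swap periods on a log scale
#'
#' Histogram of `log10(period)` with unit total mass, optionally with a
#' 3-component Gaussian mixture fitted to the log10 periods (equivalently, a
#' log-normal mixture of the periods) whose component means estimate the
#' three characteristic swap modes: single-monomer fluctuations, blob-scale
#' rearrangements, and whole-block exchanges.
#'
#' @param events a `swap_events` object or a numeric vector of periods.
#' @param n_bins number of histogram bins.
#' @param fit_modes fit the mixture? (requires enough events; the mixture is
#'   fitted by EM via \pkg{mclust} with unequal variances)
#' @param k number of mixture components.
#' @return list with `mids`, `breaks`, `mass` (sums to 1), `density`
#'   (per unit log10), `modes` (component means in log10 period, sorted;
#'   `NULL` when not fitted), `weights`, and `periods`.
#' @export
swap_period_density <- function(events, n_bins = 40, fit_modes = TRUE, k = 3) {
  periods <- if (inherits(events, "swap_events")) events$periods else events
  periods <- periods[is.finite(periods) & periods > 0]
  if (length(periods) < 1) stop("no swap periods to analyse")
  lp <- log10(periods)
  rng <- range(lp)
  if (diff(rng) == 0) {          # degenerate: all periods equal
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
    return(list(mids = rng[1], breaks = breaks, mass = 1,
                density = 1 / diff(breaks), modes = rng[1], weights = 1,
                periods = periods))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(lp, breaks = breaks, plot = FALSE)
  mass <- h$counts / sum(h$counts)
  out <- list(mids = h$mids, breaks = breaks, mass = mass,
              density = mass / diff(breaks), modes = NULL, weights = NULL,
              periods = periods)
  if (fit_modes && length(periods) >= 10 * k) {
    fit <- NULL
    for (mn in c("V", "E")) {
      fit <- tryCatch(Mclust(lp, G = k, modelNames = mn, verbose = FALSE),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (!is.null(fit)) {
      ord <- order(fit$parameters$mean)
      out$modes <- unname(fit$parameters$mean[ord])
      out$weights <- unname(fit$parameters$pro[ord])
    } else {
      # heavily tied samples (finite recording cadence) can defeat the EM;
      # fall back to k-means centres as robust mode locations
      km <- stats::kmeans(lp, centers = k, nstart = 10)
      ord <- order(km$centers)
      out$modes <- as.numeric(km$centers[ord])
      out$weights <- as.numeric(km$size[ord] / length(lp))
    }
  }
  out
}
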