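#' Free-energy force profile along the channel
#'
#' Bins a trajectory's Helmholtz free energy by an unwrapped longitudinal
#' coordinate, averages A within each bin, and differentiates the binned
#' means by central finite differences over the occupied bin centres:
#' `F = dA/dx` (the printed sign convention; `sign = "mechanics"` flips it).
#' Sub-lattice bins below 0.5 are not meaningful because the mass centre is
#' quantised at resolution 1/N.
#'
#' @param traj an `mc_trajectory` or data frame.
#' @param coord name of the x column to bin on (`"x_cm"`, `"x_P1"`,
#'   `"x_P2"`).
#' @param energy_col name of the free-energy column (`"A"`, `"A_P1"`,
#'   `"A_P2"`).
#' @param bin_width bin width in lattice units.
#' @param sign `"printed"` (`F = +dA/dx`) or `"mechanics"` (`F = -dA/dx`).
#' @return data frame with columns `x` (bin centre), `A` (bin mean), `n`
#'   (rows in bin), `F` (NA at the two edge bins).
#' @export
force_profile <- function(traj, coord = "x_cm", energy_col = "A",
                          bin_width = 0.5, sign = c("printed", "mechanics")) {
  sign <- match.arg(sign)
  obs <- .obs_frame(traj)
  x <- obs[[coord]]
  A <- obs[[energy_col]]
  keep <- is.finite(x) & is.finite(A)
  x <- x[keep]; A <- A[keep]
  bin <- floor(x / bin_width)
  centres <- (sort(unique(bin)) + 0.5) * bin_width
  means <- tapply(A, bin, mean)
  n <- tapply(A, bin, length)
  if (length(centres) < 3)
    stop("force_profile needs at least 3 occupied bins (got ",
         length(centres), ")")
  m <- length(centres)
  F <- rep(NA_real_, m)
  F[2:(m - 1)] <- (means[3:m] - means[1:(m - 2)]) /
    (centres[3:m] - centres[1:(m - 2)])
  if (sign == "mechanics") F <- -F
  data.frame(x = centres, A = as.numeric(means), n = as.integer(n), F = F,
             row.names = NULL)
}

#' Force time series from a binned profile
#'
#' Evaluates a [force_profile] at the trajectory's recorded positions by
#' linear interpolation, giving F at recorded times for [impulse].
#'
#' @param traj an `mc_trajectory` or data frame.
#' @param profile result of [force_profile].
#' @param coord x column matching the profile.
#' @return data frame with columns `t_E`, `F`.
#' @export
force_series <- function(traj, profile, coord = "x_cm") {
  obs <- .obs_frame(traj)
  ok <- is.finite(profile$F)
  F <- approx(profile$x[ok], profile$F[ok], xout = obs[[coord]],
              rule = 2)$y
  data.frame(t_E = obs$t_E, F = F)
}

.trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

#' Force impulse over a time window
#'
#' Trapezoidal integral of the force over `[t_start, t_start + window]`. The
#' printed prefactor convention divides by the absolute window start
#' (`I = (1/t) integral F dt`, which makes I depend on the time origin); the
#' alternative `"window"` normalisation divides by the window length,
#' yielding the mean force.
#'
#' @param t,F force series (times in t_E and force values).
#' @param t_start window start time.
#' @param window window length in t_E.
#' @param normalization `"printed"` (1/t_start) or `"window"` (1/window).
#' @return numeric scalar.
#' @export
impulse <- function(t, F, t_start, window,
                    normalization = c("printed", "window")) {
  normalization <- match.arg(normalization)
  if (t_start + window > max(t) || t_start < min(t))
    stop("impulse window exceeds the available samples")
  keep <- t >= t_start & t <= t_start + window
  if (sum(keep) < 2) stop("impulse window contains fewer than 2 samples")
  val <- .trapz(t[keep], F[keep])
  if (normalization == "printed") val / t_start else val / window
}

#' Cumulative impulse curve
#'
#' Impulse with a sliding window end: `I(t') = (1/t_start) integral from
#' t_start to t'` for every recorded `t' > t_start`, for plotting the
#' cumulative push exerted by each block around a swap episode.
#'
#' @inheritParams impulse
#' @return data frame with columns `t_E`, `I`.
#' @export
impulse_curve <- function(t, F, t_start,
                          normalization = c("printed", "window")) {
  normalization <- match.arg(normalization)
  keep <- which(t >= t_start)
  if (length(keep) < 2) stop("not enough samples beyond t_start")
  tt <- t[keep]; FF <- F[keep]
  inc <- diff(tt) * (FF[-1] + FF[-length(FF)]) / 2
  I <- c(0, cumsum(inc))
  norm <- if (normalization == "printed") t_start else pmax(tt - t_start, 1)
  data.frame(t_E = tt, I = I / norm)
}
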