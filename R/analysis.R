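#' Fit an anomalous-diffusion exponent on a log-log window
#'
#' Ordinary least squares of `log10 g` on `log10 dt` restricted to a lag
#' window. The slope is the anomalous-diffusion exponent nu of
#' `<r^2> ~ t^nu` (1 diffusive, <1 subdiffusive, >1 superdiffusive,
#' 2 ballistic).
#'
#' @param curve data frame with columns `dt` and `g` (or `gB`).
#' @param window numeric length-2, lag window `[lo, hi]`; default the whole
#'   curve.
#' @return An object of class `scaling_fit`: list with `nu`, `stderr`,
#'   `window`, `r2`, `n`.
#' @export
fit_exponent <- function(curve, window = NULL) {
  gcol <- if ("g" %in% names(curve)) "g" else "gB"
  dt <- curve$dt
  g <- curve[[gcol]]
  if (is.null(window)) window <- range(dt)
  keep <- dt >= window[1] & dt <= window[2] & is.finite(g)
  if (sum(keep) < 5)
    stop("fit_exponent needs at least 5 curve points inside the window")
  if (any(g[keep] <= 0))
    stop("fit_exponent requires positive g values inside the window")
  fit <- lm(log10(g[keep]) ~ log10(dt[keep]))
  sm <- summary(fit)
  structure(list(nu = unname(coef(fit)[2]),
                 stderr = sm$coefficients[2, 2],
                 window = window, r2 = sm$r.squared, n = sum(keep)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> nu = %.4f +/- %.4f over dt in [%g, %g] (n = %d, R2 = %.4f)\n",
              x$nu, x$stderr, x$window[1], x$window[2], x$n, x$r2))
  invisible(x)
}

#' Segment an autocorrelation curve into scaling regimes
#'
#' Computes local log-log slopes over sliding half-decade windows centred on
#' each curve point, merges contiguous points whose local slope stays within
#' `slope_tol` of the running regime mean, and refits each merged regime by
#' pooled OLS. Crossover stretches shorter than `min_span` decades are
#' dropped, so the result is the ordered list of genuine scaling regimes.
#' Slopes are unaffected by multiplicative rescaling of g.
#'
#' @param curve data frame with columns `dt` and `g` (or `gB`), positive g.
#' @param slope_tol merge tolerance on the local slope.
#' @param window_decades width (in decades of dt) of the local-slope window.
#' @param min_span minimum regime width in decades.
#' @return list of `scaling_fit` objects, ordered by lag window.
#' @export
segment_regimes <- function(curve, slope_tol = 0.15, window_decades = 0.5,
                            min_span = 0.3) {
  gcol <- if ("g" %in% names(curve)) "g" else "gB"
  keep <- is.finite(curve[[gcol]]) & curve[[gcol]] > 0
  ld <- log10(curve$dt[keep])
  lg <- log10(curve[[gcol]][keep])
  if (diff(range(ld)) < 1.5)
    stop("curve must span at least 1.5 decades in dt to segment regimes")
  np <- length(ld)
  local <- rep(NA_real_, np)
  hw <- window_decades / 2
  for (i in seq_len(np)) {
    w <- which(abs(ld - ld[i]) <= hw)
    if (length(w) >= 3)
      local[i] <- coef(lm(lg[w] ~ ld[w]))[2]
  }
  ok <- which(is.finite(local))
  if (length(ok) < 3) stop("too few points with defined local slopes")
  # greedy merge of contiguous points into constant-slope runs
  runs <- list()
  start <- ok[1]; acc <- local[ok[1]]
  prev <- ok[1]
  for (i in ok[-1]) {
    if (abs(local[i] - mean(acc)) <= slope_tol) {
      acc <- c(acc, local[i]); prev <- i
    } else {
      runs[[length(runs) + 1]] <- c(start, prev)
      start <- i; acc <- local[i]; prev <- i
    }
  }
  runs[[length(runs) + 1]] <- c(start, prev)
  fits <- list()
  for (r in runs) {
    lo <- curve$dt[keep][r[1]]; hi <- curve$dt[keep][r[2]]
    if (log10(hi / lo) < min_span) next
    fits[[length(fits) + 1]] <- fit_exponent(curve, c(lo, hi))
  }
  if (length(fits) == 0)
    stop("no regime wider than ", min_span, " decades found")
  fits
}

#' Ensemble-averaged autocorrelation curves
#'
#' Runs `length(seeds)` independent replicas of one configuration and
#' averages their g (and optionally g_B) curves pointwise on a common
#' logarithmic lag grid. Averaging before fitting suppresses the
#' origin-correlation noise of single trajectories.
#'
#' @param config a [run_config]; set `bead_every > 0` to get g_B curves.
#' @param seeds integer vector of RNG seeds, one per replica.
#' @param dt optional common lag grid for g.
#' @param per_decade grid density when `dt` is defaulted.
#' @return list with `g` (data frame `dt`, `g`), `gB_P1`, `gB_P2`
#'   (or NULL), and `n_seeds`.
#' @export
run_ensemble <- function(config, seeds, dt = NULL, per_decade = 20) {
  gs <- NULL; g1 <- NULL; g2 <- NULL
  for (s in seeds) {
    traj <- run_simulation(config, seed = s)
    cg <- autocorr_g(traj, dt = dt, per_decade = per_decade)
    if (is.null(dt)) dt <- cg$dt
    gs <- cbind(gs, cg$g)
    if (config$bead_every > 0) {
      b1 <- autocorr_gB(traj, part = "P1", per_decade = per_decade)
      b2 <- autocorr_gB(traj, part = "P2", per_decade = per_decade)
      g1 <- cbind(g1, b1$gB)
      g2 <- cbind(g2, b2$gB)
      dtB <- b1$dt
    }
    rm(traj)
  }
  out <- list(g = data.frame(dt = dt, g = rowMeans(gs)),
              gB_P1 = NULL, gB_P2 = NULL, n_seeds = length(seeds))
  if (!is.null(g1)) {
    out$gB_P1 <- data.frame(dt = dtB, gB = rowMeans(g1))
    out$gB_P2 <- data.frame(dt = dtB, gB = rowMeans(g2))
  }
  out
}

#' Multi-condition sweep
#'
#' Runs each configuration (one per condition, e.g. a range of channel
#' widths D or chain lengths N) over a set of seeds and extracts, per
#' condition, the intermediate-regime exponent and/or the swap-period
#' mixture modes (periods pooled across the condition's seeds).
#'
#' @param configs named list of [run_config] objects; names identify the
#'   conditions.
#' @param seeds seeds used for every condition.
#' @param measure any of `"exponent"`, `"swap_modes"`.
#' @param swap_method swap detection method, see [detect_swaps].
#' @return An object of class `sweep_result`: data frame with one row per
#'   condition (columns `condition`, and per measure `nu_intermediate`,
#'   `mode1`, `mode2`, `mode3` in log10 t_E, `n_events`), with the per-
#'   condition detail in `attr(, "detail")`. Conditions that fail keep an
#'   NA row and a warning.
#' @export
sweep_conditions <- function(configs, seeds,
                             measure = c("exponent", "swap_modes"),
                             swap_method = "hysteresis") {
  measure <- match.arg(measure, several.ok = TRUE)
  rows <- list()
  detail <- list()
  for (nm in names(configs)) {
    row <- list(condition = nm, nu_intermediate = NA_real_,
                mode1 = NA_real_, mode2 = NA_real_, mode3 = NA_real_,
                n_events = NA_integer_)
    det <- list()
    res <- tryCatch({
      cfg <- configs[[nm]]
      periods <- numeric(0)
      gs <- NULL; dt <- NULL
      for (s in seeds) {
        traj <- run_simulation(cfg, seed = s)
        if ("swap_modes" %in% measure) {
          ev <- detect_swaps(traj, delta = cfg$delta, method = swap_method)
          periods <- c(periods, ev$periods)
        }
        if ("exponent" %in% measure) {
          cg <- autocorr_g(traj, dt = dt)
          if (is.null(dt)) dt <- cg$dt
          gs <- cbind(gs, cg$g)
        }
      }
      if ("exponent" %in% measure) {
        curve <- data.frame(dt = dt, g = rowMeans(gs))
        regs <- segment_regimes(curve)
        det$regimes <- regs
        det$curve <- curve
        # the intermediate regime: steepest regime strictly inside the curve
        nus <- vapply(regs, function(f) f$nu, numeric(1))
        mid <- if (length(regs) >= 3) regs[2:(length(regs) - 1)] else regs
        row$nu_intermediate <- max(vapply(mid, function(f) f$nu, numeric(1)))
        det$all_nu <- nus
      }
      if ("swap_modes" %in% measure) {
        dens <- swap_period_density(periods)
        det$density <- dens
        row$n_events <- length(periods)
        if (!is.null(dens$modes) && length(dens$modes) == 3) {
          row$mode1 <- dens$modes[1]
          row$mode2 <- dens$modes[2]
          row$mode3 <- dens$modes[3]
        }
      }
      TRUE
    }, error = function(e) {
      warning("condition ", nm, " failed: ", conditionMessage(e))
      FALSE
    })
    rows[[nm]] <- as.data.frame(row)
    detail[[nm]] <- det
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "detail") <- detail
  class(out) <- c("sweep_result", class(out))
  out
}

#' Width scaling of the second swap mode
#'
#' OLS slope of `log10(mode-2 period)` against `log10(D)` over a sweep of
#' channel widths: how the blob-scale swap time scales with confinement.
#'
#' @param D numeric vector of channel widths, or a `sweep_result` whose
#'   conditions are widths.
#' @param mode2 second-mode positions; either periods (t_E) or log10
#'   periods (set `log_input = TRUE`, the `sweep_result` default).
#' @param log_input are `mode2` values already log10?
#' @return list with `slope`, `stderr`, `n`.
#' @export
swap_mode_power <- function(D, mode2 = NULL, log_input = FALSE) {
  if (inherits(D, "sweep_result")) {
    mode2 <- D$mode2
    log_input <- TRUE
    D <- as.numeric(D$condition)
  }
  keep <- is.finite(D) & is.finite(mode2)
  if (sum(keep) < 3)
    stop("swap_mode_power needs mode-2 positions for at least 3 widths")
  y <- if (log_input) mode2[keep] else log10(mode2[keep])
  fit <- lm(y ~ log10(D[keep]))
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), stderr = sm$coefficients[2, 2],
       n = sum(keep))
}
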