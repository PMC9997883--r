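split_tracks <- function(tracks) {
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(tracks)))
  split(tracks[, c("t", "x", "y")], tracks$track_id)
}

track_interval <- function(tr) {
  dt <- diff(tr$t)
  if (length(dt) == 0) stop("track has fewer than 2 points")
  if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1))) {
    stop("track time spacing is not uniform")
  }
  dt[1]
}

#' Step-based instantaneous speeds
#'
#' Euclidean displacement between consecutive logged positions divided by
#' the logging interval, one value per step. The mean of this distribution
#' is the conventional "mean speed" of a track.
#'
#' @param track Data frame with `t`, `x`, `y` (single track, >= 2 points).
#' @return Numeric vector of speeds (pixels per time unit).
#' @export
step_speeds <- function(track) {
  dt <- track_interval(track)
  sqrt(diff(track$x)^2 + diff(track$y)^2) / dt
}

#' Mean squared displacement curve with independence weights
#'
#' MSD(dt) is the mean over all (overlapping) displacements of squared
#' displacement, pooled across tracks. Overlapping displacements are not
#' independent: a track of `n` steps holds `n` displacements at lag 1 but
#' effectively only `floor(n / lag)` independent ones at larger lags, so
#' each curve point also carries `weight = sum over tracks of
#' floor(n_track / lag)` for use in weighted fitting.
#'
#' @param tracks Data frame with `track_id`, `t`, `x`, `y`.
#' @return Data frame with `dt` (time units), `msd` (pixels^2), `weight`.
#' @export
msd_curve <- function(tracks) {
  trs <- split_tracks(tracks)
  interval <- track_interval(trs[[1]])
  max_lag <- max(vapply(trs, nrow, 0L)) - 1L
  sums <- numeric(max_lag)
  counts <- numeric(max_lag)
  weights <- numeric(max_lag)
  for (tr in trs) {
    n <- nrow(tr) - 1L  # steps
    for (lag in seq_len(n)) {
      dx <- tr$x[(lag + 1):(n + 1)] - tr$x[1:(n + 1 - lag)]
      dy <- tr$y[(lag + 1):(n + 1)] - tr$y[1:(n + 1 - lag)]
      sums[lag] <- sums[lag] + sum(dx^2 + dy^2)
      counts[lag] <- counts[lag] + length(dx)
      weights[lag] <- weights[lag] + floor(n / lag)
    }
  }
  keep <- counts > 0
  data.frame(dt = seq_len(max_lag)[keep] * interval,
             msd = sums[keep] / counts[keep],
             weight = weights[keep])
}

furth_msd <- function(dt, D, P) 4 * D * (dt - P * (1 - exp(-dt / P)))

# Levenberg-Marquardt least squares with box constraints; returns the
# parameter vector plus a convergence flag. `resid_fun(par)` returns
# residuals already multiplied by sqrt(weight).
lm_fit <- function(resid_fun, start, lower) {
  res <- minpack.lm::nls.lm(par = start, fn = resid_fun, lower = lower,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  list(par = res$par, converged = res$info %in% 1:4)
}

#' Fit the persistent-random-walk (Fuerth) MSD model
#'
#' Fits `MSD(dt) = 4 D (dt - P (1 - exp(-dt / P)))` in two stages. Lattice
#' cells barely move at time scales below their persistence time, so the
#' smallest lags deviate from this continuous model; a rough first fit on
#' all points yields order-of-magnitude estimates `(D0, P0)`, after which
#' the final fit uses only lags `dt >= P0`, on a log scale (fitting
#' `ln D` rather than `D`), weighted by the number of independent
#' displacements per point. Both stages use the independence weights.
#'
#' @param curve Data frame from [msd_curve()] (or [make_furth_msd()]):
#'   `dt`, `msd`, `weight` (weight defaults to 1 if absent).
#' @param max_lag_frac Fraction of the largest available lag beyond which
#'   points are discarded before fitting. At lags beyond a quarter of the
#'   track length fewer than four independent displacements remain per
#'   track, and their strongly correlated noise otherwise pulls the fit
#'   around; the default 0.25 removes them.
#' @return List of class `furth_fit` with `D`, `P`, stage-1 `D0`, `P0`,
#'   the fitted lag `window`, and `converged` (when the final fit fails,
#'   stage-1 values are retained and flagged).
#' @export
fit_furth <- function(curve, max_lag_frac = 0.25) {
  if (is.null(curve$weight)) curve$weight <- rep(1, nrow(curve))
  curve <- curve[curve$dt > 0 & curve$msd > 0, ]
  curve <- curve[curve$dt <= max_lag_frac * max(curve$dt), ]
  interval <- min(curve$dt)
  # stage 1: rough weighted fit over all retained lags, on the log scale
  # (the scale the curve is judged on throughout); only needs to land in
  # the right order of magnitude. Persistence below one logging interval
  # is not resolvable on this sampling, so the fit is bounded there.
  w1 <- sqrt(curve$weight / mean(curve$weight))
  stage1 <- lm_fit(
    function(p) {
      arg <- furth_msd(curve$dt, exp(p[["logD"]]), p[["P"]])
      w1 * ifelse(arg > 0, log(curve$msd) - log(arg), 0)
    },
    start = c(logD = log(max(curve$msd) / (4 * max(curve$dt))),
              P = 10 * interval),
    lower = c(logD = -700, P = interval))
  D0 <- exp(stage1$par[["logD"]])
  P0 <- stage1$par[["P"]]
  final <- curve[curve$dt >= P0, ]
  if (nrow(final) < 5) {
    warning("fewer than 5 lags beyond P0; retaining stage-1 estimates")
    return(structure(list(D = D0, P = P0, D0 = D0, P0 = P0,
                          window = range(curve$dt), converged = FALSE),
                     class = "furth_fit"))
  }
  # stage 2: weighted log-scale fit of ln D and P on lags >= P0, where the
  # cell is actually moving (lags with a non-positive model argument under
  # trial parameters are dropped from that iteration's objective)
  w2 <- sqrt(final$weight / mean(final$weight))
  stage2 <- lm_fit(
    function(p) {
      arg <- furth_msd(final$dt, exp(p[["logD"]]), p[["P"]])
      w2 * ifelse(arg > 0, log(final$msd) - log(arg), 0)
    },
    start = c(logD = log(D0), P = max(P0, interval)),
    lower = c(logD = -700, P = interval / 10))
  if (!stage2$converged) {
    warning("final MSD fit did not converge; retaining stage-1 estimates")
    return(structure(list(D = D0, P = P0, D0 = D0, P0 = P0,
                          window = range(curve$dt), converged = FALSE),
                     class = "furth_fit"))
  }
  structure(list(D = exp(stage2$par[["logD"]]), P = stage2$par[["P"]],
                 D0 = D0, P0 = P0, window = range(final$dt),
                 converged = TRUE),
            class = "furth_fit")
}

#' @export
print.furth_fit <- function(x, ...) {
  cat(sprintf("Fuerth fit: D = %.4g, P = %.4g (stage 1: D0 = %.3g, P0 = %.3g; lags %g..%g%s)\n",
              x$D, x$P, x$D0, x$P0, x$window[1], x$window[2],
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' Step-vector autocovariance curve
#'
#' `autocov(dt)` is the mean dot product of step displacement vectors
#' separated by `dt`, pooled across tracks (lag 0 gives the mean squared
#' step length). For a persistent random walk it decays exponentially with
#' time constant equal to the persistence time.
#'
#' @param tracks Data frame with `track_id`, `t`, `x`, `y` (tracks need
#'   >= 3 points).
#' @return Data frame with `dt` and `autocov`.
#' @export
autocov_curve <- function(tracks) {
  trs <- split_tracks(tracks)
  interval <- track_interval(trs[[1]])
  max_lag <- max(vapply(trs, nrow, 0L)) - 2L
  if (max_lag < 0) stop("tracks need at least 3 points")
  sums <- numeric(max_lag + 1)
  counts <- numeric(max_lag + 1)
  for (tr in trs) {
    dx <- diff(tr$x)
    dy <- diff(tr$y)
    m <- length(dx)
    for (lag in 0:(m - 1)) {
      i <- seq_len(m - lag)
      sums[lag + 1] <- sums[lag + 1] +
        sum(dx[i] * dx[i + lag] + dy[i] * dy[i + lag])
      counts[lag + 1] <- counts[lag + 1] + (m - lag)
    }
  }
  keep <- counts > 0
  data.frame(dt = (0:max_lag)[keep] * interval,
             autocov = sums[keep] / counts[keep])
}

#' Fit an exponential decay to the autocovariance
#'
#' Fits `autocov(dt) = c * exp(-dt / P)` on a window chosen to avoid two
#' artefacts: lags below `0.5 * P_msd` are dropped (lattice cells do not
#' truly move at scales far below their persistence time), and lags beyond
#' `3 * t_5pct` are dropped, where `t_5pct` is the smallest retained lag
#' at which the autocovariance falls below 5% of the curve's initial value
#' (beyond that the curve is just noise around 0, which would dominate the
#' fit). The decay constant is fitted as `P^2` so the optimiser cannot
#' wander into negative persistence; the starting point is `(c = 1,
#' Psq = P_msd^2)`.
#'
#' @param curve Data frame with `dt`, `autocov` (from [autocov_curve()] or
#'   [make_exp_autocov()]).
#' @param P_msd Persistence estimate from the MSD fit (time units), > 0.
#' @return List of class `autocov_fit` with amplitude `c`, persistence
#'   `P`, `t_5pct` (NA when the curve never decays below threshold; the
#'   window then stays open and the fit is flagged), the fitted `window`
#'   and `converged`.
#' @export
fit_autocov <- function(curve, P_msd) {
  stopifnot(P_msd > 0, nrow(curve) > 0)
  initial <- curve$autocov[which.min(curve$dt)]
  kept <- curve[curve$dt > 0.5 * P_msd, ]
  if (nrow(kept) == 0) stop("no lags beyond 0.5 * P_msd")
  below <- kept$dt[kept$autocov < 0.05 * initial]
  t5 <- if (length(below) > 0) min(below) else NA_real_
  open_window <- is.na(t5)
  if (!open_window) kept <- kept[kept$dt < 3 * t5, ]
  if (nrow(kept) < 3) {
    warning("too few lags in the autocovariance window")
    return(structure(list(c = NA_real_, P = NA_real_, t_5pct = t5,
                          window = range(kept$dt), converged = FALSE),
                     class = "autocov_fit"))
  }
  fit <- lm_fit(
    function(p) kept$autocov - p[["c0"]] * exp(-kept$dt / sqrt(p[["Psq"]])),
    start = c(c0 = 1, Psq = P_msd^2),
    lower = c(c0 = 1e-300, Psq = 1e-12))
  structure(list(c = fit$par[["c0"]], P = sqrt(fit$par[["Psq"]]),
                 t_5pct = t5, window = range(kept$dt),
                 converged = fit$converged && !open_window),
            class = "autocov_fit")
}

#' @export
print.autocov_fit <- function(x, ...) {
  cat(sprintf("Autocovariance fit: c = %.4g, P = %.4g (t_5%% = %g, lags %g..%g%s)\n",
              x$c, x$P, x$t_5pct, x$window[1], x$window[2],
              if (x$converged) "" else "; flagged"))
  invisible(x)
}

#' Grouped speed and persistence estimates
#'
#' Splits the tracks (in simulation order) into `n_groups` groups of
#' `group_size` and computes, per group, the mean step-based speed, the
#' MSD/Fuerth persistence and the autocovariance persistence, yielding
#' independent replicate estimates whose mean and SD are reported.
#'
#' @param tracks Data frame with `track_id`, `t`, `x`, `y`; the number of
#'   distinct tracks must equal `n_groups * group_size`.
#' @param n_groups,group_size Grouping (default 6 groups of 5).
#' @return List with `groups` (per-group estimates) and `summary` (mean
#'   and SD per statistic over groups).
#' @export
grouped_estimates <- function(tracks, n_groups = 6, group_size = 5) {
  ids <- unique(tracks$track_id)
  if (length(ids) != n_groups * group_size) {
    stop("expected ", n_groups * group_size, " tracks, got ", length(ids))
  }
  grp <- rep(seq_len(n_groups), each = group_size)
  rows <- lapply(seq_len(n_groups), function(g) {
    sub <- tracks[tracks$track_id %in% ids[grp == g], ]
    speeds <- unlist(lapply(split_tracks(sub), function(tr) {
      step_speeds(data.frame(t = tr$t, x = tr$x, y = tr$y))
    }))
    msd_fit <- fit_furth(msd_curve(sub))
    ac_fit <- fit_autocov(autocov_curve(sub), msd_fit$P)
    data.frame(group = g, mean_speed = mean(speeds),
               persistence_msd = msd_fit$P,
               persistence_autocov = ac_fit$P)
  })
  groups <- do.call(rbind, rows)
  stats <- c("mean_speed", "persistence_msd", "persistence_autocov")
  summary <- data.frame(
    statistic = stats,
    mean = vapply(groups[stats], mean, 0),
    sd = vapply(groups[stats], sd, 0))
  rownames(summary) <- NULL
  list(groups = groups, summary = summary)
}
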