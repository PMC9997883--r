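# Generators with known ground truth, so every analysis stage can be
# validated without running the full lattice model.

#' Noiseless persistent-random-walk MSD curve
#'
#' Evaluates `MSD(dt) = 4 D (dt - P (1 - exp(-dt / P)))` at the given
#' lags, with independence weights mimicking a track of `n_steps` steps
#' (`floor(n_steps / lag)` per lag).
#'
#' @param D Diffusion coefficient (pixels^2 per time unit), > 0.
#' @param P Persistence time (time units), > 0.
#' @param lags Lag times (> 0).
#' @param n_steps Pretended track length in steps (for the weights).
#' @return Data frame `dt, msd, weight` as from [msd_curve()].
#' @export
make_furth_msd <- function(D, P, lags, n_steps = max(lags)) {
  stopifnot(D > 0, P > 0, all(lags >= 0))
  lags <- lags[lags > 0]
  interval <- min(lags)
  data.frame(dt = lags,
             msd = furth_msd(lags, D, P),
             weight = pmax(floor(n_steps / (lags / interval)), 1))
}

#' Noiseless exponential autocovariance curve
#'
#' `autocov(dt) = c * exp(-dt / P)`.
#'
#' @param c0 Amplitude, > 0.
#' @param P Persistence time, > 0.
#' @param lags Lag times (>= 0).
#' @return Data frame `dt, autocov` as from [autocov_curve()].
#' @export
make_exp_autocov <- function(c0, P, lags) {
  stopifnot(c0 > 0, P > 0)
  data.frame(dt = lags, autocov = c0 * exp(-lags / P))
}

#' Generate persistent random walk tracks with known speed and persistence
#'
#' Angular-diffusion walk: the heading angle performs a Gaussian random
#' walk with per-step variance `2 * interval / persistence`, which makes
#' the step-vector autocovariance decay as `exp(-dt / persistence)`
#' (E[cos(theta_k - theta_0)] = exp(-k sigma^2 / 2)); the step length is
#' exactly `speed * interval`. This gives ground-truth ensembles for the
#' speed, MSD and autocovariance estimators. The calibration is itself
#' verified by test, not assumed.
#'
#' @param speed Step speed (pixels per time unit), > 0.
#' @param persistence Persistence time (time units), > 0.
#' @param n_steps Steps per track.
#' @param n_tracks Number of tracks.
#' @param interval Time per step.
#' @param seed Integer seed.
#' @return Data frame `track_id, t, x, y`.
#' @export
make_prw_tracks <- function(speed, persistence, n_steps = 2000,
                            n_tracks = 30, interval = 1, seed = NULL) {
  stopifnot(speed > 0, persistence > 0)
  with_seed(seed, {
    out <- lapply(seq_len(n_tracks), function(id) {
      theta <- cumsum(c(runif(1, 0, 2 * pi),
                        rnorm(n_steps - 1, 0,
                              sqrt(2 * interval / persistence))))
      step <- speed * interval
      data.frame(track_id = id,
                 t = (0:n_steps) * interval,
                 x = c(0, cumsum(step * cos(theta))),
                 y = c(0, cumsum(step * sin(theta))))
    })
    do.call(rbind, out)
  })
}

#' Small deterministic lattice fixtures
#'
#' Hand-built states for exercising the Hamiltonian and connectedness
#' code: a single square cell, two touching cells, a cell split into two
#' equal components, and a cell straddling the periodic boundary. All are
#' byte-identical across calls.
#'
#' @return Named list of `cpm_state` objects (`single_square`,
#'   `two_cells`, `split_cell`, `boundary_cell`).
#' @export
make_toy_lattices <- function() {
  mk <- function(w, h, fill, cells) {
    st <- lattice_state(w, h)
    st$cells <- cells
    for (i in seq_along(fill)) st$identity[fill[[i]]] <- as.integer(i)
    st
  }
  one_cell <- data.frame(id = 1L, type = 1L, V_target = 9, lambda_V = 30,
                         P_target = 24, lambda_P = 2, max_act = 20,
                         lambda_act = 100)
  two_cell <- rbind(one_cell, transform(one_cell, id = 2L))
  sq <- function(xs, ys) as.matrix(expand.grid(x = xs, y = ys))
  list(
    single_square = mk(8, 8, list(sq(3:5, 3:5)), one_cell),
    two_cells = mk(10, 8, list(sq(2:4, 3:5), sq(5:7, 3:5)), two_cell),
    split_cell = mk(10, 8, list(rbind(sq(2:3, 3:4), sq(7:8, 3:4))),
                    transform(one_cell, V_target = 8)),
    boundary_cell = mk(8, 8, list(rbind(sq(c(8, 1), 3:5), sq(2, 3:5))),
                       one_cell)
  )
}
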