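draw_seed <- function(seed = NULL) {
  if (is.null(seed)) sample.int(.Machine$integer.max, 1) else as.numeric(seed)
}

#' Advance a lattice state by whole Monte Carlo steps
#'
#' One MCS consists of `width * height` copy attempts (each sampling a
#' uniform source pixel and a uniform Moore neighbour as target), followed
#' by a decay of every positive activity value by 1 (floored at 0). Runs in
#' compiled code; the attempt-level rules are identical to [attempt_copy()].
#'
#' @param state A `cpm_state`.
#' @param params A `cpm_params`.
#' @param n_mcs Number of Monte Carlo steps.
#' @param seed Integer seed for the kernel RNG; when `NULL`, one is drawn
#'   from R's RNG (so `set.seed()` upstream makes the run reproducible).
#' @param track_cell Cell id whose centroid/exploration to log, or 0 for
#'   none.
#' @param log_interval Centroid logging interval in MCS.
#' @param log_connectedness Evaluate the tracked cell's connectedness at
#'   every log point.
#' @return List with elements `state` (the advanced `cpm_state`), `track`
#'   (matrix `t, x, y` of torus-unwrapped centroids; empty when
#'   `track_cell = 0`), `explored` (count of pixels the tracked cell ever
#'   occupied), `connectedness` (per-log-point values),
#'   `min_connectedness`, `annihilated` (did the tracked cell lose its last
#'   pixel), and `annihilated_ids` (any cells that vanished).
#' @export
advance_state <- function(state, params, n_mcs, seed = NULL, track_cell = 0,
                          log_interval = 5, log_connectedness = FALSE) {
  res <- cpm_run_kernel(state$identity, state$activity,
                        cell_param_matrix(state), params$adhesion,
                        params$temperature, as.integer(n_mcs),
                        draw_seed(seed), as.integer(track_cell),
                        as.integer(log_interval), log_connectedness)
  state$identity <- res$identity
  state$activity <- res$activity
  list(state = state,
       track = res$track,
       explored = res$explored,
       connectedness = res$connectedness,
       min_connectedness = res$min_connectedness,
       annihilated = res$annihilated,
       annihilated_ids = res$annihilated_ids,
       volumes = res$volumes,
       perimeters = res$perimeters)
}

#' @rdname advance_state
#' @export
mcs_step <- function(state, params, seed = NULL) {
  advance_state(state, params, n_mcs = 1, seed = seed)$state
}
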