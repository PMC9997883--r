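#' Run-and-pause model parameters
#'
#' The constraint-free reference model of T-cell migration: circles that
#' alternate straight "runs" of duration `t_free` at speed `v_free` with
#' stationary pauses of duration `t_pause`, drawing a fresh uniform
#' direction at the start of every run. Unlike the Act-CPM, these
#' parameters map directly onto speed and persistence.
#'
#' @param v_free Run speed (pixels per time step), > 0.
#' @param t_free Run duration (time steps), > 0.
#' @param t_pause Pause duration (time steps), > 0.
#' @return Named numeric vector of class `beauchemin_params`.
#' @export
beauchemin_params <- function(v_free, t_free, t_pause) {
  stopifnot(v_free > 0, t_free > 0, t_pause > 0)
  structure(c(v_free = as.numeric(v_free), t_free = as.numeric(t_free),
              t_pause = as.numeric(t_pause)),
            class = "beauchemin_params")
}

#' Simulate a run-and-pause track
#'
#' Continuous-time alternation of runs and pauses in the plane, starting
#' with a run whose direction is drawn at t = 0; positions are sampled at
#' integer times, interpolating within runs.
#'
#' @param params A [beauchemin_params()] (or named vector with `v_free`,
#'   `t_free`, `t_pause`).
#' @param duration Number of time steps.
#' @param seed Integer seed.
#' @return Data frame `track_id, t, x, y` with `duration + 1` rows.
#' @export
simulate_beauchemin <- function(params, duration = 10000, seed = NULL) {
  m <- beauchemin_track_kernel(params[["v_free"]], params[["t_free"]],
                               params[["t_pause"]], as.integer(duration),
                               draw_seed(seed))
  data.frame(track_id = 1L, t = m[, 1], x = m[, 2], y = m[, 3])
}

#' Disc-coverage fitness of a track
#'
#' At every sampled time point, the integer lattice points within Euclidean
#' distance `r` of the position are marked; the fitness is the number of
#' distinct marked points divided by the disc area `pi * r^2`. With
#' `r = 13` one disc is roughly the area of a simulated T cell, making
#' this directly comparable to the CPM's explored-area fitness (cells
#' cannot break here, so fitness is simply proportional to area covered).
#'
#' @param track Data frame with `t`, `x`, `y`.
#' @param r Disc radius (pixels).
#' @return Fitness (discs' worth of area covered).
#' @export
disc_fitness <- function(track, r = 13) {
  stopifnot(r > 0)
  covered <- disc_cover_kernel(cbind(track$t, track$x, track$y), r)
  covered / (pi * r^2)
}

#' Configuration for run-and-pause evolution
#'
#' Same genetic algorithm as for the Act-CPM (log-normal mutation of all
#' three parameters, mu+lambda rank selection), but with the disc-coverage
#' fitness and only 25 generations (the fitness plateaus quickly in this
#' model because parameters map directly onto behaviour).
#'
#' @param n_pop,n_offspring,generations,sigma_mut,sigma_switch As in
#'   [evolution_config()].
#' @param init Initial parameter vector.
#' @param duration Simulation steps per fitness evaluation.
#' @param r Fitness disc radius.
#' @param seed Master seed.
#' @return An `evolution_config` tagged for the run-and-pause model.
#' @export
beauchemin_config <- function(n_pop = 10, n_offspring = 3,
                              generations = 25, sigma_mut = c(0.6, 0.2),
                              sigma_switch = 5,
                              init = c(v_free = 1, t_free = 1, t_pause = 1),
                              duration = 10000, r = 13, seed = NULL) {
  structure(list(environment = "beauchemin", n_pop = n_pop,
                 n_offspring = n_offspring, generations = generations,
                 sigma_mut = sigma_mut, sigma_switch = sigma_switch,
                 init_genotype = init, duration = duration, r = r,
                 seed = seed),
            class = "evolution_config")
}

#' Evolve run-and-pause parameters under the disc-coverage fitness
#'
#' @param config A [beauchemin_config()].
#' @return An `evolution_history` (parameter columns `v_free`, `t_free`,
#'   `t_pause`).
#' @export
evolve_beauchemin <- function(config = beauchemin_config()) {
  evaluate <- function(geno, sim_seed) {
    track <- simulate_beauchemin(geno, duration = config$duration,
                                 seed = sim_seed)
    list(fitness = disc_fitness(track, r = config$r), broken = FALSE,
         annihilated = FALSE)
  }
  run_evolution(config, evaluate = evaluate)
}
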