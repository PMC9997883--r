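#' Configuration of an evolutionary run
#'
#' A mu+lambda genetic algorithm: each of `n_pop` parents produces
#' `n_offspring` mutated offspring; all `(n_offspring + 1) * n_pop`
#' individuals (parents re-evaluated by a fresh simulation) are ranked by
#' fitness and the top `n_pop` survive. Mutation acts on the log scale with
#' standard deviation `sigma_mut[1]` for the first `sigma_switch`
#' generations and `sigma_mut[2]` afterwards; the larger early step helps
#' populations drift off the flat fitness region at the low initial
#' parameter values where cells cannot yet move.
#'
#' @param environment `"free"` (empty torus) or `"skin"` (packed
#'   keratinocyte tissue).
#' @param n_pop Population size.
#' @param n_offspring Offspring per parent.
#' @param generations Number of generations.
#' @param sigma_mut Two-phase mutation SDs (log scale).
#' @param sigma_switch Last generation using `sigma_mut[1]`.
#' @param init_genotype Initial genotype of all founders; defaults to
#'   `max_act = 5, lambda_act = 5` in the free environment and
#'   `max_act = 5, lambda_act = 100` in skin (tissue resistance requires a
#'   higher starting force for the same "not yet motile" baseline).
#' @param grid,duration,burnin,log_interval,fitness_volume Simulation
#'   settings passed to the environment builders and [run_simulation()].
#' @param params `cpm_params`; defaults chosen by `environment`.
#' @param seed Master seed; every per-individual simulation seed is derived
#'   from it.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(environment = c("free", "skin"), n_pop = 10,
                             n_offspring = 3, generations = 50,
                             sigma_mut = c(0.6, 0.2), sigma_switch = 5,
                             init_genotype = NULL, grid = c(150, 150),
                             duration = 10000, burnin = 500,
                             log_interval = 5, fitness_volume = 500,
                             params = NULL, seed = NULL) {
  environment <- match.arg(environment)
  if (is.null(init_genotype)) {
    init_genotype <- if (environment == "free") genotype(5, 5)
                     else genotype(5, 100)
  }
  if (is.null(params)) {
    params <- if (environment == "free") free_params() else skin_params()
  }
  stopifnot(n_pop >= 1, n_offspring >= 1, length(sigma_mut) == 2,
            all(sigma_mut > 0))
  structure(list(environment = environment, n_pop = n_pop,
                 n_offspring = n_offspring, generations = generations,
                 sigma_mut = sigma_mut, sigma_switch = sigma_switch,
                 init_genotype = init_genotype, grid = grid,
                 duration = duration, burnin = burnin,
                 log_interval = log_interval,
                 fitness_volume = fitness_volume, params = params,
                 seed = seed),
            class = "evolution_config")
}

sigma_at <- function(config, generation) {
  if (generation <= config$sigma_switch) config$sigma_mut[1]
  else config$sigma_mut[2]
}

#' Mutate a genotype (log-normal)
#'
#' Each parameter `x` independently becomes `exp(ln x + eps)` with
#' `eps ~ Normal(0, sigma_mut)`, so mutated values stay strictly positive
#' and mutation is symmetric on the log scale. Draws from R's RNG.
#'
#' @param genotype Named positive numeric vector (any length).
#' @param sigma_mut Mutation SD on the log scale, >= 0.
#' @return Mutated vector of the same shape.
#' @export
mutate <- function(genotype, sigma_mut) {
  stopifnot(all(genotype > 0), sigma_mut >= 0)
  if (sigma_mut == 0) return(genotype)
  out <- exp(log(unclass(genotype)) + rnorm(length(genotype), 0, sigma_mut))
  attributes(out) <- attributes(genotype)
  out
}

# Default evaluator: build a fresh environment and simulate migration.
# A fresh random tissue is generated per individual (seed recorded in the
# history row), so no individual is selected for matching one particular
# tissue realisation.
simulation_evaluator <- function(config) {
  function(geno, sim_seed) {
    state <- if (config$environment == "free") {
      init_free(genotype(geno[["max_act"]], geno[["lambda_act"]]),
                params = config$params, grid = config$grid,
                burnin = config$burnin, seed = sim_seed)
    } else {
      init_skin(genotype(geno[["max_act"]], geno[["lambda_act"]]),
                params = config$params, grid = config$grid,
                seed = sim_seed)
    }
    sim <- run_simulation(state, config$params, duration = config$duration,
                          log_interval = config$log_interval,
                          fitness_volume = config$fitness_volume,
                          seed = sim_seed + 1)
    sim$record
  }
}

#' Produce the next generation
#'
#' Generates `n_offspring` mutated offspring per parent, evaluates all
#' `(n_offspring + 1) * n_pop` individuals (parents are re-evaluated by a
#' fresh simulation), ranks by fitness and keeps the top `n_pop`. Ties are
#' broken uniformly at random. Parents persist unmutated; mutation only
#' creates new offspring rows.
#'
#' @param population Data frame of parent genotypes (one column per
#'   parameter), `n_pop` rows.
#' @param config An `evolution_config`.
#' @param generation Generation number (selects the mutation SD).
#' @param evaluate Function `(genotype_vector, seed) -> record list` with
#'   at least `fitness`; defaults to a full migration simulation in the
#'   configured environment. Injectable for testing and for other models.
#' @return List with `survivors` (data frame, `n_pop` rows) and `evaluated`
#'   (all individuals with `parent`, parameter columns, `fitness`,
#'   `broken`, `annihilated`, `survivor`, `sim_seed`).
#' @export
next_generation <- function(population, config, generation,
                            evaluate = NULL) {
  if (is.null(evaluate)) evaluate <- simulation_evaluator(config)
  stopifnot(nrow(population) == config$n_pop)
  sigma <- sigma_at(config, generation)
  pars <- names(population)
  rows <- vector("list", (config$n_offspring + 1) * config$n_pop)
  k <- 0
  for (i in seq_len(config$n_pop)) {
    parent <- as.numeric(population[i, pars])
    names(parent) <- pars
    k <- k + 1
    rows[[k]] <- c(list(parent = i), as.list(parent))
    for (j in seq_len(config$n_offspring)) {
      k <- k + 1
      rows[[k]] <- c(list(parent = i), as.list(mutate(parent, sigma)))
    }
  }
  evaluated <- do.call(rbind, lapply(rows, as.data.frame))
  evaluated$individual <- seq_len(nrow(evaluated))
  n <- nrow(evaluated)
  evaluated$sim_seed <- sample.int(.Machine$integer.max - 1, n)
  fitness <- numeric(n)
  broken <- logical(n)
  annihilated <- logical(n)
  for (i in seq_len(n)) {
    g <- as.numeric(evaluated[i, pars])
    names(g) <- pars
    rec <- evaluate(g, evaluated$sim_seed[i])
    fitness[i] <- rec$fitness
    broken[i] <- isTRUE(rec$broken)
    annihilated[i] <- isTRUE(rec$annihilated)
  }
  evaluated$fitness <- fitness
  evaluated$broken <- broken
  evaluated$annihilated <- annihilated
  rank_order <- order(-evaluated$fitness, runif(n))
  survivors_idx <- rank_order[seq_len(config$n_pop)]
  evaluated$survivor <- seq_len(n) %in% survivors_idx
  survivors <- evaluated[survivors_idx, pars, drop = FALSE]
  rownames(survivors) <- NULL
  evaluated <- evaluated[, c("individual", "parent", pars, "sim_seed",
                             "fitness", "broken", "annihilated",
                             "survivor")]
  list(survivors = survivors, evaluated = evaluated)
}

#' Run a full evolutionary simulation
#'
#' Starts from `n_pop` copies of the configured initial genotype and
#' repeats mutation, evaluation and rank selection for the configured
#' number of generations. Fully reproducible from `config$seed`.
#'
#' @param config An `evolution_config`.
#' @param evaluate Optional evaluator override (see [next_generation()]).
#' @return An object of class `evolution_history`: list with `config` and
#'   `history`, a data frame with one row per evaluated individual per
#'   generation (columns `generation`, `individual`, `parent`, the
#'   parameter columns, `sim_seed`, `fitness`, `broken`, `annihilated`,
#'   `survivor`).
#' @export
run_evolution <- function(config, evaluate = NULL) {
  with_seed(config$seed, {
    population <- as.data.frame(as.list(unclass(config$init_genotype)))
    population <- population[rep(1, config$n_pop), , drop = FALSE]
    rownames(population) <- NULL
    chunks <- vector("list", config$generations)
    for (g in seq_len(config$generations)) {
      step <- next_generation(population, config, g, evaluate)
      step$evaluated$generation <- g
      chunks[[g]] <- step$evaluated
      population <- step$survivors
    }
    history <- do.call(rbind, chunks)
    history <- history[, c("generation", setdiff(names(history),
                                                 "generation"))]
    structure(list(config = config, history = history),
              class = "evolution_history")
  })
}

#' @export
print.evolution_history <- function(x, ...) {
  h <- x$history
  last <- h[h$generation == max(h$generation) & h$survivor, ]
  pars <- setdiff(names(h), c("generation", "individual", "parent",
                              "sim_seed", "fitness", "broken",
                              "annihilated", "survivor"))
  cat(sprintf("Evolutionary run: %d generations, %d evaluated/generation\n",
              max(h$generation), sum(h$generation == 1)))
  cat(sprintf("final survivor means: %s; best fitness %.2f\n",
              paste(sprintf("%s = %.3g", pars,
                            vapply(last[pars], mean, 0)), collapse = ", "),
              max(last$fitness)))
  invisible(x)
}

history_param_cols <- function(history) {
  setdiff(names(history), c("run", "generation", "individual", "parent",
                            "sim_seed", "fitness", "broken", "annihilated",
                            "survivor"))
}

#' Consensus optimum over evolutionary runs
#'
#' Runs that did not converge are removed: a run is dropped when either
#' parameter's survivor mean changes by at least `convergence_threshold`
#' (relative, raw scale) between generations `G - window + 1` and `G`.
#' Surviving individuals' parameter values from the last `window`
#' generations are then pooled across the remaining runs and averaged on a
#' log scale (populations evolve on a log scale, so the consensus does
#' too), and the result is rounded to the nearest `round_to`.
#'
#' @param histories An `evolution_history` or list of them.
#' @param window Number of trailing generations to pool.
#' @param convergence_threshold Relative change above which a run counts as
#'   non-converged.
#' @param round_to Rounding grain for the reported optimum.
#' @return Named numeric vector of consensus parameter values.
#' @export
estimate_optimum <- function(histories, window = 10,
                             convergence_threshold = 0.2, round_to = 5) {
  if (inherits(histories, "evolution_history")) histories <- list(histories)
  pooled <- list()
  for (h in histories) {
    hist <- if (inherits(h, "evolution_history")) h$history else h
    pars <- history_param_cols(hist)
    gmax <- max(hist$generation)
    if (gmax < window) stop("histories need at least ", window,
                            " generations")
    surv <- hist[hist$survivor, ]
    first_mean <- colMeans(surv[surv$generation == gmax - window + 1, pars,
                                drop = FALSE])
    last_mean <- colMeans(surv[surv$generation == gmax, pars,
                               drop = FALSE])
    rel_change <- abs(last_mean - first_mean) / first_mean
    if (any(rel_change >= convergence_threshold)) next
    pooled[[length(pooled) + 1]] <-
      surv[surv$generation > gmax - window, pars, drop = FALSE]
  }
  if (length(pooled) == 0) stop("no converged runs")
  values <- do.call(rbind, pooled)
  est <- exp(colMeans(log(values)))
  round(est / round_to) * round_to
}

#' Scaled-down free-environment evolution settings
#'
#' The full study conditions (150x150 grid, 10,000 MCS per evaluation, 50
#' generations, 10 runs) take on the order of days on one CPU. This preset
#' keeps every model parameter and the full population structure but scales
#' the problem down — 100x100 grid, 2,000 MCS evaluations, 15 generations —
#' which is enough for the qualitative evolutionary trend (rising
#' `max_act`, `lambda_act` and fitness) to emerge reproducibly.
#'
#' @param seed Master seed.
#' @param ... Further overrides passed to [evolution_config()].
#' @return An `evolution_config`.
#' @export
scaled_free_config <- function(seed = NULL, ...) {
  evolution_config("free", grid = c(100, 100), duration = 2000,
                   generations = 15, seed = seed, ...)
}

#' Parameter cross around an optimum
#'
#' The 13 genotypes `{(max_act^i, lambda_act*)} U {(max_act*,
#' lambda_act^i)}` with `x^i = exp(ln x* +/- i * step)`, `i in 0..i_max`
#' (the centre counted once), used to probe speed, persistence and
#' breaking around an evolved optimum.
#'
#' @param optimum Named vector with `max_act` and `lambda_act`.
#' @param i_max Largest multiplier index.
#' @param step Log-scale step.
#' @return Data frame of `max_act`, `lambda_act` and an `axis`/`i` label.
#' @export
sweep_points <- function(optimum, i_max = 3, step = 0.1) {
  ma <- optimum[["max_act"]]
  la <- optimum[["lambda_act"]]
  is <- c(-(i_max:1), 0, 1:i_max)
  along_ma <- data.frame(max_act = exp(log(ma) + is * step), lambda_act = la,
                         axis = "max_act", i = is)
  along_la <- data.frame(max_act = ma, lambda_act = exp(log(la) + is * step),
                         axis = "lambda_act", i = is)
  out <- rbind(along_ma, along_la[along_la$i != 0, ])
  rownames(out) <- NULL
  out
}

#' Standard parameter points along the free-environment trajectory
#'
#' The five `(max_act, lambda_act)` combinations used to characterise
#' motility along the evolutionary trajectory, from the immotile founder
#' to near the evolved optimum.
#'
#' @return Data frame with `label`, `max_act`, `lambda_act`.
#' @export
trajectory_presets <- function() {
  data.frame(label = paste0("p", 1:5),
             max_act = c(5, 50, 110, 70, 50),
             lambda_act = c(5, 17, 30, 150, 1185))
}
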