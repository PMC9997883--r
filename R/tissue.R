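# Evaluate code under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# n pixels forming a compact disc around (x0, y0), toroidal metric
disc_pixels <- function(width, height, x0, y0, n) {
  xs <- rep(seq_len(width), times = height)
  ys <- rep(seq_len(height), each = width)
  dx <- abs(xs - x0); dx <- pmin(dx, width - dx)
  dy <- abs(ys - y0); dy <- pmin(dy, height - dy)
  ord <- order(dx^2 + dy^2, xs, ys)[seq_len(n)]
  cbind(x = xs[ord], y = ys[ord])
}

#' Build the empty ("free") environment with one T cell
#'
#' Seeds a single T cell as a compact disc of about target-volume pixels at
#' the centre of an empty torus, then runs a burn-in so the cell reaches
#' its equilibrium volume and shape before measurements start.
#'
#' @param genotype A [genotype()] for the T cell.
#' @param params A `cpm_params`; defaults to [free_params()].
#' @param grid `c(width, height)` in pixels.
#' @param burnin Burn-in duration in MCS.
#' @param seed Integer seed; the run is reproducible given the same seed.
#' @return A `cpm_state` containing exactly one T cell (id 1).
#' @export
init_free <- function(genotype, params = free_params(),
                      grid = c(150, 150), burnin = 500, seed = NULL) {
  with_seed(seed, {
    state <- lattice_state(grid[1], grid[2])
    added <- add_cell(state, type = 1L, constraints = params$tcell,
                      max_act = genotype[["max_act"]],
                      lambda_act = genotype[["lambda_act"]])
    state <- added$state
    px <- disc_pixels(grid[1], grid[2], ceiling(grid[1] / 2),
                      ceiling(grid[2] / 2), round(params$tcell$V_target))
    state$identity[px] <- added$id
    res <- advance_state(state, params, n_mcs = burnin)
    if (res$annihilated || added$id %in% res$annihilated_ids ||
        sum(res$state$identity == added$id) == 0) {
      stop("T cell annihilated during burn-in")
    }
    res$state
  })
}

# uniform random position whose footprint square is entirely background
sample_free_position <- function(state, half = 2L, max_tries = 5000) {
  for (i in seq_len(max_tries)) {
    x <- sample.int(state$width, 1)
    y <- sample.int(state$height, 1)
    xs <- wrap1(x + (-half:half), state$width)
    ys <- wrap1(y + (-half:half), state$height)
    if (all(state$identity[xs, ys] == 0L)) return(c(x, y))
  }
  stop("no free position found for seeding")
}

#' Build the packed "skin" environment
#'
#' Keratinocytes are seeded one at a time at uniform random background
#' positions and each allowed to grow for `growth_interval` MCS before the
#' next is placed (seeding them simultaneously would entangle and break
#' cells). During this phase keratinocytes carry a tighter perimeter target
#' (`seed_perimeter`, making them rounder). After all have been seeded the
#' tissue equilibrates for `equilibrate` MCS; then the first-seeded
#' keratinocyte is replaced by a T cell carrying `genotype`, and the
#' remaining keratinocytes get their final perimeter target from `params`.
#'
#' If a keratinocyte annihilates during setup the whole construction is
#' retried with a fresh derived seed (with a message); this is rare.
#'
#' @param genotype A [genotype()] for the embedded T cell.
#' @param params A `cpm_params`; defaults to [skin_params()].
#' @param n_keratinocytes Number of keratinocytes seeded (the first becomes
#'   the T cell, so the final tissue has `n_keratinocytes - 1` of them).
#' @param grid `c(width, height)` in pixels.
#' @param growth_interval MCS of growth per newly seeded cell.
#' @param equilibrate MCS of equilibration after all seeding.
#' @param seed_perimeter Transient perimeter target during seeding.
#' @param seed Integer seed.
#' @param max_retries Setup attempts before giving up.
#' @return A `cpm_state` with one T cell (id 1) embedded among
#'   `n_keratinocytes - 1` keratinocytes.
#' @export
init_skin <- function(genotype, params = skin_params(),
                      n_keratinocytes = 31, grid = c(150, 150),
                      growth_interval = 50, equilibrate = 500,
                      seed_perimeter = 200, seed = NULL, max_retries = 5) {
  stopifnot(!is.null(params$keratinocyte))
  with_seed(seed, {
    for (try_i in seq_len(max_retries)) {
      st <- try_skin_setup(params, n_keratinocytes, grid, growth_interval,
                           equilibrate, seed_perimeter)
      if (!is.null(st)) {
        return(finish_skin(st, genotype, params))
      }
      message("skin setup: a keratinocyte annihilated; retrying with a ",
              "fresh seed (attempt ", try_i + 1, ")")
    }
    stop("skin setup failed after ", max_retries, " attempts")
  })
}

try_skin_setup <- function(params, n_keratinocytes, grid, growth_interval,
                           equilibrate, seed_perimeter) {
  kc <- params$keratinocyte
  kc_seed <- kc
  kc_seed$P_target <- seed_perimeter
  state <- lattice_state(grid[1], grid[2])
  for (i in seq_len(n_keratinocytes)) {
    pos <- sample_free_position(state)
    added <- add_cell(state, type = 2L, constraints = kc_seed)
    state <- added$state
    xs <- wrap1(pos[1] + (-2:2), grid[1])
    ys <- wrap1(pos[2] + (-2:2), grid[2])
    state$identity[xs, ys] <- added$id
    res <- advance_state(state, params, n_mcs = growth_interval)
    if (length(res$annihilated_ids) > 0) return(NULL)
    state <- res$state
  }
  res <- advance_state(state, params, n_mcs = equilibrate)
  if (length(res$annihilated_ids) > 0) return(NULL)
  res$state
}

finish_skin <- function(state, genotype, params) {
  # remaining keratinocytes get their final (true) perimeter target
  state$cells$P_target <- params$keratinocyte$P_target
  # first-seeded keratinocyte becomes the T cell; its pixels keep their
  # location but start without protrusive activity
  state$cells[1, c("type", "V_target", "lambda_V", "P_target",
                   "lambda_P")] <-
    c(1L, params$tcell$V_target, params$tcell$lambda_V,
      params$tcell$P_target, params$tcell$lambda_P)
  state$cells$max_act[1] <- genotype[["max_act"]]
  state$cells$lambda_act[1] <- genotype[["lambda_act"]]
  state$activity[state$identity == 1L] <- 0
  state
}
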