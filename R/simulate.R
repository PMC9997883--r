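#' Run a single-cell migration simulation
#'
#' Advances the state for `duration` MCS, logging the T cell's
#' (torus-unwrapped) centroid every `log_interval` MCS and evaluating its
#' connectedness at every log point. Every pixel the T cell ever occupies
#' is accumulated into the explored area, recorded at copy-acceptance time
#' (not just at log points). Fitness is the explored area measured in cell
#' volumes of `fitness_volume` pixels, and drops to 0 if the cell "broke"
#' (connectedness below `break_threshold` at any log point) or lost its
#' last pixel.
#'
#' @param state A `cpm_state` containing exactly one T cell (type 1), e.g.
#'   from [init_free()] or [init_skin()].
#' @param params A `cpm_params`.
#' @param genotype Optional [genotype()] overriding the T cell's current
#'   `max_act`/`lambda_act`.
#' @param duration Simulation length in MCS.
#' @param log_interval Centroid logging interval in MCS.
#' @param fitness_volume Area unit for fitness (pixels).
#' @param break_threshold Connectedness below which the cell counts as
#'   broken.
#' @param seed Integer seed.
#' @return List with `track` (data frame `track_id, t, x, y`), `record`
#'   (list with `explored_pixels`, `fitness`, `min_connectedness`,
#'   `broken`, `annihilated`) and `state` (final lattice state).
#' @export
run_simulation <- function(state, params, genotype = NULL,
                           duration = 10000, log_interval = 5,
                           fitness_volume = 500, break_threshold = 0.9,
                           seed = NULL) {
  tcells <- state$cells$id[state$cells$type == 1L]
  if (length(tcells) != 1) stop("state must contain exactly one T cell")
  tid <- tcells[1]
  if (!is.null(genotype)) {
    state$cells$max_act[tid] <- genotype[["max_act"]]
    state$cells$lambda_act[tid] <- genotype[["lambda_act"]]
  }
  res <- advance_state(state, params, n_mcs = duration, seed = seed,
                       track_cell = tid, log_interval = log_interval,
                       log_connectedness = TRUE)
  track <- data.frame(track_id = 1L, t = res$track[, 1],
                      x = res$track[, 2], y = res$track[, 3])
  broken <- res$min_connectedness < break_threshold
  fitness <- if (broken || res$annihilated) 0 else
    res$explored / fitness_volume
  list(track = track,
       record = list(explored_pixels = res$explored,
                     fitness = fitness,
                     min_connectedness = res$min_connectedness,
                     broken = broken,
                     annihilated = res$annihilated),
       state = res$state)
}

#' Torus-consistent centroid of a cell
#'
#' On a periodic lattice the arithmetic mean of pixel coordinates is
#' meaningless for cells straddling the boundary. The centroid is instead
#' computed under the minimal-image convention relative to a reference
#' point: `previous_centroid` if given (so consecutive calls accumulate
#' into a continuous, unwrapped trajectory), else the cell's first pixel.
#'
#' @param state A `cpm_state`.
#' @param cell_id Cell id (must own at least one pixel).
#' @param previous_centroid Optional `c(x, y)` reference from the previous
#'   time point.
#' @return Numeric `c(x, y)`, continuous pixel coordinates.
#' @export
centroid <- function(state, cell_id, previous_centroid = NULL) {
  px <- cell_pixels(state, cell_id)
  if (nrow(px) == 0) stop("cell ", cell_id, " has no pixels")
  ref <- if (is.null(previous_centroid)) px[1, ] else previous_centroid
  dx <- px[, 1] - ref[1]
  dy <- px[, 2] - ref[2]
  dx <- dx - state$width * round(dx / state$width)
  dy <- dy - state$height * round(dy / state$height)
  c(x = ref[1] + mean(dx), y = ref[2] + mean(dy))
}

#' Connectedness of a pixel set
#'
#' The probability that two uniformly drawn pixels lie in the same
#' connected component: `C = sum_k (n_k / N)^2` over Moore-connected
#' components of sizes `n_k`. An intact cell has `C = 1`; a cell split in
#' two equal halves has `C = 0.5`; shedding a single pixel barely lowers
#' it. Cells with `C < 0.9` at any point of a simulation are considered
#' broken.
#'
#' @param pixels Two-column matrix of `(x, y)` pixel coordinates.
#' @param width,height Optional grid dimensions; when given, adjacency
#'   wraps around the torus.
#' @return Connectedness in `(0, 1]`.
#' @export
connectedness <- function(pixels, width = NULL, height = NULL) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (is.null(n) || n == 0) stop("empty pixel set")
  key_base <- 2L * max(pixels[, 2], if (!is.null(height)) height else 0) + 4L
  keyize <- function(x, y) x * key_base + y
  keys <- keyize(pixels[, 1], pixels[, 2])
  off <- moore_offsets()
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      j <- queue[[1]]
      queue <- queue[-1]
      nx <- pixels[j, 1] + off[, 1]
      ny <- pixels[j, 2] + off[, 2]
      if (!is.null(width)) nx <- wrap1(nx, width)
      if (!is.null(height)) ny <- wrap1(ny, height)
      hits <- match(keyize(nx, ny), keys)
      hits <- hits[!is.na(hits)]
      new <- hits[comp[hits] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  sizes <- tabulate(comp)
  sum((sizes / n)^2)
}
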