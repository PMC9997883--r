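moore_offsets <- function() {
  cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
        dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
}

wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

# matrix of m[x+dx, y+dy] with toroidal wrap, same shape as m
shift_torus <- function(m, dx, dy) {
  m[wrap1(seq_len(nrow(m)) + dx, nrow(m)),
    wrap1(seq_len(ncol(m)) + dy, ncol(m)), drop = FALSE]
}

#' Moore neighbourhood of a pixel
#'
#' The 8 pixels surrounding `p` on the periodic lattice.
#'
#' @param p Integer vector `c(x, y)` (1-based).
#' @param state A `cpm_state` (only the grid dimensions are used).
#' @return An 8x2 matrix of `(x, y)` coordinates with wrap-around.
#' @export
moore_neighbors <- function(p, state) {
  off <- moore_offsets()
  cbind(x = wrap1(p[1] + off[, 1], state$width),
        y = wrap1(p[2] + off[, 2], state$height))
}

#' Total Hamiltonian (adhesion + volume + perimeter)
#'
#' Computes the global energy by brute force: adhesion summed once per
#' unordered unlike Moore pixel pair, plus the quadratic volume and
#' perimeter penalties `lambda * (X - X_target)^2` per cell. The
#' protrusion-activity term only ever enters energy *differences* of copy
#' attempts, not the stored total, and is therefore not part of this sum.
#' This function is deliberately direct (it rescans the whole grid) and
#' serves as the reference against which the incremental [delta_h_physical()]
#' is validated.
#'
#' @param state A `cpm_state`.
#' @param params A `cpm_params`.
#' @return The energy (dimensionless CPM units).
#' @export
total_hamiltonian <- function(state, params) {
  id <- state$identity
  typevec <- c(0L, state$cells$type)
  tmat <- matrix(typevec[id + 1L], nrow(id), ncol(id))
  off <- moore_offsets()
  adh <- 0
  for (k in seq_len(nrow(off))) {
    sid <- shift_torus(id, off[k, 1], off[k, 2])
    stp <- shift_torus(tmat, off[k, 1], off[k, 2])
    unlike <- id != sid
    if (any(unlike)) {
      adh <- adh +
        sum(params$adhesion[cbind(tmat[unlike] + 1L, stp[unlike] + 1L)])
    }
  }
  h <- adh / 2  # each unordered pair was visited from both sides
  if (nrow(state$cells) > 0) {
    cb <- state$cells
    vols <- cell_volumes(state)
    perims <- cell_perimeters(state)
    h <- h + sum(cb$lambda_V * (vols - cb$V_target)^2) +
      sum(cb$lambda_P * (perims - cb$P_target)^2)
  }
  h
}

#' Per-cell perimeters
#'
#' Perimeter of a cell = number of Moore pairs `(p in cell, q not in cell)`.
#'
#' @param state A `cpm_state`.
#' @return Numeric vector, one entry per cell id.
#' @export
cell_perimeters <- function(state) {
  id <- state$identity
  n <- nrow(state$cells)
  if (n == 0) return(numeric(0))
  perims <- numeric(n)
  off <- moore_offsets()
  for (k in seq_len(nrow(off))) {
    sid <- shift_torus(id, off[k, 1], off[k, 2])
    boundary <- id > 0L & id != sid
    if (any(boundary)) {
      tab <- tabulate(id[boundary], nbins = n)
      perims <- perims + tab
    }
  }
  perims
}

pixel_index <- function(p, state) p[1] + (p[2] - 1L) * state$width

#' Energy difference of a candidate copy: physical terms
#'
#' The change in adhesion + volume + perimeter energy if the cell identity
#' of `source` were copied into `target`, computed incrementally from the
#' local neighbourhood (the same code path the simulation kernel uses). By
#' construction this equals `total_hamiltonian(after) -
#' total_hamiltonian(before)` exactly.
#'
#' @param state A `cpm_state`.
#' @param source,target Pixel coordinates `c(x, y)`; must belong to
#'   different cells.
#' @param params A `cpm_params`.
#' @return The energy difference, with the individual terms in attribute
#'   `"components"`.
#' @export
delta_h_physical <- function(state, source, target, params) {
  comp <- cpm_delta_h_kernel(state$identity, state$activity,
                             cell_param_matrix(state), params$adhesion,
                             params$temperature,
                             pixel_index(source, state),
                             pixel_index(target, state))
  structure(comp$adhesion + comp$volume + comp$perimeter,
            components = comp[c("adhesion", "volume", "perimeter")])
}

#' Geometric mean of protrusive activity around a pixel
#'
#' Over the pixel itself plus those of its Moore neighbours belonging to the
#' same cell; 0 for background pixels and whenever any included activity
#' is 0.
#'
#' @param p Pixel `c(x, y)`.
#' @param state A `cpm_state`.
#' @return Non-negative scalar (MCS units).
#' @export
gm_act <- function(p, state) {
  id <- state$identity[p[1], p[2]]
  if (id == 0L) return(0)
  nbs <- moore_neighbors(p, state)
  same <- state$identity[nbs] == id
  vals <- c(state$activity[p[1], p[2]], state$activity[nbs][same])
  if (any(vals == 0)) return(0)
  exp(mean(log(vals)))
}

#' Energy difference of a candidate copy: protrusion-activity term
#'
#' `-(lambda_act / max_act) * (GM_act(source) - GM_act(target))`: negative
#' (favourable) when the source sits in a more active region than the
#' target, which is the positive feedback that drives protrusion. If
#' `max_act` is 0 the feedback is disabled and the term is 0.
#'
#' @param state A `cpm_state`.
#' @param source,target Pixel coordinates `c(x, y)` of different cells.
#' @param genotype A [genotype()] (or any vector with `max_act`,
#'   `lambda_act`) supplying the feedback parameters.
#' @return The energy difference.
#' @export
delta_h_act <- function(state, source, target, genotype) {
  if (state$identity[source[1], source[2]] ==
      state$identity[target[1], target[2]]) {
    stop("source and target belong to the same cell")
  }
  ma <- genotype[["max_act"]]
  la <- genotype[["lambda_act"]]
  if (ma == 0) return(0)
  -(la / ma) * (gm_act(source, state) - gm_act(target, state))
}

#' Metropolis acceptance probability
#'
#' `1` for `delta_h <= 0`, `exp(-delta_h / temperature)` otherwise — the
#' standard CPM acceptance rule.
#'
#' @param delta_h Energy difference(s).
#' @param temperature Metropolis temperature, > 0.
#' @return Probability in `[0, 1]`, vectorised over `delta_h`.
#' @export
copy_probability <- function(delta_h, temperature) {
  ifelse(delta_h <= 0, 1, exp(-delta_h / temperature))
}

# Activity parameters governing a copy attempt: those of the source cell,
# or of the target cell when the source is background.
act_params_for <- function(state, source_id, target_id) {
  ref <- if (source_id != 0L) source_id else target_id
  if (ref == 0L) return(c(max_act = 0, lambda_act = 0))
  c(max_act = state$cells$max_act[ref],
    lambda_act = state$cells$lambda_act[ref])
}

#' Perform one random copy attempt
#'
#' Picks a uniform random source pixel and a uniform random Moore neighbour
#' as target (using R's RNG). If both belong to the same cell nothing
#' happens; otherwise the total energy difference (physical + activity) is
#' computed and the copy accepted with the Metropolis probability. On
#' acceptance the target takes the source's identity and its activity is
#' set to the gaining cell's `max_act` (0 if the gaining side is the
#' background).
#'
#' This is the readable single-attempt reference; bulk dynamics run through
#' the compiled kernel via [advance_state()]/[mcs_step()].
#'
#' @param state A `cpm_state`.
#' @param params A `cpm_params`.
#' @return List with elements `state`, `attempted` (FALSE for same-cell
#'   no-ops), `accepted`, and `delta_h` (NA for no-ops).
#' @export
attempt_copy <- function(state, params) {
  src <- c(sample.int(state$width, 1), sample.int(state$height, 1))
  nbs <- moore_neighbors(src, state)
  tgt <- nbs[sample.int(8, 1), ]
  sid <- state$identity[src[1], src[2]]
  tid <- state$identity[tgt[1], tgt[2]]
  if (sid == tid) {
    return(list(state = state, attempted = FALSE, accepted = FALSE,
                delta_h = NA_real_))
  }
  dh <- as.numeric(delta_h_physical(state, src, tgt, params)) +
    delta_h_act(state, src, tgt, act_params_for(state, sid, tid))
  accepted <- runif(1) < copy_probability(dh, params$temperature)
  if (accepted) {
    state$identity[tgt[1], tgt[2]] <- sid
    state$activity[tgt[1], tgt[2]] <-
      if (sid == 0L) 0 else state$cells$max_act[sid]
  }
  list(state = state, attempted = TRUE, accepted = accepted, delta_h = dh)
}
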