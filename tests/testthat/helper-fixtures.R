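# Random small lattices and parameter sets for property-style tests.
# All randomness comes from R's RNG; callers set the seed.

random_test_state <- function(width = 14, height = 14, n_cells = 2) {
  cells <- data.frame(
    id = seq_len(n_cells),
    type = sample(1:2, n_cells, replace = TRUE),
    V_target = sample(20:60, n_cells, replace = TRUE),
    lambda_V = sample(c(0, 2, 30), n_cells, replace = TRUE),
    P_target = sample(30:80, n_cells, replace = TRUE),
    lambda_P = sample(c(0, 1, 2), n_cells, replace = TRUE),
    max_act = sample(c(0, 10, 20), n_cells, replace = TRUE),
    lambda_act = sample(c(0, 50, 200), n_cells, replace = TRUE))
  id <- matrix(sample(0:n_cells, width * height, replace = TRUE),
               width, height)
  act <- matrix(0, width, height)
  for (cc in seq_len(n_cells)) {
    px <- id == cc
    if (cells$max_act[cc] > 0) {
      act[px] <- runif(sum(px), 0, cells$max_act[cc])
    }
  }
  lattice_state(width, height, id, act, cells)
}

random_test_params <- function() {
  J <- matrix(runif(9, 0, 30), 3, 3)
  J <- (J + t(J)) / 2
  J[1, 1] <- 0
  dimnames(J) <- list(c("bg", "tcell", "keratinocyte"),
                      c("bg", "tcell", "keratinocyte"))
  cpm_params(temperature = runif(1, 5, 30), adhesion = J)
}

# apply an accepted copy the way the model defines it
apply_copy_r <- function(state, src, tgt) {
  sid <- state$identity[src[1], src[2]]
  state$identity[tgt[1], tgt[2]] <- sid
  state$activity[tgt[1], tgt[2]] <-
    if (sid == 0L) 0 else state$cells$max_act[sid]
  state
}

# a state whose single cell covers a block, with uniform activity
block_cell_state <- function(width = 9, height = 9, xs = 3:5, ys = 3:5,
                             activity = 0, max_act = 50,
                             lambda_act = 1000, V_target = NULL,
                             P_target = NULL, lambda_V = 30,
                             lambda_P = 2) {
  px <- as.matrix(expand.grid(x = xs, y = ys))
  if (is.null(V_target)) V_target <- nrow(px)
  st <- lattice_state(width, height)
  st$cells <- data.frame(id = 1L, type = 1L, V_target = V_target,
                         lambda_V = lambda_V,
                         P_target = if (is.null(P_target)) 0 else P_target,
                         lambda_P = lambda_P, max_act = max_act,
                         lambda_act = lambda_act)
  st$identity[px] <- 1L
  st$activity[px] <- activity
  if (is.null(P_target)) {
    st$cells$P_target <- cell_perimeters(st)[1]
  }
  st
}

# deterministic stub evaluator for GA tests: fitness from the genotype only
product_evaluator <- function(geno, sim_seed) {
  list(fitness = prod(geno), broken = FALSE, annihilated = FALSE)
}

# brute-force count of lattice points within r of any track position
brute_disc_cover <- function(track, r) {
  pts <- unique(do.call(rbind, lapply(seq_len(nrow(track)), function(i) {
    cx <- track$x[i]
    cy <- track$y[i]
    g <- expand.grid(x = floor(cx - r):ceiling(cx + r),
                     y = floor(cy - r):ceiling(cy + r))
    g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, ]
  })))
  nrow(pts)
}
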