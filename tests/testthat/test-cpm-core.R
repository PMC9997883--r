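test_that("Moore neighbourhood has 8 distinct pixels and wraps the torus", {
  st <- lattice_state(150, 150)
  nb <- moore_neighbors(c(75, 75), st)
  expect_equal(nrow(nb), 8)
  expect_equal(nrow(unique(nb)), 8)
  expect_true(all(abs(nb[, 1] - 75) <= 1 & abs(nb[, 2] - 75) <= 1))
  corner <- moore_neighbors(c(1, 1), st)
  expect_true(any(corner[, 1] == 150 & corner[, 2] == 150))
})

test_that("Moore neighbour relation is symmetric", {
  st <- lattice_state(7, 11)
  set.seed(4)
  for (rep in 1:20) {
    p <- c(sample.int(7, 1), sample.int(11, 1))
    for (k in 1:8) {
      q <- moore_neighbors(p, st)[k, ]
      back <- moore_neighbors(q, st)
      expect_true(any(back[, 1] == p[1] & back[, 2] == p[2]))
    }
  }
})

test_that("total Hamiltonian: background-only grid has zero energy", {
  st <- lattice_state(10, 10)
  expect_equal(total_hamiltonian(st, free_params()), 0)
})

test_that("a cell at its volume and perimeter targets pays adhesion only", {
  st <- block_cell_state(xs = 3:5, ys = 3:5)  # 3x3 block, targets = actual
  params <- free_params()
  # each boundary pair crosses to background exactly once: 32 Moore pairs
  expect_equal(cell_perimeters(st)[1], 32)
  expect_equal(total_hamiltonian(st, params), 20 * 32)
})

test_that("2x2 cell with free constraints: energy is J times unlike pairs", {
  st <- block_cell_state(width = 12, height = 12, xs = 5:6, ys = 5:6,
                         lambda_V = 0, lambda_P = 0)
  # brute-force enumeration of unordered unlike Moore pairs
  pairs <- 0
  for (x in 1:12) for (y in 1:12) {
    if (st$identity[x, y] == 0L) next
    nb <- moore_neighbors(c(x, y), st)
    pairs <- pairs + sum(st$identity[nb] == 0L)
  }
  expect_equal(total_hamiltonian(st, free_params()), 20 * pairs)
})

test_that("volume term of the copy energy follows the quadratic penalty", {
  # cell one pixel short of target: gaining a pixel relaxes the penalty
  st <- block_cell_state(width = 10, height = 10, xs = 3:5, ys = 3:5,
                         V_target = 10, lambda_V = 30, lambda_P = 0)
  params <- free_params()
  dh <- delta_h_physical(st, source = c(4, 4), target = c(6, 4), params)
  expect_equal(attr(dh, "components")$volume, 0 - 30 * (-1)^2)
  # cell exactly at target: gaining costs +lambda_V
  st$cells$V_target <- 9
  dh <- delta_h_physical(st, source = c(4, 4), target = c(6, 4), params)
  expect_equal(attr(dh, "components")$volume, 30)
})

test_that("incremental delta-H equals the brute-force energy difference", {
  set.seed(101)
  checked <- 0
  while (checked < 1000) {
    st <- random_test_state(width = sample(6:14, 1),
                            height = sample(6:14, 1))
    params <- random_test_params()
    h_before <- total_hamiltonian(st, params)
    for (a in 1:40) {
      src <- c(sample.int(st$width, 1), sample.int(st$height, 1))
      tgt <- moore_neighbors(src, st)[sample.int(8, 1), ]
      if (st$identity[src[1], src[2]] == st$identity[tgt[1], tgt[2]]) next
      dh <- as.numeric(delta_h_physical(st, src, tgt, params))
      after <- apply_copy_r(st, src, tgt)
      brute <- total_hamiltonian(after, params) - h_before
      expect_equal(dh, brute, tolerance = 1e-9)
      checked <- checked + 1
      if (checked >= 1000) break
    }
  }
  expect_gte(checked, 1000)
})

test_that("delta-H errors when source and target share a cell", {
  st <- block_cell_state()
  expect_error(delta_h_physical(st, c(3, 3), c(4, 4), free_params()),
               "same cell")
  expect_error(delta_h_act(st, c(3, 3), c(4, 4), genotype(50, 1000)),
               "same cell")
})

test_that("activity geometric mean: equal, zero, and mixed neighbourhoods", {
  st <- block_cell_state(activity = 7)
  expect_equal(gm_act(c(4, 4), st), 7)       # all included equal
  st$activity[4, 4] <- 0
  expect_equal(gm_act(c(4, 4), st), 0)       # zero factor annihilates
  expect_equal(gm_act(c(1, 1), st), 0)       # background pixel
  # two-pixel cell with activities 4 and 16: geometric mean 8
  st2 <- lattice_state(8, 8)
  st2$cells <- data.frame(id = 1L, type = 1L, V_target = 2, lambda_V = 0,
                          P_target = 0, lambda_P = 0, max_act = 20,
                          lambda_act = 100)
  st2$identity[3, 3] <- 1L
  st2$identity[4, 3] <- 1L
  st2$activity[3, 3] <- 4
  st2$activity[4, 3] <- 16
  expect_equal(gm_act(c(3, 3), st2), 8)
})

test_that("R and kernel activity geometric means agree on random states", {
  set.seed(77)
  for (rep in 1:30) {
    st <- random_test_state()
    p <- c(sample.int(st$width, 1), sample.int(st$height, 1))
    expect_equal(gm_act(p, st),
                 actevolve:::cpm_gm_act_kernel(
                   st$identity, st$activity,
                   p[1] + (p[2] - 1) * st$width))
  }
})

test_that("protrusion term rewards copying from active into passive regions", {
  # fully active source cell next to background: evolved-optimum parameters
  st <- block_cell_state(activity = 50, max_act = 50, lambda_act = 1165)
  expect_equal(delta_h_act(st, c(4, 4), c(1, 1), genotype(50, 1165)), -1165)
  # retraction into a more active region costs energy
  st2 <- lattice_state(12, 8)
  one <- data.frame(id = 1L, type = 1L, V_target = 9, lambda_V = 0,
                    P_target = 0, lambda_P = 0, max_act = 50,
                    lambda_act = 1000)
  st2$cells <- rbind(one, transform(one, id = 2L))
  st2$identity[as.matrix(expand.grid(2:4, 3:5))] <- 1L
  st2$identity[as.matrix(expand.grid(6:8, 3:5))] <- 2L
  st2$activity[st2$identity == 1L] <- 25
  st2$activity[st2$identity == 2L] <- 50
  expect_equal(delta_h_act(st2, c(3, 4), c(7, 4), genotype(50, 1000)), 500)
  # equal geometric means cancel
  st2$activity[st2$identity == 2L] <- 25
  expect_equal(delta_h_act(st2, c(3, 4), c(7, 4), genotype(50, 1000)), 0)
  # disabled feedback
  expect_equal(delta_h_act(st2, c(3, 4), c(7, 4),
                           c(max_act = 0, lambda_act = 1000)), 0)
})

test_that("Metropolis rule: downhill always accepted, uphill at exp(-dH/T)", {
  expect_equal(copy_probability(-5, 20), 1)
  expect_equal(copy_probability(0, 20), 1)
  expect_equal(copy_probability(20, 20), exp(-1))
  # kernel acceptance frequency over many trials
  n <- 2e5
  acc <- actevolve:::cpm_metropolis_trials(20, 20, n, 991)
  expect_equal(acc / n, exp(-1), tolerance = 0.02)
  expect_equal(actevolve:::cpm_metropolis_trials(-1, 20, 1000, 5), 1000)
})

test_that("single attempts conserve the identity partition", {
  set.seed(31)
  st <- block_cell_state(width = 10, height = 10)
  params <- free_params()
  for (i in 1:50) {
    out <- attempt_copy(st, params)
    st2 <- out$state
    expect_equal(length(st2$identity), 100)
    expect_true(all(st2$identity %in% c(0L, 1L)))
    st <- st2
  }
})

test_that("one MCS conserves pixels and runs N copy attempts worth of dynamics", {
  set.seed(5)
  st <- init_free(genotype(20, 200), grid = c(50, 50), burnin = 50,
                  seed = 9)
  st2 <- mcs_step(st, free_params(), seed = 10)
  expect_equal(prod(dim(st2$identity)), 2500)
  expect_equal(sum(cell_volumes(st2)) + sum(st2$identity == 0L), 2500)
})

test_that("activity decays by one per MCS and is floored at zero", {
  # a cell covering the whole torus has no interface: no copies can happen
  st <- lattice_state(6, 6)
  st$cells <- data.frame(id = 1L, type = 1L, V_target = 36, lambda_V = 30,
                         P_target = 0, lambda_P = 0, max_act = 5,
                         lambda_act = 100)
  st$identity[] <- 1L
  st$activity[] <- 3
  st$activity[2, 2] <- 1
  params <- free_params()
  res <- advance_state(st, params, n_mcs = 2, seed = 3)
  expect_equal(res$state$activity[3, 3], 1)
  expect_equal(res$state$activity[2, 2], 0)
  res <- advance_state(res$state, params, n_mcs = 5, seed = 4)
  expect_true(all(res$state$activity == 0))
})

test_that("activity stays within [0, max_act] during active migration", {
  st <- init_free(genotype(30, 500), grid = c(60, 60), burnin = 100,
                  seed = 21)
  res <- advance_state(st, free_params(), n_mcs = 200, seed = 22)
  expect_true(all(res$state$activity >= 0))
  expect_true(all(res$state$activity <= 30))
  expect_true(all(res$state$activity[res$state$identity == 0L] == 0))
})

test_that("a passive cell's volume equilibrates at its target", {
  st <- init_free(genotype(1, 1e-6), grid = c(80, 80), burnin = 200,
                  seed = 41)
  params <- free_params()
  vols <- numeric(20)
  for (i in 1:20) {
    res <- advance_state(st, params, n_mcs = 100, seed = 41 + i)
    st <- res$state
    vols[i] <- res$volumes[1]
  }
  expect_equal(mean(vols), 500, tolerance = 0.02)
})

test_that("without the protrusion term, motion has no directional bias", {
  disp <- t(sapply(1:20, function(s) {
    st <- init_free(genotype(1, 1e-6), grid = c(60, 60), burnin = 100,
                    seed = 500 + s)
    res <- advance_state(st, free_params(), n_mcs = 1000, seed = 600 + s,
                         track_cell = 1, log_interval = 100)
    tail_xy <- res$track[nrow(res$track), 2:3]
    head_xy <- res$track[1, 2:3]
    unlist(tail_xy - head_xy)
  }))
  expect_lt(abs(mean(disp[, 1])), 2)
  expect_lt(abs(mean(disp[, 2])), 2)
})

test_that("simulations replay identically from the same seed", {
  st <- init_free(genotype(40, 600), grid = c(60, 60), burnin = 100,
                  seed = 77)
  a <- advance_state(st, free_params(), n_mcs = 300, seed = 123,
                     track_cell = 1, log_interval = 5)
  b <- advance_state(st, free_params(), n_mcs = 300, seed = 123,
                     track_cell = 1, log_interval = 5)
  expect_identical(a$state$identity, b$state$identity)
  expect_identical(a$track, b$track)
})
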