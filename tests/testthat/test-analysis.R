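straight_track <- function(v = 1, n = 100, interval = 1) {
  data.frame(track_id = 1L, t = (0:n) * interval,
             x = v * (0:n) * interval, y = 0)
}

test_that("step speeds: stationary, pythagorean, and constant tracks", {
  still <- data.frame(track_id = 1, t = seq(0, 50, 5), x = 3, y = 4)
  expect_true(all(step_speeds(still) == 0))
  two <- data.frame(track_id = 1, t = c(0, 5), x = c(0, 3), y = c(0, 4))
  expect_equal(step_speeds(two), 1)
  st <- straight_track(v = 0.7, n = 50, interval = 5)
  expect_equal(mean(step_speeds(st)), 0.7)
  expect_error(step_speeds(data.frame(track_id = 1, t = 0, x = 0, y = 0)),
               "fewer than 2")
})

test_that("MSD of ballistic motion is quadratic with floor-rule weights", {
  curve <- msd_curve(straight_track(v = 2, n = 100))
  expect_equal(curve$msd, (2 * curve$dt)^2, tolerance = 1e-12)
  expect_equal(curve$weight[curve$dt == 20], 5)   # floor(100/20)
  expect_equal(curve$weight[curve$dt == 100], 1)  # single displacement
  expect_equal(curve$weight[curve$dt == 1], 100)
})

test_that("MSD pools displacements across tracks", {
  tr1 <- straight_track(v = 1, n = 10)
  tr2 <- straight_track(v = 3, n = 10)
  tr2$track_id <- 2L
  curve <- msd_curve(rbind(tr1, tr2))
  expect_equal(curve$msd, ((1 + 9) / 2) * curve$dt^2)  # mean of v^2
  expect_equal(curve$weight[curve$dt == 5], 4)         # 2 + 2
})

test_that("Fuerth fitting recovers noiseless model parameters exactly", {
  curve <- make_furth_msd(D = 1, P = 10, lags = 1:200, n_steps = 2000)
  fit <- fit_furth(curve)
  expect_true(fit$converged)
  expect_equal(fit$D, 1, tolerance = 1e-6)
  expect_equal(fit$P, 10, tolerance = 1e-6)
  # small-lag limit is ballistic, large-lag limit diffusive with slope 4D
  expect_equal(curve$msd[1], 2 * 1 * 1^2 / 10, tolerance = 0.05)
  big <- make_furth_msd(1, 10, c(5000, 5001))
  expect_equal(diff(big$msd), 4 * 1, tolerance = 1e-6)
})

test_that("autocovariance: parallel, alternating, and uncorrelated steps", {
  curve <- autocov_curve(straight_track(v = 2, n = 30))
  expect_true(all(abs(curve$autocov - 4) < 1e-12))  # l^2 at every lag
  zig <- data.frame(track_id = 1, t = 0:20,
                    x = rep(c(0, 1), length.out = 21), y = 0)
  zc <- autocov_curve(zig)
  expect_equal(zc$autocov[zc$dt == 1], -1)
  expect_equal(zc$autocov[zc$dt == 2], 1)
  set.seed(2)
  iso <- do.call(rbind, lapply(1:40, function(id) {
    data.frame(track_id = id, t = 0:100,
               x = cumsum(c(0, rnorm(100))), y = cumsum(c(0, rnorm(100))))
  }))
  ic <- autocov_curve(iso)
  expect_equal(mean(abs(ic$autocov[ic$dt >= 1 & ic$dt <= 10])), 0,
               tolerance = 0.05)
})

test_that("exponential autocovariance fitting is self-consistent", {
  curve <- make_exp_autocov(1, 5, 0:60)
  fit <- fit_autocov(curve, P_msd = 5)
  expect_true(fit$converged)
  expect_equal(fit$c, 1, tolerance = 1e-6)
  expect_equal(fit$P, 5, tolerance = 1e-6)
  # the 5% point of exp(-dt/5) at integer lags is 15 (5 ln 20 = 14.98)
  expect_equal(fit$t_5pct, 15)
  expect_equal(5 * log(20), 14.979, tolerance = 1e-3)
})

test_that("a non-decaying autocovariance leaves the window open, flagged", {
  flat <- data.frame(dt = 0:40, autocov = rep(2, 41))
  fit <- fit_autocov(flat, P_msd = 4)
  expect_true(is.na(fit$t_5pct))
  expect_false(fit$converged)
  expect_gt(fit$P, 100)  # essentially no decay
})

test_that("independence weighting reduces persistence error on noisy curves", {
  set.seed(8)
  errs <- replicate(20, {
    curve <- make_furth_msd(D = 2, P = 20, lags = 1:400, n_steps = 400)
    noise <- rnorm(nrow(curve), 0, 0.25 / sqrt(curve$weight))
    curve$msd <- curve$msd * exp(noise)
    wfit <- fit_furth(curve)
    ufit <- fit_furth(transform(curve, weight = 1))
    c(weighted = abs(wfit$P - 20), unweighted = abs(ufit$P - 20))
  })
  expect_lt(mean(errs["weighted", ]), mean(errs["unweighted", ]))
})

test_that("grouped estimates: 6 groups of 5, zero spread for clones", {
  base <- make_prw_tracks(1, 20, n_steps = 300, n_tracks = 1, seed = 3)
  clones <- do.call(rbind, lapply(1:30, function(id) {
    tr <- base
    tr$track_id <- id
    tr
  }))
  est <- grouped_estimates(clones)
  expect_equal(nrow(est$groups), 6)
  expect_true(all(est$summary$sd == 0))
  expect_error(grouped_estimates(clones[clones$track_id <= 12, ]),
               "expected 30 tracks")
})

test_that("speed and persistence are recovered from generated random walks", {
  tracks <- make_prw_tracks(speed = 1, persistence = 20, n_steps = 2000,
                            n_tracks = 30, seed = 14)
  speeds <- unlist(lapply(split(tracks, tracks$track_id), step_speeds))
  expect_equal(mean(speeds), 1, tolerance = 0.05)
  msd_fit <- fit_furth(msd_curve(tracks))
  expect_equal(msd_fit$P, 20, tolerance = 0.25)
  ac_fit <- fit_autocov(autocov_curve(tracks), msd_fit$P)
  expect_equal(ac_fit$P, 20, tolerance = 0.25)
  # the two persistence routes agree on the same ensemble
  expect_lt(abs(msd_fit$P - ac_fit$P) / ac_fit$P, 0.3)
})
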