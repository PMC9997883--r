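test_that("log-normal mutation is symmetric on the log scale and positive", {
  g <- genotype(5, 5)
  expect_identical(mutate(g, 0), g)
  set.seed(9)
  draws <- replicate(5e4, mutate(c(a = 5, b = 7), 0.6))
  ratios <- log(draws / c(5, 7))
  expect_equal(mean(ratios), 0, tolerance = 0.02)
  expect_equal(sd(ratios), 0.6, tolerance = 0.02)
  expect_true(all(draws > 0))
  # e.g. a +0.6 log-step multiplies by e^0.6
  expect_equal(5 * exp(0.6), 9.110594, tolerance = 1e-6)
})

test_that("selection keeps exactly the fittest individuals", {
  cfg <- evolution_config("free", generations = 1, seed = 1)
  pop <- data.frame(max_act = seq(1, 10), lambda_act = seq(2, 20, by = 2))
  set.seed(42)
  step <- next_generation(pop, cfg, generation = 1,
                          evaluate = product_evaluator)
  ev <- step$evaluated
  expect_equal(nrow(ev), 40)
  expect_equal(sum(ev$survivor), 10)
  # monotone selection: worst survivor at least as fit as best casualty
  expect_gte(min(ev$fitness[ev$survivor]), max(ev$fitness[!ev$survivor]))
  # survivors are drawn from the evaluated multiset, unmodified
  expect_true(all(apply(step$survivors, 1, function(r) {
    any(ev$max_act == r[["max_act"]] & ev$lambda_act == r[["lambda_act"]])
  })))
})

test_that("all-zero fitness still yields a full survivor set", {
  cfg <- evolution_config("free", generations = 1, seed = 1)
  pop <- data.frame(max_act = rep(5, 10), lambda_act = rep(5, 10))
  set.seed(7)
  step <- next_generation(pop, cfg, generation = 1,
                          evaluate = function(g, s) {
                            list(fitness = 0, broken = TRUE,
                                 annihilated = FALSE)
                          })
  expect_equal(nrow(step$survivors), 10)
  expect_true(all(step$evaluated$fitness == 0))
})

test_that("evolutionary runs are reproducible and well-formed", {
  cfg <- evolution_config("free", generations = 4, seed = 99)
  h1 <- run_evolution(cfg, evaluate = product_evaluator)
  h2 <- run_evolution(cfg, evaluate = product_evaluator)
  expect_identical(h1$history, h2$history)
  hist <- h1$history
  expect_equal(max(hist$generation), 4)
  expect_equal(as.integer(table(hist$generation)), rep(40L, 4))
  expect_equal(as.integer(tapply(hist$survivor, hist$generation, sum)),
               rep(10L, 4))
  expect_true(all(hist$max_act > 0 & hist$lambda_act > 0))
  # with multiplicative fitness, survivor means must ratchet upwards
  surv <- hist[hist$survivor, ]
  means <- tapply(surv$max_act * surv$lambda_act, surv$generation, mean)
  expect_gt(means[[4]], means[[1]])
})

test_that("the mutation step width drops after the configured generation", {
  cfg <- evolution_config("free", generations = 1, seed = 1)
  expect_equal(actevolve:::sigma_at(cfg, 1), 0.6)
  expect_equal(actevolve:::sigma_at(cfg, 5), 0.6)
  expect_equal(actevolve:::sigma_at(cfg, 6), 0.2)
})

test_that("environment presets give the published starting genotypes", {
  expect_equal(unclass(evolution_config("free", seed = 1)$init_genotype),
               c(max_act = 5, lambda_act = 5))
  expect_equal(unclass(evolution_config("skin", seed = 1)$init_genotype),
               c(max_act = 5, lambda_act = 100))
})

fake_history <- function(ma, la, generations = 12, n_surv = 10) {
  rows <- do.call(rbind, lapply(seq_len(generations), function(g) {
    data.frame(generation = g, individual = seq_len(n_surv), parent = 1,
               max_act = rep_len(ma(g), n_surv),
               lambda_act = rep_len(la(g), n_surv),
               sim_seed = 1, fitness = 1, broken = FALSE,
               annihilated = FALSE, survivor = TRUE)
  }))
  rows
}

test_that("consensus optimum: identity, log-averaging, and rounding", {
  h <- fake_history(function(g) 50, function(g) 1165)
  expect_equal(estimate_optimum(list(h)),
               c(max_act = 50, lambda_act = 1165))
  # equal numbers of 45 and 55 pool to exp(mean(log)) = 49.75 -> 50
  h2 <- fake_history(function(g) c(45, 55), function(g) 100)
  expect_equal(estimate_optimum(list(h2))[["max_act"]], 50)
  expect_equal(exp(mean(log(c(45, 55)))), 49.749, tolerance = 1e-4)
})

test_that("non-converged runs are excluded from the consensus", {
  drifting <- fake_history(function(g) 50,
                           function(g) 5 * (500 / 5)^((g - 3) / 9 * (g > 2)))
  stable <- fake_history(function(g) 50, function(g) 1165)
  expect_equal(estimate_optimum(list(drifting, stable)),
               c(max_act = 50, lambda_act = 1165))
  expect_error(estimate_optimum(list(drifting)), "no converged")
})

test_that("the sweep cross has 13 points spaced 0.1 apart in log space", {
  pts <- sweep_points(c(max_act = 50, lambda_act = 1165))
  expect_equal(nrow(pts), 13)
  expect_equal(nrow(unique(pts[, c("max_act", "lambda_act")])), 13)
  expect_equal(max(pts$max_act), 50 * exp(0.3), tolerance = 1e-12)
  expect_equal(50 * exp(0.3), 67.49294, tolerance = 1e-6)
  centre <- pts[pts$i == 0, ]
  expect_equal(centre$max_act, 50)
  expect_equal(centre$lambda_act, 1165)
  # i = 0 appears exactly once
  expect_equal(sum(pts$i == 0), 1)
})

test_that("the trajectory preset points are available", {
  pre <- trajectory_presets()
  expect_equal(nrow(pre), 5)
  expect_true(all(c(5, 50, 110, 70, 50) == pre$max_act))
  expect_true(all(c(5, 17, 30, 150, 1185) == pre$lambda_act))
})
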