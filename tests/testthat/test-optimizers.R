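test_that("initialization respects bounds and degenerate intervals", {
  cfg <- optimizer_config("de_rand_1", D = 3, lower = 0, upper = 1,
                          N = 30, G = 5, seed = 1)
  set.seed(1)
  pop <- initialize_population(sphere, cfg)
  expect_true(all(pop$X >= 0 & pop$X <= 1))
  expect_equal(pop$fitness, apply(pop$X, 1, sphere))

  cfgc <- optimizer_config("de_rand_1", D = 2, lower = 3, upper = 3,
                           N = 5, G = 5)
  set.seed(1)
  popc <- initialize_population(sphere, cfgc)
  expect_true(all(popc$X == 3))
})

test_that("initial coordinates are uniform on the box", {
  cfg <- optimizer_config("de_rand_1", D = 1, lower = 0, upper = 1,
                          N = 10000, G = 1)
  set.seed(7)
  pop <- initialize_population(function(x) 0, cfg)
  gof <- suppressWarnings(ks.test(pop$X[, 1], "punif"))
  expect_gt(gof$p.value, 0.01)
})

test_that("stage partition follows the stage-to-ratio map", {
  G <- 25
  f <- runif(20)
  expect_equal(stage_partition(f, 0, G)$sizes, c(4L, 10L, 6L))
  expect_equal(stage_partition(f, 10, G)$sizes, c(8L, 8L, 4L))
  expect_equal(stage_partition(f, 20, G)$sizes, c(12L, 6L, 2L))
  # boundaries are real-valued: g = G/3 is still early, just above is middle
  expect_equal(stage_partition(f, 25 / 3, G)$stage, "early")
  expect_equal(stage_partition(f, 25 / 3 + 1e-9, G)$stage, "middle")

  for (N in c(10, 20, 50)) {
    f <- runif(N)
    for (g in c(0, ceiling(G / 2), G - 1)) {
      p <- stage_partition(f, g, G)
      expect_equal(sum(p$sizes), N)
      expect_true(all(p$sizes >= 1))
      idx <- c(p$els, p$mis, p$ins)
      expect_setequal(idx, seq_len(N))
      # ELS holds the best-ranked individuals
      expect_true(max(f[p$els]) <= min(f[p$mis]))
      expect_true(max(f[p$mis]) <= min(f[p$ins]))
    }
  }
})

test_that("mutation factor schedules hit their endpoints", {
  set.seed(1)
  expect_equal(mutation_factors(25, 25)$F1, 0)
  expect_equal(mutation_factors(0, 25)$F3, 0.6)
  expect_equal(mutation_factors(25, 25)$F3, 0.3)
  # F1 is bounded by alpha1 * (1 - g/G)^2 and uses a fresh uniform draw
  set.seed(2)
  draws <- replicate(50, mutation_factors(5, 25)$F1)
  expect_true(all(draws >= 0 & draws <= (1 - 5 / 25)^2))
  expect_gt(length(unique(draws)), 1)
  expect_error(mutation_factors(0, 0), "positive")
})

test_that("binomial crossover honours CR limits and its expectation", {
  target <- rep(0, 10); mutant <- rep(1, 10)
  set.seed(3)
  expect_equal(crossover_binomial(target, mutant, 1), mutant)
  # CR = 0: exactly one coordinate (the forced index) comes from the mutant
  for (r in 1:20) expect_equal(sum(crossover_binomial(target, mutant, 0)), 1)
  # Monte-Carlo mean inheritance fraction vs the closed form CR + (1 - CR)/D
  set.seed(4)
  frac <- replicate(1e5, sum(crossover_binomial(target, mutant, 0.75)) / 10)
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - (0.75 + 0.25 / 10)), 3 * se)
})

test_that("bound clipping is idempotent and coordinate-wise", {
  lb <- c(0, -1); ub <- c(1, 1)
  expect_equal(clip_to_bounds(c(0.5, 0), lb, ub), c(0.5, 0))
  expect_equal(clip_to_bounds(c(6, 0), lb, ub), c(1, 0))
  expect_equal(clip_to_bounds(c(0.5, -6), lb, ub), c(0.5, -1))
})

test_that("greedy selection is strict with target-favouring ties", {
  expect_true(select_greedy(2, 1))
  expect_false(select_greedy(1, 2))
  expect_false(select_greedy(1, 1))
  expect_false(select_greedy(1, NaN))
  expect_true(select_greedy(Inf, 1))
  expect_error(select_greedy(NaN, Inf), "non-finite")
})

test_that("classic mutation rules collapse as their formulas dictate", {
  # DE/best/1 with F = 0 returns the incumbent best
  cfg <- optimizer_config("de_best_1", D = 2, lower = -1, upper = 1,
                          N = 6, G = 1, F = 0)
  X <- matrix(runif(12, -1, 1), 6, 2)
  f <- apply(X, 1, sphere)
  set.seed(5)
  v <- qmstune:::make_mutant(X, f, 2, which.min(f), 0, cfg, NULL)
  expect_equal(v, X[which.min(f), ])
  # DE/rand-to-best/1 with lambda = 0, F = 0 returns the target itself
  cfg2 <- optimizer_config("de_rand_to_best_1", D = 2, lower = -1, upper = 1,
                           N = 6, G = 1, F = 0, lambda = 0)
  v2 <- qmstune:::make_mutant(X, f, 3, which.min(f), 0, cfg2, NULL)
  expect_equal(v2, X[3, ])
})

test_that("the middle-subpopulation rule matches a hand evaluation", {
  # v = x_i + F2 (x_best - x_i) + F3 (x_r1 - x_r2) with x_i = (0,0),
  # x_best = (1,1), x_r1 - x_r2 = (1,-1), F2 = 0.4, F3 = 0.5 -> (0.9, -0.1).
  # Replay the seeded donor draw to learn which indices are picked, then
  # place the donor vectors there.
  set.seed(11)
  r <- qmstune:::draw_indices(2, 5, 1)
  b <- setdiff(2:5, r)[1]
  X <- matrix(0, 5, 2)
  X[b, ] <- c(1, 1)
  X[r[1], ] <- c(1, 0)
  X[r[2], ] <- c(0, 1)
  cfg <- optimizer_config("de_improved", D = 2, lower = -5, upper = 5,
                          N = 5, G = 10, F2 = 0.4, alpha2 = 0.5, alpha3 = 0)
  part <- list(els = integer(0), mis = 1L, ins = setdiff(2:5, 1))
  set.seed(11)
  v <- qmstune:::make_mutant(X, rep(0, 5), 1, b, 0, cfg, part)
  expect_equal(v, c(0.9, -0.1))
})

test_that("improved DE degenerates exactly to DE/rand-to-best/1/bin", {
  inst <- bench_instance("F5", 5, 3)
  obj <- function(x) bench_evaluate(inst, x)
  Fv <- 0.7; lam <- 0.45
  all_mis <- matrix(rep(c(0, 1, 0), 3), 3, byrow = TRUE)
  cfg_i <- optimizer_config("de_improved", D = 5, lower = -100, upper = 100,
                            N = 20, G = 25, CR = 0.75,
                            alpha2 = Fv, alpha3 = 0, F2 = lam,
                            stage_ratios = all_mis, seed = 123)
  cfg_c <- optimizer_config("de_rand_to_best_1", D = 5, lower = -100,
                            upper = 100, N = 20, G = 25, CR = 0.75,
                            F = Fv, lambda = lam, seed = 123)
  ri <- run_de(obj, cfg_i)
  rc <- run_de(obj, cfg_c)
  expect_identical(ri$par, rc$par)
  expect_identical(ri$value, rc$value)
  expect_identical(ri$curve, rc$curve)
})

test_that("all DE variants solve the sphere and respect the contract", {
  strategies <- c("de_rand_1", "de_best_1", "de_rand_to_best_1",
                  "de_improved")
  for (strat in strategies) {
    hits <- 0
    for (s in 1:50) {
      cfg <- optimizer_config(strat, D = 2, lower = -5, upper = 5,
                              N = 20, G = 50, seed = s)
      seen_out_of_bounds <- FALSE
      obj <- function(x) {
        if (any(x < -5 | x > 5)) seen_out_of_bounds <<- TRUE
        sphere(x)
      }
      res <- run_de(obj, cfg)
      expect_false(seen_out_of_bounds)
      expect_length(res$curve, 51)
      expect_true(all(diff(res$curve) <= 0))
      expect_equal(res$curve[51], res$value)
      expect_equal(res$evaluations, 20 * 51)
      if (res$value < 1e-2) hits <- hits + 1
    }
    expect_gte(hits, 48)  # >= 95% of 50 seeds
  }
})

test_that("PSO inertia weight, convergence and fixed point behave", {
  expect_equal(inertia_weight(0, 25), 0.9)
  expect_equal(inertia_weight(25, 25), 0.4)
  hits <- 0
  for (s in 1:50) {
    cfg <- optimizer_config("pso", D = 2, lower = -5, upper = 5,
                            N = 20, G = 50, seed = s)
    res <- run_pso(sphere, cfg)
    expect_true(all(diff(res$curve) <= 0))
    if (res$value < 1e-2) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90% of 50 seeds
  # degenerate box: swarm starts (and stays) at a single point
  cfgc <- optimizer_config("pso", D = 2, lower = 2, upper = 2, N = 5, G = 10,
                           seed = 1)
  resc <- run_pso(sphere, cfgc)
  expect_equal(resc$par, c(2, 2))
  expect_true(all(resc$curve == 8))
})

test_that("every algorithm matches a brute-force grid on a 1-D quadratic", {
  quad <- function(x) (x - 0.317)^2
  grid_min <- min(quad(seq(-1, 1, by = 1e-4)))
  for (strat in c("de_rand_1", "de_best_1", "de_rand_to_best_1",
                  "de_improved", "pso")) {
    cfg <- optimizer_config(strat, D = 1, lower = -1, upper = 1,
                            N = 20, G = 25, seed = 4)
    res <- run_optimizer(quad, cfg)
    expect_lt(abs(res$value - grid_min), 1e-3)
  }
})

test_that("fixed seeds give bit-identical runs", {
  inst <- bench_instance("F7", 4, 6)
  obj <- function(x) bench_evaluate(inst, x)
  for (strat in c("de_improved", "pso")) {
    cfg <- optimizer_config(strat, D = 4, lower = -100, upper = 100,
                            N = 10, G = 10, seed = 77)
    a <- run_optimizer(obj, cfg)
    b <- run_optimizer(obj, cfg)
    expect_identical(a, b)
  }
})

test_that("configuration validation rejects bad inputs", {
  expect_error(optimizer_config("de_improved", D = 2, lower = 0, upper = 1,
                                N = 4), "N >= 5")
  expect_error(optimizer_config("de_rand_1", D = 2, lower = 1, upper = 0),
               "lower bound")
  cfg <- optimizer_config("pso", D = 2, lower = 0, upper = 1)
  expect_error(run_de(sphere, cfg), "run_pso")
})
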