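test_that("pheromone fields start at unit concentration", {
  f <- pheromone_field(10, m = 5)
  expect_true(all(f$tau == 1))
  expect_equal(dim(f$candidates), c(10L, 5L))
  expect_equal(f$candidates[1, ], seq(-1, 1, length.out = 5))
  expect_error(pheromone_field(0), "n_slots")
})

test_that("ant construction follows the transition rule", {
  # one candidate per slot: always that vector
  f1 <- pheromone_field(6, m = 1, range = c(0.4, 0.4))
  a <- ant_construct(f1, n = 5, seed = 1)
  expect_true(all(a == 0.4))

  # alpha = 1: deterministic argmax of the pheromone
  f <- pheromone_field(3, m = 4)
  f$alpha <- 1
  f$tau[1, ] <- c(1, 5, 1, 1)
  f$tau[2, ] <- c(9, 1, 1, 1)
  f$tau[3, ] <- c(1, 1, 1, 7)
  a <- ant_construct(f, n = 3, seed = 2)
  cand <- f$candidates
  expect_true(all(a[, 1] == cand[1, 2] & a[, 2] == cand[2, 1] &
                  a[, 3] == cand[3, 4]))

  # alpha = 0 with uniform pheromone: empirical slot frequencies uniform
  fu <- pheromone_field(1, m = 4)
  fu$alpha <- 0
  draws <- ant_construct(fu, n = 10000, seed = 3)
  freq <- table(factor(draws, levels = fu$candidates[1, ])) / 10000
  # binomial noise: sd ~ sqrt(.25*.75/1e4) ~ 0.0043; allow 5 sd
  expect_true(all(abs(freq - 0.25) < 0.022))

  # seeded construction is reproducible
  expect_identical(ant_construct(f, n = 4, seed = 9),
                   ant_construct(f, n = 4, seed = 9))
})

test_that("pheromone updates volatilize exactly and deposit by fitness", {
  f <- pheromone_field(4, m = 3)
  ants <- matrix(runif(8, -1, 1), 2, 4)
  # empty elite: pure volatilization by exactly rho
  f1 <- update_pheromone(f, ants, c(1, 2), n_elite = 0)
  expect_equal(f1$tau, f$tau * 0.9)
  f2 <- update_pheromone(f1, ants, c(1, 2), n_elite = 0)
  expect_equal(f2$tau, f$tau * 0.81)
  expect_true(all(f2$tau > 0))

  # single ant, single slot: tau_new = 0.9 * tau + Q / fitness
  g <- pheromone_field(1, m = 3, range = c(-1, 1))
  ant <- matrix(1, 1, 1)  # snaps to the third candidate (value 1)
  g1 <- update_pheromone(g, ant, fitness = 0.5, n_elite = 1, Q = 1)
  expect_equal(g1$tau[1, ], c(0.9, 0.9, 0.9 + 1 / 0.5))

  expect_warning(update_pheromone(g, ant, fitness = NaN), "non-finite")
  expect_error(update_pheromone(g, ant[0, , drop = FALSE], numeric(0)),
               "at least one")
})

test_that("the genetic step honours its operator contracts", {
  set.seed(1)
  pop <- matrix(runif(50, -1, 1), 5, 10)
  fit <- c(0.5, 0.2, 0.9, 0.4, 0.7)

  # identical parents cross over into an identical child
  twins <- pop[c(1, 1), ]
  out <- ga_step(twins, c(1, 1), crossover_rate = 1, mutation_rate = 0, seed = 4)
  expect_equal(out[1, ], pop[1, ])
  expect_equal(out[2, ], pop[1, ])

  # elitism: the best individual survives unchanged
  out <- ga_step(pop, fit, seed = 5)
  expect_equal(out[1, ], pop[2, ])

  # zero operator rates: the population is untouched
  expect_identical(ga_step(pop, fit, crossover_rate = 0, mutation_rate = 0),
                   pop)
  expect_error(ga_step(pop[1, , drop = FALSE], 1), "at least 2")
})

test_that("the hybrid search improves fitness monotonically and reproducibly", {
  d <- thd_runs()
  sp <- stratified_split(d, 21, 8, seed = 3)
  cfg <- gaaco_config(n_ants = 10, n_generations = 12, n_ga_steps = 3,
                      seed = 21)
  res <- run_gaaco(sp$train, sp$validation, config = cfg)
  expect_true(all(diff(res$trace$best) <= 0))
  expect_equal(res$best_fitness, min(res$trace$best))
  # the search beats the first generation's random ants
  expect_lt(res$best_fitness, res$trace$best[1])
  res2 <- run_gaaco(sp$train, sp$validation, config = cfg)
  expect_identical(res$best_weights, res2$best_weights)
  expect_identical(res$trace, res2$trace)
})

test_that("with one candidate and no variation the search is a fixed point", {
  d <- thd_runs()
  sp <- stratified_split(d, 21, 8, seed = 4)
  cfg <- gaaco_config(n_ants = 5, n_generations = 6, m = 1,
                      candidate_range = c(0.3, 0.3), crossover_rate = 0,
                      mutation_rate = 0, n_ga_steps = 2, seed = 8)
  res <- run_gaaco(sp$train, sp$validation, config = cfg)
  expect_true(all(res$best_weights == 0.3))
  expect_equal(diff(range(res$trace$best)), 0)
})

test_that("the GA-ACO hand-off trains end to end", {
  d <- thd_runs()
  out <- train_gaaco_bp(d, gcfg = gaaco_config(n_ants = 10, n_generations = 8,
                                               n_ga_steps = 3, seed = 31),
                        tcfg = train_config(max_epochs = 200))
  expect_s3_class(out$net, "mlp_surrogate")
  expect_true(out$net$trained)
  expect_equal(out$metrics$n, 29L)
  expect_s3_class(out$gaaco, "gaaco_result")
  # hand-off adopted: the trained run started from the best GA-ACO vector
  expect_length(out$gaaco$best_weights, n_weights(4))
})
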