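test_that("encounter payoffs are zero-sum and match bit counting", {
  pop1 <- bit_population(matrix(1L, 4, 4), role = "prey")
  g <- c(1L, 1L, 1L, 1L)
  expect_equal(coupled_fitness(g, "predator", pop1, samples = 4), 1.0)
  expect_equal(coupled_fitness(g, "prey", pop1, samples = 4), 0.0)
  # zero-sum closure on random pairs
  set.seed(5)
  for (i in 1:50) {
    a <- sample(0:1, 8, replace = TRUE)
    op <- bit_population(matrix(sample(0:1, 8, replace = TRUE), 1),
                         role = "prey")
    expect_equal(coupled_fitness(a, "predator", op, samples = 1, seed = i) +
                   coupled_fitness(a, "prey", op, samples = 1, seed = i), 1)
  }
  expect_error(
    coupled_fitness(g, "predator",
                    bit_population(matrix(0L, 0, 4), role = "prey")),
    "extinct")
})

test_that("fitness against a uniform-random population is near one half", {
  set.seed(7)
  op <- bit_population(matrix(sample(0:1, 256 * 8, replace = TRUE), 256),
                       role = "prey")
  f <- coupled_fitness(rep(1L, 8), "predator", op, samples = 256, seed = 1)
  # each encounter payoff is Binomial(8, 1/2)/8; mean over 256 opponents
  se <- sqrt(0.25 / 8) / sqrt(256)
  expect_lt(abs(f - 0.5), 3 * se)
})

test_that("memory_update is the exponential moving average", {
  expect_equal(memory_update(0.3, 0.8, 0), 0.8)
  expect_equal(memory_update(0.7, 0.7, 0.4), 0.7)  # fixed point
  # hand recursion: lambda = 0.5, inputs 1, 0, 0 from 0
  f1 <- memory_update(0, 1, 0.5)
  f2 <- memory_update(f1, 0, 0.5)
  f3 <- memory_update(f2, 0, 0.5)
  expect_equal(c(f1, f2, f3), c(0.5, 0.25, 0.125))
  expect_error(memory_update(0.5, 0.5, 1), "lambda")
  expect_error(memory_update(0.5, 1.5, 0.5), "fitness")
})

test_that("no variation operators means populations only resample", {
  params <- ga_params(L = 6, pop_size = 10, mutation_rate = 0,
                      crossover_rate = 0, repro_exponent = 0,
                      lifetime_samples = 10, generations = 5, seed = 2)
  clone <- matrix(rep(c(1L, 0L, 1L, 0L, 1L, 0L), each = 10), 10)
  run <- run_coevolution(params,
                         init_predators = bit_population(clone, "predator"),
                         init_prey = bit_population(clone, "prey"))
  expect_true(all(run$predators$genomes == clone))
  expect_true(all(run$prey$genomes == clone))
  expect_equal(unique(run$series$meanfit_pred), 1.0)  # clones match exactly
  expect_equal(unique(run$series$meanfit_prey), 0.0)
})

test_that("mutation- and crossover-free evolution creates no new genotypes", {
  # resampling alone can raise the mean pairwise Hamming distance (losing
  # copies of the majority genotype reweights the pairs), so the diversity
  # sanity check is on the genotype set: without variation operators it can
  # only shrink
  params <- ga_params(L = 10, pop_size = 20, mutation_rate = 0,
                      crossover_rate = 0, lifetime_samples = 5,
                      generations = 10, seed = 3)
  keyset <- function(pop) unique(apply(pop$genomes, 1, paste0, collapse = ""))
  set.seed(31)
  pred0 <- metatempo:::random_population(20, 10, "predator")
  prey0 <- metatempo:::random_population(20, 10, "prey")
  run <- run_coevolution(params, init_predators = pred0, init_prey = prey0)
  expect_true(all(keyset(run$predators) %in% keyset(pred0)))
  expect_true(all(keyset(run$prey) %in% keyset(prey0)))
})

test_that("frozen prey lets predators find the exhaustive best response", {
  prey0 <- bit_population(matrix(0L, 64, 8), role = "prey")
  br <- best_response_exhaustive("predator", prey0)
  expect_equal(br$genome, rep(0L, 8))
  expect_equal(br$fitness, 1)
  params <- ga_params(L = 8, pop_size = 64, mutation_rate = 0.01,
                      crossover_rate = 0.7, lifetime_samples = 10,
                      generations = 60, seed = 3)
  run <- run_coevolution(params, freeze = "prey", init_prey = prey0)
  expect_gte(utils::tail(run$series$meanfit_pred, 1), 0.95)
  expect_equal(modal_genome(run$predators), br$genome)
})

test_that("best-response convergence holds across most seeds", {
  prey_fix <- matrix(rep(c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L), each = 32), 32)
  prey0 <- bit_population(prey_fix, role = "prey")
  br <- best_response_exhaustive("predator", prey0)$genome
  hits <- vapply(1:10, function(sd) {
    params <- ga_params(L = 8, pop_size = 64, mutation_rate = 0.01,
                        crossover_rate = 0.7, lifetime_samples = 10,
                        generations = 60, seed = sd)
    run <- run_coevolution(params, freeze = "prey", init_prey = prey0)
    identical(modal_genome(run$predators), br)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("reproduction coupling shifts offspring shares against the unfit", {
  # prey pinned at the predators' exact genome -> prey fitness ~ 0
  params <- ga_params(L = 6, pop_size = 20, mutation_rate = 0,
                      crossover_rate = 0, repro_exponent = 1,
                      lifetime_samples = 5, generations = 1, seed = 4)
  same <- matrix(1L, 20, 6)
  run <- run_coevolution(params,
                         init_predators = bit_population(same, "predator"),
                         init_prey = bit_population(same, "prey"))
  expect_lt(1 - run$series$share_pred[1], 0.5)
})

test_that("runs are bit-identical given equal (params, seed)", {
  params <- ga_params(L = 12, pop_size = 24, generations = 20, seed = 99,
                      memory_lambda = 0.5, repro_exponent = 0.5,
                      lifetime_samples = 8)
  r1 <- run_coevolution(params)
  r2 <- run_coevolution(params)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$predators$genomes, r2$predators$genomes)
  # lambda = 0 makes filtered identical to instantaneous
  p0 <- ga_params(L = 12, pop_size = 24, generations = 15, seed = 7,
                  lifetime_samples = 8)
  r0 <- run_coevolution(p0)
  expect_identical(r0$series$meanfit_pred, r0$series$filtered_pred)
})
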