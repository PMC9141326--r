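cm_default <- cost_model(epsilon = 1, m_steps = 4, m_detect = 0)

test_that("joint_cost is n * m * epsilon", {
  expect_equal(joint_cost(cm_default, 16), 64)
  expect_equal(joint_cost(cost_model(0.5, 1), 10), 5)
  expect_equal(joint_cost(cm_default, 0), 0)
  expect_error(joint_cost(cm_default, -1), "n")
})

test_that("separate_cost evaluates the two-timescale ledger formula", {
  part <- timescale_partition(8, 8, tau_ratio = 1 / 4, delta = 0)
  expect_equal(separate_cost(cm_default, part), 40)
  # equal timescales collapse to the joint cost
  part1 <- timescale_partition(8, 8, tau_ratio = 1, delta = 0)
  expect_equal(separate_cost(cm_default, part1), joint_cost(cm_default, 16))
  # large overhead can exceed the joint cost
  part_hi <- timescale_partition(8, 8, tau_ratio = 1 / 4, delta = 30)
  expect_equal(separate_cost(cm_default, part_hi), 70)
  expect_gt(separate_cost(cm_default, part_hi), joint_cost(cm_default, 16))
  expect_error(timescale_partition(8, 8, tau_ratio = 0), "tau_ratio")
  expect_error(timescale_partition(8, 8, tau_ratio = 1.5), "tau_ratio")
})

test_that("metaprocessing margin is the delta = 0 saving", {
  part <- timescale_partition(8, 8, tau_ratio = 1 / 4)
  expect_equal(metaprocessing_margin(cm_default, part), 24)
  expect_equal(
    metaprocessing_margin(cm_default, timescale_partition(8, 8, 1)), 0)
  # algebraic identity: margin = joint - separate at delta = 0
  for (tr in c(0.1, 0.5, 0.9)) {
    p <- timescale_partition(5, 11, tr, delta = 0)
    expect_equal(metaprocessing_margin(cm_default, p),
                 joint_cost(cm_default, 16) - separate_cost(cm_default, p))
  }
})

test_that("selection coefficient and fitness ratio follow the saving", {
  part <- timescale_partition(8, 8, tau_ratio = 1 / 4, delta = 0)
  s <- selection_coefficient(cm_default, part)
  expect_equal(s, 0.375)
  expect_equal(fitness_ratio(s, 10), 1.375^10)
  # no saving -> s = 0, ratio 1 for all N
  p1 <- timescale_partition(8, 8, 1, delta = 0)
  expect_equal(selection_coefficient(cm_default, p1), 0)
  expect_equal(fitness_ratio(0, 50), 1)
  # delta above the margin -> s < 0, ratio shrinking in N
  p_hi <- timescale_partition(8, 8, 1 / 4, delta = 30)
  s_neg <- selection_coefficient(cm_default, p_hi)
  expect_lt(s_neg, 0)
  expect_gt(fitness_ratio(s_neg, 5), fitness_ratio(s_neg, 10))
  expect_error(
    selection_coefficient(cost_model(1, 1), timescale_partition(0, 0, 0.5)),
    "undefined")
})

test_that("phase boundary: cheaper architecture flips exactly at the margin", {
  part0 <- timescale_partition(8, 8, tau_ratio = 1 / 4)
  margin <- metaprocessing_margin(cm_default, part0)
  deltas <- seq(0, 2 * margin, length.out = 20)
  for (d in deltas) {
    p <- timescale_partition(8, 8, 1 / 4, delta = d)
    saving <- joint_cost(cm_default, 16) - separate_cost(cm_default, p)
    expect_equal(saving > 0, d < margin)
  }
})

test_that("monotonicity in tau2, n2, m, epsilon", {
  sep <- function(tr) separate_cost(
    cm_default, timescale_partition(8, 8, tr, delta = 0))
  trs <- 1 / c(2, 4, 8, 16)  # increasing tau2
  expect_true(all(diff(vapply(trs, sep, numeric(1))) < 0))
  marg <- function(n2, m, eps, tr = 1 / 4) metaprocessing_margin(
    cost_model(eps, m), timescale_partition(8, n2, tr))
  expect_true(all(diff(vapply(1:5, function(n2) marg(n2, 4, 1), numeric(1))) > 0))
  expect_true(all(diff(vapply(1:5, function(m) marg(8, m, 1), numeric(1))) > 0))
  expect_true(all(diff(vapply(1:5, function(e) marg(8, 4, e), numeric(1))) > 0))
  tr_grid <- c(0.125, 0.25, 0.5, 1)  # margin increases with tau2
  expect_true(all(diff(vapply(tr_grid, function(tr) marg(8, 4, 1, tr),
                              numeric(1))) < 0))
})

test_that("physical cost model applies the Landauer floor", {
  expect_error(cost_model_physical(300, beta = 0.1), "beta")
  cm <- cost_model_physical(300, beta = log(2))
  expect_equal(cm$epsilon, log(2) * 1.380649e-23 * 300)
})

test_that("ledger equals the formula exactly on periodic schedules", {
  stream <- generate_stream(stream_spec(8, 8, tau2 = 4, schedule = "periodic",
                                        cycles = 10000, seed = 1))
  led <- simulate_ledger(stream, "metaprocessor", cm_default)
  part <- timescale_partition(8, 8, tau_ratio = 1 / 4, delta = 0)
  expect_identical(led$mean_per_cycle, separate_cost(cm_default, part))
  mono <- simulate_ledger(stream, "monolithic", cm_default)
  expect_identical(mono$mean_per_cycle, joint_cost(cm_default, 16))
  expect_equal(led$total, sum(led$records$energy_spent))
  expect_true(all(led$records$energy_spent >= 0))
})

test_that("ledger converges to the formula on geometric schedules", {
  cm <- cost_model(epsilon = 1, m_steps = 4, m_detect = 1)
  stream <- generate_stream(stream_spec(8, 8, tau2 = 4,
                                        schedule = "geometric",
                                        cycles = 1e5, seed = 7))
  led <- simulate_ledger(stream, "metaprocessor", cm)
  part <- timescale_partition(8, 8, tau_ratio = 1 / 4)  # delta from m_detect
  expect_lt(abs(led$mean_per_cycle / separate_cost(cm, part) - 1), 0.01)
})

test_that("detector overhead enters the ledger as n2 * m_detect * epsilon", {
  cm <- cost_model(epsilon = 2, m_steps = 3, m_detect = 2)
  stream <- generate_stream(stream_spec(4, 6, tau2 = 3, schedule = "periodic",
                                        cycles = 9, seed = 1))
  led <- simulate_ledger(stream, "metaprocessor", cm)
  # per-cycle: 4*3*2 fast + 6*2*2 detector, + 6*3*2 on the 3 change cycles
  expect_equal(led$total, 9 * (24 + 24) + 3 * 36)
})

test_that("neutral competition fixes either lineage equally often", {
  fx <- compete_lineages(0, pop_size = 100, generations = 400,
                         replicates = 200, seed = 11)
  decided <- fx$fixed_meta + fx$fixed_mono
  expect_gt(decided, 150)  # drift at N=100 over 400 generations decides most
  # binomial 99% interval around 0.5 of the decided replicates
  half <- 2.58 * sqrt(0.25 / decided)
  expect_lt(abs(fx$fixed_meta / decided - 0.5), half)
})

test_that("s = 0.375 fixes the efficient lineage almost surely", {
  fx <- compete_lineages(0.375, pop_size = 1000, generations = 100,
                         replicates = 100, seed = 1)
  expect_gte(fx$fixed_meta, 95)
})

test_that("deterministic limit recovers the replicator slope exactly", {
  det <- compete_lineages(0.375, pop_size = 10, generations = 50,
                          deterministic = TRUE)
  expect_equal(det$mean_logratio_slope, log(1.375), tolerance = 1e-9)
  # stochastic slope agrees within 3 standard errors
  fx <- compete_lineages(0.2, pop_size = 5000, generations = 40,
                         replicates = 50, seed = 3)
  expect_lt(abs(fx$mean_logratio_slope - log(1.2)), 0.02)
  expect_error(compete_lineages(-1, 10, 10), "s")
})
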