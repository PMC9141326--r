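lvp <- lv_params(1, 0.1, 1.5, 0.075)

test_that("lv_derivatives match direct arithmetic and equilibria", {
  st <- ecoevo_state(10, 5)
  expect_equal(lv_derivatives(st, lvp), c(dx = 5, dy = -3.75))
  eq <- ecoevo_state(lvp$gamma0 / lvp$delta0, lvp$alpha0 / lvp$beta0)
  expect_equal(lv_derivatives(eq, lvp), c(dx = 0, dy = 0))
  # predator-free limit: exponential prey growth
  expect_equal(lv_derivatives(ecoevo_state(7, 0), lvp), c(dx = 7, dy = 0))
  expect_error(lv_params(0, 1, 1, 1), "alpha0")
})

test_that("lv_invariant is conserved along the flow and minimal at equilibrium", {
  set.seed(11)
  # finite-difference time derivative of V along the vector field ~ 0
  for (i in 1:20) {
    st <- ecoevo_state(runif(1, 1, 40), runif(1, 1, 20))
    d <- lv_derivatives(st, lvp)
    h <- 1e-6
    st2 <- list(x = st$x + h * d[["dx"]], y = st$y + h * d[["dy"]])
    dv <- (lv_invariant(st2, lvp) - lv_invariant(st, lvp)) / h
    expect_lt(abs(dv), 1e-4)
  }
  eq <- ecoevo_state(lvp$gamma0 / lvp$delta0, lvp$alpha0 / lvp$beta0)
  v_eq <- lv_invariant(eq, lvp)
  samples <- replicate(200, lv_invariant(
    list(x = runif(1, 0.5, 60), y = runif(1, 0.5, 30)), lvp))
  expect_true(all(samples >= v_eq))
  expect_error(lv_invariant(list(x = -1, y = 2), lvp), "positive")
})

test_that("integration conserves the LV invariant to 1e-6 relative", {
  traj <- integrate_ecodyn("lv", ecoevo_state(10, 5), lvp, c(0, 100))
  iv <- apply(traj$series, 1, function(r)
    lv_invariant(list(x = r[["x"]], y = r[["y"]]), lvp))
  expect_lt(max(abs(iv - iv[1])) / abs(iv[1]), 1e-6)
})

test_that("coexistence equilibrium is stationary to machine precision", {
  eq <- ecoevo_state(lvp$gamma0 / lvp$delta0, lvp$alpha0 / lvp$beta0)
  traj <- integrate_ecodyn("lv", eq, lvp, c(0, 50), n_out = 100)
  expect_equal(max(abs(traj$series$x - eq$x)), 0, tolerance = 1e-10)
  expect_equal(max(abs(traj$series$y - eq$y)), 0, tolerance = 1e-10)
})

test_that("prey peaks precede predator peaks in every detected cycle", {
  traj <- integrate_ecodyn("lv", ecoevo_state(10, 5), lvp, c(0, 100))
  px <- oscillation_peaks(traj, "x")$peaks
  py <- oscillation_peaks(traj, "y")$peaks
  # for each prey peak, the next predator peak comes before the next prey peak
  for (i in seq_len(nrow(px) - 1)) {
    lag <- py$time - px$time[i]
    lag <- lag[lag > 0]
    expect_true(length(lag) > 0)
    expect_lt(min(lag), px$time[i + 1] - px$time[i])
  }
  # conservative system: near-constant amplitude envelope
  amps <- oscillation_peaks(traj, "x")$amplitudes
  expect_lt((max(amps) - min(amps)) / mean(amps), 0.05)
})

test_that("oscillation_peaks handles constant and synthetic inputs", {
  flat <- data.frame(t = 0:10, x = rep(2, 11))
  expect_equal(nrow(oscillation_peaks(flat, "x")$peaks), 0)
  tt <- seq(0, 4 * pi, length.out = 400)
  wave <- data.frame(t = tt, x = sin(tt))
  pk <- oscillation_peaks(wave, "x")$peaks
  # exact recovery at the sampled resolution: the grid argmax of each lobe
  expect_equal(pk$time, c(tt[which.max(sin(tt) * (tt < pi))],
                          tt[which.max(sin(tt) * (tt > 2 * pi))]))
  short <- data.frame(t = 0:1, x = 0:1)
  expect_warning(oscillation_peaks(short, "x"), "too short")
})

test_that("trait gradients match central finite differences of fitness", {
  skip_if_not_installed("numDeriv")
  set.seed(21)
  for (fr in c("mass_action", "holling2")) {
    ep <- ecoevo_params(lvp, V1 = 0.3, V2 = 0.4, c1 = 0.5, c2 = 0.7,
                        conversion = 0.75, functional_response = fr,
                        K = if (fr == "holling2") 40 else NULL,
                        h = if (fr == "holling2") 0.2 else NULL)
    for (i in 1:50) {
      st <- ecoevo_state(runif(1, 1, 40), runif(1, 1, 20),
                         runif(1, -2, 2), runif(1, -2, 2))
      g <- trait_gradients(st, ep)
      fd_u <- numDeriv::grad(function(ui)
        percap_fitness(st, ep, u_i = ui)[["w1"]], st$u)
      fd_v <- numDeriv::grad(function(vi)
        percap_fitness(st, ep, v_i = vi)[["w2"]], st$v)
      expect_equal(g[["du"]], ep$V1 * fd_u, tolerance = 1e-6)
      expect_equal(g[["dv"]], ep$V2 * fd_v, tolerance = 1e-6)
    }
  }
})

test_that("zero genetic variance freezes the traits", {
  ep <- ecoevo_params(lvp, V1 = 0, V2 = 0, c1 = 1, c2 = 1, conversion = 0.75)
  st <- ecoevo_state(10, 5, 0.3, -0.2)
  expect_equal(trait_gradients(st, ep), c(du = 0, dv = 0))
})

test_that("coevolution converges to plain LV as variances vanish", {
  ep <- ecoevo_params(lvp, V1 = 1e-6, V2 = 1e-6, c1 = 0.5, c2 = 0.5,
                      conversion = 0.75)
  t_lv <- integrate_ecodyn("lv", ecoevo_state(10, 5), lvp, c(0, 30),
                           n_out = 300)
  t_co <- integrate_ecodyn("lv_coevo", ecoevo_state(10, 5, 0, 0), ep,
                           c(0, 30), n_out = 300)
  expect_lt(max(abs(t_co$series$x - t_lv$series$x)), 1e-3)
  expect_lt(max(abs(t_co$series$y - t_lv$series$y)), 1e-3)
})

test_that("shipped damped-coevolution config loses its oscillations", {
  cfg <- jsonlite::read_json(
    system.file("configs", "coevo_damped.json", package = "metatempo"),
    simplifyVector = TRUE)
  ep <- ecoevo_params(lv_params(cfg$alpha0, cfg$beta0, cfg$gamma0,
                                cfg$delta0),
                      V1 = cfg$V1, V2 = cfg$V2, c1 = cfg$c1, c2 = cfg$c2,
                      conversion = cfg$conversion)
  traj <- integrate_ecodyn("lv_coevo", ecoevo_state(cfg$x0, cfg$y0),
                           ep, c(0, cfg$t_end), n_out = cfg$n_out)
  amps <- oscillation_peaks(traj, "x")$amplitudes
  expect_gte(length(amps), 3)
  expect_gt(amps[1], amps[2])
  expect_gt(amps[2], amps[3])
  x <- traj$series$x; n <- length(x)
  cv <- function(z) stats::sd(z) / mean(z)
  cv_first <- cv(x[1:round(0.2 * n)])
  cv_last <- cv(x[round(0.8 * n):n])
  expect_lt(cv_last, 0.1 * cv_first)
  # same initial ecology without evolution keeps cycling
  t_lv <- integrate_ecodyn("lv", ecoevo_state(cfg$x0, cfg$y0),
                           lv_params(cfg$alpha0, cfg$beta0, cfg$gamma0,
                                     cfg$delta0),
                           c(0, cfg$t_end), n_out = cfg$n_out)
  xl <- t_lv$series$x
  expect_gte(cv(xl[round(0.8 * n):n]) / cv(xl[1:round(0.2 * n)]), 0.8)
})

test_that("Rosenzweig-MacArthur equilibrium matches the root-finding oracle", {
  ep <- ecoevo_params(lvp, conversion = 0.75,
                      functional_response = "holling2", K = 60, h = 0.05)
  # interior equilibrium: conv*b*x/(1+b*h*x) = gamma -> solve for x
  b <- 2 * lvp$beta0 / 2
  f <- function(x) ep$conversion * b * x / (1 + b * x * ep$h) - lvp$gamma0
  x_star <- stats::uniroot(f, c(1, 1000), tol = 1e-12)$root
  y_star <- lvp$alpha0 * (1 - x_star / ep$K) * (1 + b * ep$h * x_star) / b
  st <- ecoevo_state(x_star, y_star)
  w <- percap_fitness(st, ep)
  expect_equal(unname(w), c(0, 0), tolerance = 1e-8)
  # and it is stationary under integration
  traj <- integrate_ecodyn("rm", st, ep, c(0, 20), n_out = 50)
  expect_equal(utils::tail(traj$series$x, 1), x_star, tolerance = 1e-6)
})

test_that("solver failure reports a structured error", {
  blow <- function(t, y) y^2  # finite-time blow-up
  expect_error(ode_integrate(blow, 1, c(0, 10), max_steps = 200),
               "exceeded")
})
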