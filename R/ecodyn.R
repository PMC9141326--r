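#' Baseline Lotka--Volterra parameters
#'
#' The classical predator--prey interaction dx/dt = alpha*x - beta*x*y,
#' dy/dt = delta*x*y - gamma*y with all four rates positive: alpha = prey
#' per-capita growth, beta = predation rate, delta = predator growth per
#' consumed prey, gamma = predator per-capita mortality.
#'
#' @param alpha0,beta0,gamma0,delta0 Positive reals.
#' @return An object of class \code{"lv_params"}.
#' @export
lv_params <- function(alpha0, beta0, gamma0, delta0) {
  structure(list(
    alpha0 = check_scalar(alpha0, "alpha0", lower = 0, closed_lower = FALSE),
    beta0 = check_scalar(beta0, "beta0", lower = 0, closed_lower = FALSE),
    gamma0 = check_scalar(gamma0, "gamma0", lower = 0, closed_lower = FALSE),
    delta0 = check_scalar(delta0, "delta0", lower = 0, closed_lower = FALSE)),
    class = "lv_params")
}

#' Eco-evolutionary parameters: ecology plus trait genetics
#'
#' Extends [lv_params()] with quantitative-genetic trait dynamics. The prey
#' carries a defence trait u and the predator an offence trait v, entering
#' the ecological rates as alpha(u) = alpha0 - c1*u^2 (defence is costly),
#' beta(u, v) = 2*beta0 / (1 + exp(u - v)) (offence and defence push the
#' encounter rate in opposite directions, saturating at twice the baseline
#' so quadratic costs always contain the marginal benefit), gamma(v) =
#' gamma0 + c2*v^2 (offence is costly), and delta = conversion *
#' beta(u, v). Traits evolve at a rate
#' equal to their genetic variance times the fitness gradient, the
#' derivative of per-capita growth with respect to a rare mutant's
#' phenotype evaluated at the resident value.
#'
#' @param lv An [lv_params()] object (baseline rates at u = v = 0).
#' @param V1 Genetic variance of the prey trait (>= 0).
#' @param V2 Genetic variance of the predator trait (>= 0).
#' @param c1 Prey trait cost coefficient (> 0).
#' @param c2 Predator trait cost coefficient (> 0).
#' @param conversion Conversion efficiency linking attack rate to predator
#'   growth (> 0).
#' @param functional_response \code{"mass_action"} (classical bilinear) or
#'   \code{"holling2"} (Rosenzweig--MacArthur: logistic prey growth with
#'   carrying capacity \code{K} and a saturating type-II response with
#'   handling time \code{h}).
#' @param K Prey carrying capacity (> 0; holling2 only).
#' @param h Handling time (> 0; holling2 only).
#' @return An object of class \code{"ecoevo_params"}.
#' @export
ecoevo_params <- function(lv, V1 = 0, V2 = 0, c1 = 1, c2 = 1,
                          conversion = 1,
                          functional_response = c("mass_action", "holling2"),
                          K = NULL, h = NULL) {
  if (!inherits(lv, "lv_params")) stop_field("lv", "not an lv_params")
  functional_response <- match.arg(functional_response)
  if (functional_response == "holling2") {
    K <- check_scalar(K, "K", lower = 0, closed_lower = FALSE)
    h <- check_scalar(h, "h", lower = 0, closed_lower = FALSE)
  }
  structure(list(
    lv = lv,
    V1 = check_scalar(V1, "V1", lower = 0),
    V2 = check_scalar(V2, "V2", lower = 0),
    c1 = check_scalar(c1, "c1", lower = 0, closed_lower = FALSE),
    c2 = check_scalar(c2, "c2", lower = 0, closed_lower = FALSE),
    conversion = check_scalar(conversion, "conversion", lower = 0,
                              closed_lower = FALSE),
    functional_response = functional_response, K = K, h = h),
    class = "ecoevo_params")
}

#' Eco-evolutionary state
#'
#' @param x Prey density (>= 0).
#' @param y Predator density (>= 0).
#' @param u Prey defence trait.
#' @param v Predator offence trait.
#' @export
ecoevo_state <- function(x, y, u = 0, v = 0) {
  structure(list(x = check_scalar(x, "x", lower = 0),
                 y = check_scalar(y, "y", lower = 0),
                 u = check_scalar(u, "u"), v = check_scalar(v, "v")),
            class = "ecoevo_state")
}

#' Lotka--Volterra growth rates
#'
#' @param state An [ecoevo_state()] (traits ignored) or a list with x, y.
#' @param params An [lv_params()].
#' @return Named vector \code{c(dx, dy)}.
#' @export
lv_derivatives <- function(state, params) {
  if (!inherits(params, "lv_params")) stop_field("params", "not an lv_params")
  x <- state$x; y <- state$y
  c(dx = params$alpha0 * x - params$beta0 * x * y,
    dy = params$delta0 * x * y - params$gamma0 * y)
}

#' First integral of the Lotka--Volterra system
#'
#' V(x, y) = delta*x - gamma*log(x) + beta*y - alpha*log(y) is constant
#' along exact trajectories and minimal at the coexistence equilibrium
#' (gamma/delta, alpha/beta); its drift along a numerical trajectory bounds
#' the integration error.
#'
#' @inheritParams lv_derivatives
#' @export
lv_invariant <- function(state, params) {
  if (!inherits(params, "lv_params")) stop_field("params", "not an lv_params")
  if (state$x <= 0 || state$y <= 0)
    stop_field("state", "invariant requires strictly positive densities")
  params$delta0 * state$x - params$gamma0 * log(state$x) +
    params$beta0 * state$y - params$alpha0 * log(state$y)
}

# trait-dependent rates: quadratic costs; bounded (sigmoid) encounter
# trade-off so quadratic costs can always contain the marginal benefit
# (an unbounded form such as beta0*exp(v-u) drives trait runaway and
# mutual extinction)
rate_alpha <- function(p, u) p$lv$alpha0 - p$c1 * u^2
rate_beta  <- function(p, u, v) 2 * p$lv$beta0 / (1 + exp(u - v))
rate_gamma <- function(p, v) p$lv$gamma0 + p$c2 * v^2
# d beta / d v = -d beta / d u = beta * (1 - beta / (2 beta0))
rate_beta_dv <- function(p, b) b * (1 - b / (2 * p$lv$beta0))

#' Per-capita fitness of a rare mutant in the resident ecology
#'
#' Prey fitness w1 is the per-capita growth rate of a mutant with defence
#' trait \code{u_i} in the ecology set by the resident state; predator
#' fitness w2 likewise for a mutant offence trait \code{v_i}. Used both by
#' the analytic [trait_gradients()] and as the target of finite-difference
#' checks.
#'
#' @param state Resident [ecoevo_state()].
#' @param params [ecoevo_params()].
#' @param u_i,v_i Mutant trait values (default: resident values).
#' @return Named vector \code{c(w1, w2)}.
#' @export
percap_fitness <- function(state, params, u_i = state$u, v_i = state$v) {
  x <- state$x; y <- state$y
  if (params$functional_response == "mass_action") {
    w1 <- rate_alpha(params, u_i) - rate_beta(params, u_i, state$v) * y
    w2 <- params$conversion * rate_beta(params, state$u, v_i) * x -
      rate_gamma(params, v_i)
  } else {
    b1 <- rate_beta(params, u_i, state$v)
    b2 <- rate_beta(params, state$u, v_i)
    w1 <- rate_alpha(params, u_i) * (1 - x / params$K) -
      b1 * y / (1 + b1 * params$h * x)
    w2 <- params$conversion * b2 * x / (1 + b2 * params$h * x) -
      rate_gamma(params, v_i)
  }
  c(w1 = unname(w1), w2 = unname(w2))
}

#' Trait evolution rates (fitness-gradient dynamics)
#'
#' Each trait changes at its genetic variance times the selection gradient:
#' du/dt = V1 * dw1/du_i |_{u_i = u}, dv/dt = V2 * dw2/dv_i |_{v_i = v},
#' the mutant derivative taken before setting mutant = resident. Gradients
#' are analytic; the test suite checks them against central finite
#' differences of [percap_fitness()].
#'
#' @inheritParams percap_fitness
#' @return Named vector \code{c(du, dv)}.
#' @export
trait_gradients <- function(state, params) {
  if (!inherits(params, "ecoevo_params"))
    stop_field("params", "not an ecoevo_params")
  x <- state$x; y <- state$y; u <- state$u; v <- state$v
  b <- rate_beta(params, u, v)
  bv <- rate_beta_dv(params, b)  # = -d beta/d u
  if (params$functional_response == "mass_action") {
    dw1 <- -2 * params$c1 * u + bv * y          # d/du [alpha(u) - beta(u,v) y]
    dw2 <- params$conversion * bv * x - 2 * params$c2 * v
  } else {
    sat <- 1 + b * params$h * x
    dw1 <- -2 * params$c1 * u * (1 - x / params$K) + bv * y / sat^2
    dw2 <- params$conversion * bv * x / sat^2 - 2 * params$c2 * v
  }
  c(du = unname(params$V1 * dw1), dv = unname(params$V2 * dw2))
}

ecology_derivatives <- function(x, y, u, v, params) {
  st <- list(x = x, y = y, u = u, v = v)
  w <- percap_fitness(structure(st, class = "ecoevo_state"), params)
  c(x * w[["w1"]], y * w[["w2"]])
}

#' Integrate an ecological or eco-evolutionary system
#'
#' Systems: \code{"lv"} (2-d classical), \code{"rm"} (2-d
#' Rosenzweig--MacArthur), and their 4-d coevolutionary extensions
#' \code{"lv_coevo"}, \code{"rm_coevo"} where traits follow
#' [trait_gradients()]. Integration uses the package's adaptive
#' Dormand--Prince scheme; densities falling below \code{extinction_floor}
#' are clamped to zero in the reported trajectory.
#'
#' @param system One of \code{"lv"}, \code{"lv_coevo"}, \code{"rm"},
#'   \code{"rm_coevo"}.
#' @param init An [ecoevo_state()].
#' @param params [lv_params()] for 2-d systems (or an [ecoevo_params()]
#'   whose ecology is used); [ecoevo_params()] for coevolutionary systems.
#' @param t_span Length-2 numeric: start and end time.
#' @param n_out Number of equally spaced output times.
#' @param rtol,atol Solver tolerances.
#' @param extinction_floor Densities below this are clamped to 0.
#' @return An object of class \code{"trajectory"}: data frame \code{series}
#'   with columns t, x, y (and u, v for coevolutionary systems), the
#'   solver \code{stats}, and the call's metadata.
#' @export
integrate_ecodyn <- function(system = c("lv", "lv_coevo", "rm", "rm_coevo"),
                             init, params, t_span, n_out = 2000,
                             rtol = 1e-8, atol = 1e-10,
                             extinction_floor = 1e-9) {
  system <- match.arg(system)
  if (!inherits(init, "ecoevo_state")) stop_field("init", "not an ecoevo_state")
  if (length(t_span) != 2 || !all(is.finite(t_span)) || t_span[2] <= t_span[1])
    stop_field("t_span", "must be two finite increasing times")
  coevo <- system %in% c("lv_coevo", "rm_coevo")
  fr <- if (system %in% c("rm", "rm_coevo")) "holling2" else "mass_action"
  # wrapping bare LV rates: delta = conversion * beta, so conversion is
  # fixed by delta0/beta0 to reproduce dy/dt = delta*x*y - gamma*y exactly
  ep <- if (inherits(params, "ecoevo_params")) params
        else ecoevo_params(params, conversion = params$delta0 / params$beta0)
  if (ep$functional_response != fr) {
    if (fr == "holling2")
      stop_field("params", "rm systems need ecoevo_params with functional_response='holling2'")
    ep$functional_response <- "mass_action"
  }
  times <- seq(t_span[1], t_span[2], length.out = n_out)
  floor_pos <- function(z) pmax(z, 0)
  if (coevo) {
    f <- function(t, s) {
      xy <- ecology_derivatives(floor_pos(s[1]), floor_pos(s[2]), s[3], s[4], ep)
      uv <- trait_gradients(structure(list(x = floor_pos(s[1]),
                                           y = floor_pos(s[2]),
                                           u = s[3], v = s[4]),
                                      class = "ecoevo_state"), ep)
      unname(c(xy, uv))
    }
    y0 <- c(init$x, init$y, init$u, init$v)
  } else {
    f <- function(t, s)
      ecology_derivatives(floor_pos(s[1]), floor_pos(s[2]), init$u, init$v, ep)
    y0 <- c(init$x, init$y)
  }
  sol <- tryCatch(
    ode_integrate(f, y0, times, rtol = rtol, atol = atol),
    ode_failure = function(e) {
      stop(sprintf("integration failed at t = %.6g (state: %s): %s",
                   e$last_t, paste(signif(e$last_y, 6), collapse = ", "),
                   conditionMessage(e)), call. = FALSE)
    })
  dens <- sol$y[, 1:2, drop = FALSE]
  dens[dens < extinction_floor] <- 0
  series <- data.frame(t = sol$times, x = dens[, 1], y = dens[, 2])
  if (coevo) { series$u <- sol$y[, 3]; series$v <- sol$y[, 4] }
  structure(list(series = series, stats = sol$stats, system = system,
                 params = ep, init = init),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> system=%s, %d points, t in [%g, %g]\n",
              x$system, nrow(x$series), min(x$series$t), max(x$series$t)))
  invisible(x)
}

#' Locate oscillation peaks and the amplitude envelope
#'
#' Local maxima by three-point comparison (optionally after a centred
#' moving-average smoothing); the amplitude envelope is the drop from each
#' peak to the following trough.
#'
#' @param traj A [integrate_ecodyn()] trajectory, or a data frame with a
#'   time column \code{t}.
#' @param variable Column to analyse (e.g. \code{"x"}).
#' @param smooth Odd moving-average window (1 = none).
#' @return A list with data frame \code{peaks} (time, value), data frame
#'   \code{troughs}, and numeric \code{amplitudes} (peak minus next trough).
#' @export
oscillation_peaks <- function(traj, variable = "x", smooth = 1L) {
  series <- if (inherits(traj, "trajectory")) traj$series else traj
  if (nrow(series) < 3) {
    warning("trajectory too short for peak detection")
    return(list(peaks = data.frame(time = numeric(), value = numeric()),
                troughs = data.frame(time = numeric(), value = numeric()),
                amplitudes = numeric()))
  }
  z <- series[[variable]]
  if (smooth > 1) {
    k <- as.integer(smooth)
    if (k %% 2 == 0) k <- k + 1L
    z <- stats::filter(z, rep(1 / k, k), sides = 2)
    keep <- !is.na(z)
    z <- as.numeric(z[keep]); tt <- series$t[keep]
  } else tt <- series$t
  n <- length(z)
  im <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  it <- which(z[2:(n - 1)] < z[1:(n - 2)] & z[2:(n - 1)] <= z[3:n]) + 1L
  peaks <- data.frame(time = tt[im], value = z[im])
  troughs <- data.frame(time = tt[it], value = z[it])
  amps <- vapply(seq_len(nrow(peaks)), function(i) {
    nx <- troughs$time > peaks$time[i]
    if (any(nx)) peaks$value[i] - troughs$value[which(nx)[1]] else NA_real_
  }, numeric(1))
  list(peaks = peaks, troughs = troughs, amplitudes = amps[!is.na(amps)])
}
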