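# Adaptive explicit Runge-Kutta integrator (Dormand-Prince 5(4)).
# Written in-package because no ODE-solving package is available in the
# target environment. Embedded 4th-order error estimate drives PI step-size
# control; output is returned at caller-requested times via the scheme's
# 4th-order dense interpolant (cubic Hermite on the accepted steps).

dopri_tableau <- local({
  A <- matrix(0, 7, 7)
  A[2, 1] <- 1 / 5
  A[3, 1:2] <- c(3 / 40, 9 / 40)
  A[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
  A[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
  A[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
                 -5103 / 18656)
  A[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  cc <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  list(A = A, b5 = b5, b4 = b4, c = cc)
})

#' Integrate an ODE system with an adaptive Runge--Kutta scheme
#'
#' Dormand--Prince 5(4) with proportional-integral step-size control and
#' first-same-as-last reuse. Solutions are reported at the requested output
#' times by cubic Hermite interpolation on the accepted steps, so tightening
#' the output grid does not change the integration path.
#'
#' @param f Derivative function \code{f(t, y)} returning \code{dy/dt}.
#' @param y0 Initial state vector.
#' @param times Strictly increasing output times; \code{times[1]} is t0.
#' @param rtol,atol Relative and absolute error tolerances.
#' @param max_steps Hard cap on accepted + rejected steps.
#' @return A list with matrix \code{y} (rows = output times), \code{times},
#'   and \code{stats} (accepted/rejected step counts, f evaluations).
#' @keywords internal
ode_integrate <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                          max_steps = 5e5) {
  if (length(times) < 2 || any(diff(times) <= 0))
    stop_field("times", "must be strictly increasing with length >= 2")
  tb <- dopri_tableau
  d <- length(y0)
  out <- matrix(NA_real_, length(times), d)
  out[1, ] <- y0
  t <- times[1]; y <- y0
  k1 <- f(t, y); nfev <- 1L
  h <- initial_step(f, t, y, k1, rtol, atol)
  t_end <- times[length(times)]
  next_out <- 2L
  n_acc <- 0L; n_rej <- 0L
  err_prev <- 1
  K <- matrix(0, 7, d)
  while (t < t_end) {
    if (n_acc + n_rej >= max_steps) {
      stop(structure(class = c("ode_failure", "error", "condition"),
                     list(message = sprintf(
                       "ODE solver exceeded %d steps at t = %.6g", max_steps, t),
                       call = NULL, last_t = t, last_y = y)))
    }
    h <- min(h, t_end - t)
    K[1, ] <- k1
    for (i in 2:7) {
      yi <- y + h * drop(tb$A[i, 1:(i - 1), drop = FALSE] %*%
                           K[1:(i - 1), , drop = FALSE])
      K[i, ] <- f(t + tb$c[i] * h, yi)
    }
    nfev <- nfev + 6L
    y5 <- y + h * drop(tb$b5 %*% K)
    err_vec <- h * drop((tb$b5 - tb$b4) %*% K)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean((err_vec / sc)^2))
    if (!is.finite(err)) err <- 2  # reject and shrink on overflow
    if (err <= 1) {
      t_new <- t + h
      # dense output: cubic Hermite using derivatives at both ends (K[7,]
      # is f(t_new, y5) by the FSAL property)
      while (next_out <= length(times) && times[next_out] <= t_new + 1e-14 * abs(t_new)) {
        s <- (times[next_out] - t) / h
        h00 <- (1 + 2 * s) * (1 - s)^2
        h10 <- s * (1 - s)^2
        h01 <- s^2 * (3 - 2 * s)
        h11 <- s^2 * (s - 1)
        out[next_out, ] <- h00 * y + h10 * h * K[1, ] +
          h01 * y5 + h11 * h * K[7, ]
        next_out <- next_out + 1L
      }
      y <- y5; t <- t_new
      k1 <- K[7, ]  # FSAL
      n_acc <- n_acc + 1L
      fac <- 0.9 * err^(-0.7 / 5) * err_prev^(0.4 / 5)
      h <- h * min(5, max(0.2, fac))
      err_prev <- max(err, 1e-4)
    } else {
      n_rej <- n_rej + 1L
      h <- h * max(0.2, 0.9 * err^(-1 / 5))
    }
  }
  out[length(times), ] <- y
  list(times = times, y = out,
       stats = list(accepted = n_acc, rejected = n_rej, n_eval = nfev,
                    rtol = rtol, atol = atol))
}

initial_step <- function(f, t0, y0, f0, rtol, atol) {
  sc <- atol + rtol * abs(y0)
  d0 <- sqrt(mean((y0 / sc)^2))
  d1 <- sqrt(mean((f0 / sc)^2))
  h0 <- if (d0 < 1e-5 || d1 < 1e-5) 1e-6 else 0.01 * d0 / d1
  y1 <- y0 + h0 * f0
  f1 <- f(t0 + h0, y1)
  d2 <- sqrt(mean(((f1 - f0) / sc)^2)) / h0
  h1 <- if (max(d1, d2) <= 1e-15) max(1e-6, h0 * 1e-3)
        else (0.01 / max(d1, d2))^(1 / 5)
  min(100 * h0, h1)
}
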