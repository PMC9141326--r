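#' Pattern space: the background ("real") pattern distribution
#'
#' Patterns are d-dimensional feature vectors; the background is a mixture
#' of isotropic Gaussians. The one-dimensional configuration (d = 1)
#' corresponds to an arms race constrained to a single physical dimension.
#'
#' @param d Pattern dimension (>= 1, default 2).
#' @param means Component means: k x d matrix (or vector for k = 1).
#' @param cov_scale Shared standard deviation (> 0).
#' @param weights Mixture weights (sum to 1); default uniform.
#' @return An object of class \code{"pattern_space"}.
#' @export
pattern_space <- function(d = 2L, means = matrix(0, 1, d), cov_scale = 1,
                          weights = NULL) {
  d <- check_scalar(d, "d", lower = 1, integer = TRUE)
  if (!is.matrix(means)) means <- matrix(means, ncol = d)
  if (ncol(means) != d) stop_field("means", "must have d columns")
  if (is.null(weights)) weights <- rep(1 / nrow(means), nrow(means))
  weights <- check_prob_vector(weights, "weights")
  if (length(weights) != nrow(means))
    stop_field("weights", "one weight per mixture component")
  cov_scale <- check_scalar(cov_scale, "cov_scale", lower = 0,
                            closed_lower = FALSE)
  structure(list(d = d, means = means, cov_scale = cov_scale,
                 weights = weights),
            class = "pattern_space")
}

#' Generator (prey camouflage) parameters
#'
#' The prey's pattern distribution: a Gaussian mixture with learnable
#' component means, shared covariance scale, and weights (stored as logits
#' so gradient steps preserve the simplex constraint).
#'
#' @param means k x d matrix of component means.
#' @param cov_scale Shared standard deviation (> 0).
#' @param weights Mixture weights (sum to 1).
#' @return An object of class \code{"generator_params"}.
#' @export
generator_params <- function(means, cov_scale = 1, weights = NULL) {
  if (!is.matrix(means)) means <- matrix(means, nrow = 1)
  if (is.null(weights)) weights <- rep(1 / nrow(means), nrow(means))
  weights <- check_prob_vector(weights, "weights")
  cov_scale <- check_scalar(cov_scale, "cov_scale", lower = 0,
                            closed_lower = FALSE)
  structure(list(means = means, cov_scale = cov_scale,
                 logits = log(pmax(weights, 1e-12))),
            class = "generator_params")
}

gen_weights <- function(gen) {
  w <- exp(gen$logits - max(gen$logits))
  w / sum(w)
}

sample_mixture <- function(n, means, cov_scale, weights) {
  k <- nrow(means); d <- ncol(means)
  comp <- sample.int(k, n, replace = TRUE, prob = weights)
  means[comp, , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = cov_scale), n, d)
}

#' Sample background patterns
#' @param space A [pattern_space()].
#' @param n Sample count.
#' @export
sample_background <- function(space, n) {
  sample_mixture(n, space$means, space$cov_scale, space$weights)
}

#' Sample generated (prey) patterns
#' @param gen A [generator_params()].
#' @param n Sample count.
#' @export
sample_generator <- function(gen, n) {
  sample_mixture(n, gen$means, gen$cov_scale, gen_weights(gen))
}

# monomial features up to the given degree (degree 2 default: x_i and
# x_i * x_j for i <= j)
poly_features <- function(X, degree = 2L) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  d <- ncol(X)
  feats <- X
  if (degree >= 2) {
    for (i in seq_len(d)) for (j in i:d)
      feats <- cbind(feats, X[, i] * X[, j])
  }
  if (degree >= 3) {
    for (i in seq_len(d)) feats <- cbind(feats, X[, i]^3)
  }
  feats
}

n_poly_features <- function(d, degree = 2L) {
  nf <- d
  if (degree >= 2) nf <- nf + d * (d + 1) / 2
  if (degree >= 3) nf <- nf + d
  as.integer(nf)
}

#' Discriminator (predator classifier) parameters
#'
#' A logistic classifier over a fixed polynomial feature expansion of the
#' pattern vector; score = P(pattern is generated).
#'
#' @param d Pattern dimension.
#' @param degree Polynomial degree of the feature map (default 2).
#' @param weights Feature weights (default all zero = untrained).
#' @param bias Intercept.
#' @return An object of class \code{"discriminator_params"}.
#' @export
discriminator_params <- function(d, degree = 2L, weights = NULL, bias = 0) {
  d <- check_scalar(d, "d", lower = 1, integer = TRUE)
  degree <- check_scalar(degree, "degree", lower = 1, upper = 3,
                         integer = TRUE)
  nf <- n_poly_features(d, degree)
  if (is.null(weights)) weights <- rep(0, nf)
  if (length(weights) != nf || !all(is.finite(weights)))
    stop_field("weights", sprintf("must be %d finite values", nf))
  bias <- check_scalar(bias, "bias")
  structure(list(d = d, degree = degree, weights = weights, bias = bias),
            class = "discriminator_params")
}

disc_linear <- function(disc, X) {
  drop(poly_features(X, disc$degree) %*% disc$weights) + disc$bias
}

disc_score <- function(disc, X) {
  1 / (1 + exp(-disc_linear(disc, X)))
}

#' Detection rate of the discriminator against the generator
#'
#' Fraction of \code{n_eval} generator samples the discriminator classifies
#' as generated (score strictly above 0.5; a tie at exactly 0.5 classifies
#' "real", favouring the prey).
#'
#' @param disc A [discriminator_params()].
#' @param gen A [generator_params()].
#' @param space A [pattern_space()] (unused for sampling, kept for
#'   interface symmetry and validation).
#' @param n_eval Number of evaluation samples (>= 1).
#' @param seed Optional seed (\code{NULL} = current RNG stream).
#' @return Rate in [0, 1].
#' @export
detection_rate <- function(disc, gen, space = NULL, n_eval = 1000L,
                           seed = NULL) {
  n_eval <- check_scalar(n_eval, "n_eval", lower = 1, integer = TRUE)
  run <- function() {
    x <- sample_generator(gen, n_eval)
    mean(disc_score(disc, x) > 0.5)
  }
  if (is.null(seed)) run() else with_seed(substream_seed(seed, "detect"), run())
}

#' One discriminator update (gradient ascent on the logistic likelihood)
#'
#' Labels: generated = 1, real = 0. Performs one ascent step on the mean
#' log-likelihood of the correct labels over the combined batch.
#'
#' @param disc A [discriminator_params()].
#' @param real Matrix of background samples (rows = patterns).
#' @param generated Matrix of generator samples.
#' @param learning_rate Step size (>= 0).
#' @return Updated [discriminator_params()].
#' @export
update_discriminator <- function(disc, real, generated, learning_rate = 0.5) {
  learning_rate <- check_scalar(learning_rate, "learning_rate", lower = 0)
  if (!nrow(real) || !nrow(generated))
    stop_field("real", "batches must be non-empty")
  X <- rbind(real, generated)
  y <- c(rep(0, nrow(real)), rep(1, nrow(generated)))
  phi <- poly_features(X, disc$degree)
  s <- 1 / (1 + exp(-(drop(phi %*% disc$weights) + disc$bias)))
  resid <- y - s
  gw <- drop(crossprod(phi, resid)) / length(y)
  gb <- mean(resid)
  if (!all(is.finite(gw)) || !is.finite(gb))
    stop(sprintf(
      "non-finite discriminator gradient (batch means: real %.3g, generated %.3g)",
      mean(real), mean(generated)), call. = FALSE)
  discriminator_params(disc$d, disc$degree,
                       weights = disc$weights + learning_rate * gw,
                       bias = disc$bias + learning_rate * gb)
}

# d/dtheta log p_theta(x) for the mixture: responsibilities drive the
# mean, scale, and logit gradients
mixture_score_grads <- function(X, means, cov_scale, weights) {
  n <- nrow(X); k <- nrow(means); d <- ncol(means)
  logcomp <- matrix(0, n, k)
  for (j in seq_len(k)) {
    diff <- sweep(X, 2, means[j, ])
    logcomp[, j] <- log(weights[j]) - d * log(cov_scale) -
      rowSums(diff^2) / (2 * cov_scale^2)
  }
  mx <- apply(logcomp, 1, max)
  r <- exp(logcomp - mx)
  r <- r / rowSums(r)
  list(resp = r)
}

#' One generator update (score-function gradient on the detection score)
#'
#' Takes one stochastic gradient step on the generator's mixture
#' parameters decreasing the mean discriminator score of its samples. Uses
#' the score-function (likelihood-ratio) estimator with the batch-mean
#' score as baseline, so a flat discriminator yields an exactly zero
#' gradient. Covariance scales are clamped at \code{cov_floor}.
#'
#' @param gen A [generator_params()].
#' @param disc A [discriminator_params()].
#' @param space A [pattern_space()] (interface symmetry).
#' @param batch_size Samples drawn for the estimate.
#' @param learning_rate Step size (>= 0).
#' @param seed Optional seed (\code{NULL} = current RNG stream).
#' @param cov_floor Lower bound on cov_scale (default 1e-3).
#' @return Updated [generator_params()].
#' @export
update_generator <- function(gen, disc, space = NULL, batch_size = 200L,
                             learning_rate = 0.1, seed = NULL,
                             cov_floor = 1e-3) {
  learning_rate <- check_scalar(learning_rate, "learning_rate", lower = 0)
  batch_size <- check_scalar(batch_size, "batch_size", lower = 2,
                             integer = TRUE)
  run <- function() {
    w <- gen_weights(gen)
    X <- sample_mixture(batch_size, gen$means, gen$cov_scale, w)
    f <- disc_score(disc, X)
    adv <- f - mean(f)  # baseline: batch mean
    sg <- mixture_score_grads(X, gen$means, gen$cov_scale, w)
    r <- sg$resp
    k <- nrow(gen$means); d <- ncol(gen$means)
    g_means <- matrix(0, k, d)
    g_scale <- 0
    g_logits <- numeric(k)
    for (j in seq_len(k)) {
      diff <- sweep(X, 2, gen$means[j, ])
      coef <- adv * r[, j]
      g_means[j, ] <- colSums(coef * diff) / (gen$cov_scale^2 * batch_size)
      g_scale <- g_scale +
        sum(coef * (rowSums(diff^2) / gen$cov_scale^3 - d / gen$cov_scale)) /
        batch_size
      g_logits[j] <- sum(adv * (r[, j] - w[j])) / batch_size
    }
    new_scale <- max(cov_floor, gen$cov_scale - learning_rate * g_scale)
    if (gen$cov_scale - learning_rate * g_scale < cov_floor)
      warning("generator covariance clamped at the floor", call. = FALSE)
    out <- gen
    out$means <- gen$means - learning_rate * g_means
    out$cov_scale <- new_scale
    out$logits <- gen$logits - learning_rate * g_logits
    out
  }
  if (is.null(seed)) run() else with_seed(substream_seed(seed, "genupd"), run())
}

#' Default arms-race configuration
#'
#' @param space A [pattern_space()].
#' @param gen Initial [generator_params()].
#' @param disc Initial [discriminator_params()] (default untrained).
#' @param batch_size Training batch per side per iteration.
#' @param n_eval Samples per detection-rate evaluation.
#' @param lr_disc,lr_gen Learning rates.
#' @param disc_steps Gradient ascent steps the discriminator takes per
#'   iteration (on that iteration's batch); several steps approximate the
#'   batch maximum-likelihood fit.
#' @param calibrate If TRUE (default), after the discriminator's steps the
#'   intercept is recentred so the combined batch's median linear score is
#'   zero; the classification rule stays "score > 0.5" but chance-level
#'   detection then sits at 0.5 rather than depending on the arbitrary
#'   direction of near-zero weights.
#' @param window Sliding window K for the termination rules.
#' @param tol Equilibrium tolerance around chance level.
#' @param max_iters Iteration cap.
#' @param freeze_generator If TRUE the prey never updates (used for the
#'   extinction demonstration).
#' @export
arms_race_config <- function(space, gen, disc = NULL, batch_size = 1000L,
                             n_eval = 2000L, lr_disc = 0.5, lr_gen = 0.05,
                             disc_steps = 25L, calibrate = TRUE,
                             window = 20L, tol = 0.05, max_iters = 2000L,
                             freeze_generator = FALSE) {
  if (!inherits(space, "pattern_space")) stop_field("space", "not a pattern_space")
  if (!inherits(gen, "generator_params")) stop_field("gen", "not a generator_params")
  if (is.null(disc)) disc <- discriminator_params(space$d)
  list(space = space, gen = gen, disc = disc,
       batch_size = check_scalar(batch_size, "batch_size", lower = 1,
                                 integer = TRUE),
       n_eval = check_scalar(n_eval, "n_eval", lower = 1, integer = TRUE),
       lr_disc = check_scalar(lr_disc, "lr_disc", lower = 0),
       lr_gen = check_scalar(lr_gen, "lr_gen", lower = 0),
       disc_steps = check_scalar(disc_steps, "disc_steps", lower = 1,
                                 integer = TRUE),
       calibrate = isTRUE(calibrate),
       window = check_scalar(window, "window", lower = 1, integer = TRUE),
       tol = check_scalar(tol, "tol", lower = 0, upper = 0.5),
       max_iters = check_scalar(max_iters, "max_iters", lower = 1,
                                integer = TRUE),
       freeze_generator = isTRUE(freeze_generator))
}

#' Run the camouflage arms race
#'
#' Alternates discriminator and generator updates and evaluates the
#' detection rate each iteration. Termination rules, checked on a sliding
#' window of K iterations once at least K have run: \describe{
#'   \item{prey_extinct}{detection rate = 1.0 on \emph{every} iteration of
#'     the window — the predator finds 100\% of the generated targets on
#'     every iteration.}
#'   \item{equilibrium}{rate within \code{tol} of chance (0.5) throughout
#'     the window.}
#'   \item{predator_blind}{rate at or below \code{0.5 - tol} throughout the
#'     window (sustained below-chance detection; the symmetric rule, an
#'     extension to the stated prey-side rule).}
#'   \item{max_iters}{iteration cap reached with no rule fired.}}
#'
#' @param config An [arms_race_config()].
#' @param seed Integer seed (one stream drives the whole run).
#' @return An object of class \code{"arms_race_outcome"}: \code{status},
#'   \code{iterations}, \code{final_rate}, the per-iteration \code{series}
#'   data frame (iter, detection_rate, disc_norm), and the final
#'   \code{gen}/\code{disc} parameters.
#' @export
run_arms_race <- function(config, seed = 1L) {
  with_seed(substream_seed(seed, "armsrace"), {
    gen <- config$gen; disc <- config$disc
    K <- config$window
    rates <- numeric(0)
    status <- "max_iters"
    it <- 0L
    while (it < config$max_iters) {
      it <- it + 1L
      real <- sample_background(config$space, config$batch_size)
      fake <- sample_generator(gen, config$batch_size)
      for (k in seq_len(config$disc_steps))
        disc <- update_discriminator(disc, real, fake, config$lr_disc)
      if (config$calibrate) {
        lp <- disc_linear(disc, rbind(real, fake))
        disc$bias <- disc$bias - stats::median(lp)
      }
      if (!config$freeze_generator)
        gen <- update_generator(gen, disc, config$space,
                                batch_size = config$batch_size,
                                learning_rate = config$lr_gen)
      rates[it] <- detection_rate(disc, gen, config$space, config$n_eval)
      if (it >= K) {
        win <- rates[(it - K + 1L):it]
        if (all(win == 1)) { status <- "prey_extinct"; break }
        if (all(abs(win - 0.5) <= config$tol)) { status <- "equilibrium"; break }
        if (all(win <= 0.5 - config$tol)) { status <- "predator_blind"; break }
      }
    }
    series <- data.frame(iter = seq_len(it), detection_rate = rates,
                         disc_norm = NA_real_)
    series$disc_norm[it] <- sqrt(sum(disc$weights^2) + disc$bias^2)
    structure(list(status = status, iterations = it,
                   final_rate = rates[it], series = series,
                   gen = gen, disc = disc, window = K),
              class = "arms_race_outcome")
  })
}

#' @export
print.arms_race_outcome <- function(x, ...) {
  cat(sprintf("<arms_race_outcome> %s after %d iterations (final detection rate %.3f)\n",
              x$status, x$iterations, x$final_rate))
  invisible(x)
}
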