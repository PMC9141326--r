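#' Discrete generative model over external states
#'
#' A finite Bayesian agent: a prior \code{p(e)} over external (environmental)
#' states and a row-stochastic likelihood \code{p(m | e)} giving the
#' probability of each observable blanket state m under each external state.
#' The model's parameters play the role of the agent's internal state; the
#' agent's current belief is a separate [belief()] object.
#'
#' @param prior Probability vector over external states (sums to 1 within
#'   1e-12).
#' @param likelihood Matrix with one row per external state and one column
#'   per blanket state; each row sums to 1 within 1e-12.
#' @param external_states Optional character labels for external states.
#' @param blanket_states Optional character labels for blanket states.
#' @return An object of class \code{"generative_model"}.
#' @export
generative_model <- function(prior, likelihood,
                             external_states = NULL, blanket_states = NULL) {
  prior <- check_prob_vector(prior, "prior")
  if (!is.matrix(likelihood) || nrow(likelihood) != length(prior))
    stop_field("likelihood", "must be a matrix with one row per external state")
  if (any(likelihood < 0))
    stop_field("likelihood", "entries must be non-negative")
  rs <- rowSums(likelihood)
  if (any(abs(rs - 1) > 1e-12))
    stop_field("likelihood", "every row must sum to 1 within 1e-12")
  if (is.null(external_states))
    external_states <- paste0("e", seq_along(prior))
  if (is.null(blanket_states))
    blanket_states <- paste0("m", seq_len(ncol(likelihood)))
  if (length(external_states) != length(prior))
    stop_field("external_states", "label count must match prior length")
  if (length(blanket_states) != ncol(likelihood))
    stop_field("blanket_states", "label count must match likelihood columns")
  dimnames(likelihood) <- list(external_states, blanket_states)
  names(prior) <- external_states
  structure(list(prior = prior, likelihood = likelihood,
                 external_states = external_states,
                 blanket_states = blanket_states),
            class = "generative_model")
}

#' Variational belief over external states
#'
#' @param q Probability vector over external states.
#' @return An object of class \code{"belief"}.
#' @export
belief <- function(q) {
  structure(list(q = check_prob_vector(q, "q")), class = "belief")
}

resolve_blanket <- function(model, m) {
  if (is.character(m)) {
    j <- match(m, model$blanket_states)
    if (is.na(j)) stop_field("m", sprintf("unknown blanket state '%s'", m))
    j
  } else {
    check_scalar(m, "m", lower = 1, upper = length(model$blanket_states),
                 integer = TRUE)
  }
}

#' Kullback--Leibler divergence between two discrete distributions
#'
#' \code{KL(p || q) = sum p * log(p / q)} in nats, with the convention
#' \code{0 * log(0/q) = 0}. Where \code{p > 0} but \code{q = 0} the
#' divergence is infinite; \code{Inf} is returned rather than an error.
#'
#' @param p,q Probability vectors of equal length.
#' @return Non-negative divergence in nats (possibly \code{Inf}).
#' @export
kl_divergence <- function(p, q) {
  p <- check_prob_vector(p, "p")
  q <- check_prob_vector(q, "q")
  if (length(p) != length(q))
    stop_field("q", "must have the same length as p")
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * (log(p[pos]) - log(q[pos])))
}

#' Variational free energy of a belief given an observation
#'
#' For blanket state m, \code{F = -log p(m) + KL(q || p(. | m))}: surprisal
#' (negative log model evidence, with \code{p(m) = sum_e p(e) p(m|e)}) plus
#' the divergence of the belief from the exact posterior. F upper-bounds the
#' surprisal for every belief and attains it exactly when the belief is the
#' posterior. (Conditioning on the model parameters contributes only a
#' constant offset for a fixed model and is dropped.)
#'
#' @param model A [generative_model()].
#' @param m Blanket state: index or label.
#' @param bel A [belief()].
#' @return A list of class \code{"vfe"} with \code{total},
#'   \code{evidence_term} (-log p(m)), and \code{kl_term}; \code{total =
#'   evidence_term + kl_term} to machine precision.
#' @export
vfe <- function(model, m, bel) {
  j <- resolve_blanket(model, m)
  if (!inherits(bel, "belief")) stop_field("bel", "not a belief")
  if (length(bel$q) != length(model$prior))
    stop_field("bel", "belief length must match the number of external states")
  joint <- model$prior * model$likelihood[, j]
  pm <- sum(joint)
  if (pm == 0) {
    return(structure(list(total = Inf, evidence_term = Inf, kl_term = NA_real_),
                     class = "vfe"))
  }
  posterior <- joint / pm
  kl <- kl_divergence(bel$q, posterior)
  structure(list(total = -log(pm) + kl, evidence_term = -log(pm),
                 kl_term = kl),
            class = "vfe")
}

#' @export
print.vfe <- function(x, ...) {
  cat(sprintf("<vfe> total %.6g nats = surprisal %.6g + KL %.6g\n",
              x$total, x$evidence_term, x$kl_term))
  invisible(x)
}

#' Exact Bayes posterior belief for an observation
#'
#' Returns \code{p(e | m)}, the belief that minimises the variational free
#' energy over all beliefs (at which the bound on surprisal is tight).
#'
#' @inheritParams vfe
#' @export
posterior_belief <- function(model, m) {
  j <- resolve_blanket(model, m)
  joint <- model$prior * model$likelihood[, j]
  pm <- sum(joint)
  if (pm == 0)
    stop_field("m", "blanket state has zero evidence under the model")
  belief(joint / pm)
}

#' Fitness as one minus total prediction error
#'
#' Survival probability g = 1 - delta, mapping the generative model's total
#' prediction error delta in [0, 1] to a fitness in [0, 1].
#'
#' @param delta Total prediction error in [0, 1].
#' @export
prediction_fitness <- function(delta) {
  1 - check_scalar(delta, "delta", lower = 0, upper = 1)
}

#' Mean VFE of a lagged-belief agent under likelihood drift
#'
#' Simulates an agent tracking a persistent external state: each cycle the
#' state is kept with probability \code{persistence} (otherwise redrawn from
#' the prior), the current model's likelihood emits a blanket state, and the
#' observation's VFE is scored under the belief the agent carried in from
#' the \emph{previous} cycle (its lagged filter posterior). The belief is
#' then updated by a one-step Bayes filter under the current model.
#'
#' The agent's own generative model is \code{models[[1]]} and is used for
#' all scoring and belief updating; the schedule drives the \emph{emission}
#' law only. With a constant schedule (emission = the agent's model) the
#' carried belief accumulates evidence about the persistent state and the
#' mean VFE settles low. When the emission law drifts away from the agent's
#' model, observations systematically mislead the carried belief, so the
#' mean VFE rises -- unanticipated variation in the agent--environment
#' coupling increases free energy. Two modelling points matter: the drift
#' must be unanticipated (an agent filtering with the true current model
#' tracks the drift at no cost), and the external state must persist (with
#' independent redraws every cycle, beliefs averaged over any emission law
#' with the shared marginal reduce to the prior and the expected excess is
#' identically zero).
#'
#' @param models A list of [generative_model()] objects sharing state
#'   spaces; \code{models[[1]]} is the agent's model, and cycle t emits from
#'   \code{models[[1 + (t-1) %% length(models)]]}.
#' @param horizon Number of cycles (>= 2).
#' @param seed Integer seed.
#' @param persistence Probability the external state carries over between
#'   cycles, in [0, 1) (default 0.95).
#' @return A list with \code{mean_vfe}, \code{se} (standard error of the
#'   per-cycle VFE mean), and the per-cycle series \code{vfe_series}.
#' @export
average_vfe_under_drift <- function(models, horizon, seed = 1L,
                                    persistence = 0.95) {
  if (!is.list(models) || !length(models) ||
      !all(vapply(models, inherits, logical(1), "generative_model")))
    stop_field("models", "must be a non-empty list of generative_model objects")
  ne <- length(models[[1]]$prior)
  nm <- length(models[[1]]$blanket_states)
  for (md in models) {
    if (length(md$prior) != ne || length(md$blanket_states) != nm)
      stop_field("models", "all models must share external and blanket state spaces")
  }
  horizon <- check_scalar(horizon, "horizon", lower = 2, integer = TRUE)
  persistence <- check_scalar(persistence, "persistence", lower = 0,
                              upper = 1, closed_upper = FALSE)
  with_seed(substream_seed(seed, "vfedrift"), {
    agent <- models[[1]]
    emitter_at <- function(t) models[[1L + (t - 1L) %% length(models)]]
    e <- sample.int(ne, 1L, prob = agent$prior)
    m_obs <- sample.int(nm, 1L, prob = agent$likelihood[e, ])
    bel <- posterior_belief(agent, m_obs)
    series <- numeric(horizon - 1L)
    for (t in 2L:horizon) {
      em <- emitter_at(t)
      if (stats::runif(1) >= persistence)
        e <- sample.int(ne, 1L, prob = em$prior)
      m_obs <- sample.int(nm, 1L, prob = em$likelihood[e, ])
      series[t - 1L] <- vfe(agent, m_obs, bel)$total
      # one-step Bayes filter under the agent's model:
      # persistence-mixed prediction, then update
      pred <- persistence * bel$q + (1 - persistence) * agent$prior
      post <- pred * agent$likelihood[, m_obs]
      if (sum(post) == 0) {  # observation impossible under the carried
        pred <- agent$prior  # belief: reset to the prior
        post <- pred * agent$likelihood[, m_obs]
      }
      bel <- belief(post / sum(post))
    }
    list(mean_vfe = mean(series),
         se = stats::sd(series) / sqrt(length(series)),
         vfe_series = series)
  })
}
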