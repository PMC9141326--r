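#' Thermodynamic cost model for per-bit information processing
#'
#' Landauer's principle prices every erased (hence rewritten) bit at no less
#' than kB*T*ln2 of free energy; a realistic processor pays eps = beta*kB*T
#' per bit with efficiency factor beta >= ln 2. The model stores eps as a
#' single positive energy per processed bit (default 1, natural units),
#' the number of computational steps \code{m_steps} each input bit costs per
#' sensation--action cycle, and \code{m_detect}, the per-slow-bit cost of the
#' always-on change detector that a metaprocessing architecture runs.
#'
#' @param epsilon Energy per processed bit (> 0). Default 1 (natural units).
#' @param m_steps Computational steps per input bit per cycle (integer >= 1).
#' @param m_detect Detector steps per slow bit per cycle (integer >= 0);
#'   parameterises the metaprocessing overhead.
#' @return An object of class \code{"cost_model"}.
#' @seealso [cost_model_physical()] for SI units.
#' @export
cost_model <- function(epsilon = 1, m_steps = 1L, m_detect = 0L) {
  structure(list(
    epsilon = check_scalar(epsilon, "epsilon", lower = 0, closed_lower = FALSE),
    m_steps = check_scalar(m_steps, "m_steps", lower = 1, integer = TRUE),
    m_detect = check_scalar(m_detect, "m_detect", lower = 0, integer = TRUE)),
    class = "cost_model")
}

#' Cost model from temperature and thermodynamic efficiency
#'
#' Convenience constructor setting epsilon = beta * kB * T in joules, with
#' kB = 1.380649e-23 J/K and efficiency beta >= ln 2 (the Landauer limit).
#'
#' @param temperature_K Temperature in kelvin (> 0).
#' @param beta Thermodynamic efficiency factor (>= ln 2).
#' @inheritParams cost_model
#' @export
cost_model_physical <- function(temperature_K, beta = log(2),
                                m_steps = 1L, m_detect = 0L) {
  temperature_K <- check_scalar(temperature_K, "temperature_K",
                                lower = 0, closed_lower = FALSE)
  beta <- check_scalar(beta, "beta", lower = log(2))
  kB <- 1.380649e-23
  cost_model(epsilon = beta * kB * temperature_K,
             m_steps = m_steps, m_detect = m_detect)
}

#' Two-timescale partition of the sensory input
#'
#' Describes how the n input bits split into a fast sector (\code{n1} bits,
#' changing every cycle) and a slow sector (\code{n2} bits, changing every
#' \code{1/tau_ratio} cycles on average), plus the per-cycle overhead energy
#' \code{delta} of the change detector ("switch") that separate processing
#' requires. If \code{delta} is omitted it is concretised as
#' \code{n2 * m_detect * epsilon} when a cost model is supplied alongside.
#'
#' @param n1 Fast-sector bit count (integer >= 0).
#' @param n2 Slow-sector bit count (integer >= 0).
#' @param tau_ratio Ratio of the cycle time to the slow timescale, in (0, 1].
#' @param delta Overhead energy per cycle (>= 0), or \code{NULL} to derive
#'   it from a cost model's \code{m_detect}.
#' @return An object of class \code{"timescale_partition"}.
#' @export
timescale_partition <- function(n1, n2, tau_ratio, delta = NULL) {
  n1 <- check_scalar(n1, "n1", lower = 0, integer = TRUE)
  n2 <- check_scalar(n2, "n2", lower = 0, integer = TRUE)
  tau_ratio <- check_scalar(tau_ratio, "tau_ratio", lower = 0, upper = 1,
                            closed_lower = FALSE)
  if (!is.null(delta)) delta <- check_scalar(delta, "delta", lower = 0)
  structure(list(n1 = n1, n2 = n2, tau_ratio = tau_ratio, delta = delta),
            class = "timescale_partition")
}

part_delta <- function(part, cost) {
  if (!is.null(part$delta)) part$delta
  else part$n2 * cost$m_detect * cost$epsilon
}

#' Joint (monolithic) processing cost per cycle
#'
#' An architecture that reprocesses all \code{n} input bits on every
#' sensation--action cycle pays \code{n * m_steps * epsilon} per cycle.
#'
#' @param cost A [cost_model()].
#' @param n Total number of input bits (>= 0).
#' @return Energy per cycle.
#' @export
joint_cost <- function(cost, n) {
  n <- check_scalar(n, "n", lower = 0)
  n * cost$m_steps * cost$epsilon
}

#' Separate (metaprocessing) processing cost per cycle
#'
#' With the slow sector reprocessed only when it changes, the per-cycle cost
#' is \code{Xi = (n1 + tau_ratio * n2) * m_steps * epsilon + delta}, where
#' \code{delta} is the overhead of detecting slow-sector changes.
#'
#' @param cost A [cost_model()].
#' @param part A [timescale_partition()].
#' @return Energy per cycle.
#' @export
separate_cost <- function(cost, part) {
  if (!inherits(part, "timescale_partition"))
    stop_field("part", "not a timescale_partition")
  (part$n1 + part$tau_ratio * part$n2) * cost$m_steps * cost$epsilon +
    part_delta(part, cost)
}

#' Maximum affordable metaprocessing overhead
#'
#' Separate processing beats joint processing exactly when its overhead
#' \code{delta} stays below \code{(1 - tau_ratio) * n2 * m_steps * epsilon}
#' -- the energy saved on slow-sector reprocessing. At equal timescales
#' (\code{tau_ratio = 1}) the margin is zero: metaprocessing never pays.
#'
#' @inheritParams separate_cost
#' @return The margin Delta_max (energy per cycle).
#' @export
metaprocessing_margin <- function(cost, part) {
  if (!inherits(part, "timescale_partition"))
    stop_field("part", "not a timescale_partition")
  (1 - part$tau_ratio) * part$n2 * cost$m_steps * cost$epsilon
}

#' Selection coefficient of the metaprocessing architecture
#'
#' The per-cycle energy saving of separate processing, normalised by the
#' joint per-cycle budget: \code{s = (joint - separate) / joint}. The
#' normalisation makes the advantage dimensionless; the unnormalised
#' exponential-amplification form is recovered when energy units are chosen
#' so that the joint budget equals 1.
#'
#' @inheritParams separate_cost
#' @param n Total bit count; must equal \code{part$n1 + part$n2}.
#' @return Dimensionless selection coefficient s (positive when separate
#'   processing is cheaper).
#' @seealso [fitness_ratio()]
#' @export
selection_coefficient <- function(cost, part, n = part$n1 + part$n2) {
  n <- check_scalar(n, "n", lower = 0)
  if (n != part$n1 + part$n2)
    stop_field("n", "must equal part$n1 + part$n2")
  jc <- joint_cost(cost, n)
  if (jc == 0) stop_field("n", "joint cost is zero; selection coefficient undefined")
  (jc - separate_cost(cost, part)) / jc
}

#' Fitness ratio after N generations
#'
#' An energy saving with selection coefficient s compounds across
#' generations: after N generations the efficient lineage's relative
#' fitness is \code{(1 + s)^N}, growing (or shrinking, for s < 0)
#' exponentially at rate \code{log(1 + s)} per generation.
#'
#' @param s Selection coefficient (> -1).
#' @param N Number of generations (>= 0).
#' @export
fitness_ratio <- function(s, N) {
  s <- check_scalar(s, "s", lower = -1, closed_lower = FALSE)
  N <- check_scalar(N, "N", lower = 0)
  (1 + s)^N
}

#' Simulate an energy ledger for an architecture on a stream
#'
#' Charges the agent cycle by cycle. The monolithic architecture pays
#' \code{(n1+n2) * m_steps * epsilon} every cycle. The metaprocessor pays
#' \code{n1 * m_steps * epsilon} every cycle, an always-on detector cost
#' \code{n2 * m_detect * epsilon} every cycle, and the slow-sector
#' processing cost \code{n2 * m_steps * epsilon} only on cycles where the
#' slow sector changed.
#'
#' @param stream An [generate_stream()] result.
#' @param architecture \code{"monolithic"} or \code{"metaprocessor"}.
#' @param cost A [cost_model()].
#' @return An object of class \code{"energy_ledger"}: data frame
#'   \code{records} (cycle, architecture, bits_processed, energy_spent),
#'   plus \code{total} and \code{mean_per_cycle}.
#' @export
simulate_ledger <- function(stream,
                            architecture = c("monolithic", "metaprocessor"),
                            cost) {
  if (!inherits(stream, "input_stream"))
    stop_field("stream", "not an input_stream")
  architecture <- match.arg(architecture)
  spec <- stream$spec
  n <- spec$n1 + spec$n2
  if (architecture == "monolithic") {
    bits <- rep(n, spec$cycles)
    energy <- bits * cost$m_steps * cost$epsilon
  } else {
    bits <- spec$n1 + ifelse(stream$change_flags, spec$n2, 0)
    energy <- bits * cost$m_steps * cost$epsilon +
      spec$n2 * cost$m_detect * cost$epsilon
  }
  records <- data.frame(cycle = seq_len(spec$cycles) - 1L,
                        architecture = architecture,
                        bits_processed = bits,
                        energy_spent = energy,
                        stringsAsFactors = FALSE)
  structure(list(records = records, total = sum(energy),
                 mean_per_cycle = mean(energy)),
            class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat(sprintf("<energy_ledger> %d cycles (%s): total %.6g, mean/cycle %.6g\n",
              nrow(x$records), x$records$architecture[1], x$total,
              x$mean_per_cycle))
  invisible(x)
}

#' Wright--Fisher competition between metaprocessing and monolithic lineages
#'
#' Two haploid lineages with relative fitness 1 + s (metaprocessing) and 1
#' (monolithic) start at frequency 0.5 in a population of fixed size and are
#' resampled binomially with fitness-weighted probabilities each generation.
#' Reports how often the metaprocessing lineage fixates and the mean
#' per-generation slope of \code{log(p/(1-p))} while both lineages segregate
#' (which equals \code{log(1+s)} in the deterministic, infinite-population
#' limit).
#'
#' @param s Selection coefficient (> -1).
#' @param pop_size Population size (integer >= 2); ignored when
#'   \code{deterministic}.
#' @param generations Number of generations to simulate.
#' @param replicates Number of independent replicates.
#' @param seed Integer seed.
#' @param deterministic If TRUE, iterate the infinite-population replicator
#'   map instead of binomial resampling (single replicate, no fixation).
#' @return An object of class \code{"fixation_summary"}: \code{replicates},
#'   \code{fixed_meta}, \code{fixed_mono}, \code{mean_logratio_slope},
#'   \code{s_analytic}, and per-replicate final frequencies \code{freqs}.
#' @export
compete_lineages <- function(s, pop_size, generations, replicates = 1L,
                             seed = 1L, deterministic = FALSE) {
  s <- check_scalar(s, "s", lower = -1, closed_lower = FALSE)
  generations <- check_scalar(generations, "generations", lower = 1,
                              integer = TRUE)
  if (deterministic) {
    # infinite-population replicator map; slopes are accumulated only while
    # both lineages retain numerically resolvable frequency (the map
    # saturates p at 1.0 in floating point after ~50/log(1+s) generations)
    p <- 0.5
    slopes <- numeric(0)
    for (g in seq_len(generations)) {
      p_new <- p * (1 + s) / (p * (1 + s) + (1 - p))
      if (p_new > 1e-6 && p_new < 1 - 1e-6)
        slopes <- c(slopes, log(p_new / (1 - p_new)) - log(p / (1 - p)))
      p <- p_new
    }
    return(structure(list(replicates = 1L, fixed_meta = NA_integer_,
                          fixed_mono = NA_integer_,
                          mean_logratio_slope = mean(slopes),
                          s_analytic = s, freqs = p),
                     class = "fixation_summary"))
  }
  pop_size <- check_scalar(pop_size, "pop_size", lower = 2, integer = TRUE)
  replicates <- check_scalar(replicates, "replicates", lower = 1,
                             integer = TRUE)
  fixed_meta <- 0L; fixed_mono <- 0L
  slopes <- c(); freqs <- numeric(replicates)
  with_seed(substream_seed(seed, "compete"), {
    for (r in seq_len(replicates)) {
      k <- as.integer(round(pop_size / 2))
      for (g in seq_len(generations)) {
        p <- k / pop_size
        if (p == 0 || p == 1) break
        p_sel <- p * (1 + s) / (p * (1 + s) + (1 - p))
        k_new <- stats::rbinom(1L, pop_size, p_sel)
        if (k_new > 0L && k_new < pop_size)
          slopes <- c(slopes, log(k_new / (pop_size - k_new)) -
                        log(k / (pop_size - k)))
        k <- k_new
      }
      freqs[r] <- k / pop_size
      if (k == pop_size) fixed_meta <- fixed_meta + 1L
      if (k == 0L) fixed_mono <- fixed_mono + 1L
    }
  })
  structure(list(replicates = replicates, fixed_meta = fixed_meta,
                 fixed_mono = fixed_mono,
                 mean_logratio_slope = if (length(slopes)) mean(slopes) else NA_real_,
                 s_analytic = s, freqs = freqs),
            class = "fixation_summary")
}

#' @export
print.fixation_summary <- function(x, ...) {
  cat(sprintf(
    "<fixation_summary> s=%.4g: meta fixed %s/%d, mean log-ratio slope %.4g (ln(1+s)=%.4g)\n",
    x$s_analytic, ifelse(is.na(x$fixed_meta), "NA", x$fixed_meta),
    x$replicates, x$mean_logratio_slope, log(1 + x$s_analytic)))
  invisible(x)
}
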