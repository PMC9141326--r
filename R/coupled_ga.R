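#' Parameters for a coupled (two-population) genetic algorithm
#'
#' Two bitstring populations — predators and prey — each compute the other's
#' fitness, so selection chases a moving target (Red Queen dynamics). Two
#' stabilising mechanisms are exposed: a fitness memory (exponential moving
#' average with decay \code{memory_lambda}, so a lineage remembers how fit
#' it has been against the other species in previous lifetimes) and a
#' performance-dependent reproduction rate (offspring shares scale with mean
#' filtered fitness to the power \code{repro_exponent}, conserving the total
#' number of individuals across both populations).
#'
#' @param L Genome length in bits (>= 1).
#' @param pop_size Individuals per population at initialisation.
#' @param mutation_rate Per-bit flip probability in [0, 1].
#' @param crossover_rate Per-mating probability of single-point crossover.
#' @param selection \code{"tournament_k"} (size-2 tournament, default) or
#'   \code{"proportional"}.
#' @param memory_lambda Fitness-memory decay in [0, 1); 0 = memoryless.
#' @param repro_exponent Reproduction-coupling strength kappa >= 0; 0 =
#'   fixed equal population sizes.
#' @param lifetime_samples Opponents sampled per fitness evaluation
#'   (partial, continuous "lifetime" evaluation; the all-pairs limit is
#'   \code{lifetime_samples = pop_size}).
#' @param generations Number of generations for [run_coevolution()].
#' @param seed Integer seed.
#' @param elitism Copies of the best individual preserved per population
#'   (0 = off, default).
#' @return An object of class \code{"ga_params"}.
#' @export
ga_params <- function(L, pop_size, mutation_rate = 0.01,
                      crossover_rate = 0.7,
                      selection = c("tournament_k", "proportional"),
                      memory_lambda = 0, repro_exponent = 0,
                      lifetime_samples = 10L, generations = 100L,
                      seed = 1L, elitism = 0L) {
  structure(list(
    L = check_scalar(L, "L", lower = 1, integer = TRUE),
    pop_size = check_scalar(pop_size, "pop_size", lower = 2, integer = TRUE),
    mutation_rate = check_scalar(mutation_rate, "mutation_rate",
                                 lower = 0, upper = 1),
    crossover_rate = check_scalar(crossover_rate, "crossover_rate",
                                  lower = 0, upper = 1),
    selection = match.arg(selection),
    memory_lambda = check_scalar(memory_lambda, "memory_lambda",
                                 lower = 0, upper = 1, closed_upper = FALSE),
    repro_exponent = check_scalar(repro_exponent, "repro_exponent", lower = 0),
    lifetime_samples = check_scalar(lifetime_samples, "lifetime_samples",
                                    lower = 1, integer = TRUE),
    generations = check_scalar(generations, "generations", lower = 1,
                               integer = TRUE),
    seed = check_scalar(seed, "seed", integer = TRUE),
    elitism = check_scalar(elitism, "elitism", lower = 0, integer = TRUE)),
    class = "ga_params")
}

#' Bitstring population
#'
#' @param genomes Integer 0/1 matrix, one row per individual.
#' @param role \code{"predator"} or \code{"prey"}.
#' @param filtered_fitness Memory-filtered fitness per individual in [0,1];
#'   defaults to the neutral value 0.5.
#' @export
bit_population <- function(genomes, role = c("predator", "prey"),
                           filtered_fitness = NULL) {
  role <- match.arg(role)
  if (!is.matrix(genomes) || !all(genomes %in% c(0L, 1L)))
    stop_field("genomes", "must be a 0/1 matrix")
  if (is.null(filtered_fitness))
    filtered_fitness <- rep(0.5, nrow(genomes))
  if (length(filtered_fitness) != nrow(genomes) ||
      any(filtered_fitness < 0 | filtered_fitness > 1))
    stop_field("filtered_fitness", "must be one value in [0,1] per genome")
  structure(list(genomes = genomes, filtered_fitness = filtered_fitness,
                 role = role),
            class = "bit_population")
}

random_population <- function(n, L, role) {
  bit_population(matrix(sample(0:1, n * L, replace = TRUE), nrow = n),
                 role = role)
}

#' Antagonistic game specification
#'
#' The shipped game is bit \code{"matching"} pursuit: against a sampled
#' opponent, the predator's payoff is the fraction of matching bits and the
#' prey's payoff is one minus that fraction, so every encounter is zero-sum
#' with payoffs summing to 1.
#'
#' @param game Game name; only \code{"matching"} ships.
#' @export
game_spec <- function(game = "matching") {
  game <- match.arg(game, "matching")
  structure(list(game = game), class = "game_spec")
}

encounter_payoff <- function(genome, opponent, role) {
  match_frac <- mean(genome == opponent)
  if (role == "predator") match_frac else 1 - match_frac
}

#' Coupled fitness of one genome against the opposing population
#'
#' Mean encounter payoff over \code{samples} opponents drawn uniformly
#' without replacement from the opposing population.
#'
#' @param genome 0/1 vector.
#' @param role \code{"predator"} or \code{"prey"} (which payoff orientation
#'   the focal genome receives).
#' @param opposing A [bit_population()].
#' @param game A [game_spec()].
#' @param samples Number of opponents (<= opposing population size).
#' @param seed Optional integer seed; \code{NULL} draws from the current
#'   RNG stream (used inside [run_coevolution()]).
#' @return Fitness in [0, 1].
#' @export
coupled_fitness <- function(genome, role, opposing, game = game_spec(),
                            samples = nrow(opposing$genomes), seed = NULL) {
  if (!inherits(opposing, "bit_population"))
    stop_field("opposing", "not a bit_population")
  n_op <- nrow(opposing$genomes)
  if (n_op == 0)
    stop("coevolutionary partner extinct: opposing population is empty",
         call. = FALSE)
  samples <- check_scalar(samples, "samples", lower = 1, upper = n_op,
                          integer = TRUE)
  eval_fn <- function() {
    idx <- if (samples == n_op) seq_len(n_op)
           else sample.int(n_op, samples, replace = FALSE)
    mean(vapply(idx, function(i)
      encounter_payoff(genome, opposing$genomes[i, ], role), numeric(1)))
  }
  if (is.null(seed)) eval_fn() else with_seed(substream_seed(seed, "cfit"), eval_fn())
}

#' Exponential-moving-average fitness memory
#'
#' filtered = lambda * previous + (1 - lambda) * instantaneous. At
#' lambda = 0 this reduces to the memoryless instantaneous fitness.
#'
#' @param previous_filtered,instantaneous Values in [0, 1] (vectorised).
#' @param lambda Decay in [0, 1).
#' @export
memory_update <- function(previous_filtered, instantaneous, lambda) {
  lambda <- check_scalar(lambda, "lambda", lower = 0, upper = 1,
                         closed_upper = FALSE)
  if (any(previous_filtered < 0 | previous_filtered > 1, na.rm = TRUE) ||
      any(instantaneous < 0 | instantaneous > 1, na.rm = TRUE))
    stop_field("instantaneous", "fitness values must lie in [0,1]")
  lambda * previous_filtered + (1 - lambda) * instantaneous
}

# mean pairwise Hamming distance via per-column allele counts (exact,
# O(n L) instead of O(n^2 L))
mean_pairwise_hamming <- function(genomes) {
  n <- nrow(genomes)
  if (n < 2) return(0)
  k <- colSums(genomes)
  sum(2 * k * (n - k)) / (n * (n - 1))
}

select_parents <- function(fitness, n_pairs, selection) {
  n <- length(fitness)
  if (selection == "tournament_k") {
    pick <- function() {
      cand <- sample.int(n, 2L, replace = TRUE)
      cand[which.max(fitness[cand])]
    }
    matrix(vapply(seq_len(2L * n_pairs), function(i) pick(), integer(1)),
           ncol = 2L)
  } else {
    w <- fitness + 1e-12
    matrix(sample.int(n, 2L * n_pairs, replace = TRUE, prob = w / sum(w)),
           ncol = 2L)
  }
}

breed <- function(pop, n_offspring, params) {
  L <- params$L
  n_pairs <- ceiling(n_offspring / 2)
  parents <- select_parents(pop$filtered_fitness, n_pairs, params$selection)
  kids <- matrix(0L, 2L * n_pairs, L)
  kid_fit <- numeric(2L * n_pairs)
  for (p in seq_len(n_pairs)) {
    a <- pop$genomes[parents[p, 1], ]
    b <- pop$genomes[parents[p, 2], ]
    if (L > 1 && stats::runif(1) < params$crossover_rate) {
      cut <- sample.int(L - 1L, 1L)
      c1 <- c(a[1:cut], b[(cut + 1):L])
      c2 <- c(b[1:cut], a[(cut + 1):L])
    } else { c1 <- a; c2 <- b }
    kids[2 * p - 1, ] <- c1
    kids[2 * p, ] <- c2
    # offspring inherit the mean filtered fitness of their parents
    mf <- mean(pop$filtered_fitness[parents[p, ]])
    kid_fit[2 * p - 1] <- mf; kid_fit[2 * p] <- mf
  }
  if (params$mutation_rate > 0) {
    flips <- matrix(stats::runif(length(kids)) < params$mutation_rate,
                    nrow = nrow(kids))
    kids[flips] <- 1L - kids[flips]
  }
  keep <- seq_len(n_offspring)
  if (params$elitism > 0) {
    best <- order(pop$filtered_fitness, decreasing = TRUE)[
      seq_len(min(params$elitism, n_offspring))]
    kids[seq_along(best), ] <- pop$genomes[best, , drop = FALSE]
    kid_fit[seq_along(best)] <- pop$filtered_fitness[best]
  }
  bit_population(kids[keep, , drop = FALSE], role = pop$role,
                 filtered_fitness = kid_fit[keep])
}

#' Advance the coupled populations by one generation
#'
#' Evaluates every genome's coupled fitness against the opposing
#' population, folds it into the fitness memory, breeds each population
#' (tournament selection, single-point crossover, per-bit mutation), and
#' splits the conserved total of individuals between the populations in
#' proportion to (mean filtered fitness)^kappa. A population whose share
#' rounds to zero goes extinct and the step signals a structured
#' termination.
#'
#' @param predators,prey [bit_population()] objects.
#' @param params A [ga_params()].
#' @param game A [game_spec()].
#' @param freeze \code{"none"}, \code{"prey"}, or \code{"predators"}: a
#'   frozen population is evaluated but not re-bred (used for best-response
#'   experiments against a static opponent).
#' @return A list with the new \code{predators}, \code{prey}, and
#'   \code{stats} (mean instantaneous and filtered fitness, diversity,
#'   offspring shares, extinction flag/role). Consumes the current RNG
#'   stream; seed at the run level.
#' @export
step_generation <- function(predators, prey, params, game = game_spec(),
                            freeze = c("none", "prey", "predators")) {
  freeze <- match.arg(freeze)
  for (pop in list(predators, prey))
    if (!inherits(pop, "bit_population"))
      stop_field("predators", "both populations must be bit_population objects")
  # vectorised coupled_fitness: agreement fractions via one matrix product
  eval_pop <- function(pop, opposing) {
    G <- pop$genomes; O <- opposing$genomes
    A <- (G %*% t(O) + (1 - G) %*% t(1 - O)) / ncol(G)
    ns <- min(params$lifetime_samples, nrow(O))
    f <- if (ns == nrow(O)) rowMeans(A)
    else vapply(seq_len(nrow(G)), function(i)
      mean(A[i, sample.int(nrow(O), ns)]), numeric(1))
    if (pop$role == "predator") f else 1 - f
  }
  inst_pred <- eval_pop(predators, prey)
  inst_prey <- eval_pop(prey, predators)
  predators$filtered_fitness <- memory_update(predators$filtered_fitness,
                                              inst_pred,
                                              params$memory_lambda)
  prey$filtered_fitness <- memory_update(prey$filtered_fitness, inst_prey,
                                         params$memory_lambda)
  total <- nrow(predators$genomes) + nrow(prey$genomes)
  fp <- mean(predators$filtered_fitness)
  fq <- mean(prey$filtered_fitness)
  if (params$repro_exponent > 0) {
    wp <- fp^params$repro_exponent
    wq <- fq^params$repro_exponent
    share_pred <- if (wp + wq == 0) 0.5 else wp / (wp + wq)
  } else share_pred <- nrow(predators$genomes) / total
  n_pred <- as.integer(round(total * share_pred))
  n_prey <- total - n_pred
  extinct <- if (n_pred == 0L) "predator" else if (n_prey == 0L) "prey" else NA_character_
  stats <- list(mean_inst_pred = mean(inst_pred),
                mean_inst_prey = mean(inst_prey),
                mean_filtered_pred = fp, mean_filtered_prey = fq,
                div_pred = mean_pairwise_hamming(predators$genomes),
                div_prey = mean_pairwise_hamming(prey$genomes),
                share_pred = share_pred,
                n_pred = n_pred, n_prey = n_prey,
                extinct = extinct)
  if (!is.na(extinct))
    return(list(predators = predators, prey = prey, stats = stats))
  new_pred <- if (freeze == "predators") predators
              else breed(predators, n_pred, params)
  new_prey <- if (freeze == "prey") prey
              else breed(prey, n_prey, params)
  list(predators = new_pred, prey = new_prey, stats = stats)
}

#' Run a coupled-GA coevolution
#'
#' Iterates [step_generation()] from random initial populations for
#' \code{params$generations} generations or until one population's
#' offspring share rounds to zero (extinction, an outcome rather than an
#' error). Fully deterministic given (params, seed).
#'
#' @param params A [ga_params()].
#' @param game A [game_spec()].
#' @param freeze Population to hold static (see [step_generation()]).
#' @param init_predators,init_prey Optional starting [bit_population()]s
#'   (random if omitted).
#' @return An object of class \code{"coevolution_run"}: data frame
#'   \code{series} (generation, meanfit_pred, meanfit_prey, filtered means,
#'   div_pred, div_prey, share_pred, n_pred, n_prey), \code{outcome}
#'   (\code{"completed"} or \code{"extinct:<role>"}), and the final
#'   populations.
#' @export
run_coevolution <- function(params, game = game_spec(),
                            freeze = c("none", "prey", "predators"),
                            init_predators = NULL, init_prey = NULL) {
  freeze <- match.arg(freeze)
  with_seed(substream_seed(params$seed, "cga"), {
    predators <- if (is.null(init_predators))
      random_population(params$pop_size, params$L, "predator")
      else init_predators
    prey <- if (is.null(init_prey))
      random_population(params$pop_size, params$L, "prey") else init_prey
    rows <- vector("list", params$generations)
    outcome <- "completed"
    for (g in seq_len(params$generations)) {
      st <- step_generation(predators, prey, params, game, freeze)
      rows[[g]] <- data.frame(
        generation = g,
        meanfit_pred = st$stats$mean_inst_pred,
        meanfit_prey = st$stats$mean_inst_prey,
        filtered_pred = st$stats$mean_filtered_pred,
        filtered_prey = st$stats$mean_filtered_prey,
        div_pred = st$stats$div_pred, div_prey = st$stats$div_prey,
        share_pred = st$stats$share_pred,
        n_pred = st$stats$n_pred, n_prey = st$stats$n_prey)
      if (!is.na(st$stats$extinct)) {
        outcome <- paste0("extinct:", st$stats$extinct)
        rows <- rows[seq_len(g)]
        predators <- st$predators; prey <- st$prey
        break
      }
      predators <- st$predators; prey <- st$prey
    }
    structure(list(series = do.call(rbind, rows), outcome = outcome,
                   predators = predators, prey = prey, params = params),
              class = "coevolution_run")
  })
}

#' @export
print.coevolution_run <- function(x, ...) {
  cat(sprintf(
    "<coevolution_run> %d generations, outcome %s; final mean fitness pred %.3f / prey %.3f\n",
    nrow(x$series), x$outcome,
    utils::tail(x$series$meanfit_pred, 1), utils::tail(x$series$meanfit_prey, 1)))
  invisible(x)
}

#' Exhaustive best response for the bit-matching game
#'
#' For genome lengths up to \code{max_L}, enumerates all 2^L genomes and
#' returns the one maximising mean payoff against the opposing population
#' (the oracle for frozen-opponent convergence tests). For the matching
#' game the best predator response is the bitwise majority of the opposing
#' genomes; enumeration is kept as the independent route.
#'
#' @param role Focal role.
#' @param opposing A [bit_population()].
#' @param max_L Refuse enumeration beyond this length (default 12).
#' @export
best_response_exhaustive <- function(role, opposing, max_L = 12L) {
  L <- ncol(opposing$genomes)
  if (L > max_L) stop_field("max_L", "genome too long for enumeration")
  best <- NULL; best_f <- -Inf
  for (k in 0:(2^L - 1)) {
    g <- as.integer(intToBits(k)[1:L])
    f <- mean(vapply(seq_len(nrow(opposing$genomes)), function(i)
      encounter_payoff(g, opposing$genomes[i, ], role), numeric(1)))
    if (f > best_f) { best_f <- f; best <- g }
  }
  list(genome = best, fitness = best_f)
}

#' Modal genome of a population
#'
#' @param pop A [bit_population()].
#' @return The most frequent genome (ties broken by first occurrence).
#' @export
modal_genome <- function(pop) {
  keys <- apply(pop$genomes, 1, paste0, collapse = "")
  tab <- sort(table(keys), decreasing = TRUE)
  as.integer(strsplit(names(tab)[1], "")[[1]])
}
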