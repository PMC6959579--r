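# Minimal real-coded genetic algorithm for bounded, noisy-free black-box
# maximization (piecewise-constant objectives such as classification
# accuracy). Deterministic given the seed in ga_control().

#' Genetic-algorithm settings
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param mutation_rate per-gene probability of resampling uniformly within
#'   bounds.
#' @param elitism number of top individuals copied unchanged each
#'   generation.
#' @param seed RNG seed; the global RNG stream is left untouched.
#' @return list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 50, generations = 100,
                       mutation_rate = 0.05, elitism = 2, seed = 0) {
  stopifnot(pop_size >= 4, generations >= 1, elitism >= 0,
            elitism < pop_size, mutation_rate >= 0, mutation_rate <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), seed = seed),
            class = "ga_control")
}

#' Maximize a bounded black-box function by a genetic algorithm
#'
#' Uniform crossover between tournament-selected parents, per-gene uniform
#' resampling mutation, and elitism.
#'
#' @param fn objective taking a length-`n_par` numeric vector, returning a
#'   scalar to maximize.
#' @param n_par number of parameters.
#' @param lower,upper scalar or length-`n_par` bounds.
#' @param control a [ga_control()].
#' @return list: `par` (best solution), `value` (its objective),
#'   `trace` (best objective per generation).
#' @export
ga_maximize <- function(fn, n_par, lower = 0, upper = 1,
                        control = ga_control()) {
  lower <- rep_len(lower, n_par)
  upper <- rep_len(upper, n_par)
  with_preserved_rng({
    set.seed(control$seed)
    np <- control$pop_size
    pop <- matrix(stats::runif(np * n_par, lower, upper),
                  np, n_par, byrow = TRUE)
    fitness <- apply(pop, 1, fn)
    trace <- numeric(control$generations)
    for (g in seq_len(control$generations)) {
      ord <- order(fitness, decreasing = TRUE)
      newpop <- matrix(0, np, n_par)
      n_elite <- control$elitism
      if (n_elite > 0) newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
      tournament <- function() {
        cand <- sample.int(np, 2)
        cand[which.max(fitness[cand])]
      }
      for (i in seq(n_elite + 1, np)) {
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        take <- stats::runif(n_par) < 0.5
        child <- ifelse(take, p1, p2)
        mut <- stats::runif(n_par) < control$mutation_rate
        if (any(mut)) child[mut] <- stats::runif(sum(mut), lower[mut], upper[mut])
        newpop[i, ] <- child
      }
      pop <- newpop
      fitness <- apply(pop, 1, fn)
      # elitism guarantees monotone best fitness when elitism > 0
      trace[g] <- max(fitness)
    }
    best <- which.max(fitness)
    list(par = pop[best, ], value = fitness[best], trace = trace)
  })
}
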