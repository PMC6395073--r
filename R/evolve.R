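#' Search bounds for the conductance optimization
#'
#' The 9-dimensional search box: lower/upper bounds for the 8 maximal
#' conductances (uS) and the calcium buffering time constant (ms).
#'
#' @return A 9 x 2 matrix (rows named Na..leak, tau_Ca) of [lo, hi] bounds.
#' @export
stg_search_bounds <- function() {
  b <- rbind(Na = c(0, 2e3), CaT = c(0, 2e2), CaS = c(0, 2e2),
             A = c(0, 2e2), KCa = c(0, 2e3), Kd = c(0, 2e2),
             H = c(0, 2e2), leak = c(0, 20), tau_Ca = c(0, 1e3))
  colnames(b) <- c("lo", "hi")
  b
}

#' Genetic-algorithm configuration
#'
#' @param population Population size (the published searches used 1000).
#' @param generations Number of generations.
#' @param mutation_rate Per-gene probability of resampling uniformly within
#'   bounds (default 5%).
#' @param elitism Selection pressure of the rank-based breeding scheme: each
#'   rank is chosen `elitism` times as often as the rank below it (1 =
#'   uniform breeding probability; the published searches used 1.2).
#' @param bounds Per-gene [lo, hi] matrix; default [stg_search_bounds()].
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 1000, generations = 100,
                      mutation_rate = 0.05, elitism = 1.2,
                      bounds = stg_search_bounds(), seed = 1) {
  if (population < 2) stop("population must be at least 2")
  if (is.null(dim(bounds)) || ncol(bounds) != 2 || nrow(bounds) < 1 ||
      any(bounds[, 2] <= bounds[, 1])) {
    stop("bounds must be an n x 2 matrix with hi > lo")
  }
  if (elitism < 1 || elitism > 2) {
    stop("elitism must lie in [1, 2] (1 = uniform breeding probability)")
  }
  structure(list(population = population, generations = generations,
                 mutation_rate = mutation_rate, elitism = elitism,
                 bounds = bounds, seed = seed),
            class = "ga_config")
}

# geometric ranking selection weights: each rank breeds `elitism` times as
# often as the rank below it; elitism = 1 is uniform breeding probability
.rank_weights <- function(n, elitism) {
  if (n == 1) return(1)
  rank <- seq_len(n) - 1 # 0 = worst
  w <- elitism^rank
  w / mean(w)
}

#' Minimize an objective with a genetic algorithm
#'
#' Standard generational GA over a box: uniform random initialization,
#' linear-ranking parent selection with pressure set by `elitism`, uniform
#' per-gene crossover (probability 1/2), per-gene mutation by uniform
#' resampling within bounds, and elitist preservation of the best-ever
#' individual. Fully reproducible from the config seed.
#'
#' @param objective Function mapping a parameter vector (length
#'   `nrow(bounds)`) to a finite scalar score; failures must be encoded as
#'   finite penalty scores.
#' @param config A [ga_config()].
#' @param progress If `TRUE`, prints the best score each 10 generations.
#' @param init_population Optional population x genes matrix used instead of
#'   uniform random initialization (e.g. to continue or breed from known
#'   solutions).
#' @return A list with `best` (parameter vector), `best_score`, `history`
#'   (data frame: generation, best, mean of the current population), and
#'   `population`/`scores` of the final generation.
#' @export
ga_minimize <- function(objective, config = ga_config(), progress = FALSE,
                        init_population = NULL) {
  bounds <- config$bounds
  ng <- nrow(bounds)
  np <- config$population
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  pop <- if (!is.null(init_population)) {
    stopifnot(nrow(init_population) == np, ncol(init_population) == ng)
    `dimnames<-`(as.matrix(init_population), list(NULL, rownames(bounds)))
  } else {
    matrix(stats::runif(np * ng, min = rep(bounds[, 1], each = np),
                        max = rep(bounds[, 2], each = np)),
           nrow = np, ncol = ng,
           dimnames = list(NULL, rownames(bounds)))
  }
  scores <- apply(pop, 1, objective)
  if (any(!is.finite(scores))) stop("objective returned a non-finite score")
  best_i <- which.min(scores)
  best <- pop[best_i, ]
  best_score <- scores[best_i]
  hist <- data.frame(generation = 0, best = best_score, mean = mean(scores))

  for (gen in seq_len(config$generations)) {
    ord <- order(scores, decreasing = TRUE) # worst first -> rank 0
    w <- numeric(np)
    w[ord] <- .rank_weights(np, config$elitism)
    parents <- matrix(sample.int(np, 2 * np, replace = TRUE, prob = w),
                      ncol = 2)
    take_first <- matrix(stats::runif(np * ng) < 0.5, np, ng)
    child <- ifelse(take_first, pop[parents[, 1], ], pop[parents[, 2], ])
    mut <- matrix(stats::runif(np * ng) < config$mutation_rate, np, ng)
    if (any(mut)) {
      res <- matrix(stats::runif(np * ng, min = rep(bounds[, 1], each = np),
                                 max = rep(bounds[, 2], each = np)), np, ng)
      child[mut] <- res[mut]
    }
    # elitist preservation: best-ever replaces the first child
    child[1, ] <- best
    pop <- child
    scores <- apply(pop, 1, objective)
    gi <- which.min(scores)
    if (scores[gi] < best_score) {
      best_score <- scores[gi]
      best <- pop[gi, ]
    }
    hist <- rbind(hist, data.frame(generation = gen, best = best_score,
                                   mean = mean(scores)))
    if (progress && gen %% 10 == 0) {
      message(sprintf("generation %d: best %.6g", gen, best_score))
    }
  }
  list(best = best, best_score = best_score, history = hist,
       population = pop, scores = scores)
}

#' Search for bursting (or tonic) model neurons
#'
#' Convenience wrapper: builds the landscape objective for a target and
#' minimizes it over the standard search box.
#'
#' @param target A [burster_target()] or [tonic_target()].
#' @param config A [ga_config()].
#' @param kinetics,method Passed to the objective.
#' @param progress Passed to [ga_minimize()].
#' @return The [ga_minimize()] result; `best` is the (g, tau_Ca) vector and
#'   `best_params` the corresponding [stg_parameters()] object.
#' @export
evolve_models <- function(target = burster_target(), config = ga_config(),
                          kinetics = NULL, method = "table",
                          progress = FALSE) {
  obj <- landscape_objective(target, kinetics = kinetics, method = method)
  res <- ga_minimize(obj, config, progress = progress)
  res$best_params <- stg_parameters(res$best[1:8], tau_ca = res$best[9])
  res
}
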