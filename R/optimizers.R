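#' Hyperparameter search space
#'
#' Named box-constrained dimensions, each linear- or log-scaled. Optimizers
#' work internally on the unit hypercube and decode through the scale, so
#' log-scaled cost/gamma ranges are searched uniformly in the exponent.
#' The default space is the standard SVM tuning grid: costs
#' `c1, c2 in [2^-8, 2^8]` and RBF `gamma in [2^-10, 2^4]`, all log-scaled.
#'
#' @param names,lower,upper,scale parallel vectors describing the
#'   dimensions; `scale` entries are `"linear"` or `"log"` (log requires
#'   positive bounds).
#' @return A `SearchSpace` data frame.
#' @export
search_space <- function(names, lower, upper,
                         scale = rep("linear", length(names))) {
  stopifnot(length(lower) == length(names), length(upper) == length(names))
  if (length(names) == 0L) stop("search space must have at least one dimension")
  if (any(lower >= upper)) stop("every dimension needs lower < upper")
  if (any(scale == "log" & lower <= 0))
    stop("log scale requires positive bounds")
  structure(data.frame(name = names, lower = lower, upper = upper,
                       scale = scale, stringsAsFactors = FALSE),
            class = c("SearchSpace", "data.frame"))
}

#' @rdname search_space
#' @export
default_classifier_space <- function() {
  search_space(c("c1", "c2", "gamma"),
               lower = c(2^-8, 2^-8, 2^-10),
               upper = c(2^8, 2^8, 2^4),
               scale = c("log", "log", "log"))
}

# map unit-cube coordinates to parameter values and back
decode_point <- function(space, u) {
  out <- ifelse(space$scale == "log",
                exp(log(space$lower) + u * (log(space$upper) - log(space$lower))),
                space$lower + u * (space$upper - space$lower))
  stats::setNames(out, space$name)
}

#' Optimizer configuration
#'
#' Defaults follow the study settings: 300 iterations for every algorithm;
#' population 40 and 20-bit encoding per parameter for GA/QGA with
#' generation gap 0.95, crossover probability 0.7, mutation probability
#' 0.01 and quantum rotation angle 0.01 rad; population 20 and acceleration
#' constants (1.5, 1.70) for PSO/CPSO, with the canonical linearly decaying
#' inertia weight 0.9 -> 0.4.
#'
#' @param algorithm one of `"pso"`, `"cpso"`, `"ga"`, `"qga"`, `"random"`.
#' @param max_iterations iteration budget.
#' @param population population / swarm size (`NULL` = algorithm default).
#' @param chromosome_length bits per encoded parameter (GA/QGA).
#' @param generation_gap fraction of the GA population replaced per
#'   generation.
#' @param p_crossover,p_mutation GA genetic operator probabilities.
#' @param rotation_angle QGA rotation-gate step in radians.
#' @param acceleration PSO cognitive/social constants `(c1, c2)`.
#' @param inertia PSO inertia weight schedule `(start, end)`.
#' @param seed integer seed; runs are bit-identical given the seed.
#' @return An `OptimizerConfig`.
#' @export
optimizer_config <- function(algorithm = c("pso", "cpso", "ga", "qga",
                                           "random"),
                             max_iterations = 300L, population = NULL,
                             chromosome_length = 20L,
                             generation_gap = 0.95, p_crossover = 0.7,
                             p_mutation = 0.01, rotation_angle = 0.01,
                             acceleration = c(1.5, 1.70),
                             inertia = c(0.9, 0.4), seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(population))
    population <- if (algorithm %in% c("ga", "qga")) 40L else 20L
  stopifnot(max_iterations >= 1L, population >= 2L,
            chromosome_length >= 1L,
            generation_gap >= 0, generation_gap <= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1)
  structure(list(algorithm = algorithm,
                 max_iterations = as.integer(max_iterations),
                 population = as.integer(population),
                 chromosome_length = as.integer(chromosome_length),
                 generation_gap = generation_gap,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 rotation_angle = rotation_angle,
                 acceleration = acceleration, inertia = inertia,
                 seed = as.integer(seed)),
            class = "OptimizerConfig")
}

#' Run a hyperparameter optimizer
#'
#' Maximizes `fitness(params)` over a [search_space()]. All algorithms
#' report the elitist best-so-far trace (non-decreasing by construction)
#' and are bit-identical under a fixed seed.
#'
#' @param fitness function taking a named parameter vector, returning a
#'   scalar to maximize (e.g. [cv_fitness()]).
#' @param space a [search_space()].
#' @param config an [optimizer_config()]; its `algorithm` field selects the
#'   method.
#' @return An `OptimizerResult`: `best_params`, `best_fitness`,
#'   `fitness_trace` (per-iteration best-so-far), `evaluations`, `seed`.
#' @export
optimize_params <- function(fitness, space, config = optimizer_config()) {
  stopifnot(inherits(space, "SearchSpace"), inherits(config, "OptimizerConfig"))
  set.seed(config$seed)
  switch(config$algorithm,
         pso = pso_optimize(fitness, space, config),
         cpso = cpso_optimize(fitness, space, config),
         ga = ga_optimize(fitness, space, config),
         qga = qga_optimize(fitness, space, config),
         random = random_search(fitness, space, config))
}

optimizer_result <- function(space, best_u, best_fit, trace, evals, config) {
  structure(list(best_params = decode_point(space, best_u),
                 best_fitness = best_fit, fitness_trace = trace,
                 evaluations = evals, seed = config$seed,
                 algorithm = config$algorithm),
            class = "OptimizerResult")
}

eval_points <- function(fitness, space, U) {
  apply(U, 1L, function(u) fitness(decode_point(space, u)))
}

#' @rdname optimize_params
#' @export
pso_optimize <- function(fitness, space, config) {
  d <- nrow(space); n <- config$population
  X <- matrix(stats::runif(n * d), n, d)
  pso_core(fitness, space, config, X, chaotic = FALSE)
}

# canonical global-best PSO over the unit cube; optional chaotic local
# search around the global best (CPSO)
pso_core <- function(fitness, space, config, X, chaotic) {
  d <- nrow(space); n <- config$population
  V <- matrix(stats::runif(n * d, -0.1, 0.1), n, d)
  fit <- eval_points(fitness, space, X)
  P <- X; pfit <- fit
  g <- which.max(pfit)
  gbest <- P[g, ]; gfit <- pfit[g]
  trace <- numeric(config$max_iterations)
  evals <- n
  if (chaotic) z <- chaos_next(stats::runif(d, 0.1, 0.9))
  for (it in seq_len(config$max_iterations)) {
    w <- config$inertia[1L] +
      (config$inertia[2L] - config$inertia[1L]) *
      (it - 1) / max(config$max_iterations - 1, 1)
    r1 <- matrix(stats::runif(n * d), n, d)
    r2 <- matrix(stats::runif(n * d), n, d)
    V <- w * V + config$acceleration[1L] * r1 * (P - X) +
      config$acceleration[2L] * r2 * (matrix(gbest, n, d, byrow = TRUE) - X)
    V <- pmin(pmax(V, -0.5), 0.5)
    X <- pmin(pmax(X + V, 0), 1)
    fit <- eval_points(fitness, space, X)
    evals <- evals + n
    better <- fit > pfit
    P[better, ] <- X[better, ]; pfit[better] <- fit[better]
    g <- which.max(pfit)
    if (pfit[g] > gfit) { gbest <- P[g, ]; gfit <- pfit[g] }
    if (chaotic) {
      # chaotic perturbation of the global best, radius decaying to zero
      z <- chaos_next(z)
      radius <- 0.2 * (1 - (it - 1) / config$max_iterations)
      cand <- pmin(pmax(gbest + radius * (2 * z - 1), 0), 1)
      cfit <- fitness(decode_point(space, cand))
      evals <- evals + 1L
      if (cfit > gfit) { gbest <- cand; gfit <- cfit }
    }
    trace[it] <- gfit
  }
  optimizer_result(space, gbest, gfit, trace, evals, config)
}

#' @rdname optimize_params
#' @export
cpso_optimize <- function(fitness, space, config) {
  d <- nrow(space); n <- config$population
  # logistic-map chaotic initialization instead of uniform draws
  z <- stats::runif(d, 0.1, 0.9)
  X <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    z <- chaos_next(z)
    X[i, ] <- z
  }
  pso_core(fitness, space, config, X, chaotic = TRUE)
}

#' Logistic map step used by the chaotic PSO
#'
#' `x -> 4 x (1 - x)`, the fully chaotic logistic map; applied elementwise.
#'
#' @param x numeric vector in `[0, 1]`.
#' @export
chaos_next <- function(x) 4 * x * (1 - x)

#' @rdname optimize_params
#' @export
ga_optimize <- function(fitness, space, config) {
  d <- nrow(space); n <- config$population
  nb <- config$chromosome_length
  pop <- matrix(stats::runif(n * d * nb) < 0.5, n, d * nb)
  fit <- eval_points(fitness, space, decode_bits(pop, d, nb))
  evals <- n
  trace <- numeric(config$max_iterations)
  best <- which.max(fit)
  gbest_bits <- pop[best, ]; gfit <- fit[best]
  for (it in seq_len(config$max_iterations)) {
    n_off <- round(config$generation_gap * n)
    if (n_off >= 1L) {
      parents <- pop[roulette_select(fit, n_off), , drop = FALSE]
      off <- crossover_sp(parents, config$p_crossover)
      flip <- matrix(stats::runif(length(off)) < config$p_mutation,
                     nrow(off), ncol(off))
      off <- xor(off, flip)
      off_fit <- eval_points(fitness, space, decode_bits(off, d, nb))
      evals <- evals + n_off
      # elitist reinsertion: offspring replace the worst parents
      keep <- order(fit, decreasing = TRUE)[seq_len(n - n_off)]
      pop <- rbind(pop[keep, , drop = FALSE], off)
      fit <- c(fit[keep], off_fit)
    }
    b <- which.max(fit)
    if (fit[b] > gfit) { gfit <- fit[b]; gbest_bits <- pop[b, ] }
    trace[it] <- gfit
  }
  optimizer_result(space, decode_bits(matrix(gbest_bits, 1L), d, nb)[1L, ],
                   gfit, trace, evals, config)
}

# gray-free fixed-point decoding: nb bits per dimension to [0, 1]
decode_bits <- function(pop, d, nb) {
  weights <- 2^((nb - 1L):0)
  denom <- 2^nb - 1
  out <- matrix(NA_real_, nrow(pop), d)
  for (j in seq_len(d)) {
    block <- pop[, ((j - 1L) * nb + 1L):(j * nb), drop = FALSE]
    out[, j] <- as.vector(block %*% weights) / denom
  }
  out
}

encode_bits <- function(u, nb) {
  val <- round(u * (2^nb - 1))
  vapply((nb - 1L):0, function(p) (val %/% 2^p) %% 2 == 1, logical(length(u)))
}

roulette_select <- function(fit, k) {
  w <- fit - min(fit) + 1e-12
  sample.int(length(fit), k, replace = TRUE, prob = w)
}

crossover_sp <- function(parents, p_cross) {
  n <- nrow(parents); L <- ncol(parents)
  if (n < 2L) return(parents)
  for (i in seq(1L, n - 1L, by = 2L)) {
    if (stats::runif(1L) < p_cross && L >= 2L) {
      cut <- sample.int(L - 1L, 1L)
      tmp <- parents[i, (cut + 1L):L]
      parents[i, (cut + 1L):L] <- parents[i + 1L, (cut + 1L):L]
      parents[i + 1L, (cut + 1L):L] <- tmp
    }
  }
  parents
}

#' @rdname optimize_params
#' @export
qga_optimize <- function(fitness, space, config) {
  d <- nrow(space); n <- config$population
  nb <- config$chromosome_length
  L <- d * nb
  # qubit register per individual: theta parameterizes (alpha, beta) =
  # (cos theta, sin theta); initialized to the equal superposition pi/4
  theta <- matrix(pi / 4, n, L)
  trace <- numeric(config$max_iterations)
  gfit <- -Inf; gbits <- NULL
  evals <- 0L
  for (it in seq_len(config$max_iterations)) {
    prob1 <- sin(theta)^2
    bits <- matrix(stats::runif(n * L), n, L) < prob1   # quantum measurement
    fit <- eval_points(fitness, space, decode_bits(bits, d, nb))
    evals <- evals + n
    b <- which.max(fit)
    if (fit[b] > gfit) { gfit <- fit[b]; gbits <- bits[b, ] }
    # rotation-gate update: steer each qubit toward the best bitstring
    # when the individual is worse than the best (standard lookup table,
    # fixed magnitude)
    for (i in seq_len(n)) {
      if (fit[i] >= gfit) next
      differs <- bits[i, ] != gbits
      dir <- ifelse(gbits, 1, -1)       # increase P(1) if best bit is 1
      theta[i, differs] <- theta[i, differs] +
        config$rotation_angle * dir[differs]
    }
    theta <- pmin(pmax(theta, 0), pi / 2)
    trace[it] <- gfit
  }
  res <- optimizer_result(space, decode_bits(matrix(gbits, 1L), d, nb)[1L, ],
                          gfit, trace, evals, config)
  res$qubit_amplitudes <- list(alpha = cos(theta), beta = sin(theta))
  res
}

#' @rdname optimize_params
#' @export
random_search <- function(fitness, space, config) {
  d <- nrow(space)
  n <- config$population
  gfit <- -Inf; gbest <- NULL
  trace <- numeric(config$max_iterations)
  for (it in seq_len(config$max_iterations)) {
    U <- matrix(stats::runif(n * d), n, d)
    fit <- eval_points(fitness, space, U)
    b <- which.max(fit)
    if (fit[b] > gfit) { gfit <- fit[b]; gbest <- U[b, ] }
    trace[it] <- gfit
  }
  optimizer_result(space, gbest, gfit, trace,
                   config$max_iterations * n, config)
}

#' Cross-validation fitness for hyperparameter search
#'
#' Builds a classifier from a parameter vector and returns its stratified
#' k-fold cross-validation accuracy — the optimizer fitness used throughout
#' (10 folds by default). Deterministic given the seed.
#'
#' @param params named parameter vector (e.g. `c1`, `c2`, `gamma`).
#' @param features a `FeatureMatrix` (or sample matrix with `labels`).
#' @param labels per-sample labels when `features` is a plain matrix.
#' @param classifier_factory function `(params) -> function(x, y) -> model`;
#'   defaults to an RBF LS-TWSVM built from `params["c1"]`, `params["c2"]`,
#'   `params["gamma"]`.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return CV accuracy in `[0, 1]`.
#' @export
cv_fitness <- function(params, features, labels = NULL,
                       classifier_factory = lstwsvm_factory,
                       folds = 10L, seed = 1L) {
  d <- if (inherits(features, "FeatureMatrix"))
    list(x = features$values, y = features$labels)
  else list(x = as.matrix(features), y = labels)
  cv_accuracy(d$x, d$y, classifier_factory(params), folds, seed)
}

#' @rdname cv_fitness
#' @export
lstwsvm_factory <- function(params) {
  kern <- if ("gamma" %in% names(params))
    kernel_spec("rbf", gamma = params[["gamma"]])
  else kernel_spec("linear")
  function(x, y) {
    if (length(unique(y)) == 2L && all(sort(unique(y)) == c(-1, 1)))
      train_lstwsvm(x, y, params[["c1"]], params[["c2"]], kern)
    else train_multiclass(x, y, "lstwsvm",
                          c(params[["c1"]], params[["c2"]]), kern)
  }
}
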