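sphere_space <- function() search_space(c("x1", "x2", "x3"),
                                        rep(-5, 3), rep(5, 3))
neg_sphere <- function(p) -sum(p^2)

test_that("search spaces validate bounds and decode both scales", {
  expect_error(search_space("a", 2, 1), "lower < upper")
  expect_error(search_space("a", -1, 1, "log"), "positive")
  expect_error(search_space(character(0), numeric(0), numeric(0)),
               "at least one dimension")
  sp <- search_space(c("lin", "lg"), c(0, 1), c(10, 100),
                     c("linear", "log"))
  p <- eegtwin:::decode_point(sp, c(0.5, 0.5))
  expect_equal(unname(p), c(5, 10))
  expect_equal(names(p), c("lin", "lg"))
})

test_that("a collapsed dimension returns its only point", {
  sp <- search_space("x", 3, 3 + 1e-9)
  r <- optimize_params(function(p) -p^2,
                       sp, optimizer_config("pso", max_iterations = 5,
                                            seed = 1))
  expect_equal(unname(r$best_params), 3, tolerance = 1e-6)
})

test_that("all optimizers report in-bounds, non-decreasing, reproducible runs", {
  sp <- sphere_space()
  for (alg in c("pso", "cpso", "ga", "qga", "random")) {
    cfg <- optimizer_config(alg, max_iterations = 15, seed = 3)
    r1 <- optimize_params(neg_sphere, sp, cfg)
    r2 <- optimize_params(neg_sphere, sp, cfg)
    expect_identical(r1, r2)
    expect_true(all(diff(r1$fitness_trace) >= 0))
    expect_true(all(r1$best_params >= sp$lower & r1$best_params <= sp$upper))
    expect_equal(r1$best_fitness, utils::tail(r1$fitness_trace, 1))
  }
})

test_that("each optimizer contracts the sphere problem quickly", {
  sp <- sphere_space()
  tol <- c(pso = 1e-3, cpso = 1e-3, ga = 1e-2, qga = 1e-2)
  for (alg in names(tol)) {
    errs <- vapply(1:5, function(s)
      -optimize_params(neg_sphere, sp,
                       optimizer_config(alg, max_iterations = 300,
                                        seed = s))$best_fitness,
      numeric(1))
    expect_lt(median(errs), tol[[alg]])
  }
})

test_that("the logistic map and chaotic initialization behave as defined", {
  expect_equal(chaos_next(0.3), 0.84)
  expect_equal(chaos_next(c(0.5, 0.1)), c(1, 0.36))
  # chaotic initial positions never leave the box
  sp <- search_space(c("a", "b"), c(-2, 0), c(2, 1))
  for (s in 1:25) {
    set.seed(s)
    r <- cpso_optimize(function(p) 0, sp,
                       optimizer_config("cpso", max_iterations = 1,
                                        population = 20, seed = s))
    expect_true(all(r$best_params >= sp$lower & r$best_params <= sp$upper))
  }
})

test_that("chaotic PSO is not inferior to plain PSO on a multimodal surface", {
  sp <- search_space(c("x", "y"), c(-5.12, -5.12), c(5.12, 5.12))
  rastrigin <- function(p) -(20 + sum(p^2 - 10 * cos(2 * pi * p)))
  pe <- vapply(1:20, function(s)
    -optimize_params(rastrigin, sp,
                     optimizer_config("pso", max_iterations = 60,
                                      seed = s))$best_fitness, numeric(1))
  ce <- vapply(1:20, function(s)
    -optimize_params(rastrigin, sp,
                     optimizer_config("cpso", max_iterations = 60,
                                      seed = s))$best_fitness, numeric(1))
  expect_lte(median(ce), median(pe) + 1e-6)
})

test_that("20-bit encoding round-trips grid points within quantization error", {
  for (u in c(0.0001, 0.123456, 0.5, 0.9, 0.999999)) {
    bits <- eegtwin:::encode_bits(u, 20L)
    back <- eegtwin:::decode_bits(matrix(as.logical(bits), 1L), 1L, 20L)[1, 1]
    expect_lte(abs(back - u), 1 / (2^20 - 1))
  }
})

test_that("a GA with no operators and zero generation gap is static", {
  sp <- sphere_space()
  cfg <- optimizer_config("ga", max_iterations = 20, population = 10,
                          generation_gap = 0, p_crossover = 0,
                          p_mutation = 0, seed = 5)
  r <- optimize_params(neg_sphere, sp, cfg)
  expect_equal(length(unique(r$fitness_trace)), 1L)
  expect_equal(r$evaluations, 10L)
})

test_that("QGA qubits stay normalized and start as fair coins", {
  sp <- sphere_space()
  r <- optimize_params(neg_sphere, sp,
                       optimizer_config("qga", max_iterations = 30,
                                        population = 10, seed = 2))
  amp <- r$qubit_amplitudes
  expect_lt(max(abs(amp$alpha^2 + amp$beta^2 - 1)), 1e-12)
  # equal-superposition measurement is a fair coin
  set.seed(6)
  bits <- stats::runif(1e4) < sin(pi / 4)^2
  expect_gt(mean(bits), 0.45)
  expect_lt(mean(bits), 0.55)
})

test_that("CV fitness is deterministic, perfect on separable and chance on shuffled", {
  set.seed(3)
  x <- matrix(rnorm(200 * 4), 200)
  y_shuf <- sample(rep(c(-1, 1), 100))
  f1 <- cv_fitness(c(c1 = 1, c2 = 1, gamma = 0.5), x, y_shuf,
                   folds = 10, seed = 2)
  f2 <- cv_fitness(c(c1 = 1, c2 = 1, gamma = 0.5), x, y_shuf,
                   folds = 10, seed = 2)
  expect_identical(f1, f2)
  expect_gt(f1, 0.5 - 1.96 * sqrt(0.25 / 200))
  expect_lt(f1, 0.5 + 1.96 * sqrt(0.25 / 200))
  xsep <- rbind(x[1:100, ] + 4, x[101:200, ] - 4)
  expect_equal(cv_fitness(c(c1 = 1, c2 = 1, gamma = 0.5), xsep,
                          rep(c(1, -1), each = 100), folds = 10, seed = 2),
               1)
  expect_error(cv_fitness(c(c1 = 1, c2 = 1, gamma = 0.5), x, y_shuf,
                          folds = 150, seed = 1), "fold count")
})
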