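test_that("the symmetric two-point problem has the textbook solution", {
  m <- train_svm(matrix(c(-1, 1), 2, 1), c(-1, 1), cost = 1e6)
  expect_equal(m$w, 1, tolerance = 1e-8)
  expect_equal(m$b, 0, tolerance = 1e-8)
  # margin boundaries at +-1
  expect_equal(as.numeric(decision_values(m, matrix(c(-1, 1), 2, 1))),
               c(-1, 1), tolerance = 1e-8)
})

test_that("separable data: zero training error and margin 2/||w||", {
  b <- make_blobs(n_per_class = 10, sep = 4, seed = 1)
  m <- train_svm(b$x, b$y, cost = 1e6)
  f <- decision_values(m, b$x)
  expect_equal(mean(sign(f) == b$y), 1)
  expect_true(all(b$y * f >= 1 - 1e-6))
  expect_equal(min(b$y * f), 1, tolerance = 1e-6)
  # geometric margin equals 2/||w||
  expect_equal(2 * min(b$y * f) / sqrt(sum(m$w^2)), 2 / sqrt(sum(m$w^2)),
               tolerance = 1e-9)
  expect_true(all(m$xi < 1e-6))
})

test_that("XOR is linearly inseparable but RBF-separable", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), 4, 2, byrow = TRUE)
  y <- c(1, 1, -1, -1)
  lin <- train_svm(x, y, cost = 10)
  expect_equal(mean(predict(lin, x) == y), 0.5)
  rbf <- train_svm(x, y, cost = 10, kernel_spec("rbf", gamma = 1))
  expect_equal(mean(predict(rbf, x) == y), 1)
})

test_that("training error is non-increasing in the penalty factor", {
  set.seed(8)
  b <- make_blobs(n_per_class = 30, sep = 1.5, seed = 8)   # overlapping
  errs <- vapply(c(0.01, 0.1, 1, 10, 100), function(C)
    mean(predict(train_svm(b$x, b$y, C), b$x) != b$y), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("negating labels maps (w, b) to (-w, -b) and swaps twin planes", {
  b <- make_blobs(n_per_class = 15, sep = 2, seed = 2)
  m <- train_svm(b$x, b$y, 1)
  mf <- train_svm(b$x, -b$y, 1)
  expect_equal(mf$w, -m$w, tolerance = 1e-7)
  expect_equal(mf$b, -m$b, tolerance = 1e-7)
  # twin planes swap; coefficient vectors describe the same plane with
  # opposite sign
  t1 <- train_lstwsvm(b$x, b$y, 2, 3)
  t2 <- train_lstwsvm(b$x, -b$y, 3, 2)
  expect_equal(t1$plane1$w, -t2$plane2$w, tolerance = 1e-9)
  expect_equal(t1$plane1$b, -t2$plane2$b, tolerance = 1e-9)
  expect_equal(t1$plane2$w, -t2$plane1$w, tolerance = 1e-9)
  expect_equal(t1$plane2$b, -t2$plane1$b, tolerance = 1e-9)
})

test_that("invalid training inputs are rejected", {
  b <- make_blobs(4)
  expect_error(train_svm(b$x, b$y, cost = 0), "positive")
  expect_error(train_svm(b$x, rep(1, 8), 1), "\\{\\+1, -1\\}")
  expect_error(train_svm(b$x, rep_len(1:2, 8), 1), "\\{\\+1, -1\\}")
  expect_error(train_twsvm(b$x, b$y, c1 = -1, c2 = 1), "positive")
  expect_error(train_lstwsvm(b$x, b$y, c1 = 1, c2 = 0), "positive")
  m <- train_svm(b$x, b$y, 1)
  expect_error(predict(m, matrix(0, 1, 5)), "dimension mismatch")
})

test_that("twin planes pass along parallel point clouds", {
  pc <- make_parallel_clouds(n = 30, seed = 1)
  for (trainer in list(train_twsvm, train_lstwsvm)) {
    m <- trainer(pc$x, pc$y, 1, 1)
    ang <- function(w) acos(abs(w[2]) / sqrt(sum(w^2))) * 180 / pi
    expect_lt(ang(m$plane1$w), 5)
    expect_lt(ang(m$plane2$w), 5)
    expect_lt(abs(-m$plane1$b / m$plane1$w[2] - 0), 0.1)
    expect_lt(abs(-m$plane2$b / m$plane2$w[2] - 2), 0.1)
    expect_equal(mean(predict(m, pc$x) == pc$y), 1)
  }
  # TWSVM and LS-TWSVM agree on this benign geometry within 2 degrees
  mq <- train_twsvm(pc$x, pc$y, 1, 1)
  ml <- train_lstwsvm(pc$x, pc$y, 1, 1)
  angle_between <- function(a, b)
    acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
  expect_lt(angle_between(mq$plane1$w, ml$plane1$w), 2)
  expect_lt(angle_between(mq$plane2$w, ml$plane2$w), 2)
})

test_that("with one sample per class each plane passes through its sample", {
  x <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  for (trainer in list(train_twsvm, train_lstwsvm)) {
    m <- trainer(x, c(1, -1))
    d <- eegtwin:::twin_distances(m, x)
    expect_lt(d[1, 1], 1e-8)
    expect_lt(d[2, 2], 1e-8)
  }
})

test_that("twin models handle cross data where a linear SVM cannot", {
  cr <- make_cross(n = 100, seed = 3)
  tw <- train_twsvm(cr$x, cr$y, 1e-3, 1e-3)
  sv <- train_svm(cr$x, cr$y, 1)
  expect_gte(mean(predict(tw, cr$x) == cr$y), 0.95)
  expect_lte(mean(predict(sv, cr$x) == cr$y), 0.8)
})

test_that("LS-TWSVM solves the stated linear system exactly", {
  set.seed(10)
  worst <- 0
  for (r in 1:25) {
    n1 <- sample(5:25, 1); n2 <- sample(5:25, 1); p <- sample(2:8, 1)
    A <- matrix(rnorm(n1 * p), n1); B <- matrix(rnorm(n2 * p) + 1, n2)
    c1 <- runif(1, 0.1, 10); c2 <- runif(1, 0.1, 10)
    m <- train_lstwsvm(rbind(A, B), rep(c(1, -1), c(n1, n2)), c1, c2)
    H <- cbind(A, 1); G <- cbind(B, 1)
    u1 <- solve(crossprod(G) + crossprod(H) / c1 + 1e-8 * diag(p + 1),
                -colSums(G))
    u2 <- solve(crossprod(H) + crossprod(G) / c2 + 1e-8 * diag(p + 1),
                colSums(H))
    worst <- max(worst,
                 max(abs(u1 - c(m$plane1$w, m$plane1$b))),
                 max(abs(u2 - c(m$plane2$w, m$plane2$b))))
  }
  expect_lt(worst, 1e-8)
})

test_that("kernel-expansion twin models with a linear kernel match the primal", {
  b <- make_blobs(n_per_class = 20, sep = 3, seed = 6)
  set.seed(6)
  grid <- matrix(rnorm(100), 50, 2)
  lin_kernel_as_expansion <- kernel_spec("polynomial", degree = 1, coef = 0)
  for (trainer in list(train_twsvm, train_lstwsvm)) {
    primal <- trainer(b$x, b$y, 1, 1)
    expansion <- trainer(b$x, b$y, 1, 1, kernel = lin_kernel_as_expansion)
    expect_equal(predict(expansion, grid), predict(primal, grid))
  }
})

test_that("prediction follows the nearer plane with ties going to class +1", {
  # plane1: x-axis (y = 0); plane2: the line y = 2
  m <- structure(list(plane1 = list(w = c(0, 1), b = 0),
                      plane2 = list(w = c(0, 1), b = -2),
                      norm1 = 1, norm2 = 1, costs = c(1, 1),
                      kernel = kernel_spec("linear"), reference = NULL,
                      input_dim = 2L, method = "twsvm"),
                 class = "TwinSVMModel")
  expect_equal(predict(m, matrix(c(5, 0.2), 1)), 1L)
  expect_equal(predict(m, matrix(c(5, 1.8), 1)), -1L)
  expect_equal(predict(m, matrix(c(0, 1), 1)), 1L)   # equidistant
})

test_that("held-out prediction on separable blobs is nearly perfect", {
  b <- make_blobs(n_per_class = 60, sep = 5, seed = 7)
  tr <- c(1:40, 61:100); te <- setdiff(1:120, tr)
  for (m in list(train_svm(b$x[tr, ], b$y[tr], 1),
                 train_twsvm(b$x[tr, ], b$y[tr], 1, 1),
                 train_lstwsvm(b$x[tr, ], b$y[tr], 1, 1,
                               kernel_spec("rbf", gamma = 0.5))))
    expect_gte(mean(predict(m, b$x[te, ]) == b$y[te]), 0.98)
})

test_that("one-vs-one wrapper reduces to binary and scales to 3-4 classes", {
  b <- make_blobs(n_per_class = 20, sep = 4, seed = 9)
  mm <- train_multiclass(b$x, b$y, "lstwsvm")
  bm <- train_lstwsvm(b$x, b$y, 1, 1)
  expect_length(mm$models, 1L)
  expect_equal(as.integer(predict(mm, b$x)), as.integer(predict(bm, b$x)))
  # three well-separated blobs
  set.seed(11)
  centers <- rbind(c(0, 6), c(6, -3), c(-6, -3))
  x3 <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(80), 40, 2), 2, centers[k, ], "+")))
  y3 <- rep(1:3, each = 40)
  tr <- sort(c(sample(1:40, 30), sample(41:80, 30), sample(81:120, 30)))
  m3 <- train_multiclass(x3[tr, ], y3[tr], "lstwsvm")
  expect_gte(mean(predict(m3, x3[-tr, ]) == y3[-tr]), 0.95)
  # 4 classes -> 6 pairwise models
  y4 <- rep(1:4, 30)
  m4 <- train_multiclass(matrix(rnorm(240), 120, 2), y4, "lstwsvm")
  expect_length(m4$models, 6L)
})

test_that("models round-trip through JSON serialization", {
  b <- make_blobs(n_per_class = 10, sep = 3, seed = 12)
  set.seed(12); grid <- matrix(rnorm(40), 20, 2)
  models <- list(
    train_svm(b$x, b$y, 2, kernel_spec("rbf", gamma = 0.7)),
    train_lstwsvm(b$x, b$y, 1, 2, kernel_spec("rbf", gamma = 0.3)),
    train_twsvm(b$x, b$y, 1, 1),
    train_multiclass(b$x, ifelse(b$y == 1, 1, 2), "lstwsvm"))
  for (m in models) {
    path <- tempfile(fileext = ".json")
    write_model(m, path)
    back <- read_model(path)
    expect_equal(as.integer(predict(back, grid)),
                 as.integer(predict(m, grid)))
    unlink(path)
  }
})
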