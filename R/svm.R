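#' Train a soft-margin support vector machine
#'
#' Solves the soft-margin SVM
#' \deqn{\min_{w,b,\xi} \tfrac12 w^\top w + \lambda \sum_i \xi_i
#'       \quad \mathrm{s.t.}\quad \beta_i(w^\top \alpha_i + b) \ge 1-\xi_i,\
#'       \xi_i \ge 0,}
#' in the dual by sequential minimal optimization with maximal-violating-pair
#' working-set selection, which supports arbitrary kernels. The penalty
#' `cost` (\eqn{\lambda}) controls how heavily margin violations are
#' punished; for separable data and large `cost` the solution attains zero
#' training error with geometric margin \eqn{2/\lVert w\rVert}.
#'
#' @param x numeric sample matrix (rows = samples) or a `FeatureMatrix`.
#' @param y labels, exactly the set `{+1, -1}` (ignored when `x` is a
#'   `FeatureMatrix`).
#' @param cost penalty factor lambda (> 0).
#' @param kernel a [kernel_spec()].
#' @param tol KKT violation tolerance of the dual solver.
#' @return An `SVMModel` with dual coefficients, offset `b`, slack values
#'   `xi`, the dual objective value, and (linear kernel) the explicit
#'   weight vector `w`.
#' @export
train_svm <- function(x, y = NULL, cost = 1,
                      kernel = kernel_spec("linear"), tol = 1e-10) {
  d <- as_training_set(x, y)
  check_binary(d$y)
  if (cost <= 0) stop("`cost` must be positive")
  K <- kernel_matrix(kernel, d$x)
  sol <- smo_solve(K, d$y, cost, tol)
  coef <- sol$alpha * d$y
  f <- as.vector(K %*% coef) + sol$b
  w <- if (kernel$family == "linear") as.vector(crossprod(d$x, coef)) else NULL
  structure(list(alpha = sol$alpha, coef = coef, b = sol$b, w = w,
                 cost = cost, kernel = kernel, x = d$x, y = d$y,
                 xi = pmax(0, 1 - d$y * f),
                 dual_objective = sol$objective,
                 iterations = sol$iterations),
            class = "SVMModel")
}

# SMO for min_a 1/2 a'Qa - e'a, 0 <= a <= C, y'a = 0, Q = (y y') * K.
# Working pair = maximal KKT violators; b from free vectors (midpoint of
# the violation interval if none are free).
smo_solve <- function(K, y, C, tol = 1e-10, max_iter = 200000L) {
  n <- length(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)          # gradient of the dual objective, Q a - e
  it <- 0L
  repeat {
    it <- it + 1L
    yg <- -y * grad
    up <- (y > 0 & alpha < C - 1e-14 * C) | (y < 0 & alpha > 1e-14 * C)
    lo <- (y > 0 & alpha > 1e-14 * C) | (y < 0 & alpha < C - 1e-14 * C)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] <= tol || it > max_iter) break
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 1e-14) quad <- 1e-14
    t_star <- (yg[i] - yg[j]) / quad
    t_max <- min(if (y[i] > 0) C - alpha[i] else alpha[i],
                 if (y[j] > 0) alpha[j] else C - alpha[j])
    t_step <- min(t_star, t_max)
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    # delta grad = Q[,i] (y_i t) - Q[,j] (y_j t) = y (K[,i] - K[,j]) t
    grad <- grad + y * (K[, i] - K[, j]) * t_step
  }
  yg <- -y * grad
  free <- alpha > 1e-10 * C & alpha < C * (1 - 1e-10)
  b <- if (any(free)) mean(yg[free]) else {
    up <- (y > 0 & alpha < C / 2) | (y < 0 & alpha > C / 2)
    (max(yg[up], -Inf) + min(yg[!up], Inf)) / 2
  }
  # grad = Qa - e, so a'Qa = a'(grad + e) and the dual objective
  # 1/2 a'Qa - e'a reduces to (a'grad - e'a) / 2
  list(alpha = alpha, b = b,
       objective = 0.5 * (sum(alpha * grad) - sum(alpha)),
       iterations = it)
}

#' @export
predict.SVMModel <- function(object, newdata, ...) {
  newdata <- feature_values(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("feature dimension mismatch: model ", ncol(object$x),
         ", data ", ncol(newdata))
  f <- as.vector(kernel_matrix(object$kernel, newdata, object$x) %*%
                   object$coef) + object$b
  ifelse(f >= 0, 1L, -1L)
}

#' Decision values of an SVM or twin-SVM model
#'
#' For an `SVMModel`, the signed distance surrogate `w'x + b` (kernel
#' expansion); for a `TwinSVMModel`, the difference of perpendicular plane
#' distances `d2 - d1` (positive favors class +1).
#'
#' @param model a trained model.
#' @param newdata sample matrix or `FeatureMatrix`.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, newdata) {
  newdata <- feature_values(newdata)
  if (inherits(model, "SVMModel"))
    return(as.vector(kernel_matrix(model$kernel, newdata, model$x) %*%
                       model$coef) + model$b)
  if (inherits(model, "TwinSVMModel")) {
    d <- twin_distances(model, newdata)
    return(d[, 2L] - d[, 1L])
  }
  stop("unsupported model class")
}

as_training_set <- function(x, y) {
  if (inherits(x, "FeatureMatrix")) return(list(x = x$values, y = x$labels))
  list(x = as.matrix(x), y = y)
}

feature_values <- function(x) {
  if (inherits(x, "FeatureMatrix")) x$values
  else if (is.null(dim(x))) matrix(x, nrow = 1L)
  else as.matrix(x)
}

check_binary <- function(y) {
  u <- sort(unique(y))
  if (!identical(as.numeric(u), c(-1, 1)))
    stop("binary classifiers require exactly the label set {+1, -1}; ",
         "use train_multiclass() for other labelings")
}
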