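#' Train a Twin Support Vector Machine
#'
#' TWSVM fits one "near-end" hyperplane per class: plane k minimizes the
#' squared distances of its own class's samples to itself while pushing the
#' other class's samples beyond unit distance via a hinge penalty with cost
#' `c_k`. Each plane is obtained from one small quadratic program whose size
#' equals the opposite class's sample count; the QPs are solved by exact
#' projected coordinate descent on the box-constrained dual. Prediction
#' assigns a sample to the class whose plane is nearer (perpendicular
#' distance, kernel metric for nonlinear kernels); exact ties go to class
#' +1.
#'
#' With a nonlinear kernel, planes are expressed as kernel expansions over
#' the full training set.
#'
#' @param x sample matrix (rows = samples) or `FeatureMatrix`.
#' @param y labels in `{+1, -1}`.
#' @param c1,c2 hinge penalty of plane 1 (near class +1) and plane 2
#'   (near class -1); both > 0.
#' @param kernel a [kernel_spec()].
#' @param ridge Tikhonov term added to the within-class Gram matrix for
#'   conditioning.
#' @return A `TwinSVMModel` with `plane1`, `plane2` (each `(w, b)`), costs,
#'   kernel and, for nonlinear kernels, the reference samples.
#' @export
train_twsvm <- function(x, y = NULL, c1 = 1, c2 = 1,
                        kernel = kernel_spec("linear"), ridge = 1e-8) {
  d <- as_training_set(x, y)
  check_binary(d$y)
  if (c1 <= 0 || c2 <= 0) stop("costs must be positive")
  m <- twin_design(d$x, d$y, kernel)
  # plane 1 (near class +1): dual min 1/2 a' G (H'H)^-1 G' a - e'a,
  # 0 <= a <= c1; u1 = -(H'H)^-1 G' a
  HtH <- crossprod(m$H) + ridge * diag(ncol(m$H))
  GtG <- crossprod(m$G) + ridge * diag(ncol(m$G))
  M1 <- m$G %*% solve(HtH, t(m$G))
  a1 <- box_qp(M1, rep(1, nrow(m$G)), c1)
  u1 <- -solve(HtH, crossprod(m$G, a1))
  M2 <- m$H %*% solve(GtG, t(m$H))
  a2 <- box_qp(M2, rep(1, nrow(m$H)), c2)
  u2 <- solve(GtG, crossprod(m$H, a2))
  twin_model(u1, u2, m, c(c1, c2), kernel, method = "twsvm")
}

#' Train a Least-Squares Twin Support Vector Machine
#'
#' The least-squares variant replaces TWSVM's inequality constraints with
#' equalities and the hinge loss with a squared loss, so each plane is the
#' solution of one symmetric positive-definite linear system instead of a
#' quadratic program: for plane 1,
#' \deqn{(G^\top G + \tfrac{1}{c_1} H^\top H + \epsilon I)\,u_1 = -G^\top e,}
#' where `H = [A 1]` stacks the own-class samples, `G = [B 1]` the other
#' class, and `u1 = (w1, b1)`; symmetrically for plane 2. This preserves the
#' twin geometry while reducing training to two linear solves.
#'
#' @inheritParams train_twsvm
#' @param c1,c2 squared-loss penalty weights (> 0).
#' @return A `TwinSVMModel`.
#' @export
train_lstwsvm <- function(x, y = NULL, c1 = 1, c2 = 1,
                          kernel = kernel_spec("linear"), ridge = 1e-8) {
  d <- as_training_set(x, y)
  check_binary(d$y)
  if (c1 <= 0 || c2 <= 0) stop("costs must be positive")
  m <- twin_design(d$x, d$y, kernel)
  p <- ncol(m$H)
  A1 <- crossprod(m$G) + crossprod(m$H) / c1 + ridge * diag(p)
  A2 <- crossprod(m$H) + crossprod(m$G) / c2 + ridge * diag(p)
  u1 <- tryCatch(solve(A1, -crossprod(m$G, rep(1, nrow(m$G)))),
                 error = function(e)
                   stop("singular system for plane 1; raise `ridge` (",
                        conditionMessage(e), ")"))
  u2 <- tryCatch(solve(A2, crossprod(m$H, rep(1, nrow(m$H)))),
                 error = function(e)
                   stop("singular system for plane 2; raise `ridge` (",
                        conditionMessage(e), ")"))
  twin_model(u1, u2, m, c(c1, c2), kernel, method = "lstwsvm")
}

# augmented design matrices for the twin formulations; nonlinear kernels
# map samples to kernel evaluations against the full training set
twin_design <- function(x, y, kernel) {
  A <- x[y == 1, , drop = FALSE]
  B <- x[y == -1, , drop = FALSE]
  if (kernel$family == "linear") {
    ref <- NULL
    H <- cbind(A, 1)
    G <- cbind(B, 1)
    Kref <- NULL
  } else {
    ref <- x
    H <- cbind(kernel_matrix(kernel, A, ref), 1)
    G <- cbind(kernel_matrix(kernel, B, ref), 1)
    Kref <- kernel_matrix(kernel, ref)
  }
  list(H = H, G = G, ref = ref, Kref = Kref, dim = ncol(x))
}

twin_model <- function(u1, u2, design, costs, kernel, method) {
  u1 <- as.vector(u1); u2 <- as.vector(u2)
  p <- length(u1)
  norm_in_metric <- function(w) {
    if (is.null(design$Kref)) sqrt(sum(w^2))
    else sqrt(max(as.numeric(t(w) %*% design$Kref %*% w), 0))
  }
  structure(list(
    plane1 = list(w = u1[-p], b = u1[p]),
    plane2 = list(w = u2[-p], b = u2[p]),
    norm1 = norm_in_metric(u1[-p]), norm2 = norm_in_metric(u2[-p]),
    costs = costs, kernel = kernel, reference = design$ref,
    input_dim = design$dim, method = method),
    class = "TwinSVMModel")
}

# exact projected coordinate descent for min 1/2 a'Ma - q'a, 0 <= a <= c
box_qp <- function(M, q, c, tol = 1e-12, max_sweeps = 20000L) {
  n <- length(q)
  a <- numeric(n)
  g <- -q                       # gradient M a - q at a = 0
  dM <- pmax(diag(M), 1e-14)
  for (s in seq_len(max_sweeps)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      ai <- min(max(a[i] - g[i] / dM[i], 0), c)
      di <- ai - a[i]
      if (di != 0) {
        g <- g + M[, i] * di
        a[i] <- ai
        delta_max <- max(delta_max, abs(di))
      }
    }
    if (delta_max < tol * max(1, c)) break
  }
  a
}

# perpendicular distances of samples to both twin planes
twin_distances <- function(model, newdata) {
  X <- feature_values(newdata)
  if (ncol(X) != model$input_dim)
    stop("feature dimension mismatch: model ", model$input_dim,
         ", data ", ncol(X))
  Phi <- if (is.null(model$reference)) X
         else kernel_matrix(model$kernel, X, model$reference)
  d1 <- abs(Phi %*% model$plane1$w + model$plane1$b) / max(model$norm1, 1e-300)
  d2 <- abs(Phi %*% model$plane2$w + model$plane2$b) / max(model$norm2, 1e-300)
  cbind(as.vector(d1), as.vector(d2))
}

#' @export
predict.TwinSVMModel <- function(object, newdata, ...) {
  d <- twin_distances(object, newdata)
  ifelse(d[, 1L] <= d[, 2L], 1L, -1L)   # ties go to class +1
}
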