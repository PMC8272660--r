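#' Kernel specification
#'
#' @param family one of `"linear"`, `"rbf"`, `"polynomial"`.
#' @param gamma inverse squared length scale for the RBF kernel (> 0).
#' @param degree polynomial degree (>= 1).
#' @param coef additive constant of the polynomial kernel.
#' @return A `KernelSpec`.
#' @export
kernel_spec <- function(family = c("linear", "rbf", "polynomial"),
                        gamma = 1, degree = 3L, coef = 1) {
  family <- match.arg(family)
  if (family == "rbf" && gamma <= 0) stop("rbf kernel requires gamma > 0")
  if (family == "polynomial" && degree < 1) stop("degree must be >= 1")
  structure(list(family = family, gamma = gamma,
                 degree = as.integer(degree), coef = coef),
            class = "KernelSpec")
}

#' Evaluate a kernel Gram matrix
#'
#' @param spec a [kernel_spec()].
#' @param x,y numeric matrices with samples in rows (`y` defaults to `x`).
#' @return The `nrow(x)` x `nrow(y)` Gram matrix.
#' @export
kernel_matrix <- function(spec, x, y = x) {
  x <- as.matrix(x); y <- as.matrix(y)
  switch(spec$family,
    linear = tcrossprod(x, y),
    polynomial = (tcrossprod(x, y) + spec$coef)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
      exp(-spec$gamma * pmax(d2, 0))
    })
}
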