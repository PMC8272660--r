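#' One-vs-one multiclass wrapper for twin-SVM-family classifiers
#'
#' Trains one binary model per unordered class pair (the lower class label
#' is mapped to +1) and predicts by majority vote; vote ties are broken by
#' the summed signed plane-distance margins, and any remaining tie by the
#' lower class label. With two classes this reduces exactly to the binary
#' model.
#'
#' @param x sample matrix or `FeatureMatrix`.
#' @param y integer labels (>= 2 classes).
#' @param base one of `"lstwsvm"`, `"twsvm"`, `"svm"`.
#' @param costs length-2 penalties passed to the base trainer (for
#'   `"svm"`, the first entry is the cost).
#' @param kernel a [kernel_spec()].
#' @return A `MulticlassModel` holding `n(n-1)/2` pairwise models.
#' @export
train_multiclass <- function(x, y = NULL,
                             base = c("lstwsvm", "twsvm", "svm"),
                             costs = c(1, 1),
                             kernel = kernel_spec("linear")) {
  base <- match.arg(base)
  d <- as_training_set(x, y)
  classes <- sort(unique(d$y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  small <- classes[table(factor(d$y, classes)) < 2L]
  if (length(small) > 0L)
    message("class(es) with < 2 samples: ", paste(small, collapse = ", "),
            "; unusable for cross-validation")
  pairs <- utils::combn(classes, 2L)
  models <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    idx <- d$y %in% c(a, b)
    yy <- ifelse(d$y[idx] == a, 1, -1)
    xx <- d$x[idx, , drop = FALSE]
    models[[k]] <- switch(base,
      lstwsvm = train_lstwsvm(xx, yy, costs[1L], costs[2L], kernel),
      twsvm = train_twsvm(xx, yy, costs[1L], costs[2L], kernel),
      svm = train_svm(xx, yy, costs[1L], kernel))
  }
  structure(list(models = models, pairs = pairs, classes = classes,
                 base = base, costs = costs, kernel = kernel),
            class = "MulticlassModel")
}

#' @export
predict.MulticlassModel <- function(object, newdata, ...) {
  X <- feature_values(newdata)
  n <- nrow(X)
  nc <- length(object$classes)
  votes <- matrix(0, n, nc, dimnames = list(NULL, object$classes))
  margin <- matrix(0, n, nc)
  for (k in seq_along(object$models)) {
    a <- match(object$pairs[1L, k], object$classes)
    b <- match(object$pairs[2L, k], object$classes)
    s <- decision_values(object$models[[k]], X)
    win_a <- s >= 0
    votes[, a] <- votes[, a] + win_a
    votes[, b] <- votes[, b] + !win_a
    margin[, a] <- margin[, a] + s
    margin[, b] <- margin[, b] - s
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) top <- top[margin[i, top] == max(margin[i, top])]
    out[i] <- object$classes[top[1L]]   # lowest class label on full ties
  }
  out
}

#' Serialize a trained classifier to JSON text
#'
#' Writes kernel specification, plane/weight parameters and reference
#' samples so that [read_model()] reproduces a model giving identical
#' predictions.
#'
#' @param model an `SVMModel`, `TwinSVMModel` or `MulticlassModel`.
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(serialize_model(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

serialize_model <- function(model) {
  if (inherits(model, "SVMModel"))
    list(type = "SVMModel", kernel = unclass(model$kernel),
         coef = model$coef, b = model$b, w = model$w, cost = model$cost,
         x = model$x, y = model$y)
  else if (inherits(model, "TwinSVMModel"))
    list(type = "TwinSVMModel", kernel = unclass(model$kernel),
         plane1 = model$plane1, plane2 = model$plane2,
         norm1 = model$norm1, norm2 = model$norm2, costs = model$costs,
         reference = model$reference, input_dim = model$input_dim,
         method = model$method)
  else if (inherits(model, "MulticlassModel"))
    list(type = "MulticlassModel", base = model$base,
         classes = model$classes, costs = model$costs,
         kernel = unclass(model$kernel),
         pairs = model$pairs,
         models = lapply(model$models, serialize_model))
  else stop("unsupported model class")
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  deserialize_model(jsonlite::read_json(path, simplifyVector = TRUE,
                                        simplifyDataFrame = FALSE))
}

deserialize_model <- function(obj) {
  kern <- if (!is.null(obj$kernel))
    kernel_spec(obj$kernel$family, obj$kernel$gamma %||% 1,
                obj$kernel$degree %||% 3L, obj$kernel$coef %||% 1)
  switch(obj$type,
    SVMModel = structure(list(
      coef = obj$coef, b = obj$b,
      w = if (length(obj$w)) obj$w else NULL,
      cost = obj$cost, kernel = kern,
      x = as.matrix(obj$x), y = obj$y), class = "SVMModel"),
    TwinSVMModel = structure(list(
      plane1 = list(w = obj$plane1$w, b = obj$plane1$b),
      plane2 = list(w = obj$plane2$w, b = obj$plane2$b),
      norm1 = obj$norm1, norm2 = obj$norm2, costs = obj$costs,
      kernel = kern,
      reference = if (length(obj$reference)) as.matrix(obj$reference),
      input_dim = obj$input_dim, method = obj$method),
      class = "TwinSVMModel"),
    MulticlassModel = structure(list(
      models = lapply(obj$models, deserialize_model),
      pairs = matrix(unlist(obj$pairs), nrow = 2L),
      classes = obj$classes, base = obj$base, costs = obj$costs,
      kernel = kern), class = "MulticlassModel"),
    stop("unknown model type: ", obj$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
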