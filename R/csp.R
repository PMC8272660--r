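#' Fit Common Spatial Pattern filters for two classes
#'
#' Computes per-trial channel covariances, trace-normalizes each, averages
#' within class, shrinks each class covariance toward the identity, and
#' solves the generalized eigenproblem `C1 w = lambda (C1 + C2) w` by
#' whitening the composite covariance and diagonalizing the whitened C1.
#' The retained filters are the eigenvectors at both ends of the spectrum
#' (largest variance ratio for class 1 and for class 2).
#'
#' @param epochs an [epoch_set()] with exactly two classes.
#' @param n_components number of spatial filters to retain (even; taken as
#'   pairs from both ends of the eigenvalue spectrum). Default 4.
#' @param regularization shrinkage fraction in `[0, 1]` applied to each
#'   class covariance toward `tr(C)/n I`. Default 0.05.
#' @return A `CSPModel` with `filters` (component x channel, rows ordered by
#'   descending eigenvalue), `eigenvalues` (for the retained components),
#'   `classes` (the two labels, in the order giving eigenvalue meaning:
#'   eigenvalue is the variance fraction of the first class), and the
#'   band tag of the input.
#' @export
fit_csp <- function(epochs, n_components = 4L, regularization = 0.05) {
  stopifnot(inherits(epochs, "EpochSet"))
  classes <- sort(unique(epochs$labels))
  if (length(classes) != 2L)
    stop("CSP requires exactly 2 classes (got ", length(classes),
         "); use the one-vs-one multiclass wrapper upstream")
  nc <- n_channels(epochs)
  if (n_components %% 2L != 0L || n_components > nc)
    stop("`n_components` must be even and <= the channel count")
  C1 <- class_covariance(epochs, classes[1L], regularization)
  C2 <- class_covariance(epochs, classes[2L], regularization)
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) < 1e-10 * max(ec$values))
    stop("composite covariance is rank deficient; raise `regularization`")
  # whitening transform P: P Cc P' = I
  P <- diag(1 / sqrt(ec$values), nc) %*% t(ec$vectors)
  S <- P %*% C1 %*% t(P)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  W <- t(es$vectors) %*% P          # rows: filters, eigenvalues descending
  half <- n_components / 2L
  idx <- c(seq_len(half), seq.int(nc - half + 1L, nc))
  structure(list(filters = W[idx, , drop = FALSE],
                 eigenvalues = es$values[idx],
                 n_components = as.integer(n_components),
                 classes = classes,
                 regularization = regularization,
                 channel_names = epochs$channel_names,
                 band = epochs$band),
            class = "CSPModel")
}

# average trace-normalized covariance of one class, shrunk toward identity;
# trials are weighted by 1/trace and summed in a single crossproduct
class_covariance <- function(epochs, class, regularization = 0) {
  idx <- which(epochs$labels == class)
  nc <- n_channels(epochs)
  ns <- n_samples(epochs)
  d <- epochs$data[idx, , , drop = FALSE]
  traces <- rowSums(matrix(d^2, length(idx)))   # = ns * tr(cov) per trial
  M <- matrix(aperm(d / sqrt(traces), c(2L, 1L, 3L)), nc)
  C <- tcrossprod(M) / length(idx)
  (1 - regularization) * C + regularization * (sum(diag(C)) / nc) * diag(nc)
}

#' Log-variance CSP features
#'
#' Projects each trial through the model's spatial filters and returns, per
#' retained component, the log of the component variance normalized by the
#' summed variance over retained components. Normalization makes features
#' invariant to global amplitude scaling of a trial.
#'
#' @param model a `CSPModel` from [fit_csp()].
#' @param epochs an [epoch_set()] with the same channel count.
#' @return A `FeatureMatrix`: list with `values` (trial x feature),
#'   `labels`, and `feature_names` carrying the band tag.
#' @export
csp_features <- function(model, epochs) {
  stopifnot(inherits(model, "CSPModel"), inherits(epochs, "EpochSet"))
  if (ncol(model$filters) != n_channels(epochs))
    stop("channel count mismatch: model has ", ncol(model$filters),
         ", epochs have ", n_channels(epochs))
  nt <- n_trials(epochs)
  ns <- n_samples(epochs)
  k <- nrow(model$filters)
  # project all trials at once; per-trial component variances from moments
  Y <- model$filters %*% matrix(aperm(epochs$data, c(2L, 1L, 3L)),
                                n_channels(epochs))
  s1 <- rowSums(array(Y, c(k, nt, ns)), dims = 2L)
  s2 <- rowSums(array(Y^2, c(k, nt, ns)), dims = 2L)
  v <- t((s2 - s1^2 / ns) / (ns - 1))
  tot <- rowSums(v)
  zero <- tot <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance trial(s); features floored")
    v[zero, ] <- .Machine$double.xmin
    tot[zero] <- k * .Machine$double.xmin
  }
  f <- log(pmax(v / tot, .Machine$double.xmin))
  tag <- if (is.null(model$band)) "" else
    sprintf("_%g-%g", model$band[1L], model$band[2L])
  feature_matrix(f, epochs$labels,
                 paste0("csp", seq_len(k), tag))
}

#' @rdname csp_features
#' @param values numeric trial x feature matrix.
#' @param labels integer per-trial labels.
#' @param feature_names character feature identifiers.
#' @export
feature_matrix <- function(values, labels, feature_names = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels))
    stop("row count must equal label count")
  if (any(!is.finite(values))) stop("non-finite feature values")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- feature_names
  structure(list(values = values, labels = as.integer(labels),
                 feature_names = feature_names),
            class = "FeatureMatrix")
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-delimited with a header row of feature names and a final `label`
#' column; `read_features` round-trips the result.
#'
#' @param x a `FeatureMatrix`.
#' @param path file path.
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "FeatureMatrix"))
  df <- as.data.frame(x$values)
  df$label <- x$labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  lab <- df$label
  df$label <- NULL
  feature_matrix(as.matrix(df), lab, colnames(df))
}

#' Adaptive frequency-band selection by cross-validated accuracy
#'
#' Runs stratified k-fold cross-validation of a classifier on each band's
#' feature matrix and returns the band with the highest CV accuracy. Ties
#' are broken toward the lower-frequency (lower-index) band so results are
#' reproducible.
#'
#' @param band_features list of `FeatureMatrix`, one per band, sharing
#'   labels and trial order.
#' @param folds number of CV folds (>= 2, <= smallest class count).
#' @param classifier_factory function `(x, y) -> model` where the model
#'   supports `predict(model, newx)`; defaults to a linear LS-TWSVM with
#'   unit costs.
#' @param seed integer seed for the fold shuffle.
#' @return list with `selected` (band index) and `scores` (per-band CV
#'   accuracy).
#' @export
select_band <- function(band_features, folds = 5L,
                        classifier_factory = NULL, seed = 1L) {
  if (length(band_features) == 0L) stop("need at least one band")
  if (is.null(classifier_factory))
    classifier_factory <- classwise_factory("lstwsvm", c(c1 = 1, c2 = 1),
                                            "linear")
  labels <- band_features[[1L]]$labels
  for (f in band_features)
    if (!identical(f$labels, labels))
      stop("all bands must share the same labels and trial order")
  scores <- vapply(band_features, function(f)
    cv_accuracy(f$values, labels, classifier_factory, folds, seed),
    numeric(1L))
  list(selected = which.max(scores), scores = scores)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds; deterministic given seed
stratified_folds <- function(labels, folds, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds")
  if (folds > min(table(labels)))
    stop("fold count (", folds, ") exceeds the smallest class count (",
         min(table(labels)), ")")
  set.seed(as.integer(seed))
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# k-fold CV accuracy of factory(x, y) models; used by select_band and as
# the optimizer fitness backend
cv_accuracy <- function(x, labels, factory, folds, seed = 1L) {
  assign <- stratified_folds(labels, folds, seed)
  correct <- 0L
  for (k in seq_len(max(assign))) {
    tr <- assign != k
    model <- factory(x[tr, , drop = FALSE], labels[tr])
    pred <- predict(model, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == labels[!tr])
  }
  correct / length(labels)
}
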