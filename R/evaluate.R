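#' Fisher linear discriminant baseline
#'
#' Linear discriminant with pooled within-class covariance regularized by a
#' small ridge, equal class priors. For two symmetric classes the decision
#' boundary is the midpoint hyperplane between the class means.
#'
#' @param x sample matrix (rows = samples) or `FeatureMatrix`.
#' @param y labels (ignored for a `FeatureMatrix`).
#' @param ridge diagonal regularization of the pooled covariance.
#' @return An `LDAModel` supporting `predict`.
#' @export
fit_lda <- function(x, y = NULL, ridge = 1e-6) {
  d <- as_training_set(x, y)
  classes <- sort(unique(d$y))
  p <- ncol(d$x)
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(d$x[d$y == cl, , drop = FALSE])))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- scale(d$x[d$y == cl, , drop = FALSE], center = TRUE,
                scale = FALSE)
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (nrow(d$x) - length(classes)) + ridge * diag(p)
  Winv <- tryCatch(solve(Sw), error = function(e)
    stop("singular pooled covariance; raise `ridge`"))
  structure(list(classes = classes, means = means, Winv = Winv),
            class = "LDAModel")
}

#' @export
predict.LDAModel <- function(object, newdata, ...) {
  X <- feature_values(newdata)
  # equal-prior Gaussian discriminant: x' W m_k - m_k' W m_k / 2
  scores <- X %*% object$Winv %*% t(object$means)
  offsets <- rowSums((object$means %*% object$Winv) * object$means) / 2
  scores <- sweep(scores, 2L, offsets)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Probabilistic neural network (Parzen-window) baseline
#'
#' Class-conditional densities are Gaussian kernel density estimates with a
#' shared bandwidth; classification is by maximum posterior. With
#' `priors = "equal"` the posterior is the per-class mean kernel value; with
#' `priors = "proportional"` classes are weighted by their training
#' frequency, so in the infinite-bandwidth limit the majority class wins.
#'
#' @param x sample matrix or `FeatureMatrix`.
#' @param y labels.
#' @param bandwidth Gaussian kernel bandwidth sigma (> 0).
#' @param priors `"equal"` (default) or `"proportional"`.
#' @return A `PNNModel` supporting `predict`.
#' @export
fit_pnn <- function(x, y = NULL, bandwidth = 1,
                    priors = c("equal", "proportional")) {
  if (bandwidth <= 0) stop("`bandwidth` must be positive")
  priors <- match.arg(priors)
  d <- as_training_set(x, y)
  structure(list(x = d$x, y = d$y, classes = sort(unique(d$y)),
                 bandwidth = bandwidth, priors = priors),
            class = "PNNModel")
}

#' @export
predict.PNNModel <- function(object, newdata, ...) {
  X <- feature_values(newdata)
  d2 <- outer(rowSums(X^2), rowSums(object$x^2), "+") -
    2 * tcrossprod(X, object$x)
  # subtract the row minimum before exponentiating so sigma -> 0 stays finite
  d2 <- pmax(d2, 0) / (2 * object$bandwidth^2)
  Kmat <- exp(-(d2 - apply(d2, 1L, min)))
  scores <- vapply(object$classes, function(cl) {
    cols <- object$y == cl
    s <- rowSums(Kmat[, cols, drop = FALSE])
    if (object$priors == "equal") s / sum(cols) else s
  }, numeric(nrow(X)))
  object$classes[max.col(as.matrix(scores), ties.method = "first")]
}

#' Cross-validated accuracy of the baseline classifiers
#'
#' @param features a `FeatureMatrix`.
#' @param folds number of stratified CV folds.
#' @param seed fold-shuffle seed.
#' @param bandwidth PNN kernel bandwidth.
#' @return Accuracy in percent.
#' @export
baseline_lda <- function(features, folds = 10L, seed = 1L) {
  100 * cv_accuracy(features$values, features$labels,
                    function(x, y) fit_lda(x, y), folds, seed)
}

#' @rdname baseline_lda
#' @export
baseline_pnn <- function(features, bandwidth = 1, folds = 10L, seed = 1L) {
  100 * cv_accuracy(features$values, features$labels,
                    function(x, y) fit_pnn(x, y, bandwidth), folds, seed)
}

#' Summary statistics for per-subject accuracies
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' standard error (SD / sqrt(n)), all on the percent scale of the input.
#'
#' @param accuracies non-empty numeric vector of per-subject accuracies (%).
#' @return list with `mean`, `sd`, `se`, `n`.
#' @examples
#' summarize_accuracies(c(70, 90))  # mean 80, sd 14.14, se 10
#' @export
summarize_accuracies <- function(accuracies) {
  if (length(accuracies) == 0L) stop("empty accuracy list")
  n <- length(accuracies)
  s <- if (n > 1L) stats::sd(accuracies) else 0
  list(mean = mean(accuracies), sd = s, se = s / sqrt(n), n = n)
}

#' Multi-subject, multi-method evaluation report
#'
#' Runs the requested methods on every subject with identical train/test
#' splits (the per-subject seed is shared across methods, so the comparison
#' is paired) and assembles a report in the style of a per-subject accuracy
#' table: one row per subject plus Mean, SD and SE rows. Both the sample
#' standard deviation and the standard error are reported.
#'
#' @param subjects list of [epoch_set()] objects, one per subject.
#' @param methods character subset of `"pso-ls-twin-svm"`, `"lstwsvm"`,
#'   `"twsvm"`, `"svm"`, `"lda"`, `"pnn"`.
#' @param config a [pipeline_config()].
#' @return An `EvaluationReport`: `accuracy` (subject x method matrix, %),
#'   `mean`, `sd`, `se` per method, `seeds` per subject, and
#'   `config_snapshot`.
#' @export
compare_methods <- function(subjects, methods = c("pso-ls-twin-svm", "lda",
                                                  "pnn"),
                            config = pipeline_config()) {
  known <- c("pso-ls-twin-svm", "lstwsvm", "twsvm", "svm", "lda", "pnn")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L)
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (length(subjects) == 0L) stop("need at least one subject")
  seeds <- config$seed + seq_along(subjects)
  acc <- matrix(NA_real_, length(subjects), length(methods),
                dimnames = list(paste0("subject_", seq_along(subjects)),
                                methods))
  for (s in seq_along(subjects)) {
    cfg_s <- config
    cfg_s$seed <- seeds[s]
    for (m in seq_along(methods))
      acc[s, m] <- as.numeric(run_pipeline(subjects[[s]], cfg_s,
                                           method = methods[m]))
  }
  sums <- apply(acc, 2L, summarize_accuracies)
  structure(list(methods = methods, accuracy = acc,
                 mean = vapply(sums, `[[`, numeric(1L), "mean"),
                 sd = vapply(sums, `[[`, numeric(1L), "sd"),
                 se = vapply(sums, `[[`, numeric(1L), "se"),
                 seeds = seeds, config_snapshot = config),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  tab <- rbind(x$accuracy, Mean = x$mean, SD = x$sd, SE = x$se)
  print(round(tab, 2L))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' Tab-delimited: per-subject rows then Mean, SD and SE rows; a config
#' snapshot is written alongside as YAML when `config_path` is given.
#'
#' @param report an `EvaluationReport`.
#' @param path output TSV path.
#' @param config_path optional path for the YAML config snapshot.
#' @export
write_report <- function(report, path, config_path = NULL) {
  tab <- rbind(report$accuracy, Mean = report$mean, SD = report$sd,
               SE = report$se)
  df <- data.frame(testing_object = rownames(tab), round(tab, 2L),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(config_path))
    write_pipeline_config(report$config_snapshot, config_path)
  invisible(path)
}

#' Reference per-subject accuracy table
#'
#' The bundled benchmark comparison of per-subject recognition accuracies
#' (percent) for the tuned PSO-LS-TWIN-SVM pipeline against LDA,
#' back-propagation network and PNN baselines on ten testing objects.
#' [summarize_accuracies()] on each column reproduces the table's summary
#' rows.
#'
#' @return data frame with columns `testing_object`, `pso_ls_twin_svm`,
#'   `lda`, `bp`, `pnn`.
#' @export
reference_accuracies <- function() {
  utils::read.table(system.file("extdata", "reference_accuracy_table.tsv",
                                package = "eegtwin"),
                    header = TRUE, sep = "\t")
}
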