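#' Full pipeline configuration
#'
#' Collects every setting of the recognition pipeline: artifact-removal
#' reference channels, filter bank, CSP, classifier family and kernel,
#' optimizer, and cross-validation layout. The object is a plain list and
#' serializes losslessly to YAML/JSON ([write_pipeline_config()]), so a
#' report can be regenerated from its config snapshot.
#'
#' @param reference_channels channels regressed out before filtering
#'   (skipped silently for sets that do not contain them).
#' @param bands filter-bank bands (list of `(low, high)` Hz).
#' @param filter_order overall band-pass order.
#' @param n_components retained CSP filters.
#' @param regularization CSP covariance shrinkage.
#' @param base classifier family: `"lstwsvm"`, `"twsvm"` or `"svm"`.
#' @param kernel_family `"linear"`, `"rbf"` or `"polynomial"`.
#' @param costs fixed penalties used when no optimizer runs (and as the
#'   band-selection classifier's costs).
#' @param gamma fixed RBF width used when no optimizer runs.
#' @param optimizer list of [optimizer_config()] arguments for the tuned
#'   pipeline (algorithm, max_iterations, population, ...).
#' @param outer_folds held-out evaluation folds.
#' @param selection_folds CV folds of the band-selection stage.
#' @param tuning_folds CV folds of the optimizer fitness (default 10).
#' @param pnn_bandwidth Parzen bandwidth of the PNN baseline.
#' @param seed master seed.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(reference_channels = "EOG",
                            bands = default_bands(), filter_order = 4L,
                            n_components = 4L, regularization = 0.05,
                            base = "lstwsvm", kernel_family = "rbf",
                            costs = c(1, 1), gamma = 0.1,
                            optimizer = list(algorithm = "pso",
                                             max_iterations = 300L,
                                             population = 20L),
                            outer_folds = 5L, selection_folds = 5L,
                            tuning_folds = 10L, pnn_bandwidth = 1,
                            seed = 1L) {
  structure(list(reference_channels = reference_channels, bands = bands,
                 filter_order = as.integer(filter_order),
                 n_components = as.integer(n_components),
                 regularization = regularization, base = base,
                 kernel_family = kernel_family, costs = costs,
                 gamma = gamma, optimizer = optimizer,
                 outer_folds = as.integer(outer_folds),
                 selection_folds = as.integer(selection_folds),
                 tuning_folds = as.integer(tuning_folds),
                 pnn_bandwidth = pnn_bandwidth,
                 seed = as.integer(seed)),
            class = c("PipelineConfig", "list"))
}

#' @rdname pipeline_config
#' @param config a `PipelineConfig`.
#' @param path file path (`.yaml` or `.json` by extension).
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
  else yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  obj$bands <- lapply(obj$bands, as.numeric)
  for (f in intersect(c("max_iterations", "population", "chromosome_length"),
                      names(obj$optimizer)))
    obj$optimizer[[f]] <- as.integer(obj$optimizer[[f]])
  do.call(pipeline_config, obj)
}

#' Run the end-to-end recognition pipeline on one subject
#'
#' Stages, in order: per-trial reference regression (artifact removal,
#' when reference channels are present), band-pass filter bank, per-band
#' CSP fitted on training folds only, adaptive band selection by inner CV
#' on the training folds, hyperparameter tuning of the classifier by the
#' configured optimizer (inner CV fitness, training folds only), and
#' held-out prediction on the outer test folds. Band selection and tuning
#' never see test-fold data, so the reported accuracy is leakage-free.
#'
#' @param epochs an [epoch_set()].
#' @param config a [pipeline_config()].
#' @param method classifier stage: `"pso-ls-twin-svm"` (optimizer-tuned
#'   LS-TWSVM), `"lstwsvm"`, `"twsvm"`, `"svm"` (fixed hyperparameters),
#'   `"lda"` or `"pnn"` (baselines on the selected band's CSP features).
#' @return Held-out accuracy in percent, with attributes
#'   `"selected_bands"` (per outer fold) and `"tuned_params"` (per outer
#'   fold, tuned methods only).
#' @export
run_pipeline <- function(epochs, config = pipeline_config(),
                         method = "pso-ls-twin-svm") {
  stopifnot(inherits(epochs, "EpochSet"))
  known <- c("pso-ls-twin-svm", "lstwsvm", "twsvm", "svm", "lda", "pnn")
  if (!method %in% known)
    stop("unknown method '", method, "'; expected one of: ",
         paste(known, collapse = ", "))
  if (length(unique(epochs$labels)) < 2L)
    stop("pipeline stage 'input': need at least 2 classes")
  refs <- intersect(config$reference_channels, epochs$channel_names)
  if (length(refs) > 0L)
    epochs <- with_stage("artifact removal",
                         remove_artifacts(epochs, refs))
  spec <- filter_bank_spec(config$bands, config$filter_order)
  nyq <- epochs$sampling_rate / 2
  spec$bands <- Filter(function(b) b[2L] < nyq, spec$bands)
  if (length(spec$bands) == 0L)
    stop("pipeline stage 'filter bank': no band below the Nyquist frequency")
  band_sets <- with_stage("filter bank", apply_filter_bank(epochs, spec))
  assign <- stratified_folds(epochs$labels, config$outer_folds,
                             seed = config$seed)
  sel_bands <- integer(max(assign))
  tuned <- vector("list", max(assign))
  correct <- 0L
  for (k in seq_len(max(assign))) {
    tr <- assign != k
    res <- with_stage(sprintf("outer fold %d", k),
                      pipeline_fold(band_sets, tr, config, method, k))
    sel_bands[k] <- res$band
    tuned[[k]] <- res$params
    correct <- correct + sum(res$pred == epochs$labels[!tr])
  }
  acc <- 100 * correct / length(epochs$labels)
  attr(acc, "selected_bands") <- sel_bands
  attr(acc, "tuned_params") <- tuned
  acc
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
}

# one outer fold: CSP fit + band selection + (optional) tuning on the
# training trials, prediction on the held-out trials
pipeline_fold <- function(band_sets, tr, config, method, fold_index) {
  train_feats <- list(); test_feats <- list()
  for (b in seq_along(band_sets)) {
    ep <- band_sets[[b]]
    f <- ovo_csp_features(subset_trials(ep, tr), subset_trials(ep, !tr),
                          config$n_components, config$regularization)
    train_feats[[b]] <- f$train
    test_feats[[b]] <- f$test
  }
  sel_factory <- function(x, y) fixed_classifier(x, y, config)
  sel <- select_band(train_feats, folds = config$selection_folds,
                     classifier_factory = sel_factory,
                     seed = config$seed + 1000L + fold_index)
  ftr <- train_feats[[sel$selected]]
  fte <- test_feats[[sel$selected]]
  params <- NULL
  if (method == "pso-ls-twin-svm") {
    space <- if (config$kernel_family == "rbf") default_classifier_space()
    else search_space(c("c1", "c2"), c(2^-8, 2^-8), c(2^8, 2^8),
                      c("log", "log"))
    oc_args <- config$optimizer
    oc_args$seed <- config$seed + 2000L + fold_index
    oc <- do.call(optimizer_config, oc_args)
    factory <- function(p) classwise_factory(config$base, p,
                                             config$kernel_family)
    fit_fun <- function(p) cv_fitness(p, ftr,
                                      classifier_factory = factory,
                                      folds = config$tuning_folds,
                                      seed = config$seed + 3000L + fold_index)
    res <- optimize_params(fit_fun, space, oc)
    params <- res$best_params
    model <- factory(params)(ftr$values, ftr$labels)
    pred <- predict(model, fte$values)
  } else if (method %in% c("lstwsvm", "twsvm", "svm")) {
    cfg2 <- config; cfg2$base <- method
    model <- fixed_classifier(ftr$values, ftr$labels, cfg2)
    pred <- predict(model, fte$values)
  } else if (method == "lda") {
    model <- fit_lda(ftr$values, ftr$labels)
    pred <- predict(model, fte$values)
  } else {
    model <- fit_pnn(ftr$values, ftr$labels,
                     bandwidth = config$pnn_bandwidth)
    pred <- predict(model, fte$values)
  }
  list(pred = pred, band = sel$selected, params = params)
}

# CSP features for >= 2 classes: two-class CSP directly, or one-vs-one
# pairwise CSP with concatenated features for multiclass
ovo_csp_features <- function(train_ep, test_ep, n_components, regularization) {
  classes <- sort(unique(train_ep$labels))
  if (length(classes) == 2L) {
    model <- fit_csp(train_ep, n_components, regularization)
    return(list(train = csp_features(model, train_ep),
                test = csp_features(model, test_ep)))
  }
  pairs <- utils::combn(classes, 2L)
  tr_vals <- list(); te_vals <- list(); nms <- character(0)
  for (k in seq_len(ncol(pairs))) {
    idx <- train_ep$labels %in% pairs[, k]
    model <- fit_csp(subset_trials(train_ep, idx), n_components,
                     regularization)
    ftr <- csp_features(model, train_ep)
    fte <- csp_features(model, test_ep)
    tag <- sprintf("_p%d%d", pairs[1L, k], pairs[2L, k])
    tr_vals[[k]] <- ftr$values; te_vals[[k]] <- fte$values
    nms <- c(nms, paste0(ftr$feature_names, tag))
  }
  list(train = feature_matrix(do.call(cbind, tr_vals), train_ep$labels, nms),
       test = feature_matrix(do.call(cbind, te_vals), test_ep$labels, nms))
}

# classifier with the config's fixed hyperparameters (used for band
# selection and for the untuned svm/twsvm/lstwsvm methods)
fixed_classifier <- function(x, y, config) {
  classwise_factory(config$base,
                    c(c1 = config$costs[1L], c2 = config$costs[2L],
                      gamma = config$gamma),
                    config$kernel_family)(x, y)
}

# binary or one-vs-one trainer for a parameter vector
classwise_factory <- function(base, params, kernel_family) {
  kern <- switch(kernel_family,
                 linear = kernel_spec("linear"),
                 rbf = kernel_spec("rbf", gamma = params[["gamma"]]),
                 polynomial = kernel_spec("polynomial"))
  train_binary <- function(x, yy)
    switch(base,
           lstwsvm = train_lstwsvm(x, yy, params[["c1"]], params[["c2"]], kern),
           twsvm = train_twsvm(x, yy, params[["c1"]], params[["c2"]], kern),
           svm = train_svm(x, yy, params[["c1"]], kern))
  function(x, y) {
    u <- sort(unique(y))
    if (length(u) == 2L && identical(as.numeric(u), c(-1, 1)))
      train_binary(x, y)
    else if (length(u) == 2L)
      structure(list(model = train_binary(x, ifelse(y == u[1L], 1, -1)),
                     classes = u), class = "RelabeledModel")
    else
      train_multiclass(x, y, base, c(params[["c1"]], params[["c2"]]), kern)
  }
}

#' @export
predict.RelabeledModel <- function(object, newdata, ...) {
  ifelse(predict(object$model, newdata) == 1L,
         object$classes[1L], object$classes[2L])
}
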