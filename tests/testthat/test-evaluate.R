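test_that("summary statistics have the closed-form values", {
  s <- summarize_accuracies(c(80, 80, 80))
  expect_equal(s$mean, 80)
  expect_equal(s$sd, 0)
  expect_equal(s$se, 0)
  s2 <- summarize_accuracies(c(70, 90))
  expect_equal(s2$mean, 80)
  expect_equal(s2$sd, sqrt(200), tolerance = 1e-12)
  expect_equal(s2$se, 10)
  expect_error(summarize_accuracies(numeric(0)), "empty")
})

test_that("the bundled reference table reproduces its printed summary rows", {
  tab <- reference_accuracies()
  expect_equal(dim(tab), c(10L, 5L))
  means <- vapply(tab[, -1], function(col) summarize_accuracies(col)$mean,
                  numeric(1))
  expect_equal(round(unname(means), 2), c(76.47, 72.21, 73.44, 71.21))
})

test_that("LDA separates blobs, sits at the symmetric midpoint, and is chance on noise", {
  set.seed(1)
  x <- rbind(matrix(rnorm(200, 2), 100), matrix(rnorm(200, -2), 100))
  y <- rep(c(1, 2), each = 100)
  expect_gte(baseline_lda(feature_matrix(x, y), folds = 10, seed = 1), 98)
  # 1-D symmetric classes at +-1: decision boundary within |0.05| of 0
  set.seed(3)
  x1 <- matrix(c(rnorm(500, 1), rnorm(500, -1)), ncol = 1)
  m1 <- fit_lda(x1, rep(c(1, 2), each = 500))
  g <- seq(-0.5, 0.5, by = 0.001)
  pred <- predict(m1, matrix(g, ncol = 1))
  boundary <- g[max(which(pred == 2))]
  expect_lt(abs(boundary), 0.05)
  # shuffled labels stay at chance
  set.seed(3)
  acc <- baseline_lda(feature_matrix(x, sample(y)), folds = 10, seed = 1)
  expect_lt(abs(acc - 50), 100 * 1.96 * sqrt(0.25 / 200))
})

test_that("LDA agrees with the MASS reference on well-posed data", {
  set.seed(4)
  x <- rbind(matrix(rnorm(120, 1.5), 60), matrix(rnorm(120, -1.5), 60))
  y <- rep(c(1, 2), each = 60)
  ours <- predict(fit_lda(x, y), x)
  ref <- as.integer(predict(MASS::lda(x, grouping = y), x)$class)
  expect_equal(as.integer(ours), ref)
})

test_that("PNN has the stated bandwidth limits and separates blobs", {
  set.seed(5)
  x <- rbind(matrix(rnorm(200, 2), 100), matrix(rnorm(200, -2), 100))
  y <- rep(c(1, 2), each = 100)
  expect_gte(baseline_pnn(feature_matrix(x, y), bandwidth = 1,
                          folds = 10, seed = 1), 95)
  # sigma -> 0: memorization of the training set
  expect_equal(mean(predict(fit_pnn(x, y, 1e-4), x) == y), 1)
  # sigma -> Inf with frequency priors: majority class everywhere
  xu <- rbind(matrix(rnorm(60, 2), 30), matrix(rnorm(200, -2), 100))
  yu <- rep(c(1, 2), c(30, 100))
  mp <- fit_pnn(xu, yu, 1e4, priors = "proportional")
  expect_true(all(predict(mp, x) == 2))
  expect_error(fit_pnn(x, y, 0), "positive")
})

test_that("the full pipeline recognizes a strong-ERD subject and reruns identically", {
  ep <- generate_subject(sim_config(erd_depth = 0.8, seed = 31), 1)
  pc <- fast_pipeline_config(seed = 77)
  acc <- run_pipeline(ep, pc)
  expect_gte(as.numeric(acc), 90)
  sel <- attr(acc, "selected_bands")
  expect_length(sel, 5L)
  # the modal selected band overlaps the subject's true band
  sb <- attr(ep, "subject_band")
  modal <- as.integer(names(which.max(table(sel))))
  band <- bank9()[[modal]]
  expect_true(band[1] < sb[2] && band[2] > sb[1])
  acc2 <- run_pipeline(ep, pc)
  expect_identical(as.numeric(acc), as.numeric(acc2))
  expect_identical(attr(acc, "tuned_params"), attr(acc2, "tuned_params"))
})

test_that("pipeline errors are tagged with their stage and inputs validated", {
  ep <- generate_subject(sim_config(n_trials_per_class = 10, seed = 1), 1)
  expect_error(run_pipeline(ep, fast_pipeline_config(), method = "nope"),
               "unknown method")
  one <- subset_trials(ep, ep$labels == 1)
  expect_error(run_pipeline(one, fast_pipeline_config()), "2 classes")
  lofs <- epoch_set(ep$data[, , 1:100, drop = FALSE], ep$labels, 8)
  expect_error(run_pipeline(lofs, fast_pipeline_config()), "Nyquist")
})

test_that("training artifacts ignore held-out labels (information-flow audit)", {
  ep <- generate_subject(sim_config(n_trials_per_class = 30,
                                    n_channels = 6, seed = 13), 1)
  pc <- fast_pipeline_config(seed = 5)
  spec <- filter_bank_spec(pc$bands, pc$filter_order)
  band_sets <- apply_filter_bank(ep, spec)
  assign <- eegtwin:::stratified_folds(ep$labels, pc$outer_folds, pc$seed)
  tr <- assign != 1L
  res_clean <- eegtwin:::pipeline_fold(band_sets, tr, pc,
                                       "pso-ls-twin-svm", 1L)
  # poison the held-out labels: every training artifact must be identical
  poisoned <- lapply(band_sets, function(b) {
    b$labels[!tr] <- rev(b$labels[!tr]); b
  })
  res_pois <- eegtwin:::pipeline_fold(poisoned, tr, pc,
                                      "pso-ls-twin-svm", 1L)
  expect_identical(res_clean$band, res_pois$band)
  expect_identical(res_clean$params, res_pois$params)
  expect_identical(res_clean$pred, res_pois$pred)
})

test_that("multi-method reports share splits and mirror the table layout", {
  subjects <- lapply(1:3, function(s)
    generate_subject(sim_config(n_trials_per_class = 20, n_channels = 4,
                                erd_depth = 0.5 + 0.1 * s, seed = s), 1))
  pc <- pipeline_config(bands = list(c(6, 10), c(8, 12), c(16, 20)),
                        kernel_family = "linear", outer_folds = 4L,
                        selection_folds = 3L, seed = 9)
  rep1 <- compare_methods(subjects, c("lstwsvm", "lda", "pnn"), pc)
  expect_equal(dim(rep1$accuracy), c(3L, 3L))
  expect_equal(unname(rep1$mean),
               unname(colMeans(rep1$accuracy)), tolerance = 1e-9)
  expect_equal(unname(rep1$se), unname(rep1$sd / sqrt(3)), tolerance = 1e-12)
  # regeneration from the config snapshot is bit-identical
  rep2 <- compare_methods(subjects, c("lstwsvm", "lda", "pnn"),
                          rep1$config_snapshot)
  expect_identical(rep1$accuracy, rep2$accuracy)
  expect_error(compare_methods(subjects, "bogus", pc), "unknown method")
  expect_error(compare_methods(list(), "lda", pc), "at least one subject")
  # single subject, single method: 1x1 matrix, mean equals the cell
  r1 <- compare_methods(subjects[1], "lda", pc)
  expect_equal(dim(r1$accuracy), c(1L, 1L))
  expect_equal(unname(r1$mean), unname(r1$accuracy[1, 1]))
  # report serialization
  path <- tempfile(fileext = ".tsv")
  cpath <- tempfile(fileext = ".yaml")
  write_report(rep1, path, cpath)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 6L)        # 3 subjects + Mean + SD + SE
  cfg_back <- read_pipeline_config(cpath)
  expect_equal(cfg_back$bands, pc$bands)
  expect_equal(cfg_back$seed, pc$seed)
  unlink(c(path, cpath))
})

test_that("pipeline configs round-trip through YAML and JSON", {
  pc <- fast_pipeline_config(seed = 3, n_components = 6L)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_pipeline_config(pc, path)
    back <- read_pipeline_config(path)
    expect_equal(back, pc)
    unlink(path)
  }
})
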