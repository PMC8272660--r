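# shared fixtures, built in code at test time

# two Gaussian blobs in p dimensions, labels +1 / -1
make_blobs <- function(n_per_class = 25, p = 2, sep = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, sep / 2), n_per_class, p),
             matrix(rnorm(n_per_class * p, -sep / 2), n_per_class, p))
  list(x = x, y = rep(c(1, -1), each = n_per_class))
}

# two thin horizontal clouds on y = 0 and y = 2
make_parallel_clouds <- function(n = 30, seed = 1) {
  set.seed(seed)
  x <- rbind(cbind(runif(n, -2, 2), rnorm(n, 0, 0.05)),
             cbind(runif(n, -2, 2), rnorm(n, 2, 0.05)))
  list(x = x, y = rep(c(1, -1), each = n))
}

# two elongated orthogonal clouds through the origin ("cross" data)
make_cross <- function(n = 100, seed = 3) {
  set.seed(seed)
  x <- rbind(cbind(runif(n, -3, 3), 0.1 * rnorm(n)),
             cbind(0.1 * rnorm(n), runif(n, -3, 3)))
  list(x = x, y = rep(c(1, -1), each = n))
}

# small epoch set of white noise
make_noise_epochs <- function(nt = 6, nc = 3, ns = 400, fs = 250, seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(nt * nc * ns), c(nt, nc, ns)),
            rep_len(1:2, nt), fs)
}

# epochs whose channel variances differ by class: class 1 has sd `ratio`
# on channel 1, class 2 has sd `ratio` on channel 2
make_variance_epochs <- function(n_per_class = 100, nc = 4, ns = 200,
                                 ratio = sqrt(10), seed = 1) {
  set.seed(seed)
  nt <- 2 * n_per_class
  d <- array(rnorm(nt * nc * ns), c(nt, nc, ns))
  labels <- rep(c(1, 2), each = n_per_class)
  d[labels == 1, 1, ] <- d[labels == 1, 1, ] * ratio
  d[labels == 2, 2, ] <- d[labels == 2, 2, ] * ratio
  epoch_set(d, labels, 100)
}

# coarse 9-band bank (4-8, 8-12, ..., 36-40) used by the heavier harnesses
bank9 <- function() eegtwin:::default_bands(4, 40, 4, 4)

fast_pipeline_config <- function(seed = 1L, ...) {
  pipeline_config(bands = bank9(), kernel_family = "linear",
                  optimizer = list(algorithm = "pso",
                                   max_iterations = 10L, population = 8L),
                  outer_folds = 5L, seed = as.integer(seed), ...)
}

# minimal EDF writer (16-bit little-endian) used to exercise read_edf
write_test_edf <- function(path, data, fs, labels = NULL) {
  ns <- nrow(data)            # signals
  n <- ncol(data)             # samples, one record of n/fs seconds
  if (is.null(labels)) labels <- paste0("C", seq_len(ns))
  pmin_ <- apply(data, 1, min) - 1e-6
  pmax_ <- apply(data, 1, max) + 1e-6
  dmin <- -32768; dmax <- 32767
  pad <- function(s, w) formatC(s, width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("test patient", 80), pad("test rec", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(as.character(256 * (1 + ns)), 8), pad("", 44),
                pad("1", 8), pad(format(n / fs), 8),
                pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(paste0(sapply(labels, pad, 16), collapse = ""),
              paste0(rep(pad("", 80), ns), collapse = ""),
              paste0(rep(pad("uV", 8), ns), collapse = ""),
              paste0(sapply(formatC(pmin_, digits = 5, format = "g"), pad, 8),
                     collapse = ""),
              paste0(sapply(formatC(pmax_, digits = 5, format = "g"), pad, 8),
                     collapse = ""),
              paste0(rep(pad(as.character(dmin), 8), ns), collapse = ""),
              paste0(rep(pad(as.character(dmax), 8), ns), collapse = ""),
              paste0(rep(pad("", 80), ns), collapse = ""),
              paste0(rep(pad(as.character(n), 8), ns), collapse = ""),
              paste0(rep(pad("", 32), ns), collapse = ""))
  for (f in fields) writeChar(f, con, eos = NULL)
  for (s in seq_len(ns)) {
    dig <- round(dmin + (data[s, ] - pmin_[s]) /
                   (pmax_[s] - pmin_[s]) * (dmax - dmin))
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}
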