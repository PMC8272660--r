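#' Band-pass filter bank specification
#'
#' Defines the ordered set of pass-bands used to decompose epochs into
#' rhythm signals. The default bank covers 4-40 Hz in 4-Hz-wide bands with
#' 2 Hz overlap (4-8, 6-10, ..., 36-40), which spans the mu and beta ranges
#' and gives the adaptive band-selection stage a grid to search.
#'
#' @param bands list of length-2 numeric vectors `(low, high)` in Hz, or a
#'   2-column matrix. Each band must satisfy `0 < low < high`.
#' @param filter_order overall IIR filter order (even; default 4).
#' @return A `FilterBankSpec` object.
#' @export
filter_bank_spec <- function(bands = default_bands(), filter_order = 4L) {
  if (is.matrix(bands)) bands <- split(bands, row(bands))
  bands <- lapply(bands, as.numeric)
  if (length(bands) == 0L) stop("filter bank needs at least one band")
  for (b in bands) {
    if (length(b) != 2L || b[1L] <= 0 || b[1L] >= b[2L])
      stop("invalid band (", paste(b, collapse = ", "),
           "): need 0 < low < high")
  }
  if (filter_order < 2L || filter_order %% 2L != 0L)
    stop("`filter_order` must be a positive even integer")
  structure(list(bands = bands, filter_order = as.integer(filter_order)),
            class = "FilterBankSpec")
}

default_bands <- function(low = 4, high = 40, width = 4, step = 2) {
  starts <- seq(low, high - width, by = step)
  lapply(starts, function(s) c(s, s + width))
}

# Butterworth band-pass design. signal::butter(n) with a band edge pair
# yields a filter of polynomial order 2n, so an overall order-4 band-pass
# uses n = 2.
design_bandpass <- function(band, fs, order = 4L) {
  bf <- signal::butter(order / 2L, band / (fs / 2), type = "pass")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# single IIR pass with zero initial conditions: moving-average part by
# convolution, autoregressive part by the recursive filter (both C level)
iir_apply <- function(bf, x) {
  nb <- length(bf$b)
  v <- stats::filter(c(rep(0, nb - 1L), x), bf$b, method = "convolution",
                     sides = 1L)
  v <- v[nb:length(v)]
  if (length(bf$a) > 1L)
    v <- stats::filter(v, -bf$a[-1L], method = "recursive")
  as.numeric(v)
}

# batch variant: X holds one series per row; the time recursion is the
# only loop, everything else is vectorized across series
iir_apply_rows <- function(bf, X) {
  b <- bf$b; a <- bf$a
  n <- ncol(X)
  V <- b[1L] * X
  if (length(b) > 1L)
    for (j in 2:length(b))
      V[, j:n] <- V[, j:n] + b[j] * X[, 1:(n - j + 1L), drop = FALSE]
  if (length(a) > 1L) {
    p <- length(a) - 1L
    for (t in 2:n) {
      acc <- V[, t]
      for (j in seq_len(min(p, t - 1L)))
        acc <- acc - a[j + 1L] * V[, t - j]
      V[, t] <- acc
    }
  }
  V
}

# Zero-phase band-pass of one signal vector: reflect padding of
# 3 x (filter length - 1) samples absorbs the forward and backward warm-up
# transients.
bandpass_vector <- function(x, band, fs, order = 4L, bf = NULL) {
  if (is.null(bf)) bf <- design_bandpass(band, fs, order)
  pad <- 3L * (length(bf$b) - 1L)
  n <- length(x)
  x <- x - mean(x)
  if (n <= pad)
    stop("epoch of ", n, " samples is shorter than the filter warm-up of ",
         pad, " samples; use longer epochs or a lower filter order")
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- c(head_pad, x, tail_pad)
  y <- iir_apply(bf, y)
  y <- rev(iir_apply(bf, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase band-pass filtering of epochs
#'
#' Applies a Butterworth band-pass forward and backward (zero phase) to
#' every trial and channel independently, and tags the output with the band.
#'
#' @param epochs an [epoch_set()].
#' @param band length-2 numeric `(low, high)` in Hz; must lie strictly
#'   inside `(0, Nyquist)`.
#' @param order overall filter order (even; default 4).
#' @return An `EpochSet` of the same shape with `band` set.
#' @examples
#' ep <- epoch_set(array(rnorm(600), c(2, 1, 300)), c(1, 2), 250)
#' mu <- bandpass(ep, c(8, 12))
#' @export
bandpass <- function(epochs, band, order = 4L) {
  stopifnot(inherits(epochs, "EpochSet"))
  band <- validate_band(band, epochs$sampling_rate)
  bf <- design_bandpass(band, epochs$sampling_rate, order)
  pad <- 3L * (length(bf$b) - 1L)
  n <- n_samples(epochs)
  if (n <= pad)
    stop("epoch of ", n, " samples is shorter than the filter warm-up of ",
         pad, " samples; use longer epochs or a lower filter order")
  nt <- n_trials(epochs); nc <- n_channels(epochs)
  # every (trial, channel) series as one row, filtered in one batch;
  # the DC offset is removed first (a band-pass has no DC response, and
  # demeaning keeps the start-up transient out of the pass band)
  X <- matrix(epochs$data, nt * nc, n)
  X <- X - rowMeans(X)
  X <- cbind(2 * X[, rep(1L, pad), drop = FALSE] -
               X[, (pad + 1L):2L, drop = FALSE],
             X,
             2 * X[, rep(n, pad), drop = FALSE] -
               X[, (n - 1L):(n - pad), drop = FALSE])
  X <- iir_apply_rows(bf, X)
  X <- iir_apply_rows(bf, X[, ncol(X):1L, drop = FALSE])
  X <- X[, ncol(X):1L, drop = FALSE][, (pad + 1L):(pad + n), drop = FALSE]
  epoch_set(array(X, dim(epochs$data)), epochs$labels,
            epochs$sampling_rate, epochs$channel_names, band = band)
}

#' Apply a filter bank to epochs
#'
#' @param epochs an [epoch_set()].
#' @param spec a [filter_bank_spec()].
#' @return A list of band-tagged `EpochSet` objects, one per band, all with
#'   identical trial order and labels.
#' @export
apply_filter_bank <- function(epochs, spec) {
  stopifnot(inherits(spec, "FilterBankSpec"))
  lapply(spec$bands, function(b) bandpass(epochs, b, spec$filter_order))
}

#' Adaptive reference-regression artifact removal
#'
#' Removes ocular (or other reference-measurable) artifacts by per-trial
#' least-squares regression: within each trial, every data channel is
#' regressed on the reference channel(s) and the fitted contribution is
#' subtracted. Re-estimating the mixing coefficients on every trial makes
#' the removal adaptive to slow changes in electrode coupling. Reference
#' channels are dropped from the output.
#'
#' @param epochs an [epoch_set()].
#' @param reference_channels character vector of channel names to use as
#'   artifact references (e.g. `"EOG"`).
#' @return An `EpochSet` without the reference channels.
#' @export
remove_artifacts <- function(epochs, reference_channels) {
  stopifnot(inherits(epochs, "EpochSet"))
  ref_idx <- match(reference_channels, epochs$channel_names)
  if (anyNA(ref_idx))
    stop("reference channel(s) not found: ",
         paste(reference_channels[is.na(ref_idx)], collapse = ", "))
  keep <- setdiff(seq_len(n_channels(epochs)), ref_idx)
  out <- array(NA_real_, c(n_trials(epochs), length(keep),
                           n_samples(epochs)))
  for (i in seq_len(n_trials(epochs))) {
    X <- matrix(epochs$data[i, keep, ], nrow = length(keep))
    R <- matrix(epochs$data[i, ref_idx, ], nrow = length(ref_idx))
    live <- apply(R, 1L, function(r) any(r != 0))
    if (!all(live))
      message("trial ", i, ": constant-zero reference channel(s) skipped: ",
              paste(reference_channels[!live], collapse = ", "))
    if (any(live)) {
      Rl <- R[live, , drop = FALSE]
      # B = X R' (R R')^{-1}: per-trial least-squares mixing estimate
      B <- t(solve(Rl %*% t(Rl), Rl %*% t(X)))
      X <- X - B %*% Rl
    }
    out[i, , ] <- X
  }
  epoch_set(out, epochs$labels, epochs$sampling_rate,
            epochs$channel_names[keep], epochs$band)
}
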