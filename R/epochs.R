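#' Labelled EEG epoch container
#'
#' An `EpochSet` holds a block of labelled multichannel EEG trials as a
#' 3-D numeric array (trial x channel x sample) together with the sampling
#' rate, channel names, integer class labels and an optional frequency-band
#' tag describing what filtering the data has already received.
#'
#' @param data numeric 3-D array, trial x channel x sample, nominal microvolts.
#' @param labels integer vector, one class label per trial.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_names character vector of channel identifiers; defaults to
#'   `"C1" ... "Cn"`.
#' @param band optional length-2 numeric `(low, high)` in Hz tagging the
#'   frequency band the data has been filtered to.
#' @return An object of class `EpochSet`.
#' @examples
#' x <- array(rnorm(2 * 3 * 100), c(2, 3, 100))
#' ep <- epoch_set(x, labels = c(1, 2), sampling_rate = 250)
#' n_trials(ep)
#' @export
epoch_set <- function(data, labels, sampling_rate, channel_names = NULL,
                      band = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trial x channel x sample)")
  if (!is.numeric(data)) stop("`data` must be numeric")
  if (length(labels) != dim(data)[1L])
    stop("number of labels (", length(labels),
         ") must equal number of trials (", dim(data)[1L], ")")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  if (is.null(channel_names))
    channel_names <- paste0("C", seq_len(dim(data)[2L]))
  if (length(channel_names) != dim(data)[2L])
    stop("`channel_names` length must equal the channel dimension")
  if (!is.null(band)) band <- validate_band(band, sampling_rate)
  structure(
    list(data = data, labels = as.integer(labels),
         sampling_rate = as.numeric(sampling_rate),
         channel_names = as.character(channel_names), band = band),
    class = "EpochSet")
}

validate_band <- function(band, sampling_rate) {
  if (length(band) != 2L || !is.numeric(band))
    stop("`band` must be numeric (low, high) in Hz")
  band <- as.numeric(band)
  if (band[1L] <= 0 || band[1L] >= band[2L])
    stop("invalid band: need 0 < low < high, got (",
         band[1L], ", ", band[2L], ")")
  if (band[2L] >= sampling_rate / 2)
    stop("band upper edge ", band[2L], " Hz is at or above the Nyquist ",
         "frequency ", sampling_rate / 2, " Hz")
  band
}

#' @rdname epoch_set
#' @param x an `EpochSet`.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' @rdname epoch_set
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname epoch_set
#' @export
n_samples <- function(x) dim(x$data)[3L]

#' @export
print.EpochSet <- function(x, ...) {
  cat("<EpochSet> ", n_trials(x), " trials x ", n_channels(x),
      " channels x ", n_samples(x), " samples @ ", x$sampling_rate,
      " Hz\n", sep = "")
  cat("  classes: ", paste(sprintf("%d (n=%d)", as.integer(names(tb <- table(x$labels))),
                                   as.integer(tb)), collapse = ", "), "\n", sep = "")
  if (!is.null(x$band))
    cat("  band: ", x$band[1L], "-", x$band[2L], " Hz\n", sep = "")
  invisible(x)
}

#' Subset trials of an EpochSet
#'
#' @param x an `EpochSet`.
#' @param trials integer or logical index over trials.
#' @return An `EpochSet` containing the selected trials, labels preserved.
#' @export
subset_trials <- function(x, trials) {
  epoch_set(x$data[trials, , , drop = FALSE], x$labels[trials],
            x$sampling_rate, x$channel_names, x$band)
}

#' Write / read an EpochSet as a plain-text subject directory
#'
#' The interchange format is one tab-delimited file per trial
#' (`trial_0001.tsv`, rows = channels, columns = samples), a `labels.tsv`
#' file (columns `trial`, `label`) and a `metadata.json` carrying the
#' sampling rate, channel names and optional band tag.
#'
#' @param x an `EpochSet`.
#' @param dir directory to create / read.
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` returns an
#'   `EpochSet`.
#' @export
write_epochs <- function(x, dir) {
  stopifnot(inherits(x, "EpochSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_trials(x))) {
    utils::write.table(
      x$data[i, , , drop = TRUE],
      file.path(dir, sprintf("trial_%04d.tsv", i)),
      sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(
    data.frame(trial = seq_len(n_trials(x)), label = x$labels),
    file.path(dir, "labels.tsv"), sep = "\t", row.names = FALSE)
  meta <- list(sampling_rate = x$sampling_rate,
               channel_names = x$channel_names,
               n_trials = n_trials(x), n_samples = n_samples(x))
  if (!is.null(x$band)) meta$band <- x$band
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  lab <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                           sep = "\t")
  nt <- meta$n_trials
  nc <- length(meta$channel_names)
  ns <- meta$n_samples
  dat <- array(NA_real_, c(nt, nc, ns))
  for (i in seq_len(nt)) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("trial_%04d.tsv", i)), sep = "\t"))
    dat[i, , ] <- m
  }
  epoch_set(dat, lab$label, meta$sampling_rate, meta$channel_names,
            band = meta$band)
}
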