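#' Read a European Data Format (EDF) recording
#'
#' Minimal reader for uncompressed EDF: parses the fixed-width ASCII
#' header, reads the 16-bit little-endian data records and rescales each
#' signal from digital to physical units. All signals must share one
#' sampling rate (the usual case for EEG montages).
#'
#' @param path path to an `.edf` file.
#' @return list with `data` (channel x sample matrix, physical units),
#'   `sampling_rate` (Hz), `channel_names`, `n_records`,
#'   `record_duration` (s).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                       # version
  hdr(80); hdr(80)             # patient / recording id
  hdr(8); hdr(8)               # start date / time
  hdr(8)                       # header length
  hdr(44)                      # reserved
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(width) vapply(seq_len(ns), function(i) hdr(width), "")
  labels <- field(16)
  field(80); field(8)          # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                    # prefiltering
  spr <- as.integer(field(8))  # samples per record per signal
  field(32)                    # reserved
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dat <- matrix(NA_real_, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      dat[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        phys_min[s] + gain[s] * (raw - dig_min[s])
    }
  }
  list(data = dat, sampling_rate = fs, channel_names = labels,
       n_records = n_rec, record_duration = rec_dur)
}

#' Epoch a continuous EDF recording into an EpochSet
#'
#' @param edf result of [read_edf()].
#' @param onsets epoch start times in seconds.
#' @param duration epoch length in seconds.
#' @param labels integer class label per epoch.
#' @return An [epoch_set()].
#' @export
edf_to_epochs <- function(edf, onsets, duration, labels) {
  if (length(onsets) != length(labels))
    stop("need one label per onset")
  fs <- edf$sampling_rate
  ns <- round(duration * fs)
  total <- ncol(edf$data)
  dat <- array(NA_real_, c(length(onsets), nrow(edf$data), ns))
  for (i in seq_along(onsets)) {
    start <- round(onsets[i] * fs) + 1L
    if (start + ns - 1L > total)
      stop("epoch ", i, " extends past the end of the recording")
    dat[i, , ] <- edf$data[, start:(start + ns - 1L)]
  }
  epoch_set(dat, labels, fs, edf$channel_names)
}
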