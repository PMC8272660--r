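#' Configuration for the synthetic motor-imagery EEG generator
#'
#' The generator emulates the statistical structure a motor-imagery decoder
#' relies on: a band-limited sensorimotor rhythm whose power drops on
#' class-specific channels during imagery (event-related desynchronization,
#' ERD), superimposed on 1/f^a background noise, with the informative band
#' shifted per subject to mimic inter-individual rhythm variability, and
#' optional ocular-artifact contamination.
#'
#' Channels are assigned to one designated group per class, round-robin:
#' channel j belongs to group `((j - 1) mod n_classes) + 1`. On trials of
#' class k the rhythm power on group-k channels is attenuated by the factor
#' `1 - erd_depth`.
#'
#' @param n_subjects number of subjects the study simulates.
#' @param n_trials_per_class trials per class per subject.
#' @param n_classes number of imagery classes (>= 2).
#' @param n_channels number of EEG channels.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_length epoch duration in seconds.
#' @param informative_band nominal `(low, high)` Hz of the class-informative
#'   rhythm (default mu, 8-12 Hz).
#' @param band_jitter half-width in Hz of the uniform per-subject shift of
#'   the informative band.
#' @param erd_depth fraction in `[0, 1]`: relative attenuation of
#'   informative-band power on a class's designated channels.
#' @param noise_exponent spectral exponent `a` of the 1/f^a background.
#' @param artifact_rate fraction of trials receiving an ocular artifact.
#' @param artifact_gain amplitude multiplier for injected artifacts.
#' @param seed integer master seed; same seed + same config gives
#'   bit-identical output.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(n_subjects = 10L, n_trials_per_class = 100L,
                       n_classes = 2L, n_channels = 8L,
                       sampling_rate = 250, epoch_length = 2,
                       informative_band = c(8, 12), band_jitter = 2,
                       erd_depth = 0.8, noise_exponent = 1,
                       artifact_rate = 0, artifact_gain = 1, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials_per_class = as.integer(n_trials_per_class),
              n_classes = as.integer(n_classes),
              n_channels = as.integer(n_channels),
              sampling_rate = sampling_rate, epoch_length = epoch_length,
              informative_band = as.numeric(informative_band),
              band_jitter = band_jitter, erd_depth = erd_depth,
              noise_exponent = noise_exponent,
              artifact_rate = artifact_rate, artifact_gain = artifact_gain,
              seed = as.integer(seed))
  if (cfg$n_classes < 2L) stop("need at least 2 classes")
  if (cfg$erd_depth < 0 || cfg$erd_depth > 1)
    stop("`erd_depth` must lie in [0, 1]")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1)
    stop("`artifact_rate` must lie in [0, 1]")
  validate_band(cfg$informative_band, cfg$sampling_rate)
  if (cfg$informative_band[2L] + cfg$band_jitter >= cfg$sampling_rate / 2)
    stop("informative band plus jitter reaches the Nyquist frequency")
  structure(cfg, class = c("SimulationConfig", "list"))
}

# amplitude constants (nominal microvolts); rhythm dominates the background
# inside the informative band so the ERD power ratio is measurable
BG_RMS <- 5
RHYTHM_RMS <- 10
RHYTHM_AMP_JITTER <- 0.1  # lognormal sd of per-trial rhythm amplitude
EOG_AMP <- 100
EOG_WIDTH <- 0.15         # s; Gaussian pulse, spectral content < 4 Hz
EOG_NOISE_RMS <- 1

subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 1000003 + subject_index * 7919) %%
               2147483647)
}

# 1/f^a noise by spectral synthesis: Fourier amplitudes proportional to
# f^(-a/2) with random phases, so the PSD log-log slope is exactly -a.
one_over_f_noise <- function(n, exponent, rms) {
  nf <- floor(n / 2)
  amp <- (seq_len(nf))^(-exponent / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 1L)] <- Conj(spec)
  if (n %% 2L == 0L) full[nf + 1L] <- complex(modulus = amp[nf], argument = 0)
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Generate one subject's labelled epochs
#'
#' @param config a [sim_config()].
#' @param subject_index which subject (1-based); determines the subject's
#'   informative-band shift and random stream.
#' @return An [epoch_set()] with `n_trials_per_class * n_classes` trials in
#'   interleaved class order. The realized per-subject informative band is
#'   attached as attribute `"subject_band"`.
#' @export
generate_subject <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(subject_seed(config$seed, subject_index))
  ns <- round(config$epoch_length * config$sampling_rate)
  nc <- config$n_channels
  nt <- config$n_trials_per_class * config$n_classes
  shift <- stats::runif(1L, -config$band_jitter, config$band_jitter)
  band <- config$informative_band + shift
  group <- ((seq_len(nc) - 1L) %% config$n_classes) + 1L
  bf <- design_bandpass(band, config$sampling_rate)
  labels <- rep(seq_len(config$n_classes), times = config$n_trials_per_class)
  dat <- array(NA_real_, c(nt, nc, ns))
  for (i in seq_len(nt)) {
    for (j in seq_len(nc)) {
      bg <- one_over_f_noise(ns, config$noise_exponent, BG_RMS)
      rhythm <- bandpass_vector(stats::rnorm(ns), band,
                                config$sampling_rate, bf = bf)
      amp <- RHYTHM_RMS * exp(stats::rnorm(1L, 0, RHYTHM_AMP_JITTER))
      if (group[j] == labels[i]) amp <- amp * sqrt(1 - config$erd_depth)
      rhythm <- rhythm * amp / sqrt(mean(rhythm^2))
      dat[i, j, ] <- bg + rhythm
    }
  }
  ep <- epoch_set(dat, labels, config$sampling_rate)
  if (config$artifact_rate > 0 && config$artifact_gain != 0) {
    inj <- inject_eog_artifact(ep, config$artifact_rate,
                               config$artifact_gain,
                               seed = subject_seed(config$seed,
                                                   subject_index) + 1L)
    ep <- inj$epochs
  }
  attr(ep, "subject_band") <- band
  ep
}

#' Inject ocular (EOG) artifacts into epochs
#'
#' A fraction of trials receives a high-amplitude low-frequency (< 4 Hz)
#' Gaussian blink transient, mixed into the frontal-designated channels
#' (the first quarter of the montage) with linearly decaying per-channel
#' weights. An `"EOG"` reference channel carrying the artifact waveform
#' (plus small measurement noise) is appended so regression-based removal
#' can be applied and scored.
#'
#' @param epochs an [epoch_set()].
#' @param rate fraction of trials to contaminate, in `[0, 1]`.
#' @param gain amplitude multiplier.
#' @param seed integer seed.
#' @return A list with `epochs` (contaminated set, `"EOG"` channel
#'   appended), `reference` (trial x sample matrix of injected waveforms,
#'   zero rows for clean trials), and `contaminated` (trial indices). With
#'   `rate = 0` or `gain = 0` the input is returned unchanged and the
#'   reference is empty.
#' @export
inject_eog_artifact <- function(epochs, rate, gain, seed = 1L) {
  stopifnot(inherits(epochs, "EpochSet"))
  if (rate < 0 || rate > 1) stop("`rate` must lie in [0, 1]")
  if (rate == 0 || gain == 0)
    return(list(epochs = epochs,
                reference = matrix(0, 0, n_samples(epochs)),
                contaminated = integer(0)))
  set.seed(as.integer(seed))
  nt <- n_trials(epochs); nc <- n_channels(epochs); ns <- n_samples(epochs)
  fs <- epochs$sampling_rate
  n_front <- max(1L, ceiling(nc / 4))
  w <- seq(1, 0.4, length.out = n_front)
  n_bad <- round(rate * nt)
  bad <- sort(sample.int(nt, n_bad))
  tt <- (seq_len(ns) - 1) / fs
  ref <- matrix(0, nt, ns)
  dat <- epochs$data
  eog <- matrix(0, nt, ns)
  for (i in seq_len(nt)) {
    eog[i, ] <- one_over_f_noise(ns, 1, EOG_NOISE_RMS)
    if (i %in% bad) {
      t0 <- stats::runif(1L, 0.2, 0.8) * max(tt)
      pulse <- EOG_AMP * gain * exp(-(tt - t0)^2 / (2 * EOG_WIDTH^2))
      ref[i, ] <- pulse
      for (j in seq_len(n_front))
        dat[i, j, ] <- dat[i, j, ] + w[j] * pulse
      eog[i, ] <- eog[i, ] + pulse
    }
  }
  out <- array(NA_real_, c(nt, nc + 1L, ns))
  out[, seq_len(nc), ] <- dat
  out[, nc + 1L, ] <- eog
  ep <- epoch_set(out, epochs$labels, fs,
                  c(epochs$channel_names, "EOG"), epochs$band)
  list(epochs = ep, reference = ref, contaminated = bad)
}
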