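# Component-stable sub-seeds: adding a component never perturbs the noise
# stream of another.  Kept below 2^31 (R integers are 32-bit).
component_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483647L)

raised_cosine <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# 1/f ("pink") noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n, sd = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric fold
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

# EOG-like blink train: raised-cosine pulses of 200-400 ms at random times.
eog_blinks <- function(n, fs, rate_hz = 0.2, amplitude = 1) {
  x <- numeric(n)
  n_blinks <- stats::rpois(1, rate_hz * n / fs)
  if (n_blinks == 0) return(x)
  onsets <- sort(sample.int(n, n_blinks))
  for (o in onsets) {
    dur <- round(stats::runif(1, 0.2, 0.4) * fs)
    idx <- o:min(o + dur - 1L, n)
    x[idx] <- x[idx] + amplitude * raised_cosine(dur)[seq_along(idx)]
  }
  x
}

#' Specification of a synthetic multichannel EEG record
#'
#' Describes the generative components summed by [gen_ssvep()]:
#' common-mode interferences broadcast across channels with per-channel
#' gains (power-line tone, EOG-like blinks, slow drift, pink noise),
#' spatially localized narrowband components (fundamental plus harmonics on
#' named channels), independent channel noise, and optional rare
#' high-amplitude single-electrode artifact bursts (multiplicative gain over
#' a time window).
#'
#' @param montage an [electrode_montage]; its electrodes define the
#'   channels.
#' @param fs sampling rate in Hz.
#' @param duration record length in seconds.
#' @param common list of common components; each a list with `type` in
#'   `"sine"`, `"drift"`, `"eog_blink"`, `"pink_noise"`, `amplitude` (uV),
#'   `freq` (Hz, for `sine`), and optional `gains` (named per-channel
#'   multipliers, default 1 everywhere).
#' @param local list of localized components; each a list with `channel`,
#'   `freq` (Hz), `amplitude` (uV), optional `harmonics` (vector of relative
#'   harmonic amplitudes, first entry = fundamental) and `phase` (radians).
#' @param noise_sigma independent Gaussian noise SD per channel (uV; scalar
#'   or named vector).
#' @param bursts list of artifact bursts; each a list with `channel`,
#'   `onset_s`, `duration_s`, `gain` (channel multiplied by `gain` during
#'   the burst).
#' @param seed master seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(montage, fs = 250, duration = 5,
                           common = list(), local = list(),
                           noise_sigma = 1, bursts = list(), seed = 1L) {
  stopifnot(inherits(montage, "electrode_montage"), fs > 0, duration > 0)
  for (lc in local) {
    nh <- length(lc$harmonics %||% 1)
    if (lc$freq * nh >= fs / 2)
      stop("local component at ", lc$freq, " Hz with ", nh,
           " harmonics exceeds the Nyquist frequency")
    if ((lc$amplitude %||% 1) < 0) stop("amplitudes must be nonnegative")
  }
  for (cc in common) if ((cc$amplitude %||% 1) < 0)
    stop("amplitudes must be nonnegative")
  structure(list(montage = montage, fs = fs, duration = duration,
                 common = common, local = local, noise_sigma = noise_sigma,
                 bursts = bursts, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic SSVEP-like record
#'
#' Sums the components of a [synthetic_spec]: every common component is one
#' waveform broadcast to all channels scaled by its per-channel gains;
#' local components are sinusoids (plus harmonics) on single channels;
#' channel noise is independent Gaussian; artifact bursts multiply the
#' affected channel by their gain over their time window.  Deterministic
#' per seed, with per-component sub-seeds so adding a component does not
#' perturb the others.
#'
#' @param spec a [synthetic_spec].
#' @return List of class `synthetic_record`: `record` (samples x channels
#'   matrix, columns = montage electrodes), `fs`, `truth` (data.frame of
#'   local components: channel, freq, amplitude), and `spec`.
#' @export
gen_ssvep <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  chans <- spec$montage$electrodes
  n <- round(spec$fs * spec$duration)
  t <- seq_len(n) / spec$fs
  rec <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  comp_i <- 0L
  for (cc in spec$common) {
    comp_i <- comp_i + 1L
    set.seed(component_seed(spec$seed, comp_i))
    wave <- switch(cc$type,
      sine = cc$amplitude * sin(2 * pi * cc$freq * t +
                                  stats::runif(1, 0, 2 * pi)),
      pink_noise = pink_noise(n, sd = cc$amplitude),
      drift = {
        # slow drift: heavily smoothed random walk, SD-normalized
        k <- max(3L, round(spec$fs))
        rw <- cumsum(stats::rnorm(n + k))
        sm <- stats::filter(rw, rep(1 / k, k), sides = 1)[-seq_len(k)]
        sm <- sm - mean(sm)
        cc$amplitude * sm / max(stats::sd(sm), 1e-12)
      },
      eog_blink = eog_blinks(n, spec$fs, amplitude = cc$amplitude),
      stop("unknown common component type: ", cc$type))
    gains <- rep(1, length(chans)); names(gains) <- chans
    if (!is.null(cc$gains)) gains[names(cc$gains)] <- unlist(cc$gains)
    rec <- rec + outer(wave, gains)
  }
  truth <- data.frame(channel = character(), freq = numeric(),
                      amplitude = numeric(), stringsAsFactors = FALSE)
  for (lc in spec$local) {
    comp_i <- comp_i + 1L
    set.seed(component_seed(spec$seed, comp_i))
    harm <- lc$harmonics %||% 1
    phase <- lc$phase %||% stats::runif(1, 0, 2 * pi)
    for (k in seq_along(harm)) {
      amp <- lc$amplitude * harm[k]
      if (amp <= 0) next
      rec[, lc$channel] <- rec[, lc$channel] +
        amp * sin(2 * pi * k * lc$freq * t + phase * k)
      truth <- rbind(truth, data.frame(channel = lc$channel,
                                       freq = k * lc$freq,
                                       amplitude = amp))
    }
  }
  sig <- spec$noise_sigma
  if (length(sig) == 1L) sig <- stats::setNames(rep(sig, length(chans)),
                                                chans)
  for (ch in chans) {
    comp_i <- comp_i + 1L
    if (sig[[ch]] > 0) {
      set.seed(component_seed(spec$seed, comp_i))
      rec[, ch] <- rec[, ch] + stats::rnorm(n, sd = sig[[ch]])
    }
  }
  for (b in spec$bursts) {
    idx <- seq.int(max(1L, round(b$onset_s * spec$fs)),
                   min(n, round((b$onset_s + b$duration_s) * spec$fs)))
    rec[idx, b$channel] <- rec[idx, b$channel] * b$gain
  }
  structure(list(record = rec, fs = spec$fs, truth = truth, spec = spec),
            class = "synthetic_record")
}

#' Generate labeled gait-planning / rest epochs
#'
#' Emulates a cued-gait protocol at 400 Hz: planning epochs (1.5 s, the
#' interval preceding gait onset) carry a movement-related cortical
#' potential -- a negative low-frequency ramp on the central channels
#' (Cz/CP1/CP2 by default) -- plus an attenuated mu rhythm
#' (event-related desynchronization); rest epochs (2.0 s) are stationary.
#' Both classes share an EOG-like common-mode artifact and power-line tone,
#' and all channels carry independent Gaussian noise.  Epochs are assigned
#' to sessions in order, emulating session-wise recording blocks.
#'
#' Defaults mirror the protocol scale of a six-session recording: 24
#' planning and 36 rest epochs over 6 sessions.  Setting
#' `mrcp_amplitude = 0` and `mu_attenuation = 0` yields the null
#' configuration in which the two classes are statistically identical.
#'
#' @param montage an [electrode_montage]; effect channels default to the
#'   montage's targets.
#' @param fs sampling rate (default 400 Hz).
#' @param n_planning,n_rest epoch counts (defaults 24 and 36).
#' @param sessions number of recording sessions (default 6).
#' @param planning_s,rest_s epoch durations in seconds (1.5 and 2.0).
#' @param mrcp_amplitude terminal amplitude of the pre-movement ramp in uV
#'   (default 6).
#' @param mu_amplitude resting mu-rhythm (10 Hz) amplitude in uV (default 4).
#' @param mu_attenuation fractional mu-power reduction during planning in
#'   \[0, 1\] (default 0.5).
#' @param noise_sigma channel noise SD in uV (default 5).
#' @param common_amplitude EOG-like common-mode amplitude in uV (default 20).
#' @param line_freq power-line frequency in Hz (default 60).
#' @param line_amplitude line-tone amplitude in uV (default 2).
#' @param effect_channels channels carrying the class effects.
#' @param seed master seed.
#' @return List of class `gait_epochs`: `epochs` (list of samples x channels
#'   matrices), `label` (factor `"planning"`/`"rest"`), `session` (integer),
#'   `fs`, and `truth` (the effect parameters used).
#' @export
gen_gait_epochs <- function(montage, fs = 400, n_planning = 24, n_rest = 36,
                            sessions = 6, planning_s = 1.5, rest_s = 2.0,
                            mrcp_amplitude = 6, mu_amplitude = 4,
                            mu_attenuation = 0.5, noise_sigma = 5,
                            common_amplitude = 20, line_freq = 60,
                            line_amplitude = 2,
                            effect_channels = montage$targets,
                            seed = 1L) {
  stopifnot(inherits(montage, "electrode_montage"),
            mu_attenuation >= 0, mu_attenuation <= 1)
  chans <- montage$electrodes
  labels <- c(rep("planning", n_planning), rep("rest", n_rest))
  n_ep <- length(labels)
  session <- integer(n_ep)
  session[labels == "planning"] <- rep_len(seq_len(sessions), n_planning)
  session[labels == "rest"] <- rep_len(seq_len(sessions), n_rest)
  epochs <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    set.seed(component_seed(seed, e))
    planning <- labels[e] == "planning"
    n <- round(fs * if (planning) planning_s else rest_s)
    t <- seq_len(n) / fs
    rec <- matrix(stats::rnorm(n * length(chans), sd = noise_sigma),
                  n, length(chans), dimnames = list(NULL, chans))
    # shared interference: EOG-like drift + line tone, common phase
    com <- eog_blinks(n, fs, rate_hz = 0.4, amplitude = common_amplitude) +
      pink_noise(n, sd = common_amplitude / 4) +
      line_amplitude * sin(2 * pi * line_freq * t + stats::runif(1, 0, 2 * pi))
    rec <- rec + com  # unit gain on all channels
    # mu rhythm on the central channels, attenuated during planning
    mu_amp <- mu_amplitude * if (planning) (1 - mu_attenuation) else 1
    mu_phase <- stats::runif(1, 0, 2 * pi)
    for (ch in effect_channels)
      rec[, ch] <- rec[, ch] + mu_amp * sin(2 * pi * 10 * t + mu_phase)
    # movement-related potential: negative ramp toward onset
    if (planning && mrcp_amplitude > 0) {
      ramp <- -mrcp_amplitude * (t / max(t))^2
      for (ch in effect_channels) rec[, ch] <- rec[, ch] + ramp
    }
    epochs[[e]] <- rec
  }
  structure(list(epochs = epochs, label = factor(labels),
                 session = session, fs = fs,
                 truth = list(mrcp_amplitude = mrcp_amplitude,
                              mu_amplitude = mu_amplitude,
                              mu_attenuation = mu_attenuation,
                              noise_sigma = noise_sigma,
                              common_amplitude = common_amplitude,
                              effect_channels = effect_channels),
                 seed = as.integer(seed)),
            class = "gait_epochs")
}

#' Default synthetic SSVEP demonstration spec
#'
#' Occipital montage record with a target-localized SSVEP (fundamental plus
#' two harmonics on Oz and attenuated copies on O1/O2), a shared power-line
#' tone and EOG/pink-noise common mode, and independent channel noise --
#' the stimulus/interference structure the filters are designed for.
#'
#' @param montage an [electrode_montage] (default: the bundled occipital
#'   montage).
#' @param stim_freq stimulus frequency in Hz (default 12).
#' @param stim_amplitude fundamental amplitude in uV on Oz (default 2).
#' @param duration record seconds (default 5).
#' @param fs sampling rate (default 250).
#' @param seed master seed.
#' @return A [synthetic_spec].
#' @export
ssvep_demo_spec <- function(montage = load_montage(system.file(
                              "extdata", "montage_occipital.yaml",
                              package = "adaptref")),
                            stim_freq = 12, stim_amplitude = 2,
                            duration = 5, fs = 250, seed = 1L) {
  occ_gain <- as.list(stats::setNames(
    rep(1, length(montage$electrodes)), montage$electrodes))
  synthetic_spec(
    montage, fs = fs, duration = duration,
    common = list(
      list(type = "sine", freq = 50, amplitude = 4, gains = occ_gain),
      list(type = "pink_noise", amplitude = 3),
      list(type = "eog_blink", amplitude = 15)),
    local = list(
      # SSVEP is phase-locked to the stimulus, so the occipital carriers
      # share one phase; amplitude peaks on Oz and falls off laterally
      list(channel = "Oz", freq = stim_freq, amplitude = stim_amplitude,
           harmonics = c(1, 0.4, 0.2), phase = 0.7),
      list(channel = "O1", freq = stim_freq, amplitude = 0.6 * stim_amplitude,
           harmonics = c(1, 0.4), phase = 0.7),
      list(channel = "O2", freq = stim_freq, amplitude = 0.6 * stim_amplitude,
           harmonics = c(1, 0.4), phase = 0.7),
      list(channel = "POz", freq = stim_freq,
           amplitude = 0.4 * stim_amplitude, harmonics = 1, phase = 0.7)),
    noise_sigma = 2, seed = seed)
}
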