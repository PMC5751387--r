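# Shared fixtures, all built in code.

gait_montage <- function() {
  load_montage(system.file("extdata", "montage_gait_1020.yaml",
                           package = "adaptref"))
}

occ_montage <- function() {
  load_montage(system.file("extdata", "montage_occipital.yaml",
                           package = "adaptref"))
}

# tiny montage with explicit positions and neighbor sets
toy_montage <- function() {
  electrode_montage(
    electrodes = c("A", "B", "C", "D"),
    positions = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 3)),
    neighbors_small = list(A = c("B", "C")),
    neighbors_large = list(A = c("B", "C", "D")),
    targets = "A")
}

# stationary common-mode-dominated multichannel record (the regime the
# adaptive reference filters are designed for)
common_mode_record <- function(montage, seed, n = 1250, fs = 250,
                               burst_channel = NULL, burst_gain = 50,
                               burst_onset_s = 2, burst_duration_s = 0.5) {
  bursts <- list()
  if (!is.null(burst_channel))
    bursts <- list(list(channel = burst_channel, onset_s = burst_onset_s,
                        duration_s = burst_duration_s, gain = burst_gain))
  sp <- synthetic_spec(
    montage, fs = fs, duration = n / fs,
    common = list(list(type = "pink_noise", amplitude = 10),
                  list(type = "sine", freq = 50, amplitude = 4),
                  list(type = "sine", freq = 10, amplitude = 5)),
    noise_sigma = 2, bursts = bursts, seed = seed)
  gen_ssvep(sp)
}

# independent brute-force transcription of the concordance formula
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; vx <- 0; vy <- 0
  for (k in seq_len(n)) {
    sxy <- sxy + (x[k] - mx) * (y[k] - my)
    vx <- vx + (x[k] - mx)^2
    vy <- vy + (y[k] - my)^2
  }
  2 * (sxy / n) / (vx / n + vy / n + (mx - my)^2)
}

pnm_oracle <- function(cm) {
  K <- nrow(cm)
  sapply(seq_len(K), function(i) {
    fn <- sum(cm[i, -i]); fp <- sum(cm[-i, i])
    ((cm[i, i] - fn) + (cm[i, i] - fp)) / (sum(cm[i, ]) + sum(cm[, i]))
  })
}
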