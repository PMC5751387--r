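#' Magnitude spectrum on a fixed-resolution grid
#'
#' Rectangular-window FFT of the full epoch, zero-padded so the frequency
#' grid has spacing exactly `df` (default 0.2 Hz, as required by the SSVEP
#' signal-to-noise definition, which reads magnitudes at f +/- 0.2 k Hz).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz (must be an integer multiple of `df`).
#' @param df frequency resolution in Hz.
#' @return Object of class `magnitude_spectrum`: list with `freq`
#'   (nonnegative grid) and `mag` (magnitudes).
#' @export
magnitude_spectrum <- function(x, fs, df = 0.2) {
  stopifnot(fs > 0, df > 0)
  base <- fs / df
  if (abs(base - round(base)) > 1e-9)
    stop("`fs` must be an integer multiple of `df`")
  base <- round(base)
  nfft <- as.integer(ceiling(length(x) / base) * base)
  xf <- c(x, rep(0, nfft - length(x)))
  X <- stats::fft(xf)
  half <- seq_len(nfft %/% 2 + 1L)
  structure(list(freq = (half - 1) * fs / nfft, mag = Mod(X[half]),
                 fs = fs, df = fs / nfft, n = length(x)),
            class = "magnitude_spectrum")
}

spec_bin <- function(spec, f, tol = 1e-6) {
  i <- which(abs(spec$freq - f) < tol)
  if (length(i) != 1L)
    stop("frequency ", f, " Hz is not on the spectrum grid (resolution ",
         signif(spec$df, 3), " Hz); use a longer segment or zero-padding")
  i
}

#' SSVEP signal-to-noise ratio at a stimulus frequency
#'
#' Ratio (in dB) of the magnitude at the stimulus bin to the mean magnitude
#' of the ten flanking bins at f +/- 0.2 k Hz, k = 1..5:
#' \deqn{SNR = 20 \log_{10} \frac{O(f)}{\frac{1}{10}\sum_{k=1}^{5} O(f-0.2k) + O(f+0.2k)}.}
#'
#' @param spec a [magnitude_spectrum] with 0.2 Hz-compatible resolution.
#' @param f stimulus frequency in Hz.
#' @return SNR in dB.
#' @export
ssvep_snr <- function(spec, f) {
  stopifnot(inherits(spec, "magnitude_spectrum"))
  peak <- spec$mag[spec_bin(spec, f)]
  flank <- vapply(1:5, function(k) {
    spec$mag[spec_bin(spec, f - 0.2 * k)] +
      spec$mag[spec_bin(spec, f + 0.2 * k)]
  }, numeric(1))
  noise <- sum(flank) / 10
  20 * log10(peak / noise)
}

#' Attenuation of a spectral component by filtering
#'
#' \deqn{A = 20 \log_{10}(O(f)/I(f)) \cdot \mathrm{sign}(I(f) - O(f)),}
#' where I and O are the magnitude spectra of the unfiltered and filtered
#' target channel.  Note the sign factor makes A = -6.02 dB for both a x2
#' attenuation and a x2 amplification; consumers needing a signed gain
#' should use plain `20*log10(O/I)`.
#'
#' @param input_spec,output_spec [magnitude_spectrum] objects on equal grids.
#' @param f frequency in Hz; both magnitudes must be positive there.
#' @return Attenuation in dB.
#' @export
attenuation <- function(input_spec, output_spec, f) {
  i <- input_spec$mag[spec_bin(input_spec, f)]
  o <- output_spec$mag[spec_bin(output_spec, f)]
  if (i <= 0 || o <= 0)
    stop("zero magnitude at ", f, " Hz; attenuation undefined")
  20 * log10(o / i) * sign(i - o)
}

#' Magnitude coherence between two signals
#'
#' Welch-style estimate: the signals are split into 50%-overlapping segments
#' of `segment_s` seconds, Hann-windowed, and the averaged cross- and
#' auto-spectra combined as
#' \deqn{\Gamma_{xy}(\omega) = |C_{xy}(\omega)| / \sqrt{C_{xx}(\omega) C_{yy}(\omega)}.}
#' Segment averaging is essential: from a single unaveraged FFT the ratio is
#' identically 1.
#'
#' @param x,y equal-length numeric signals.
#' @param fs sampling rate in Hz.
#' @param segment_s segment length in seconds (default 1).
#' @return data.frame with columns `freq` (Hz) and `coherence` in \[0, 1\].
#' @export
coherence <- function(x, y, fs, segment_s = 1) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  nseg <- max(2L, round(segment_s * fs))
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  if (length(starts) < 2L)
    warning("single segment: coherence is trivially 1; use shorter segments")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  half <- seq_len(nseg %/% 2 + 1L)
  sxx <- syy <- numeric(length(half))
  sxy <- complex(length(half))
  for (s in starts) {
    idx <- seq.int(s, s + nseg - 1L)
    X <- stats::fft(w * (x[idx] - mean(x[idx])))[half]
    Y <- stats::fft(w * (y[idx] - mean(y[idx])))[half]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  den <- sqrt(sxx * syy)
  coh <- ifelse(den > 0, Mod(sxy) / den, 0)
  data.frame(freq = (half - 1) * fs / nseg, coherence = pmin(coh, 1))
}

#' Grid search for the virtual-distance operating point
#'
#' Evaluation harness scanning similarity-window lengths, dispersion cap
#' ratios and the virtual-distance coefficient on synthetic SSVEP records,
#' scoring each setup by mean component SNR minus mean absolute attenuation
#' ([ssvep_snr()] and [attenuation()] at the true component frequencies).
#' Intended for small desk-scale sweeps, mirroring how the default operating
#' point (Wf = 100 ms, w1 = 5, cap 10) was originally fitted.
#'
#' @param records list of synthetic SSVEP records from [gen_ssvep()].
#' @param montage an [electrode_montage].
#' @param target target electrode label.
#' @param window_ms_grid,w1_grid,cap_grid parameter grids.
#' @return data.frame of scored parameter combinations, best first.
#' @export
tune_filter_params <- function(records, montage, target,
                               window_ms_grid = c(50, 100, 200),
                               w1_grid = c(1, 5, 25),
                               cap_grid = 10) {
  grid <- expand.grid(window_ms = window_ms_grid, w1 = w1_grid,
                      cap_ratio = cap_grid)
  grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- filter_config(mode = "ad_war", w1 = grid$w1[i],
                         window_ms = grid$window_ms[i],
                         cap_ratio = grid$cap_ratio[i])
    scores <- vapply(records, function(rec) {
      fr <- filter_record(rec$record, montage, targets = target,
                          config = cfg, fs = rec$fs)
      truth <- rec$truth[rec$truth$channel == target, , drop = FALSE]
      ins <- magnitude_spectrum(rec$record[, target], rec$fs)
      outs <- magnitude_spectrum(fr$filtered[, target], rec$fs)
      snr <- mean(vapply(truth$freq, function(f) ssvep_snr(outs, f),
                         numeric(1)))
      att <- mean(vapply(truth$freq, function(f)
        abs(attenuation(ins, outs, f)), numeric(1)))
      snr - att
    }, numeric(1))
    grid$score[i] <- mean(scores)
  }
  grid[order(-grid$score), ]
}
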