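#' Higuchi fractal dimension
#'
#' Standard Higuchi estimate: for each lag k = 1..kmax the mean normalized
#' curve length L(k) is computed over the k decimated sub-curves, and the
#' dimension is the least-squares slope of log L(k) against log(1/k).
#' Values near 1 indicate smooth curves, near 2 noise-like signals.
#'
#' @param x numeric signal, length >= 2 * kmax.
#' @param kmax maximum lag (default 8, suited to 100-sample windows).
#' @return Scalar estimate, typically in \[1, 2\].
#' @export
higuchi_fd <- function(x, kmax = 8) {
  N <- length(x)
  if (N < 2 * kmax) stop("window too short for kmax = ", kmax)
  lk <- vapply(seq_len(kmax), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq(m, N, by = k)
      if (length(idx) < 2L) return(NA_real_)
      nseg <- length(idx) - 1L
      sum(abs(diff(x[idx]))) * (N - 1) / (nseg * k) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  lk[lk <= 0] <- .Machine$double.xmin  # flat sub-curves: avoid log(0)
  lx <- log(1 / seq_len(kmax))
  ly <- log(lk)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Sevcik fractal dimension
#'
#' Abscissa normalized to \[0, 1\] and amplitude min-max normalized to
#' \[0, 1\]; with L the length of the normalized curve,
#' \deqn{D = 1 + \ln(L) / \ln(2 (N - 1)).}
#' Scale- and offset-invariant by construction.  A constant window returns 1.
#' Note the estimate converges to 1 on a straight line only as N grows
#' (1 + ln(sqrt 2)/ln(2(N-1))).
#'
#' @param x numeric signal, length >= 2.
#' @return Scalar estimate >= 1 (up to estimation noise).
#' @export
sevcik_fd <- function(x) {
  N <- length(x)
  if (N < 2L) stop("window too short")
  rng <- diff(range(x))
  if (rng == 0) return(1)
  ys <- (x - min(x)) / rng
  xs <- seq(0, 1, length.out = N)
  L <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  1 + log(L) / log(2 * (N - 1))
}

#' Band power of a window
#'
#' Sum of FFT power over frequency bins in the half-open band \[lo, hi),
#' with zero-padding to reach at most 1 Hz bin spacing.  Power is normalized
#' so that the sum over all bins equals the time-domain mean square of the
#' window (Parseval), making band powers comparable across window lengths.
#'
#' @param x numeric window.
#' @param fs sampling rate in Hz.
#' @param band numeric length-2 vector `c(lo, hi)`, `hi <= fs/2`.
#' @return Nonnegative scalar (microvolts squared).
#' @export
band_power <- function(x, fs, band) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[2] > fs / 2) stop("band extends beyond the Nyquist frequency")
  ps <- folded_power_spectrum(x, fs)
  sum(ps$p[ps$fpos >= band[1] & ps$fpos < band[2]])
}

# Two-sided power spectrum folded onto nonnegative frequencies, zero-padded
# to <= 1 Hz bin spacing and normalized so sum(p) = mean(x^2) (Parseval).
# Shared by band_power() and extract_features() so one FFT serves all bands.
folded_power_spectrum <- function(x, fs) {
  n <- length(x)
  nfft <- max(n, as.integer(2^ceiling(log2(max(fs, n)))))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  freq <- (seq_len(nfft) - 1) * fs / nfft
  list(p = Mod(X)^2 / (nfft * n), fpos = pmin(freq, fs - freq))
}

.bp_bands <- list(
  `BP_0.1_4` = c(0.1, 4), BP_8_12 = c(8, 12), BP_13_17 = c(13, 17),
  BP_18_24 = c(18, 24), BP_26_30 = c(26, 30), BP_30_50 = c(30, 50),
  BP_50_70 = c(50, 70))

#' Names of the 12 per-channel features
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("RF", "MAV", "WL", "FDH", "FDSH", names(.bp_bands))
}

#' Extract the 12-feature bank from one multichannel window
#'
#' Per channel: RF (mean filtered amplitude over the window), MAV (mean
#' absolute value), WL (waveform length, sum of successive absolute
#' differences), FDH (Higuchi fractal dimension), FDSH (mean of the Sevcik
#' and Higuchi estimates), and seven band powers on 0.1-4, 8-12, 13-17,
#' 18-24, 26-30, 30-50 and 50-70 Hz.  Bands above Nyquist are dropped with
#' an error, so use fs >= 140 Hz for the full bank.
#'
#' @param window numeric matrix (samples x channels) covering one 250 ms
#'   window of (already spatially filtered) EEG; column names = channels.
#' @param fs sampling rate in Hz.
#' @param channels channels to featurize (default: all columns).
#' @param kmax Higuchi lag bound.
#' @param rf one of `"mean"` (default) or `"last"`: summary used for the RF
#'   feature.
#' @return Named numeric vector of length `12 * length(channels)`, names
#'   `<channel>_<feature>`.
#' @export
extract_features <- function(window, fs, channels = colnames(window),
                             kmax = 8, rf = c("mean", "last")) {
  rf <- match.arg(rf)
  window <- as.matrix(window)
  out <- numeric(0)
  for (ch in channels) {
    x <- window[, ch]
    fd_h <- higuchi_fd(x, kmax = kmax)
    fd_s <- sevcik_fd(x)
    ps <- folded_power_spectrum(x, fs)
    vals <- c(
      RF = if (rf == "mean") mean(x) else x[length(x)],
      MAV = mean(abs(x)),
      WL = sum(abs(diff(x))),
      FDH = fd_h,
      FDSH = (fd_s + fd_h) / 2,
      vapply(.bp_bands, function(b)
        sum(ps$p[ps$fpos >= b[1] & ps$fpos < b[2]]), numeric(1)))
    names(vals) <- paste(ch, feature_names(), sep = "_")
    out <- c(out, vals)
  }
  out
}

#' Sliding-window feature extraction over a record
#'
#' Applies [extract_features()] to every window of `window_ms` ending at
#' samples `window`, `window + stride`, ... (stride 1 reproduces the
#' per-sample sliding scheme; larger strides trade temporal resolution for
#' speed).
#'
#' @param record numeric matrix (samples x channels), column names =
#'   channels.
#' @param fs sampling rate in Hz.
#' @param channels channels to featurize.
#' @param window_ms window length in milliseconds (default 250).
#' @param stride stride in samples (default 1).
#' @param kmax,rf passed to [extract_features()].
#' @return List with `features` (windows x features matrix) and
#'   `end_sample` (window end indices).
#' @export
sliding_features <- function(record, fs, channels = colnames(record),
                             window_ms = 250, stride = 1L, kmax = 8,
                             rf = "mean") {
  record <- as.matrix(record)
  n <- round(window_ms * fs / 1000)
  if (nrow(record) < n)
    stop("record shorter than one ", window_ms, " ms window")
  ends <- seq.int(n, nrow(record), by = stride)
  feats <- t(vapply(ends, function(e) {
    extract_features(record[seq.int(e - n + 1L, e), , drop = FALSE],
                     fs = fs, channels = channels, kmax = kmax, rf = rf)
  }, numeric(12L * length(channels))))
  list(features = feats, end_sample = ends)
}
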