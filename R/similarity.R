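#' Concordance correlation coefficient
#'
#' Lin's concordance correlation coefficient between two equal-length signal
#' windows,
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},}
#' with biased (divide-by-n) moment estimates.  The coefficient combines
#' precision (Pearson correlation) and accuracy (agreement of means and
#' variances): \eqn{|\rho_c| \le |r|}, with equality only when the two
#' windows share mean and variance.  It drives neighbor selection and
#' virtual-distance weighting in the adaptive filters.
#'
#' Degenerate windows: if both windows are constant and equal the
#' convention is \eqn{\rho_c = 1}; if the denominator is zero with unequal
#' constants the value is 0 and the result carries attribute
#' `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length (>= 2), all values finite.
#' @return Scalar in \[-1, 1\].
#' @seealso [pearson_r()], [virtual_distance()]
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2L) stop("windows must contain at least 2 samples")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("windows must be finite")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) {
    # both windows constant: equal constants agree perfectly, unequal ones
    # carry no usable similarity information
    return(structure(if (mx == my) 1 else 0, degenerate = TRUE))
  }
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Pearson product-moment correlation of two windows
#'
#' Standard correlation; returns 0 with attribute `degenerate = TRUE` when
#' both windows are constant (flat EEG segments must not poison the filter).
#'
#' @inheritParams ccc
#' @return Scalar in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("windows must contain at least 2 samples")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 && sy == 0) return(structure(0, degenerate = TRUE))
  if (sx == 0 || sy == 0) return(structure(0, degenerate = TRUE))
  stats::cor(x, y)
}

#' CCC between a target channel and each neighbor over the current window
#'
#' Windows are aligned: the window ending at the last buffered sample covers
#' the final `n` rows of `buffer`.
#'
#' @param buffer numeric matrix (samples x channels).
#' @param target target channel index or name.
#' @param neighbors neighbor channel indices or names.
#' @param n window length in samples; defaults to `nrow(buffer)`.
#' @return Numeric vector of CCC values in neighbor order.
#' @export
ccc_to_neighbors <- function(buffer, target, neighbors, n = nrow(buffer)) {
  buffer <- as.matrix(buffer)
  if (nrow(buffer) < n)
    stop("buffer holds fewer than `n` samples (warm-up)")
  rows <- seq.int(nrow(buffer) - n + 1L, nrow(buffer))
  x <- buffer[rows, target]
  vapply(neighbors, function(j) as.numeric(ccc(x, buffer[rows, j])),
         numeric(1))
}

# Rolling CCC of x against y for every window of length n ending at samples
# n..T, via cumulative sums (O(T)).  Returns a length-T vector with NA for
# the first n-1 positions.  Degenerate windows follow the ccc() conventions.
rolling_ccc <- function(x, y, n) {
  T_ <- length(x)
  if (length(y) != T_) stop("length mismatch")
  if (T_ < n) return(rep(NA_real_, T_))
  wsum <- function(v) {
    cs <- cumsum(v)
    cs[n:T_] - c(0, cs[seq_len(T_ - n)])
  }
  sx <- wsum(x); sy <- wsum(y)
  sxx <- wsum(x * x); syy <- wsum(y * y); sxy <- wsum(x * y)
  mx <- sx / n; my <- sy / n
  vx <- pmax(sxx / n - mx^2, 0)
  vy <- pmax(syy / n - my^2, 0)
  cxy <- sxy / n - mx * my
  den <- vx + vy + (mx - my)^2
  out <- numeric(length(den))
  zero <- den <= 0
  out[!zero] <- 2 * cxy[!zero] / den[!zero]
  out[zero] <- ifelse(abs(mx[zero] - my[zero]) < 1e-12, 1, 0)
  c(rep(NA_real_, n - 1L), out)
}

# Rolling Pearson r (same windowing as rolling_ccc); degenerate windows -> 0.
rolling_pearson <- function(x, y, n) {
  T_ <- length(x)
  if (T_ < n) return(rep(NA_real_, T_))
  wsum <- function(v) {
    cs <- cumsum(v)
    cs[n:T_] - c(0, cs[seq_len(T_ - n)])
  }
  sx <- wsum(x); sy <- wsum(y)
  vx <- pmax(wsum(x * x) / n - (sx / n)^2, 0)
  vy <- pmax(wsum(y * y) / n - (sy / n)^2, 0)
  cxy <- wsum(x * y) / n - (sx / n) * (sy / n)
  den <- sqrt(vx * vy)
  r <- ifelse(den > 0, cxy / den, 0)
  c(rep(NA_real_, n - 1L), pmin(pmax(r, -1), 1))
}
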