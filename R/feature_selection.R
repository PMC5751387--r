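#' Representation entropy of a feature subset
#'
#' Shannon entropy of the normalized eigenvalue spectrum of the subset's
#' correlation matrix: with eigenvalues \eqn{\lambda} and
#' \eqn{\tilde\lambda = \lambda / \sum \lambda},
#' \deqn{RE = -\sum \tilde\lambda \ln \tilde\lambda,}
#' with the convention \eqn{0 \ln 0 = 0}.  RE is 0 for a rank-one subset
#' (maximal redundancy) and \eqn{\ln d} for d mutually uncorrelated
#' features; the correlation (not covariance) matrix makes it invariant to
#' feature rescaling, so mixed-unit features are comparable.
#'
#' @param x numeric matrix (observations x features), >= 2 of each.
#' @return Nonnegative scalar in \[0, ln d\].
#' @export
representation_entropy <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 2L)
    stop("need at least 2 features and 2 observations")
  R <- suppressWarnings(stats::cor(x))
  if (any(!is.finite(R))) {
    # constant features carry no correlation structure
    R[!is.finite(R)] <- 0
    diag(R) <- 1
  }
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  tot <- sum(lam)
  if (tot <= 0) return(structure(0, degenerate = TRUE))
  p <- lam / tot
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Maximal information compression index
#'
#' Smallest eigenvalue of the 2x2 covariance matrix of a feature pair:
#' \deqn{\lambda_2 = \tfrac{1}{2}\left[\sigma_x^2 + \sigma_y^2 -
#'   \sqrt{(\sigma_x^2 + \sigma_y^2)^2 - 4 \sigma_x^2 \sigma_y^2 (1 - \rho^2)}\right].}
#' Zero iff the features are perfectly linearly dependent; symmetric in its
#' arguments.
#'
#' @param x,y numeric feature columns, both non-constant.
#' @return Nonnegative scalar.
#' @export
mici <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("mici requires non-constant features")
  rho <- stats::cor(x, y)
  s <- vx + vy
  disc <- max(s^2 - 4 * vx * vy * (1 - rho^2), 0)
  (s - sqrt(disc)) / 2
}

#' Redundancy threshold over a collection of RE scores
#'
#' Two-step rule.  (a) Screening: scores are sorted in descending order and
#' retained while they remain statistically compatible with the maximum --
#' a score is cut (together with everything below it) as soon as its
#' one-sided standardized deficit from the maximum becomes significant
#' (deficit > 1.645 sd, p < 0.05 under a Z screen) or as soon as the local
#' gap to the previous score is anomalous (more than three times the median
#' gap seen so far within the retained run), whichever comes first.  The
#' gap cut keeps the retained set confined to the near-maximum cluster when
#' the pooled scores are multimodal, where a global-sd screen alone would
#' reach far down the distribution.  (b) Among the retained scores the one
#' with the minimum total standardized (univariate Mahalanobis) distance to
#' the other retained scores is returned as the threshold.  If all scores
#' are equal that value is returned.
#'
#' @param re_values numeric vector of RE scores (>= 1; the screening step is
#'   meaningful from 3 upward).
#' @return Scalar threshold, never exceeding `max(re_values)`.
#' @export
re_threshold <- function(re_values) {
  if (!length(re_values)) stop("no RE values")
  s <- stats::sd(re_values)
  if (!is.finite(s) || s == 0) return(re_values[1])
  d <- sort(re_values, decreasing = TRUE)
  z95 <- stats::qnorm(0.95)
  n_keep <- 1L
  for (i in seq_len(length(d) - 1L)) {
    gap <- d[i] - d[i + 1L]
    if (d[1] - d[i + 1L] > z95 * s) break          # deficit screen
    if (i > 1L) {
      prev_gaps <- -diff(d[1:i])
      if (gap > 3 * max(stats::median(prev_gaps), 0.01 * s)) break
    }
    n_keep <- i + 1L
  }
  keep <- d[seq_len(n_keep)]
  if (length(keep) == 1L) return(keep)
  sk <- stats::sd(keep)
  zk <- (keep - mean(keep)) / (if (is.finite(sk) && sk > 0) sk else 1)
  tot <- vapply(seq_along(zk), function(i) sum(abs(zk[i] - zk[-i])),
                numeric(1))
  keep[which.min(tot)]
}

#' Unsupervised feature selection by representation entropy and MICI
#'
#' Two-process procedure.  Process 1 estimates a redundancy threshold:
#' for each cluster fraction (default 10-80% of the features) `R` seeded
#' random subsets are drawn, their RE values pooled, and [re_threshold()]
#' applied.  Process 2 iterates on the working set: the feature pair of
#' minimal MICI (highest redundancy; ties broken lexicographically) is
#' identified; the pair members and all previously rejected features compete
#' as candidates, each scored by the RE of the non-redundant remainder plus
#' the candidate, and the best survives.  After each step the threshold is
#' refreshed from the pooled RE history augmented with the working-set RE.
#' Iteration stops when the working-set RE exceeds the threshold or the
#' working set would drop below 2 features.  Deterministic given `seed`.
#'
#' @param x numeric matrix (observations x features) with unique column
#'   names and >= 4 features.
#' @param n_subsets subsets drawn per cluster fraction (default 200).
#' @param fractions cluster fractions of the feature count.
#' @param seed integer seed for subset sampling.
#' @return Object of class `selection_ledger`: list with `selected`
#'   (surviving feature names), `threshold_history`, `re_history`,
#'   `removed_pairs` (data.frame of flagged pairs and resolutions),
#'   `initial_threshold`, `rng_seed`, and the configuration used.
#' @export
select_features <- function(x, n_subsets = 200,
                            fractions = seq(0.1, 0.8, by = 0.1),
                            seed = 1L) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (d < 4L) stop("need at least 4 features")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("`x` must have unique column names")
  feats <- colnames(x)

  # Process 1: pooled RE of random subsets -> threshold
  re_pool <- local({
    set.seed(seed)
    unlist(lapply(fractions, function(fr) {
      m <- max(2L, round(fr * d))
      vapply(seq_len(n_subsets), function(i) {
        as.numeric(representation_entropy(
          x[, sample.int(d, m), drop = FALSE]))
      }, numeric(1))
    }))
  })
  threshold <- re_threshold(re_pool)

  working <- feats
  rejected <- character(0)
  re_hist <- numeric(0)
  th_hist <- threshold
  removed <- data.frame(feature_a = character(), feature_b = character(),
                        mici = numeric(), kept = character(),
                        stringsAsFactors = FALSE)

  # Process 2: iterative MICI-driven replacement
  repeat {
    re_now <- as.numeric(representation_entropy(x[, working, drop = FALSE]))
    re_hist <- c(re_hist, re_now)
    if (re_now > threshold || length(working) <= 2L) break

    # most redundant pair in the working set (lexicographic tie-break)
    best <- NULL
    for (a in seq_len(length(working) - 1L)) {
      for (b in seq.int(a + 1L, length(working))) {
        m <- mici(x[, working[a]], x[, working[b]])
        if (is.null(best) || m < best$m)
          best <- list(a = working[a], b = working[b], m = m)
      }
    }
    remainder <- setdiff(working, c(best$a, best$b))
    candidates <- unique(c(best$a, best$b, rejected))
    score <- vapply(candidates, function(cnd) {
      as.numeric(representation_entropy(x[, c(remainder, cnd),
                                          drop = FALSE]))
    }, numeric(1))
    winner <- candidates[which.max(score)]
    working <- c(remainder, winner)
    rejected <- setdiff(union(rejected, c(best$a, best$b)), winner)
    removed <- rbind(removed, data.frame(
      feature_a = best$a, feature_b = best$b, mici = best$m, kept = winner,
      stringsAsFactors = FALSE))
    threshold <- re_threshold(c(re_pool, re_hist))
    th_hist <- c(th_hist, threshold)
  }
  structure(list(selected = feats[feats %in% working],
                 threshold_history = th_hist, re_history = re_hist,
                 removed_pairs = removed,
                 initial_threshold = th_hist[1],
                 rng_seed = seed,
                 config = list(n_subsets = n_subsets, fractions = fractions)),
            class = "selection_ledger")
}

#' @export
print.selection_ledger <- function(x, ...) {
  cat("Unsupervised feature selection (RE/MICI)\n")
  cat("  selected", length(x$selected), "feature(s):",
      paste(utils::head(x$selected, 8), collapse = ", "),
      if (length(x$selected) > 8) "..." else "", "\n")
  cat(sprintf("  iterations: %d   final RE: %.4f   final threshold: %.4f\n",
              length(x$re_history), utils::tail(x$re_history, 1),
              utils::tail(x$threshold_history, 1)))
  invisible(x)
}
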