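#' Confusion matrix from label vectors
#'
#' @param truth,pred factors or vectors of equal length; rows of the result
#'   are true classes, columns predicted.
#' @return Integer K x K matrix.
#' @export
confusion_matrix <- function(truth, pred) {
  lev <- union(levels(factor(truth)), levels(factor(pred)))
  table(factor(truth, levels = lev), factor(pred, levels = lev))
}

#' Confusion-matrix performance metrics
#'
#' Standard accuracy, per-class true/false positive rates, per-class F1 and
#' Cohen's Kappa, plus the per-class prediction quality
#' \deqn{PNM_i = \frac{(C_{ii} - \sum_{j \ne i} C_{ij}) + (C_{ii} - \sum_{i' \ne i} C_{i'i})}{\mathrm{row}_i + \mathrm{col}_i},}
#' which runs from 1 (row and column i purely diagonal) to -1 (all
#' predictions for class i wrong).  Also reports `pnm_min` and `fpr_max`
#' over classes, the two summaries entering the composite model-selection
#' index ([idx_metric()]).
#'
#' @param cm K x K confusion matrix (rows = truth).
#' @return Object of class `eval_metrics`: list with `acc`, `tpr`, `fpr`,
#'   `f1` (per class), `f1_macro`, `kappa`, `pnm`, `pnm_min`, `fpr_max`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || sum(cm) <= 0 || any(cm < 0))
    stop("invalid confusion matrix")
  K <- nrow(cm)
  tot <- sum(cm)
  diagc <- diag(cm)
  rows <- rowSums(cm)
  cols <- colSums(cm)
  acc <- sum(diagc) / tot
  tpr <- ifelse(rows > 0, diagc / rows, 0)
  fp <- cols - diagc
  fpr <- ifelse(tot - rows > 0, fp / (tot - rows), 0)
  prec <- ifelse(cols > 0, diagc / cols, 0)
  f1 <- ifelse(prec + tpr > 0, 2 * prec * tpr / (prec + tpr), 0)
  pe <- sum(rows * cols) / tot^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1
  pnm <- ((diagc - (rows - diagc)) + (diagc - (cols - diagc))) /
    (rows + cols)
  structure(list(acc = acc, tpr = tpr, fpr = fpr, f1 = f1,
                 f1_macro = mean(f1), kappa = kappa, pnm = pnm,
                 pnm_min = min(pnm), fpr_max = max(fpr),
                 confusion = cm),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("ACC %.4f  Kappa %.4f  FPRmax %.4f  PNMmin %.4f  F1 %.4f\n",
              x$acc, x$kappa, x$fpr_max, x$pnm_min, x$f1_macro))
  invisible(x)
}

#' Composite model-selection index
#'
#' \deqn{Idx = 1 - (0.3\,\kappa + 0.3\,(1 - FPR_{max}) + 0.15\,ACC + 0.25\,PNM_{min}),}
#' lower is better; 0 for a perfect classifier.
#'
#' @param metrics an `eval_metrics` object (from [confusion_metrics()]).
#' @return Scalar index.
#' @export
idx_metric <- function(metrics) {
  w <- c(0.3, 0.3, 0.15, 0.25)
  p <- c(metrics$kappa, 1 - metrics$fpr_max, metrics$acc, metrics$pnm_min)
  1 - sum(w * p)
}

#' Tune a linear-margin classifier and predict
#'
#' Scans the box-constraint grid with `k1`-fold inner cross-validation,
#' scoring each C by the mean composite index ([idx_metric()]); the C of
#' minimal mean index wins (ties to the smallest C).  A linear-kernel
#' support vector machine (via \pkg{e1071}) is then refit on the full
#' training set and applied to the test set.
#'
#' @param x_train,x_test numeric feature matrices.
#' @param y_train training labels (2 or more classes).
#' @param C_grid box-constraint grid (default `c(0.01, 0.05, 0.1, 1, 5, 10)`).
#' @param k1 inner folds (default 2).
#' @param seed seed controlling the inner fold assignment.
#' @return List with `pred` (test predictions), `chosen_C`, and `inner`
#'   (data.frame of C versus mean inner index).
#' @export
tune_and_classify <- function(x_train, y_train, x_test,
                              C_grid = c(0.01, 0.05, 0.1, 1, 5, 10),
                              k1 = 2, seed = 1L) {
  y_train <- factor(y_train)
  if (nlevels(y_train) < 2L) stop("training data has a single class")
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  n <- nrow(x_train)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k1), n))
  # every inner training fold must contain both classes
  for (tries in 1:20) {
    ok <- all(vapply(seq_len(k1), function(f)
      nlevels(droplevels(y_train[folds != f])) >= 2L, logical(1)))
    if (ok) break
    warning("single-class inner fold; resampling fold assignment")
    folds <- sample(rep_len(seq_len(k1), n))
  }
  mean_idx <- vapply(C_grid, function(C) {
    mean(vapply(seq_len(k1), function(f) {
      tr <- folds != f
      fit <- e1071::svm(x_train[tr, , drop = FALSE],
                        droplevels(y_train[tr]),
                        kernel = "linear", cost = C, scale = FALSE)
      pr <- stats::predict(fit, x_train[!tr, , drop = FALSE])
      idx_metric(confusion_metrics(confusion_matrix(y_train[!tr], pr)))
    }, numeric(1)))
  }, numeric(1))
  chosen <- C_grid[which.min(mean_idx)]  # which.min ties -> first = smallest
  fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = chosen,
                    scale = FALSE)
  list(pred = stats::predict(fit, x_test), chosen_C = chosen,
       inner = data.frame(C = C_grid, mean_idx = mean_idx))
}

#' CCA-based SSVEP frequency recognition
#'
#' For each candidate stimulus frequency a reference matrix of sines and
#' cosines at the fundamental and its harmonics (default 6) is built;
#' harmonics at or above Nyquist are truncated.  The candidate whose
#' reference attains the largest first canonical correlation with the epoch
#' channels is returned.
#'
#' @param epoch numeric matrix (samples x channels).
#' @param candidate_freqs candidate frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param n_harmonics number of harmonics in the reference set (default 6).
#' @return List with `freq` (predicted frequency) and `correlation` (named
#'   vector of maximal canonical correlations per candidate).
#' @export
cca_ssvep_classify <- function(epoch, candidate_freqs, fs, n_harmonics = 6) {
  epoch <- as.matrix(epoch)
  if (ncol(epoch) < 1L) stop("epoch must have at least one channel")
  t <- seq_len(nrow(epoch)) / fs
  epoch_c <- scale(epoch, center = TRUE, scale = FALSE)
  rho <- vapply(candidate_freqs, function(f) {
    h <- seq_len(n_harmonics)
    h <- h[f * h < fs / 2]
    if (!length(h)) return(0)
    refs <- do.call(cbind, lapply(h, function(k)
      cbind(sin(2 * pi * k * f * t), cos(2 * pi * k * f * t))))
    cc <- stats::cancor(epoch_c, refs, xcenter = FALSE, ycenter = TRUE)
    cc$cor[1]
  }, numeric(1))
  names(rho) <- candidate_freqs
  list(freq = candidate_freqs[which.max(rho)], correlation = rho)
}

#' Latency and continuous-recognition analysis of a prediction stream
#'
#' A planning interval counts as a recognized command when the planning
#' label persists for at least `min_ms` (88 ms, i.e. 35 samples at 400 Hz).
#' Latency is the time, relative to onset, at which the first qualifying
#' persistence completes (negative values = anticipation of the onset).
#' Over all qualifying runs the continuous-recognition summary reports the
#' median and maximum run length in milliseconds.  With no qualifying run
#' the epoch is flagged as a failed cycle.
#'
#' @param labels per-sample predicted labels over the planning interval.
#' @param fs sampling rate of the prediction stream in Hz.
#' @param planning_label label counted as planning (default `"planning"`).
#' @param t0_ms time of the first stream sample relative to onset
#'   (default -1500).
#' @param min_ms persistence requirement in milliseconds (default 88).
#' @return List with `failed`, `latency_ms`, `cr_median_ms`, `cr_max_ms`,
#'   and `runs_ms` (lengths of qualifying runs).
#' @export
recognition_timing <- function(labels, fs, planning_label = "planning",
                               t0_ms = -1500, min_ms = 88) {
  stopifnot(fs > 0)
  dt <- 1000 / fs
  min_samples <- max(1L, round(min_ms / dt))
  r <- rle(as.character(labels) == planning_label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_samples)
  if (!length(qual)) {
    return(list(failed = TRUE, latency_ms = NA_real_,
                cr_median_ms = NA_real_, cr_max_ms = NA_real_,
                runs_ms = numeric(0)))
  }
  runs_ms <- r$lengths[qual] * dt
  first <- qual[1]
  latency <- t0_ms + (starts[first] - 1L) * dt + min_samples * dt
  list(failed = FALSE, latency_ms = latency,
       cr_median_ms = stats::median(runs_ms), cr_max_ms = max(runs_ms),
       runs_ms = runs_ms)
}
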