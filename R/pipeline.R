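#' End-to-end gait-planning recognition pipeline
#'
#' Runs the four BCI stages on labeled epochs: spatial filtering of the
#' target channels, sliding-window feature extraction (12 features per
#' channel), unsupervised RE/MICI feature selection on the training windows,
#' and linear-margin classification with inner model selection by the
#' composite index.  Outer cross-validation groups epochs by recording
#' session (`k2` folds of whole sessions), so train and test windows never
#' share a session.  Classes are balanced at the window level by seeded
#' subsampling of the majority class, making 0.5 the chance accuracy.
#'
#' @param epochs a `gait_epochs` object ([gen_gait_epochs()]) or compatible
#'   list.
#' @param montage an [electrode_montage] whose targets are the decoded
#'   channels.
#' @param config a [filter_config] (default: adaptive WAR at the fitted
#'   operating point).
#' @param window_ms feature window (default 250 ms).
#' @param stride feature stride in samples (default 25; stride 1 reproduces
#'   the per-sample scheme at higher cost).
#' @param k1 inner folds for the box-constraint scan (default 2).
#' @param k2 outer session-grouped folds (default 3).
#' @param C_grid box-constraint grid.
#' @param select run RE/MICI feature selection per fold (default TRUE).
#' @param n_subsets subsets per cluster fraction in the selection stage
#'   (default 50 at pipeline scale).
#' @param balance_classes subsample the majority class per fold (default
#'   TRUE).
#' @param seed master seed (folds, selection, balancing).
#' @return Object of class `gait_report`: per-fold metrics and chosen C,
#'   pooled confusion metrics, mean accuracy, selected features per fold,
#'   timing analysis per planning epoch, and the resolved configuration
#'   (config, seed, package version).
#' @export
run_gait_pipeline <- function(epochs, montage,
                              config = filter_config(mode = "ad_war"),
                              window_ms = 250, stride = 25L, k1 = 2, k2 = 3,
                              C_grid = c(0.01, 0.05, 0.1, 1, 5, 10),
                              select = TRUE, n_subsets = 50,
                              balance_classes = TRUE, seed = 1L) {
  stopifnot(k1 >= 2, k2 >= 2)
  fs <- epochs$fs
  targets <- montage$targets
  n_ep <- length(epochs$epochs)
  # stage 1+2: filter each epoch, then sliding features on the targets
  feat_list <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    fr <- filter_record(epochs$epochs[[e]], montage, targets = targets,
                        config = config, fs = fs)
    sf <- sliding_features(fr$filtered, fs = fs, channels = targets,
                           window_ms = window_ms, stride = stride)
    feat_list[[e]] <- sf$features
  }
  win_epoch <- rep(seq_len(n_ep), vapply(feat_list, nrow, integer(1)))
  X <- do.call(rbind, feat_list)
  y <- epochs$label[win_epoch]
  sess <- epochs$session[win_epoch]
  sessions <- sort(unique(epochs$session))
  fold_of_session <- rep_len(seq_len(k2), length(sessions))
  folds <- fold_of_session[match(sess, sessions)]

  balance_idx <- function(idx, fold_seed) {
    if (!balance_classes) return(idx)
    set.seed(fold_seed)
    tab <- table(y[idx])
    m <- min(tab)
    unlist(lapply(names(tab), function(cl) {
      i <- idx[y[idx] == cl]
      if (length(i) > m) sort(sample(i, m)) else i
    }), use.names = FALSE)
  }

  fold_res <- vector("list", k2)
  pooled_cm <- NULL
  win_pred <- factor(rep(NA, length(y)), levels = levels(y))
  for (f in seq_len(k2)) {
    tr <- balance_idx(which(folds != f), component_seed(seed, 100 + f))
    te <- balance_idx(which(folds == f), component_seed(seed, 200 + f))
    x_tr <- X[tr, , drop = FALSE]
    x_te <- X[te, , drop = FALSE]
    sel_names <- colnames(X)
    ledger <- NULL
    if (select) {
      ledger <- select_features(x_tr, n_subsets = n_subsets,
                                seed = component_seed(seed, 300 + f))
      sel_names <- ledger$selected
    }
    # standardize by training statistics (mixed-unit features)
    mu <- colMeans(x_tr[, sel_names, drop = FALSE])
    sg <- apply(x_tr[, sel_names, drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    zt <- scale(x_tr[, sel_names, drop = FALSE], mu, sg)
    zs <- scale(x_te[, sel_names, drop = FALSE], mu, sg)
    cls <- tune_and_classify(zt, y[tr], zs, C_grid = C_grid, k1 = k1,
                             seed = component_seed(seed, 400 + f))
    m <- confusion_metrics(confusion_matrix(y[te], cls$pred))
    win_pred[te] <- cls$pred
    pooled_cm <- if (is.null(pooled_cm)) m$confusion else
      pooled_cm + m$confusion
    fold_res[[f]] <- list(fold = f, metrics = m, idx = idx_metric(m),
                          chosen_C = cls$chosen_C,
                          selected = sel_names, ledger = ledger,
                          n_train = length(tr), n_test = length(te))
  }
  # timing on the planning epochs from the held-out window predictions
  timing <- lapply(which(epochs$label == "planning"), function(e) {
    idx <- which(win_epoch == e & !is.na(win_pred))
    if (!length(idx)) return(NULL)
    recognition_timing(win_pred[idx], fs = fs / stride,
                       planning_label = "planning", t0_ms = -1500)
  })
  timing <- Filter(Negate(is.null), timing)
  acc_fold <- vapply(fold_res, function(r) r$metrics$acc, numeric(1))
  structure(list(folds = fold_res, mean_acc = mean(acc_fold),
                 acc_per_fold = acc_fold,
                 pooled = confusion_metrics(pooled_cm),
                 timing = timing,
                 provenance = list(config = config, seed = seed,
                                   stride = stride, window_ms = window_ms,
                                   k1 = k1, k2 = k2, C_grid = C_grid,
                                   balance_classes = balance_classes,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "adaptref")))),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat("Gait-planning recognition report\n")
  cat(sprintf("  mode %s, %d outer folds, mean ACC %.3f (per fold: %s)\n",
              x$provenance$config$mode, length(x$folds), x$mean_acc,
              paste(sprintf("%.3f", x$acc_per_fold), collapse = ", ")))
  cat("  chosen C per fold:",
      paste(vapply(x$folds, function(f) format(f$chosen_C), character(1)),
            collapse = ", "), "\n")
  ok <- Filter(function(t) !t$failed, x$timing)
  if (length(ok))
    cat(sprintf("  timing: %d/%d recognized cycles, median latency %.1f ms\n",
                length(ok), length(x$timing),
                stats::median(vapply(ok, `[[`, numeric(1), "latency_ms"))))
  invisible(x)
}

#' Paired SSVEP preservation evaluation: WAR versus adaptive WAR
#'
#' Generates (or takes) synthetic SSVEP records, filters the target channel
#' with the baseline WAR and the adaptive WAR on identical inputs, and
#' reports per-record attenuation at the true component frequency, SSVEP
#' SNR, mean coherence between input and output, and CCA frequency
#' recognition over a candidate grid.
#'
#' @param n_records number of seeded records (default 5).
#' @param montage an [electrode_montage] (default: bundled occipital
#'   montage).
#' @param target target channel (default `"Oz"`).
#' @param stim_freq stimulus frequency in Hz.
#' @param candidate_freqs CCA candidate grid (default 8-15.8 Hz in 0.2 Hz
#'   steps).
#' @param config adaptive filter configuration.
#' @param seed master seed; record r uses seed + r.
#' @return Object of class `ssvep_report`: data.frame `table` with one row
#'   per record and filter (attenuation dB, SNR dB, mean coherence, CCA
#'   prediction), CCA accuracy per filter, and provenance.
#' @export
run_ssvep_eval <- function(n_records = 5,
                           montage = load_montage(system.file(
                             "extdata", "montage_occipital.yaml",
                             package = "adaptref")),
                           target = "Oz", stim_freq = 12,
                           candidate_freqs = seq(8, 15.8, by = 0.2),
                           config = filter_config(mode = "ad_war"),
                           seed = 1L) {
  war_cfg <- filter_config(mode = "war", w1 = config$w1,
                           window_ms = config$window_ms,
                           unit_distance = config$unit_distance)
  rows <- list()
  cca_hit <- c(war = 0L, ad_war = 0L)
  for (r in seq_len(n_records)) {
    rec <- gen_ssvep(ssvep_demo_spec(montage, stim_freq = stim_freq,
                                     seed = seed + r))
    ins <- magnitude_spectrum(rec$record[, target], rec$fs)
    for (flt in c("war", "ad_war")) {
      cfg <- if (flt == "war") war_cfg else config
      # filter every declared target channel; the reference subtraction
      # removes the common-mode line tone, as a notch filter would on
      # acquisition hardware, so the CCA references see only the SSVEP
      fr <- filter_record(rec$record, montage,
                          targets = union(target, montage$targets),
                          config = cfg, fs = rec$fs)
      outs <- magnitude_spectrum(fr$filtered[, target], rec$fs)
      coh <- coherence(rec$record[, target], fr$filtered[, target], rec$fs)
      pred <- cca_ssvep_classify(fr$filtered, candidate_freqs, rec$fs)$freq
      if (isTRUE(all.equal(pred, stim_freq))) cca_hit[flt] <- cca_hit[flt] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        record = r, filter = flt,
        attenuation_db = attenuation(ins, outs, stim_freq),
        snr_db = ssvep_snr(outs, stim_freq),
        mean_coherence = mean(coh$coherence),
        cca_pred_hz = pred)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 cca_accuracy = cca_hit / n_records,
                 provenance = list(config = config, seed = seed,
                                   stim_freq = stim_freq,
                                   n_records = n_records,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "adaptref")))),
            class = "ssvep_report")
}

#' @export
print.ssvep_report <- function(x, ...) {
  cat("SSVEP preservation report (paired WAR vs Ad WAR)\n")
  ag <- stats::aggregate(cbind(attenuation_db, snr_db, mean_coherence) ~
                           filter, data = x$table, FUN = mean)
  print(ag, row.names = FALSE)
  cat("  CCA accuracy: WAR", x$cca_accuracy[["war"]],
      " Ad WAR", x$cca_accuracy[["ad_war"]], "\n")
  invisible(x)
}
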