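#' Spatial filter configuration
#'
#' Bundles the tunable parameters of the reference filters.  Defaults are
#' the fitted operating point: virtual-distance coefficient `w1 = 5` with a
#' similarity window of 100 ms, dispersion cap ratio 10, and
#' amplitude-correction correlation cutoff 0.85.
#'
#' @param mode filter mode: adaptive (`"ad_lar_small"`, `"ad_lar_large"`,
#'   `"ad_war"`) or baseline (`"lar_small"`, `"lar_large"`, `"war"`).
#' @param w1 virtual-distance coefficient (> 0).
#' @param window_ms similarity window Wf in milliseconds (> 0).
#' @param cap_ratio cap on the running dispersion ratio (see
#'   [vstd_threshold()]).
#' @param r_cut Pearson-correlation cutoff of the amplitude-correction
#'   stage, in (0, 1\].
#' @param ccc_tol closeness tolerance of the similarity threshold.
#' @param warmup_policy output policy while the similarity window is
#'   filling: `"baseline_weights"` (distance-weighted reference, default) or
#'   `"passthrough"` (unfiltered target).
#' @param unit_distance use unit inter-electrode distances for the baseline
#'   weights instead of montage positions (only relative weights matter).
#' @param eps floor on the running dispersion minimum (microvolts).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(mode = c("ad_war", "ad_lar_small", "ad_lar_large",
                                   "war", "lar_small", "lar_large"),
                          w1 = 5, window_ms = 100, cap_ratio = 10,
                          r_cut = 0.85, ccc_tol = 0.05,
                          warmup_policy = c("baseline_weights", "passthrough"),
                          unit_distance = FALSE, eps = 1e-6) {
  mode <- match.arg(mode)
  warmup_policy <- match.arg(warmup_policy)
  stopifnot(w1 > 0, window_ms > 0, r_cut > 0, r_cut <= 1, cap_ratio > 1,
            ccc_tol >= 0, eps > 0)
  structure(list(mode = mode, w1 = w1, window_ms = window_ms,
                 cap_ratio = cap_ratio, r_cut = r_cut, ccc_tol = ccc_tol,
                 warmup_policy = warmup_policy,
                 unit_distance = unit_distance, eps = eps),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Spatial filter configuration\n")
  cat(sprintf("  mode: %s   w1: %g   Wf: %g ms\n", x$mode, x$w1, x$window_ms))
  cat(sprintf("  cap_ratio: %g   r_cut: %g   ccc_tol: %g   warmup: %s\n",
              x$cap_ratio, x$r_cut, x$ccc_tol, x$warmup_policy))
  invisible(x)
}

is_adaptive <- function(mode) grepl("^ad_", mode)
base_mode <- function(mode) sub("^ad_", "", mode)

#' Similarity-derived virtual distance
#'
#' \eqn{VD = \exp(-w_1 \rho_c)}: strictly decreasing in the concordance
#' correlation, equal to 1 at \eqn{\rho_c = 0}.  Neighbors highly concordant
#' with the target are "virtually close" and receive small weight, so neural
#' information localized around the target survives the reference
#' subtraction.
#'
#' @param ccc_value concordance correlation in \[-1, 1\].
#' @param w1 positive coefficient (fitted default 5).
#' @return Positive scalar.
#' @export
virtual_distance <- function(ccc_value, w1 = 5) {
  stopifnot(w1 > 0)
  exp(-w1 * ccc_value)
}

# Normalized virtual-distance weights from CCC values (max-subtraction for
# numerical stability; identical to VD / sum(VD)).
vd_weights <- function(ccc_values, w1) {
  a <- -w1 * ccc_values
  e <- exp(a - max(a))
  e / sum(e)
}

#' Inverse-distance baseline weights
#'
#' Classic LAR/WAR weighting: \eqn{g_{ij} = (1/d_{ij}) / \sum_j (1/d_{ij})}
#' over the mode's neighbor set, so the weights sum to one.
#'
#' @param montage an [electrode_montage].
#' @param target target electrode label.
#' @param mode `"lar_small"`, `"lar_large"` or `"war"`.
#' @param unit_distance if `TRUE`, ignore positions and weight neighbors
#'   equally.
#' @return Named numeric vector of weights over the neighbor set.
#' @export
baseline_weights <- function(montage, target,
                             mode = c("lar_small", "lar_large", "war"),
                             unit_distance = FALSE) {
  mode <- match.arg(base_mode(mode),
                    c("lar_small", "lar_large", "war"))
  nb <- neighbor_set(montage, target, mode)
  if (unit_distance || is.null(montage$positions)) {
    w <- rep(1 / length(nb), length(nb))
  } else {
    d <- vapply(nb, function(j) electrode_distance(montage, target, j),
                numeric(1))
    if (any(d == 0))
      stop("coincident electrodes (zero distance) in neighbor set of '",
           target, "'")
    w <- (1 / d) / sum(1 / d)
  }
  names(w) <- nb
  w
}

#' Amplitude correction for the current sample
#'
#' Applied only when the dispersion of the selected set still exceeds the
#' adaptive threshold: the per-sample dispersion ([vstd]) is recomputed over
#' `SS` (selected neighbors plus the target, target first), and -- because
#' the adaptive threshold is itself a function of the current dispersion --
#' the threshold is re-evaluated at the updated value
#' ([vstd_threshold] with the running extremes).  Excluding an
#' artifact-bearing neighbor is thus enough to leave the remaining
#' amplitudes untouched; corrections engage only when the artifact remains
#' inside the selected set (for instance on the target itself).  When the
#' recomputed dispersion exceeds the recomputed threshold: for each
#' electrode `e` in `SS`, pairwise Pearson correlations with the other
#' members are computed on the current similarity window and `Se` is the
#' set of members whose correlation with `e` is at least `r_cut` (always
#' including `e` itself); the correction for `e` is the median of the
#' current-sample amplitudes over `Se` when `Se` has at least two members,
#' and over all of `SS` when no partner reaches the cutoff (a singleton
#' `Se` median would simply return the electrode's own value and null its
#' signal).  With a singleton `SS` the correction is zero.
#'
#' @param values_ss named current-sample amplitudes over `SS`, target first.
#' @param windows_ss numeric matrix (window samples x `SS` electrodes),
#'   columns aligned with `values_ss`.
#' @param vstd_min,vstd_max running dispersion extremes for this target.
#' @param cap_ratio cap on the dispersion ratio (see [vstd_threshold()]).
#' @param r_cut correlation cutoff (default 0.85).
#' @return Named numeric vector of corrections over `SS`.
#' @export
amplitude_correction <- function(values_ss, windows_ss, vstd_min, vstd_max,
                                 cap_ratio = 10, r_cut = 0.85) {
  p <- length(values_ss)
  ac <- rep(0, p)
  names(ac) <- names(values_ss)
  if (p < 2L) return(ac)
  v_ss <- vstd(values_ss, target = 1L)
  th_ss <- vstd_threshold(v_ss, vstd_min, vstd_max, cap_ratio)
  if (!(v_ss > th_ss)) return(ac)
  R <- suppressWarnings(stats::cor(windows_ss))
  R[!is.finite(R)] <- 0  # constant columns: treat as uncorrelated
  diag(R) <- 1
  med_all <- fast_median(values_ss)
  for (e in seq_len(p)) {
    se <- which(R[e, ] >= r_cut)  # includes e (diagonal = 1)
    ac[e] <- if (length(se) >= 2L) fast_median(values_ss[se]) else med_all
  }
  ac
}

#' Initialize streaming filter state
#'
#' @param montage an [electrode_montage].
#' @param targets target electrode labels.
#' @param config a [filter_config].
#' @param fs sampling rate in Hz.
#' @return An object of class `filter_state` to be threaded through
#'   [filter_step()].
#' @export
filter_state <- function(montage, targets, config, fs) {
  stopifnot(inherits(montage, "electrode_montage"),
            inherits(config, "filter_config"), fs > 0)
  n <- max(2L, round(config$window_ms * fs / 1000))
  per_target <- lapply(targets, function(tg) {
    list(candidates = neighbor_set(montage, tg, config$mode),
         baseline = baseline_weights(montage, tg, base_mode(config$mode),
                                     unit_distance = config$unit_distance),
         sel_state = selection_state(eps = config$eps))
  })
  names(per_target) <- targets
  structure(list(montage = montage, targets = targets, config = config,
                 fs = fs, n = n,
                 buffer = matrix(numeric(0), 0, length(montage$electrodes),
                                 dimnames = list(NULL, montage$electrodes)),
                 counter = 0L, per_target = per_target),
            class = "filter_state")
}

#' Advance the streaming filter by one sample
#'
#' Appends the sample to the ring buffer and produces one filtered value per
#' target.  During warm-up (fewer than Wf samples buffered) the configured
#' warm-up policy applies and the output is flagged.  After warm-up, for each
#' target: CCC to each candidate neighbor over the current window, neighbor
#' selection, virtual-distance weights over the selected set, amplitude
#' correction, and the weighted common-reference subtraction
#' \deqn{(V_i - AC_i) - \sum_j g_{ij} (V_j - AC_j).}
#' Selected neighbors with lower CCC receive higher weight.
#'
#' @param state a [filter_state]; returned updated.
#' @param new_sample named numeric vector of per-channel amplitudes
#'   (microvolts) covering all montage electrodes.
#' @return List with elements `state` (updated) and `output`, a list of class
#'   `filter_output` per target carrying `value`, `weights`, `ac`,
#'   `selection`, and `warmup`.
#' @export
filter_step <- function(state, new_sample) {
  stopifnot(inherits(state, "filter_state"))
  chans <- colnames(state$buffer)
  if (is.null(names(new_sample))) {
    if (length(new_sample) != length(chans))
      stop("sample has ", length(new_sample), " channels; montage has ",
           length(chans))
    names(new_sample) <- chans
  }
  if (!all(chans %in% names(new_sample)))
    stop("sample is missing montage channels")
  new_sample <- new_sample[chans]
  n <- state$n
  buf <- rbind(state$buffer, new_sample, deparse.level = 0)
  if (nrow(buf) > n) buf <- buf[seq.int(nrow(buf) - n + 1L, nrow(buf)), ,
                                drop = FALSE]
  state$buffer <- buf
  state$counter <- state$counter + 1L
  warm <- state$counter < n
  adaptive <- is_adaptive(state$config$mode)
  cfg <- state$config
  out <- lapply(state$targets, function(tg) {
    pt <- state$per_target[[tg]]
    cand <- pt$candidates
    vi <- new_sample[[tg]]
    vj <- new_sample[cand]
    if (!adaptive) {
      val <- vi - sum(pt$baseline * vj)
      return(structure(list(value = unname(val), weights = pt$baseline,
                            ac = NULL, selection = NULL, warmup = FALSE),
                       class = "filter_output"))
    }
    # running dispersion extremes track every sample, warm-up included
    if (warm) {
      v <- vstd(c(vi, vj), target = 1L)
      state$per_target[[tg]]$sel_state <<-
        update_selection_state(pt$sel_state, v)
      val <- if (cfg$warmup_policy == "passthrough") vi else
        vi - sum(pt$baseline[cand] * vj)
      return(structure(list(value = unname(val), weights = pt$baseline,
                            ac = NULL, selection = NULL, warmup = TRUE),
                       class = "filter_output"))
    }
    cc <- ccc_to_neighbors(buf, tg, cand, n = n)
    sel <- select_neighbors(c(vi, vj), cc, pt$sel_state,
                            cap_ratio = cfg$cap_ratio, ccc_tol = cfg$ccc_tol)
    state$per_target[[tg]]$sel_state <<- sel$state
    keep <- sel$selected
    g <- vd_weights(cc[keep], cfg$w1)
    names(g) <- cand[keep]
    ss_labels <- c(tg, cand[keep])
    acv <- amplitude_correction(
      stats::setNames(new_sample[ss_labels], ss_labels),
      buf[, ss_labels, drop = FALSE],
      vstd_min = sel$state$vstd_min, vstd_max = sel$state$vstd_max,
      cap_ratio = cfg$cap_ratio, r_cut = cfg$r_cut)
    val <- (vi - acv[[tg]]) -
      sum(g * (vj[keep] - acv[cand[keep]]))
    structure(list(value = unname(val), weights = g, ac = acv,
                   selection = sel, warmup = FALSE),
              class = "filter_output")
  })
  names(out) <- state$targets
  list(state = state, output = out)
}

#' Filter a whole multichannel record (batch)
#'
#' Vectorized batch equivalent of iterating [filter_step()]: output sample t
#' depends only on input samples at or before t (causal), and the result is
#' sample-for-sample identical to the streaming path.
#'
#' @param record numeric matrix (samples x channels) with column names
#'   matching the montage electrode labels, amplitudes in microvolts.
#' @param montage an [electrode_montage].
#' @param targets target electrode labels (default: the montage's declared
#'   targets).
#' @param config a [filter_config].
#' @param fs sampling rate in Hz.
#' @return Object of class `filtered_record`: list with `filtered`
#'   (samples x targets matrix), `diagnostics` (per-target data.frame with
#'   per-sample dispersion, thresholds, selection counts and flags), plus
#'   `targets`, `config`, `fs`.
#' @export
filter_record <- function(record, montage, targets = montage$targets,
                          config = filter_config(), fs) {
  stopifnot(inherits(montage, "electrode_montage"),
            inherits(config, "filter_config"), fs > 0)
  record <- as.matrix(record)
  if (is.null(colnames(record)))
    stop("`record` must have channel-labeled columns")
  missing_ch <- setdiff(montage$electrodes, colnames(record))
  if (length(missing_ch))
    stop("record lacks montage channel(s): ",
         paste(missing_ch, collapse = ", "))
  unknown <- setdiff(targets, montage$electrodes)
  if (length(unknown))
    stop("unknown target label(s): ", paste(unknown, collapse = ", "))
  T_ <- nrow(record)
  n <- max(2L, round(config$window_ms * fs / 1000))
  adaptive <- is_adaptive(config$mode)
  filtered <- matrix(NA_real_, T_, length(targets),
                     dimnames = list(NULL, targets))
  diagnostics <- vector("list", length(targets))
  names(diagnostics) <- targets
  for (tg in targets) {
    cand <- neighbor_set(montage, tg, config$mode)
    gb <- baseline_weights(montage, tg, base_mode(config$mode),
                           unit_distance = config$unit_distance)
    xi <- record[, tg]
    Vn <- record[, cand, drop = FALSE]
    if (!adaptive) {
      filtered[, tg] <- xi - as.vector(Vn %*% gb)
      diagnostics[[tg]] <- data.frame(sample = seq_len(T_), warmup = FALSE,
                                      vstd = NA_real_, vstd_th = NA_real_,
                                      all_pass = NA, n_selected = length(cand),
                                      fallback = FALSE)
      next
    }
    J <- length(cand)
    CC <- vapply(cand, function(j) rolling_ccc(xi, record[, j], n),
                 numeric(T_))
    if (T_ == 1L) CC <- matrix(CC, nrow = 1L)
    v <- sqrt(rowSums((Vn - xi)^2) / J)
    vmin <- pmax(cummin(v), config$eps)
    vmax <- pmax(cummax(v), config$eps)
    m <- pmin(vmax, config$cap_ratio * vmin)
    th <- ifelse(m <= 2 * vmin, Inf,
                 2 * vmin + (m - vmin) * (m - v) / (m - 2 * vmin))
    all_pass <- v < th
    out <- numeric(T_)
    n_selected <- rep(J, T_)
    fallback <- rep(FALSE, T_)
    warm_idx <- seq_len(min(n - 1L, T_))
    out[warm_idx] <- if (config$warmup_policy == "passthrough")
      xi[warm_idx] else
      xi[warm_idx] - as.vector(Vn[warm_idx, , drop = FALSE] %*% gb)
    if (T_ >= n) {
      post <- n:T_
      ap <- post[all_pass[post]]
      if (length(ap)) {
        # same stabilization offset as vd_weights() so both paths agree
        CCap <- CC[ap, , drop = FALSE]
        A <- exp(-config$w1 * sweep(CCap, 1, apply(CCap, 1, min)))
        G <- A / rowSums(A)
        out[ap] <- xi[ap] - rowSums(G * Vn[ap, , drop = FALSE])
      }
      for (t in post[!all_pass[post]]) {
        rows <- seq.int(t - n + 1L, t)
        # exact windowed recomputation: the rolling cumulative-sum values
        # differ from the streaming path in the last bit, which could flip
        # strict threshold comparisons and desynchronize the two paths
        cc_t <- vapply(cand, function(j)
          as.numeric(ccc(record[rows, tg], record[rows, j])), numeric(1))
        cth <- ccc_threshold(cc_t, config$ccc_tol)
        keep <- which(cc_t > cth)
        if (!length(keep)) {
          keep <- which.max(cc_t)
          fallback[t] <- TRUE
        }
        n_selected[t] <- length(keep)
        g <- vd_weights(cc_t[keep], config$w1)
        ss_labels <- c(tg, cand[keep])
        acv <- amplitude_correction(
          stats::setNames(record[t, ss_labels], ss_labels),
          record[rows, ss_labels, drop = FALSE],
          vstd_min = vmin[t], vstd_max = vmax[t],
          cap_ratio = config$cap_ratio, r_cut = config$r_cut)
        out[t] <- (xi[t] - acv[[tg]]) -
          sum(g * (record[t, cand[keep]] - acv[cand[keep]]))
      }
    }
    filtered[, tg] <- out
    diagnostics[[tg]] <- data.frame(
      sample = seq_len(T_),
      warmup = seq_len(T_) < n,
      vstd = v, vstd_th = th, all_pass = all_pass,
      n_selected = ifelse(seq_len(T_) < n, NA_integer_, n_selected),
      fallback = fallback)
  }
  structure(list(filtered = filtered, diagnostics = diagnostics,
                 targets = targets, config = config, fs = fs),
            class = "filtered_record")
}

#' @export
print.filtered_record <- function(x, ...) {
  cat("Filtered EEG record:", nrow(x$filtered), "samples x",
      ncol(x$filtered), "target(s) at", x$fs, "Hz\n")
  cat("  mode:", x$config$mode, "\n")
  for (tg in x$targets) {
    d <- x$diagnostics[[tg]]
    post <- d[!d$warmup, , drop = FALSE]
    if (nrow(post) && !all(is.na(post$all_pass)))
      cat(sprintf("  %s: all-pass on %.1f%% of post-warm-up samples\n",
                  tg, 100 * mean(post$all_pass)))
  }
  invisible(x)
}
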