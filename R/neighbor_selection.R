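# Median without method dispatch or NA handling; hot path of the per-sample
# selective branch.
fast_median <- function(x) {
  n <- length(x)
  h <- (n + 1L) %/% 2L
  if (n %% 2L) sort(x, partial = h)[h]
  else { s <- sort(x, partial = c(h, h + 1L)); (s[h] + s[h + 1L]) / 2 }
}

#' Per-sample amplitude dispersion around the target electrode
#'
#' Standard deviation of the current sample's amplitudes relative to the
#' target,
#' \deqn{V_{std} = \sqrt{\sum_{j=1}^N (V_j - V_i)^2 / (N - 1)},}
#' where the sum runs over all \eqn{N} electrodes (target included; its term
#' is zero).  Large values indicate a transient or artifact somewhere in the
#' neighborhood and switch the filter into its selective branch.
#'
#' @param sample_values numeric vector of per-electrode amplitudes at the
#'   current sample (target plus neighbors), length >= 2.
#' @param target index of the target electrode within `sample_values`.
#' @return Nonnegative scalar.
#' @export
vstd <- function(sample_values, target = 1L) {
  n <- length(sample_values)
  if (n < 2L) stop("vstd requires at least 2 electrodes")
  sqrt(sum((sample_values - sample_values[target])^2) / (n - 1))
}

#' Adaptive dispersion threshold
#'
#' Maps the current dispersion onto a threshold between the running extremes:
#' with \eqn{M^* = \min(V_{max}, \mathrm{cap} \cdot V_{min})},
#' \deqn{V_{TH} = 2 V_{min} + (M^* - V_{min}) \frac{M^* - V_{std}}{M^* - 2 V_{min}}.}
#' Dispersion near the running maximum drives the threshold down toward
#' \eqn{2 V_{min}} (selective), dispersion near the minimum drives it up
#' (permissive).  The cap \eqn{V_{max} \le \mathrm{cap} \cdot V_{min}}
#' prevents a single huge artifact from making the threshold sticky.
#' If \eqn{M^* \le 2 V_{min}} the mapping degenerates and the function
#' returns `Inf` (accept-all) with attribute `degenerate = TRUE`.
#'
#' @param vstd_ik current dispersion ([vstd]).
#' @param vstd_min,vstd_max running extremes of the dispersion for this
#'   target (`vstd_min` floored at a small positive epsilon upstream).
#' @param cap_ratio cap on `vstd_max / vstd_min` (default 10).
#' @return Scalar threshold (possibly `Inf`).
#' @export
vstd_threshold <- function(vstd_ik, vstd_min, vstd_max, cap_ratio = 10) {
  m <- min(vstd_max, cap_ratio * vstd_min)
  if (m <= 2 * vstd_min)
    return(structure(Inf, degenerate = TRUE))
  2 * vstd_min + (m - vstd_min) * (m - vstd_ik) / (m - 2 * vstd_min)
}

#' Similarity threshold over the neighbor CCC values
#'
#' With \eqn{\rho_{cM}} the median CCC and \eqn{D} the median absolute
#' deviation of the CCC values from it: returns
#' \eqn{\rho_{cM} - D - tol} when \eqn{D \le tol} (values very close; keep
#' all neighbors), else \eqn{\rho_{cM} - D}.
#'
#' @param ccc_values numeric vector of per-neighbor CCC values (>= 1).
#' @param tol closeness tolerance (default 0.05).
#' @return Scalar threshold.
#' @export
ccc_threshold <- function(ccc_values, tol = 0.05) {
  if (!length(ccc_values)) stop("need at least one neighbor CCC value")
  m <- fast_median(ccc_values)
  d <- fast_median(abs(m - ccc_values))
  if (d <= tol) m - d - tol else m - d
}

#' Initialize the per-target selection state
#'
#' Holds the running dispersion extremes.  `eps` floors `vstd_min` so the
#' threshold mapping never divides by a vanishing range.
#'
#' @param eps minimum admissible `vstd_min` (microvolts).
#' @return An object of class `selection_state`.
#' @export
selection_state <- function(eps = 1e-6) {
  structure(list(vstd_min = Inf, vstd_max = -Inf, eps = eps, n_updates = 0L),
            class = "selection_state")
}

update_selection_state <- function(state, vstd_ik) {
  state$vstd_min <- max(min(state$vstd_min, vstd_ik), state$eps)
  state$vstd_max <- max(state$vstd_max, vstd_ik, state$eps)
  state$n_updates <- state$n_updates + 1L
  state
}

#' Select admissible neighbor electrodes for one output sample
#'
#' Stage 1 of the adaptive filter.  The current dispersion is computed and
#' folded into the running extremes; if it stays below the adaptive
#' threshold every candidate neighbor is kept (`all_pass`), otherwise only
#' neighbors whose CCC to the target exceeds the similarity threshold
#' survive.  If none survives, the single neighbor of maximal CCC is kept
#' and flagged (`fallback`), preserving output continuity.
#'
#' @param sample_values named amplitudes at the current sample: target first,
#'   then the candidate neighbors (order defines `ccc_values` order).
#' @param ccc_values per-neighbor CCC values (same order as the neighbors in
#'   `sample_values[-1]`).
#' @param state a [selection_state]; updated and returned.
#' @param cap_ratio,ccc_tol see [vstd_threshold()] and [ccc_threshold()].
#' @return List of class `selection_result`: `selected` (indices into the
#'   neighbor vector), `vstd_ik`, `vstd_th`, `ccc_values`, `ccc_th`,
#'   `all_pass`, `fallback`, and the updated `state`.
#' @export
select_neighbors <- function(sample_values, ccc_values, state,
                             cap_ratio = 10, ccc_tol = 0.05) {
  n_nb <- length(sample_values) - 1L
  if (n_nb < 1L) stop("need at least one candidate neighbor")
  if (length(ccc_values) != n_nb)
    stop("`ccc_values` length must match the number of neighbors")
  v <- vstd(sample_values, target = 1L)
  state <- update_selection_state(state, v)
  th <- vstd_threshold(v, state$vstd_min, state$vstd_max, cap_ratio)
  all_pass <- v < th
  fallback <- FALSE
  cth <- NA_real_
  if (all_pass) {
    selected <- seq_len(n_nb)
  } else {
    cth <- ccc_threshold(ccc_values, ccc_tol)
    selected <- which(ccc_values > cth)
    if (!length(selected)) {
      selected <- which.max(ccc_values)
      fallback <- TRUE
    }
  }
  structure(list(selected = selected, vstd_ik = v, vstd_th = as.numeric(th),
                 ccc_values = ccc_values, ccc_th = cth,
                 all_pass = all_pass, fallback = fallback, state = state),
            class = "selection_result")
}
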