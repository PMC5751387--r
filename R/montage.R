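#' Electrode montage
#'
#' Container for electrode geometry and neighbor topology used by the spatial
#' filters.  A montage holds electrode labels (10-20 nomenclature), optional
#' 3D positions (arbitrary consistent units), explicit nearest-neighbor
#' (\code{neighbors_small}) and next-nearest-neighbor (\code{neighbors_large})
#' sets per target, and an optional per-target override of the WAR neighbor
#' set (\code{neighbors_war}); by default WAR uses every other electrode of
#' the montage.
#'
#' @param electrodes character vector of electrode labels.
#' @param positions numeric matrix with one row per electrode and columns
#'   x, y, z, or \code{NULL} if positions are unavailable (filters then
#'   require unit distances).
#' @param neighbors_small,neighbors_large named lists mapping an electrode
#'   label to a character vector of neighbor labels.
#' @param neighbors_war optional named list overriding the default
#'   all-but-target WAR neighbor rule for specific targets.
#' @param targets character vector of electrode labels designated as filter
#'   targets; each must have a non-empty small neighbor set.
#' @param reference_note free text describing the recording reference.
#'
#' @return An object of class \code{electrode_montage}.
#' @export
electrode_montage <- function(electrodes, positions = NULL,
                              neighbors_small = list(),
                              neighbors_large = list(),
                              neighbors_war = NULL,
                              targets = character(),
                              reference_note = "") {
  electrodes <- as.character(electrodes)
  if (anyDuplicated(electrodes))
    stop("duplicate electrode labels in montage")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != length(electrodes) || ncol(positions) != 3L)
      stop("`positions` must be a ", length(electrodes), " x 3 matrix")
    if (!all(is.finite(positions)))
      stop("`positions` contains non-finite values")
    rownames(positions) <- electrodes
  }
  check_nbrs <- function(nb, what) {
    if (is.null(nb)) return(list())
    if (length(nb) && is.null(names(nb)))
      stop("`", what, "` must be a named list")
    for (el in names(nb)) {
      if (!el %in% electrodes)
        stop("`", what, "`: '", el, "' is not an electrode of the montage")
      nb[[el]] <- as.character(nb[[el]])
      unknown <- setdiff(nb[[el]], electrodes)
      if (length(unknown))
        stop("`", what, "` for '", el, "' references unknown electrode(s): ",
             paste(unknown, collapse = ", "))
      if (el %in% nb[[el]])
        stop("`", what, "`: '", el, "' lists itself as a neighbor")
      if (anyDuplicated(nb[[el]]))
        stop("`", what, "` for '", el, "' has duplicate entries")
    }
    nb
  }
  neighbors_small <- check_nbrs(neighbors_small, "neighbors_small")
  neighbors_large <- check_nbrs(neighbors_large, "neighbors_large")
  neighbors_war <- check_nbrs(neighbors_war, "neighbors_war")
  targets <- as.character(targets)
  unknown <- setdiff(targets, electrodes)
  if (length(unknown))
    stop("unknown target electrode(s): ", paste(unknown, collapse = ", "))
  for (tg in targets) {
    if (!length(neighbors_small[[tg]]))
      stop("target '", tg, "' has an empty small neighbor set")
  }
  structure(list(electrodes = electrodes, positions = positions,
                 neighbors_small = neighbors_small,
                 neighbors_large = neighbors_large,
                 neighbors_war = neighbors_war,
                 targets = targets,
                 reference_note = as.character(reference_note)),
            class = "electrode_montage")
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat("Electrode montage:", length(x$electrodes), "electrodes",
      if (is.null(x$positions)) "(no positions)" else "(with positions)", "\n")
  cat("  electrodes:", paste(x$electrodes, collapse = ", "), "\n")
  if (length(x$targets))
    cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  if (nzchar(x$reference_note))
    cat("  reference:", x$reference_note, "\n")
  invisible(x)
}

#' Load a montage from a YAML file
#'
#' The file must contain an `electrodes` array (entries with `label` and
#' optionally `x`, `y`, `z`) and may contain `neighbors_small`,
#' `neighbors_large`, `neighbors_war`, `targets`, and `reference_note`.
#' Two montages ship with the package under `inst/extdata`:
#' `montage_gait_1020.yaml` (motor-cortex montage with Cz/CP1/CP2 targets)
#' and `montage_occipital.yaml` (occipital/parietal SSVEP montage).
#'
#' @param path path to the montage YAML file.
#' @return An [electrode_montage] object.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("failed to parse montage file '",
                                           path, "': ", conditionMessage(e)))
  if (is.null(doc$electrodes))
    stop("montage file missing required field `electrodes`")
  labels <- vapply(doc$electrodes, function(e) {
    if (is.null(e$label)) stop("montage `electrodes` entry missing `label`")
    as.character(e$label)
  }, character(1))
  has_pos <- all(vapply(doc$electrodes,
                        function(e) !is.null(e$x) && !is.null(e$y) &&
                          !is.null(e$z), logical(1)))
  positions <- NULL
  if (has_pos) {
    positions <- t(vapply(doc$electrodes,
                          function(e) c(e$x, e$y, e$z), numeric(3)))
  }
  electrode_montage(
    electrodes = labels, positions = positions,
    neighbors_small = doc$neighbors_small %||% list(),
    neighbors_large = doc$neighbors_large %||% list(),
    neighbors_war = doc$neighbors_war,
    targets = unlist(doc$targets) %||% character(),
    reference_note = doc$reference_note %||% ""
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neighbor set of a target electrode
#'
#' @param montage an [electrode_montage].
#' @param target electrode label.
#' @param mode `"lar_small"` (nearest neighbors), `"lar_large"` (next-nearest
#'   neighbors) or `"war"` (all other electrodes, unless the montage declares
#'   a `neighbors_war` override for this target).  The adaptive aliases
#'   `"ad_lar_small"`, `"ad_lar_large"`, `"ad_war"` are accepted and use the
#'   same topology.
#' @return Character vector of neighbor labels (never containing the target).
#' @export
neighbor_set <- function(montage, target,
                         mode = c("lar_small", "lar_large", "war",
                                  "ad_lar_small", "ad_lar_large", "ad_war")) {
  stopifnot(inherits(montage, "electrode_montage"))
  mode <- match.arg(mode)
  mode <- sub("^ad_", "", mode)
  if (!target %in% montage$electrodes)
    stop("unknown target electrode: ", target)
  nb <- switch(mode,
    lar_small = montage$neighbors_small[[target]],
    lar_large = montage$neighbors_large[[target]],
    war = {
      ov <- montage$neighbors_war[[target]]
      if (!is.null(ov)) ov else setdiff(montage$electrodes, target)
    })
  if (is.null(nb) || !length(nb))
    stop("no ", mode, " neighbors declared for target '", target, "'")
  nb
}

#' Euclidean distance between two montage electrodes
#'
#' @param montage an [electrode_montage] with positions.
#' @param i,j electrode labels.
#' @return Nonnegative scalar distance; zero iff `i == j`.
#' @export
electrode_distance <- function(montage, i, j) {
  stopifnot(inherits(montage, "electrode_montage"))
  if (is.null(montage$positions))
    stop("montage has no electrode positions; use unit distances ",
         "(`unit_distance = TRUE` in the filter configuration)")
  for (el in c(i, j))
    if (!el %in% montage$electrodes) stop("unknown electrode: ", el)
  sqrt(sum((montage$positions[i, ] - montage$positions[j, ])^2))
}

#' Idealized 10-20 electrode positions on a unit sphere
#'
#' Positions follow the standard 10-20/10-10 great-circle construction on a
#' spherical head of unit radius.  Midline (`z`) electrodes lie on the
#' sagittal great circle at 22.5-degree steps from the vertex (rows Fp, AF,
#' F, FC, C, CP, P, PO, O).  The outermost (10%) ring runs along the equator
#' from Fpz through the ear points to Oz; each row's outer electrodes
#' (F7/F8, T7/T8, P7/P8, PO7/PO8, ...) sit on that ring at the row's
#' azimuth, and intermediate electrodes (numbers 1-6) interpolate along the
#' great-circle arc between the midline electrode and the ring point
#' (1/2 at a quarter, 3/4 at half, 5/6 at three quarters of the arc).
#' Fp1/Fp2 and O1/O2 lie on the ring 18 degrees lateral of Fpz/Oz.
#' Coordinates: x right, y anterior, z up.  These are idealized (not
#' digitized) positions; only relative distances matter to the filters.
#'
#' @param labels character vector of 10-20 labels (e.g. `"Cz"`, `"CP1"`).
#' @return Numeric matrix (length(labels) x 3) with rownames = labels.
#' @export
standard_positions_1020 <- function(labels) {
  # anterior-posterior inclination of the midline electrode (deg, + = front)
  row_angle <- c(Fp = 90, AF = 67.5, F = 45, FC = 22.5, C = 0,
                 CP = -22.5, P = -45, PO = -67.5, O = -90)
  # azimuth of the row's equator-ring point, measured from Fpz (deg)
  ring_azimuth <- c(AF = 36, F = 54, FC = 72, C = 90, CP = 108,
                    P = 126, PO = 144)
  slerp <- function(u, v, f) {
    om <- acos(max(-1, min(1, sum(u * v))))
    if (om < 1e-12) return(u)
    (sin((1 - f) * om) * u + sin(f * om) * v) / sin(om)
  }
  pos <- matrix(NA_real_, length(labels), 3,
                dimnames = list(labels, c("x", "y", "z")))
  for (lab in labels) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    if (length(m) != 3L) stop("cannot parse 10-20 label: ", lab)
    row <- m[2]; num <- m[3]
    if (!row %in% names(row_angle))
      stop("unknown 10-20 row in label: ", lab)
    alpha <- row_angle[[row]] * pi / 180
    mid <- c(0, sin(alpha), cos(alpha))
    if (num == "z") {
      pos[lab, ] <- mid
      next
    }
    k <- as.integer(num)
    side <- if (k %% 2L == 1L) -1 else 1  # odd = left
    if (row %in% c("Fp", "O")) {
      # outermost rows: electrodes on the equator ring, 18 deg steps
      psi <- (if (row == "Fp") 0 else 180) +
        (if (row == "Fp") 1 else -1) * 18 * ceiling(k / 2)
      psi <- psi * pi / 180
      pos[lab, ] <- c(side * sin(psi), cos(psi), 0)
    } else {
      psi <- ring_azimuth[[row]] * pi / 180
      ring <- c(side * sin(psi), cos(psi), 0)
      f <- ceiling(k / 2) / 4
      pos[lab, ] <- slerp(mid, ring, f)
    }
  }
  pos
}

#' Derive neighbor sets by distance rank
#'
#' Optional helper for montages without explicit neighbor declarations:
#' ranks all other electrodes by distance from the target and returns the
#' `k_small` nearest as the small set and the following `k_large` as the
#' large set.
#'
#' @param montage an [electrode_montage] with positions.
#' @param target electrode label.
#' @param k_small,k_large ring sizes.
#' @return List with elements `small` and `large` (label vectors).
#' @export
derive_neighbors <- function(montage, target, k_small = 4, k_large = 6) {
  others <- setdiff(montage$electrodes, target)
  d <- vapply(others, function(j) electrode_distance(montage, target, j),
              numeric(1))
  ord <- others[order(d)]
  list(small = ord[seq_len(min(k_small, length(ord)))],
       large = ord[seq_len(min(k_small + k_large, length(ord)))][-seq_len(
         min(k_small, length(ord)))])
}
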