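# ROI grid: six 60-degree arcs starting at the visual-dominant arc that
# wraps through 0 (330-30, 30-90, 90-150, 150-210, 210-270, 270-330) and
# five magnitude bins of width 0.2. ROI label = 6 * magnitude_bin +
# angle_bin + 1, so ROI 1 is the visual-dominant lowest-magnitude cell and
# ROI 30 the auditory-visual integrative top-magnitude cell.

angle_bin_index <- function(angle_deg) {
  # 0: 330-30 (wraps), 1: 30-90, ..., 5: 270-330; half-open [low, high)
  floor(((angle_deg + 30) %% 360) / 60)
}

magnitude_bin_index <- function(magnitude) {
  # 0: [0,0.2), ..., 4: [0.8,1.0]; magnitude 1 goes to the top bin
  pmin(floor(magnitude / 0.2), 4)
}

#' Segment a sensory map into the 30 angle-by-magnitude ROIs
#'
#' @param angle_deg per-vertex angles in degrees (or a `sensory_fit`).
#' @param magnitude per-vertex magnitudes in \[0, 1\].
#' @return Integer vector of ROI labels in 1..30 (0 for flagged/`NA`
#'   vertices).
#' @export
segment_rois <- function(angle_deg, magnitude = NULL) {
  if (inherits(angle_deg, "sensory_fit")) {
    magnitude <- angle_deg$magnitude
    angle_deg <- angle_deg$angle_deg
  }
  stopifnot(length(angle_deg) == length(magnitude))
  lab <- 6L * magnitude_bin_index(magnitude) +
    angle_bin_index(angle_deg) + 1L
  lab[is.na(angle_deg) | is.na(magnitude)] <- 0L
  as.integer(lab)
}

#' Sensory and hierarchical weights of the 30 ROIs
#'
#' Sensory weights per channel: 1 on the channel's dominant arc, 0.5 on
#' the two adjacent integrative arcs, 0 elsewhere (e.g. visual: 1 on
#' 330-30, 0.5 on 30-90 and 270-330). Hierarchical weights per magnitude
#' bin: 0.1, 0.3, 0.5, 0.7, 0.9 from the 0-0.2 bin up to the 0.8-1.0 bin.
#'
#' @return List with `sensory` (3-by-30 matrix, rows V/S/A) and
#'   `hierarchical` (length-30 vector).
#' @export
roi_weights <- function() {
  arc_of_roi <- (seq_len(30L) - 1L) %% 6L        # 0..5
  bin_of_roi <- (seq_len(30L) - 1L) %/% 6L       # 0..4
  arc_weight <- function(dominant_arc) {
    w <- numeric(6)
    w[dominant_arc + 1L] <- 1
    w[(dominant_arc + 1L) %% 6L + 1L] <- 0.5
    w[(dominant_arc - 1L) %% 6L + 1L] <- 0.5
    w
  }
  sensory <- rbind(V = arc_weight(0L)[arc_of_roi + 1L],
                   S = arc_weight(2L)[arc_of_roi + 1L],
                   A = arc_weight(4L)[arc_of_roi + 1L])
  hierarchical <- c(0.1, 0.3, 0.5, 0.7, 0.9)[bin_of_roi + 1L]
  list(sensory = sensory, hierarchical = hierarchical)
}

#' Threshold and per-term rescale a decoding z matrix
#'
#' Meta-analytic z-values at or below the threshold (strictly, survival
#' requires `z > threshold`, 2.327 by default) are zeroed; for display the
#' surviving values of each term are min-max rescaled onto \[0, 1\] (a
#' term's single survivor maps to 1). Terms with no survivors are flagged
#' and excluded from projection.
#'
#' @param z terms-by-30 numeric matrix (rownames = term names).
#' @param threshold survival threshold (default 2.327).
#' @return List with `z_thresholded`, `z_rescaled`, `flagged` (logical per
#'   term), `threshold`.
#' @export
threshold_and_rescale <- function(z, threshold = 2.327) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("z matrix must be finite", call. = FALSE)
  zt <- ifelse(z > threshold, z, 0)
  zr <- zt
  flagged <- rowSums(zt > 0) == 0L
  for (i in which(!flagged)) {
    s <- zt[i, ] > 0
    lo <- min(zt[i, s]); hi <- max(zt[i, s])
    zr[i, s] <- if (hi > lo) (zt[i, s] - lo) / (hi - lo) else 1
  }
  list(z_thresholded = zt, z_rescaled = zr, flagged = flagged,
       threshold = threshold)
}

#' Sensory angle of one functional term
#'
#' Each channel's association is the sum of the term's thresholded
#' z-values times that channel's sensory weights, divided by the count of
#' non-zero z-values; the three associations pass through the hue
#' transformation.
#'
#' @param z_term thresholded z-values over the 30 ROIs.
#' @param weights the [roi_weights()] scheme.
#' @return Angle `D` in degrees, or `NA` for an all-zero term.
#' @export
term_sensory_angle <- function(z_term, weights = roi_weights()) {
  nz <- sum(z_term > 0)
  if (nz == 0L) return(NA_real_)
  a <- as.numeric(weights$sensory %*% z_term) / nz
  hue_angle(a[1L], a[2L], a[3L])
}

#' Sensory-hierarchy magnitude of one functional term
#'
#' The averaged product of the term's thresholded z-values with the ROI
#' hierarchical weights: `m = sum(z * w_h) / #nonzero(z)`, mirroring the
#' aggregation of [term_sensory_angle()].
#'
#' @inheritParams term_sensory_angle
#' @return Raw radial value `m`, or `NA` for an all-zero term.
#' @export
term_magnitude <- function(z_term, weights = roi_weights()) {
  nz <- sum(z_term > 0)
  if (nz == 0L) return(NA_real_)
  sum(z_term * weights$hierarchical) / nz
}

#' Hexagon-corrected radius
#'
#' Rescales a polar radius so that the unit circle maps onto the hexagon
#' with vertices at 30 + 60k degrees: with `d = floor(D / 30) mod 2`,
#' `M = m * sqrt(3/4) / cos(D mod 30)` when `d = 0` and
#' `M = m * sqrt(3/4) / cos(30 - (D mod 30))` otherwise (degrees).
#' `M / m` is 60-degree periodic, 1 at hexagon vertices and `sqrt(3)/2`
#' at edge midpoints.
#'
#' @param D angular position in degrees.
#' @param m raw radial value (>= 0).
#' @return Corrected radius `M`.
#' @export
hexagon_radius <- function(D, m) {
  n <- max(length(D), length(m))
  D <- rep_len(as.numeric(D), n) %% 360
  m <- rep_len(as.numeric(m), n)
  d <- floor(D / 30) %% 2
  r <- D %% 30
  ang <- ifelse(d == 0, r, 30 - r)
  m * sqrt(3 / 4) / cos(deg2rad(ang))
}

#' Project functional terms into the hexagonal coordinate space
#'
#' Runs threshold, channel weighting, hue transformation, hierarchical
#' weighting, and the hexagon radial correction for every term, placing
#' the visual anchor at D = 0.
#'
#' @param z terms-by-30 matrix of raw z-values (rownames = term names).
#' @param threshold survival threshold (default 2.327).
#' @return Data frame with one row per unflagged term: `term`, `D`
#'   (degrees), `m`, `M`, `x`, `y`.
#' @export
project_terms <- function(z, threshold = 2.327) {
  tr <- threshold_and_rescale(z, threshold)
  zt <- tr$z_thresholded
  w <- roi_weights()
  terms <- rownames(zt)
  if (is.null(terms)) terms <- paste0("term", seq_len(nrow(zt)))
  keep <- which(!tr$flagged)
  D <- vapply(keep, function(i) term_sensory_angle(zt[i, ], w), 0)
  m <- vapply(keep, function(i) term_magnitude(zt[i, ], w), 0)
  M <- hexagon_radius(D, m)
  data.frame(term = terms[keep], D = D, m = m, M = M,
             x = M * cos(deg2rad(D)), y = M * sin(deg2rad(D)),
             stringsAsFactors = FALSE)
}

#' Read a term-by-ROI z matrix from TSV
#'
#' Expects a header row with ROI labels 1..30 and one term per row (first
#' column = term name).
#'
#' @param path input TSV.
#' @return Numeric matrix with term rownames.
#' @export
read_z_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  if (ncol(m) != 30L)
    stop("z matrix must have 30 ROI columns, got ", ncol(m), call. = FALSE)
  m
}

#' Write a term-by-ROI z matrix to TSV
#'
#' @param z terms-by-30 matrix with term rownames.
#' @param path output TSV.
#' @return The path, invisibly.
#' @export
write_z_matrix <- function(z, path) {
  df <- data.frame(term = rownames(z), z, check.names = FALSE)
  colnames(df) <- c("term", seq_len(ncol(z)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
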