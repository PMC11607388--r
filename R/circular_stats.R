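deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angular variance between two angles
#'
#' The dissimilarity used for between-state and between-hemisphere angle
#' comparison: `V = 1 - |cm|` with `cm = (exp(i*t1) + exp(i*t2)) / 2` the
#' complex mean of the two unit vectors. `V` is symmetric, lies in
#' \[0, 1\] (0 for identical angles, 1 for antipodal), and is invariant
#' under common rotation. The signed wrapped difference
#' `((t2 - t1 + 180) mod 360) - 180` is reported alongside for direction
#' display (positive = anticlockwise change from t1 to t2).
#'
#' @param theta1,theta2 numeric vectors of angles in degrees (recycled).
#' @return List with `variance_v`, `resultant_r`, `signed_delta` (degrees,
#'   in (-180, 180\]), and `cm` (complex).
#' @export
angular_variance <- function(theta1, theta2) {
  n <- max(length(theta1), length(theta2))
  t1 <- rep_len(as.numeric(theta1), n)
  t2 <- rep_len(as.numeric(theta2), n)
  cm <- (exp(1i * deg2rad(t1)) + exp(1i * deg2rad(t2))) / 2
  r <- Mod(cm)
  sd_wrapped <- (t2 - t1) %% 360
  sd_wrapped[sd_wrapped > 180] <- sd_wrapped[sd_wrapped > 180] - 360
  list(variance_v = pmin(pmax(1 - r, 0), 1),
       resultant_r = r,
       signed_delta = sd_wrapped,
       cm = cm)
}

#' Circular correlation of paired angles
#'
#' Correlation coefficient for paired angular data, invariant under
#' independent rotations of either vector, in \[-1, 1\]. The default is
#' the Fisher-Lee T-linear coefficient,
#' `sum_{i<j} sin(a_i - a_j) * sin(b_i - b_j)` over the product of the
#' root sums of squared pairwise sines, which involves no circular mean
#' and therefore remains stable when the angle distribution is balanced
#' around the circle (the typical regime for sensory angles, whose mass
#' concentrates near three anchors 120 degrees apart so the sample
#' resultant nearly vanishes). `method = "jammalamadaka"` gives the
#' Jammalamadaka-SenGupta estimator,
#' `sum(sin(a - mu_a) * sin(b - mu_b))` normalized likewise, with `mu`
#' the circular means; it is unstable when either resultant is small.
#'
#' @param theta_a,theta_b equal-length vectors of angles in degrees
#'   (length >= 3). `NA` pairs are dropped.
#' @param method `"fisher_lee"` (default) or `"jammalamadaka"`.
#' @return Correlation coefficient, or `NA` when either vector has zero
#'   circular dispersion.
#' @export
circular_correlation <- function(theta_a, theta_b,
                                 method = c("fisher_lee",
                                            "jammalamadaka")) {
  method <- match.arg(method)
  if (length(theta_a) != length(theta_b))
    stop("circular_correlation requires equal lengths", call. = FALSE)
  keep <- !is.na(theta_a) & !is.na(theta_b)
  a <- deg2rad(theta_a[keep])
  b <- deg2rad(theta_b[keep])
  n <- length(a)
  if (n < 3L)
    stop("circular_correlation needs at least 3 pairs", call. = FALSE)
  if (method == "jammalamadaka") {
    mu_a <- Arg(mean(exp(1i * a)))
    mu_b <- Arg(mean(exp(1i * b)))
    sa <- sin(a - mu_a)
    sb <- sin(b - mu_b)
    den <- sqrt(sum(sa^2) * sum(sb^2))
    if (den < 1e-12) return(NA_real_)
    return(sum(sa * sb) / den)
  }
  # Fisher-Lee via O(n) identities:
  # sum_{i!=j} sin(a_i-a_j) sin(b_i-b_j) = |sum e^{i(a-b)}|^2 -
  #   |sum e^{i(a+b)}|^2 (cross terms), and
  # sum_{i!=j} sin^2(a_i-a_j) = (n^2 - |sum e^{2ia}|^2) / 2
  num <- Mod(sum(exp(1i * (a - b))))^2 - Mod(sum(exp(1i * (a + b))))^2
  da <- max((n^2 - Mod(sum(exp(2i * a)))^2) / 2, 0)
  db <- max((n^2 - Mod(sum(exp(2i * b)))^2) / 2, 0)
  den <- sqrt(da * db)
  if (den < 1e-12) return(NA_real_)
  num / 2 / den
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values; used for sensory
#' magnitudes. Returns `NA` when either vector is constant.
#'
#' @param x,y equal-length numeric vectors (length >= 3); `NA` pairs
#'   dropped.
#' @return Rank correlation coefficient.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("spearman_correlation requires equal lengths", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L)
    stop("spearman_correlation needs at least 3 pairs", call. = FALSE)
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) return(NA_real_)
  stats::cor(x[keep], y[keep], method = "spearman")
}

#' Paired-sample t test
#'
#' Classical paired t on the differences (df = n - 1), used to compare
#' cluster-mean sensory parameters between states or hemispheres.
#' Zero-variance nonzero differences yield a signed infinite-t sentinel
#' with p = 0; all-zero differences give t = 0, p = 1.
#'
#' @param values_a,values_b paired per-subject scalars (n >= 3).
#' @return List with `t`, `p` (two-sided), `df`, `mean_diff`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired_t requires paired vectors", call. = FALSE)
  n <- length(values_a)
  if (n < 3L) stop("paired_t needs n >= 3", call. = FALSE)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                mean_diff = mean(d)))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = unname(ht$estimate))
}

#' Per-subject difference maps between two states
#'
#' For every subject and vertex, the angular variance between the two
#' state angles (the sign-flip test's input for angle contrasts), the
#' signed wrapped angle difference (for direction display), and, when
#' magnitudes are supplied, the signed magnitude difference `a - b` (the
#' sign-flip input for magnitude contrasts).
#'
#' @param angles_a,angles_b subjects-by-vertices matrices of degrees.
#' @param magnitudes_a,magnitudes_b optional subjects-by-vertices matrices.
#' @return List with `variance_v`, `signed_delta`, and (optionally)
#'   `magnitude_diff`, each subjects-by-vertices.
#' @export
state_difference_maps <- function(angles_a, angles_b,
                                  magnitudes_a = NULL, magnitudes_b = NULL) {
  angles_a <- as.matrix(angles_a); angles_b <- as.matrix(angles_b)
  if (!all(dim(angles_a) == dim(angles_b)))
    stop("state angle maps must be aligned subjects x vertices",
         call. = FALSE)
  av <- angular_variance(angles_a, angles_b)
  out <- list(variance_v = matrix(av$variance_v, nrow(angles_a)),
              signed_delta = matrix(av$signed_delta, nrow(angles_a)))
  if (!is.null(magnitudes_a)) {
    magnitudes_a <- as.matrix(magnitudes_a)
    magnitudes_b <- as.matrix(magnitudes_b)
    if (!all(dim(magnitudes_a) == dim(angles_a)) ||
        !all(dim(magnitudes_b) == dim(angles_a)))
      stop("magnitude maps must align with angle maps", call. = FALSE)
    out$magnitude_diff <- magnitudes_a - magnitudes_b
  }
  out
}

#' Reliability correlation table between sessions
#'
#' Mirrors the reliability analysis: circular correlation for the angle
#' maps and Spearman correlation for the magnitude maps of every dataset
#' pair.
#'
#' @param angle_maps named list of per-dataset angle vectors (degrees).
#' @param magnitude_maps named list of per-dataset magnitude vectors,
#'   same names.
#' @return List of two symmetric correlation matrices, `angle` and
#'   `magnitude`.
#' @export
reliability_table <- function(angle_maps, magnitude_maps) {
  stopifnot(identical(names(angle_maps), names(magnitude_maps)))
  k <- length(angle_maps)
  ang <- mag <- matrix(1, k, k, dimnames = list(names(angle_maps),
                                                names(angle_maps)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    ang[i, j] <- ang[j, i] <-
      circular_correlation(angle_maps[[i]], angle_maps[[j]])
    mag[i, j] <- mag[j, i] <-
      spearman_correlation(magnitude_maps[[i]], magnitude_maps[[j]])
  }
  list(angle = ang, magnitude = mag)
}

#' @rdname angular_variance
#' @details `angular_variance_v()` returns just the variance component.
#' @export
angular_variance_v <- function(theta1, theta2) {
  angular_variance(theta1, theta2)$variance_v
}
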