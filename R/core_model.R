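#' Mean time series of a primary sensory group
#'
#' Unweighted mean across the group's member vertices at each timepoint.
#' The somatosensory group spans the union of areas 1, 2, 3a, and 3b.
#'
#' @param dataset a [surface_dataset()].
#' @param parc a [parcellation()] aligned to the dataset.
#' @param group `"V1"`, `"S1"`, or `"A1"`.
#' @return Numeric vector of length `ncol(dataset$data)`.
#' @export
mean_parcel_signal <- function(dataset, parc, group) {
  idx <- group_vertices(parc, group)
  colMeans(dataset$data[idx, , drop = FALSE])
}

#' Extract the three primary sensory predictor series
#'
#' @inheritParams mean_parcel_signal
#' @return An object of class `primary_signals`: list with standardized-unit
#'   series `t_V`, `t_S`, `t_A`.
#' @export
primary_signals <- function(dataset, parc) {
  sig <- list(t_V = mean_parcel_signal(dataset, parc, "V1"),
              t_S = mean_parcel_signal(dataset, parc, "S1"),
              t_A = mean_parcel_signal(dataset, parc, "A1"))
  validate_primary_signals(sig)
}

validate_primary_signals <- function(sig) {
  lens <- vapply(sig, length, 0L)
  if (length(unique(lens)) != 1L)
    stop("primary signals must have equal lengths", call. = FALSE)
  if (any(!vapply(sig, function(s) all(is.finite(s)), TRUE)))
    stop("primary signals must be finite", call. = FALSE)
  if (any(vapply(sig, stats::sd, 0) == 0))
    stop("primary signals must have nonzero variance", call. = FALSE)
  structure(sig, class = "primary_signals")
}

signals_matrix <- function(signals) {
  cbind(t_V = signals$t_V, t_S = signals$t_S, t_A = signals$t_A)
}

#' Non-negative least squares fit of one vertex series
#'
#' Minimizes `sum((y - bV*t_V - bS*t_S - bA*t_A)^2)` subject to all three
#' coefficients being non-negative (Lawson-Hanson active set, via
#' [pracma::lsqnonneg()]). No intercept: series are standardized.
#'
#' @param y numeric vertex time series.
#' @param signals a [primary_signals()] object (or 3-column matrix).
#' @return List with `beta` (named length-3 vector), `fitted`, `residual`,
#'   and `degenerate` (`TRUE` when the predictor matrix is rank deficient).
#' @export
fit_nnls <- function(y, signals) {
  X <- if (inherits(signals, "primary_signals")) signals_matrix(signals)
       else as.matrix(signals)
  if (length(y) != nrow(X))
    stop("series length (", length(y), ") must match predictors (",
         nrow(X), ")", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("fit_nnls requires finite inputs", call. = FALSE)
  degenerate <- qr(X)$rank < ncol(X)
  beta <- pracma::lsqnonneg(X, as.numeric(y))$x
  fitted <- as.numeric(X %*% beta)
  list(beta = stats::setNames(beta, c("beta_V", "beta_S", "beta_A")),
       fitted = fitted, residual = as.numeric(y) - fitted,
       degenerate = degenerate)
}

#' Per-vertex proportion of variance explained by the primary signals
#'
#' `ss_total = sum((y - y_bar)^2)`, `ss_exp = sum((y_pred - y_bar)^2)`,
#' `r_squared = ss_exp / ss_total`, where `y_bar` is a reference series
#' (by default the globally averaged time series, i.e. the across-vertex
#' mean signal at each timepoint). A raw ratio above 1 is clipped to 1 and
#' flagged; `ss_total = 0` leaves `r_squared` as `NA` and flags the vertex
#' for exclusion from ranking.
#'
#' @param y observed vertex series.
#' @param y_pred fitted series.
#' @param y_bar reference series (recycled if scalar).
#' @return List with `ss_total`, `ss_exp`, `r_squared`, and `flagged`.
#' @export
explained_variance <- function(y, y_pred, y_bar) {
  if (length(y_bar) == 1L) y_bar <- rep(y_bar, length(y))
  if (length(y) != length(y_pred) || length(y) != length(y_bar))
    stop("explained_variance requires equal-length series", call. = FALSE)
  ss_total <- sum((y - y_bar)^2)
  ss_exp <- sum((y_pred - y_bar)^2)
  if (ss_total == 0) {
    return(list(ss_total = 0, ss_exp = ss_exp, r_squared = NA_real_,
                flagged = TRUE))
  }
  r2 <- ss_exp / ss_total
  flagged <- r2 > 1 + 1e-10        # tolerance guards exact fits
  list(ss_total = ss_total, ss_exp = ss_exp, r_squared = min(r2, 1),
       flagged = flagged)
}

#' Rank-rescale explained-variance ratios into sensory magnitudes
#'
#' Values are ranked ascending (ties get the average rank) and the ranks
#' rescaled linearly onto \[0, 1\] as `(rank - 1) / (n - 1)`, so the
#' vertex with the largest ratio gets magnitude 1. Flagged vertices (`NA`
#' input) are excluded from the ranking and emitted as `NA`. All-identical
#' input ties every magnitude at 0.5 with a warning.
#'
#' @param r_squared numeric vector of per-vertex ratios (`NA` = flagged).
#' @return Numeric vector of magnitudes in \[0, 1\] (`NA` preserved).
#' @export
magnitude_from_r2 <- function(r_squared) {
  ok <- !is.na(r_squared)
  if (sum(ok) < 2L)
    stop("magnitude ranking needs at least 2 unflagged vertices",
         call. = FALSE)
  out <- rep(NA_real_, length(r_squared))
  rk <- rank(r_squared[ok], ties.method = "average")
  n_ok <- sum(ok)
  if (max(rk) == min(rk))
    warning("all explained-variance ratios identical; magnitudes tie at 0.5",
            call. = FALSE)
  out[ok] <- (rk - 1) / (n_ok - 1)  # ranks rescaled over 1..n
  out
}

#' Hue-transform sensory parameters into a sensory angle
#'
#' Maps a non-negative coefficient triple (visual, somatosensory, auditory)
#' onto the unit circle by the color-science hue transformation, with
#' anchors at 0 (visual), 120 (somatosensory), and 240 degrees (auditory):
#' with `delta = max(beta) - min(beta)`, the angle is 0 when `delta = 0`,
#' otherwise `60 * (bS - bA) / delta` when the maximum is visual,
#' `120 + 60 * (bA - bV) / delta` when somatosensory, and
#' `240 + 60 * (bV - bS) / delta` when auditory, reduced mod 360 into
#' \[0, 360). Exact ties at the maximum between non-adjacent channels are
#' broken in branch order (V, then S, then A); ties between hue-adjacent
#' channels give the same angle from either branch.
#'
#' @param beta_v,beta_s,beta_a non-negative numeric vectors (recycled to a
#'   common length), or a single 3-column matrix/3-vector as `beta_v`.
#' @return Numeric vector of angles in degrees, in \[0, 360).
#' @export
hue_angle <- function(beta_v, beta_s = NULL, beta_a = NULL) {
  if (is.null(beta_s)) {
    b <- if (is.matrix(beta_v)) beta_v else matrix(beta_v, ncol = 3L)
    beta_v <- b[, 1L]; beta_s <- b[, 2L]; beta_a <- b[, 3L]
  }
  n <- max(length(beta_v), length(beta_s), length(beta_a))
  beta_v <- rep_len(beta_v, n); beta_s <- rep_len(beta_s, n)
  beta_a <- rep_len(beta_a, n)
  if (any(beta_v < 0 | beta_s < 0 | beta_a < 0, na.rm = TRUE))
    stop("sensory parameters must be non-negative", call. = FALSE)
  cmax <- pmax(beta_v, beta_s, beta_a)
  cmin <- pmin(beta_v, beta_s, beta_a)
  delta <- cmax - cmin
  hue <- numeric(n)
  v_max <- delta > 0 & beta_v >= cmax
  s_max <- delta > 0 & !v_max & beta_s >= cmax
  a_max <- delta > 0 & !v_max & !s_max
  hue[v_max] <- 60 * (beta_s[v_max] - beta_a[v_max]) / delta[v_max]
  hue[s_max] <- 120 + 60 * (beta_a[s_max] - beta_v[s_max]) / delta[s_max]
  hue[a_max] <- 240 + 60 * (beta_v[a_max] - beta_s[a_max]) / delta[a_max]
  hue <- hue %% 360
  hue[hue == 360] <- 0
  hue[is.na(beta_v) | is.na(beta_s) | is.na(beta_a)] <- NA_real_
  hue
}

#' Invert the hue transformation to a coefficient triple
#'
#' Reconstructs a non-negative (visual, somatosensory, auditory) triple
#' with the requested angle, chroma `delta`, and baseline `cmin`, via the
#' standard hue-to-channel hexcone ramp. `hue_angle()` of the result
#' recovers `angle` (for `delta > 0`).
#'
#' @param angle_deg angle(s) in degrees.
#' @param delta chroma (`max - min`), non-negative.
#' @param cmin baseline added to every channel, non-negative.
#' @return Matrix with columns `beta_V`, `beta_S`, `beta_A`.
#' @export
beta_from_angle <- function(angle_deg, delta = 1, cmin = 0) {
  n <- max(length(angle_deg), length(delta), length(cmin))
  h <- rep_len(angle_deg, n) %% 360
  delta <- rep_len(delta, n); cmin <- rep_len(cmin, n)
  hp <- h / 60
  x <- delta * (1 - abs(hp %% 2 - 1))
  seg <- floor(hp) %% 6
  r <- g <- b <- numeric(n)
  r[seg == 0] <- delta[seg == 0]; g[seg == 0] <- x[seg == 0]
  r[seg == 1] <- x[seg == 1];     g[seg == 1] <- delta[seg == 1]
  g[seg == 2] <- delta[seg == 2]; b[seg == 2] <- x[seg == 2]
  g[seg == 3] <- x[seg == 3];     b[seg == 3] <- delta[seg == 3]
  b[seg == 4] <- delta[seg == 4]; r[seg == 4] <- x[seg == 4]
  b[seg == 5] <- x[seg == 5];     r[seg == 5] <- delta[seg == 5]
  cbind(beta_V = r + cmin, beta_S = g + cmin, beta_A = b + cmin)
}

#' Variance inflation factors of the three primary signals
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is the classical coefficient of
#' determination from ordinary (unconstrained) regression of predictor k
#' on the other two. Perfect collinearity yields `Inf`.
#'
#' @param signals a [primary_signals()] object or 3-column matrix.
#' @return Named numeric vector `c(t_V, t_S, t_A)`.
#' @export
vif <- function(signals) {
  X <- if (inherits(signals, "primary_signals")) signals_matrix(signals)
       else as.matrix(signals)
  out <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(out, c("t_V", "t_S", "t_A"))
}

#' Fit the two-dimensional sensory-integration model
#'
#' Runs the full per-vertex pipeline on a standardized dataset: mean
#' primary signals from the parcellation, a non-negative fit per vertex,
#' explained variance against the chosen reference series, rank-rescaled
#' magnitudes, and hue-transformed angles.
#'
#' @param dataset standardized [surface_dataset()].
#' @param parc a [parcellation()] aligned to the dataset.
#' @param ybar reference series convention for the variance decomposition:
#'   `"global_mean"` (across-vertex mean signal at each timepoint, the
#'   default) or `"temporal_mean"` (per-series temporal mean, the classical
#'   R-squared convention).
#' @param signals optionally, precomputed [primary_signals()] overriding
#'   the parcellation means.
#' @return An object of class `sensory_fit`: list with `parameters`
#'   (vertices x 3 matrix of non-negative coefficients), `r_squared`,
#'   `ss_total`, `ss_exp`, `flagged`, `angle_deg`, `magnitude`, `signals`,
#'   `vif`, `degenerate`, and the conventions used.
#' @export
build_sensory_map <- function(dataset, parc = NULL,
                              ybar = c("global_mean", "temporal_mean"),
                              signals = NULL) {
  ybar <- match.arg(ybar)
  if (is.null(signals)) {
    if (is.null(parc)) stop("either parc or signals must be given",
                            call. = FALSE)
    signals <- primary_signals(dataset, parc)
  }
  X <- signals_matrix(signals)
  nv <- n_vertices(dataset)
  if (nrow(X) != n_timepoints(dataset))
    stop("signal length must match dataset timepoints", call. = FALSE)
  degenerate <- qr(X)$rank < ncol(X)
  y_bar_series <- if (ybar == "global_mean") colMeans(dataset$data) else NULL

  beta <- matrix(0, nv, 3L,
                 dimnames = list(NULL, c("beta_V", "beta_S", "beta_A")))
  ss_total <- ss_exp <- r2 <- numeric(nv)
  flagged <- logical(nv)
  for (v in seq_len(nv)) {         # deterministic vertex-order loop
    y <- dataset$data[v, ]
    beta[v, ] <- pracma::lsqnonneg(X, y)$x
    yp <- X %*% beta[v, ]
    yb <- if (is.null(y_bar_series)) mean(y) else y_bar_series
    ev <- explained_variance(y, yp, yb)
    ss_total[v] <- ev$ss_total; ss_exp[v] <- ev$ss_exp
    r2[v] <- if (is.na(ev$r_squared)) NA_real_ else ev$r_squared
    flagged[v] <- ev$flagged
  }
  rank_input <- r2
  rank_input[flagged] <- NA_real_
  magnitude <- if (sum(!is.na(rank_input)) < 2L) {
    warning("fewer than 2 unflagged vertices; magnitudes undefined",
            call. = FALSE)
    rep(NA_real_, nv)
  } else magnitude_from_r2(rank_input)
  structure(list(parameters = beta,
                 ss_total = ss_total, ss_exp = ss_exp, r_squared = r2,
                 flagged = flagged,
                 angle_deg = hue_angle(beta),
                 magnitude = magnitude,
                 signals = signals, vif = vif(signals),
                 degenerate = degenerate,
                 ybar = ybar),
            class = "sensory_fit")
}

#' @export
print.sensory_fit <- function(x, ...) {
  cat("<sensory_fit> ", nrow(x$parameters), " vertices; ybar = ", x$ybar,
      "\n", sep = "")
  cat("  VIF:", paste(sprintf("%s=%.3g", names(x$vif), x$vif),
                      collapse = " "), "\n")
  cat("  angle range: [", sprintf("%.1f", min(x$angle_deg, na.rm = TRUE)),
      ", ", sprintf("%.1f", max(x$angle_deg, na.rm = TRUE)), "] deg\n",
      sep = "")
  invisible(x)
}

#' Circular mean of angles in degrees
#'
#' Direction of the mean resultant vector. Returns `NA` when the resultant
#' length is below `tol` (direction undefined).
#'
#' @param theta_deg numeric vector of angles in degrees.
#' @param tol resultant-length tolerance below which the mean is undefined.
#' @return Angle in \[0, 360), or `NA`.
#' @export
circular_mean <- function(theta_deg, tol = 1e-12) {
  z <- mean(exp(1i * theta_deg * pi / 180))
  if (Mod(z) < tol) return(NA_real_)
  out <- (Arg(z) * 180 / pi) %% 360
  if (out >= 360) 0 else out
}

#' Group-level sensory map from individual fits
#'
#' The group angle is the per-vertex circular mean of individual angles;
#' the group magnitude is the rank-rescale of the across-subject mean
#' explained-variance ratio. Vertices with an undefined circular mean
#' (zero resultant) get `NA` angles.
#'
#' @param individual_r2 subjects-by-vertices matrix of ratios.
#' @param individual_angles subjects-by-vertices matrix of degrees.
#' @return List with `angle_deg` and `magnitude` per vertex.
#' @export
group_level_map <- function(individual_r2, individual_angles) {
  individual_r2 <- as.matrix(individual_r2)
  individual_angles <- as.matrix(individual_angles)
  if (!all(dim(individual_r2) == dim(individual_angles)))
    stop("r2 and angle matrices must be subjects x vertices and aligned",
         call. = FALSE)
  if (nrow(individual_r2) < 2L)
    stop("group map needs at least 2 subjects", call. = FALSE)
  z <- colMeans(exp(1i * individual_angles * pi / 180))
  angle <- (Arg(z) * 180 / pi) %% 360
  angle[angle >= 360] <- 0
  angle[Mod(z) < 1e-12] <- NA_real_
  list(angle_deg = angle,
       magnitude = magnitude_from_r2(colMeans(individual_r2)))
}

#' Encode a sensory map as RGB colors
#'
#' Standard hexcone HSV-to-RGB conversion with hue = sensory angle,
#' saturation = sensory magnitude, and a fixed brightness (HSV value),
#' 0.86 by default. Zero magnitude gives gray regardless of angle.
#'
#' @param angle_deg angles in degrees (or a `sensory_fit`).
#' @param magnitude saturations in \[0, 1\] (ignored when a fit is given).
#' @param brightness HSV value in \[0, 1\].
#' @return Matrix with columns `r`, `g`, `b` in \[0, 1\].
#' @export
color_encode <- function(angle_deg, magnitude = NULL, brightness = 0.86) {
  if (inherits(angle_deg, "sensory_fit")) {
    magnitude <- angle_deg$magnitude
    angle_deg <- angle_deg$angle_deg
  }
  n <- max(length(angle_deg), length(magnitude))
  h <- rep_len(angle_deg, n) %% 360
  s <- rep_len(magnitude, n)
  chroma <- brightness * s
  ramp <- beta_from_angle(h, delta = 1)    # unit-chroma hue ramp
  rgb <- chroma * ramp + (brightness - chroma)
  colnames(rgb) <- c("r", "g", "b")
  rgb[is.na(h) | is.na(s), ] <- NA_real_
  rgb
}
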