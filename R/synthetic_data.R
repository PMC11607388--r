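# Synthetic surface data with known per-vertex mixing weights, so every
# pipeline stage can be validated end-to-end without any external dataset.

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(coordinates = v, triangles = f)
}

subdivide_once <- function(coords, tris) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  coords_list <- lapply(seq_len(nrow(coords)), function(i) coords[i, ])
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b), sep = "_")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    m <- coords_list[[a]] + coords_list[[b]]
    m <- m / sqrt(sum(m^2))
    coords_list[[length(coords_list) + 1L]] <<- m
    idx <- length(coords_list)
    cache[[key]] <- idx
    idx
  }
  new_tris <- matrix(0L, nrow(tris) * 4L, 3L)
  for (t in seq_len(nrow(tris))) {
    a <- tris[t, 1L]; b <- tris[t, 2L]; c_ <- tris[t, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
    new_tris[4L * t - 3L, ] <- c(a, ab, ca)
    new_tris[4L * t - 2L, ] <- c(b, bc, ab)
    new_tris[4L * t - 1L, ] <- c(c_, ca, bc)
    new_tris[4L * t, ] <- c(ab, bc, ca)
  }
  list(coordinates = do.call(rbind, coords_list), triangles = new_tris)
}

#' Icosphere mesh pair (left/right hemispheres)
#'
#' Unit icosphere with `10 * 4^s + 2` vertices. The right hemisphere is
#' the mirror image (x negated) with identical vertex and triangle index
#' order, so identically indexed vertices correspond across hemispheres.
#'
#' @param subdivisions integer in 0..5.
#' @return List with [surface_mesh()] elements `left` and `right`.
#' @export
make_sphere_mesh <- function(subdivisions = 2L) {
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L || subdivisions > 5L)
    stop("subdivisions must be in 0..5", call. = FALSE)
  m <- icosahedron()
  for (i in seq_len(subdivisions)) m <- subdivide_once(m$coordinates,
                                                       m$triangles)
  left <- surface_mesh(m$coordinates, m$triangles)
  right_coords <- m$coordinates
  right_coords[, 1L] <- -right_coords[, 1L]
  right <- surface_mesh(right_coords, m$triangles)
  list(left = left, right = right)
}

#' Default primary-cap centers: three unit vectors 120 degrees apart
#' @return 3-by-3 matrix, rows V1, S1, A1.
#' @export
primary_cap_centers <- function() {
  rbind(V1 = c(1, 0, 0),
        S1 = c(-0.5, sqrt(3) / 2, 0),
        A1 = c(-0.5, -sqrt(3) / 2, 0))
}

great_circle_distance <- function(coords, center) {
  u <- coords / sqrt(rowSums(coords^2))
  c0 <- center / sqrt(sum(center^2))
  acos(pmin(pmax(u %*% c0, -1), 1))[, 1L]
}

#' Vertices within a geodesic cap
#'
#' @param mesh a [surface_mesh()] on the unit sphere.
#' @param center cap center direction (3-vector).
#' @param radius geodesic radius in radians.
#' @return Integer vertex indices.
#' @export
vertices_within <- function(mesh, center, radius) {
  which(great_circle_distance(mesh$coordinates, center) <= radius)
}

#' Toy primary-sensory parcellation of an icosphere
#'
#' Three disjoint geodesic caps centered at 120-degree-separated poles
#' play the roles of V1, the somatosensory strip (split into four
#' quadrant sub-parcels named 1, 2, 3a, 3b), and A1; all remaining
#' vertices are unlabeled association cortex (code 0).
#'
#' @param mesh a [surface_mesh()] from [make_sphere_mesh()].
#' @param cap_radius geodesic cap radius in radians (default 0.5).
#' @param centers 3-by-3 matrix of cap center directions (rows V1, S1,
#'   A1).
#' @return A [parcellation()] with attributes `centers` and `cap_radius`.
#' @export
make_parcellation <- function(mesh, cap_radius = 0.5,
                              centers = primary_cap_centers()) {
  if (cap_radius <= 0) stop("cap_radius must be positive", call. = FALSE)
  d <- sapply(seq_len(3L), function(k)
    great_circle_distance(mesh$coordinates, centers[k, ]))
  inside <- d <= cap_radius
  if (any(rowSums(inside) > 1L))
    stop("caps overlap at radius ", cap_radius, call. = FALSE)
  labels <- integer(nrow(mesh$coordinates))
  labels[inside[, 1L]] <- 1L                       # V1
  labels[inside[, 3L]] <- 2L                       # A1
  s1 <- which(inside[, 2L])
  if (length(s1) == 0L || !any(inside[, 1L]) || !any(inside[, 3L]))
    stop("a sensory cap is empty at radius ", cap_radius, call. = FALSE)
  # split the somatosensory cap into four quadrant sub-parcels
  c_s <- centers[2L, ] / sqrt(sum(centers[2L, ]^2))
  up <- c(0, 0, 1)
  e1 <- up - sum(up * c_s) * c_s
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(c_s[2L] * e1[3L] - c_s[3L] * e1[2L],
          c_s[3L] * e1[1L] - c_s[1L] * e1[3L],
          c_s[1L] * e1[2L] - c_s[2L] * e1[1L])
  u <- mesh$coordinates[s1, , drop = FALSE] %*% e1
  v <- mesh$coordinates[s1, , drop = FALSE] %*% e2
  quadrant <- 1L + (u < 0) + 2L * (v < 0)
  labels[s1] <- 2L + quadrant                      # codes 3..6
  parc <- parcellation(labels,
                       name_map = c("1" = "V1", "2" = "A1", "3" = "1",
                                    "4" = "2", "5" = "3a", "6" = "3b"))
  attr(parc, "centers") <- centers
  attr(parc, "cap_radius") <- cap_radius
  parc
}

equicorrelation_matrix <- function(rho) {
  (1 - rho) * diag(3) + rho
}

#' Generate the three latent primary sensory signals
#'
#' Three standardized AR(1) series (autocorrelation 0.3) with a target
#' pairwise equicorrelation imposed through the Cholesky square root of
#' the equicorrelation matrix.
#'
#' @param n_timepoints series length (>= 10).
#' @param pairwise_correlation target correlation in \[0, 1).
#' @param seed integer RNG seed.
#' @return A [primary_signals()] object.
#' @export
generate_primary_signals <- function(n_timepoints,
                                     pairwise_correlation = 0.3,
                                     seed = 1L) {
  if (n_timepoints < 10L) stop("n_timepoints must be >= 10", call. = FALSE)
  if (pairwise_correlation < 0 || pairwise_correlation >= 1)
    stop("pairwise_correlation must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_timepoints * 3L), n_timepoints, 3L)
  for (k in 1:3)
    z[, k] <- as.numeric(stats::filter(z[, k], 0.3, method = "recursive"))
  z <- scale(z)
  x <- z %*% chol(equicorrelation_matrix(pairwise_correlation))
  x <- sweep(x, 2L, colMeans(x))
  x <- sweep(x, 2L, sqrt(colMeans(x^2)), "/")   # population-SD units
  validate_primary_signals(list(t_V = x[, 1L], t_S = x[, 2L],
                                t_A = x[, 3L]))
}

#' Ground-truth mixing weights for a synthetic cortex
#'
#' Per-vertex non-negative weights decay with geodesic distance from each
#' primary cap center (`baseline + exp(-d^2 / (2 * lambda^2))`), emulating
#' the gradients of decreasing primary-sensory association toward
#' association cortex; cap-member vertices are dominated by their own
#' latent signal. The true angle is the hue transform of the weights; the
#' true explained-variance fraction is `s2 / (s2 + sigma^2)` with
#' `s2 = beta' Sigma beta` the latent signal variance and a single global
#' noise SD `sigma = noise_level * sqrt(mean(s2))`.
#'
#' @param mesh a [surface_mesh()].
#' @param parc a [make_parcellation()] result (supplies cap centers).
#' @param noise_level noise SD as a fraction of the root-mean signal SD
#'   (default 0.5).
#' @param signal_correlation pairwise correlation of the latent signals.
#' @param lambda decay length in radians (default 0.7).
#' @param baseline weight floor for distant vertices (default 0.1).
#' @return An object of class `synthetic_truth`: list with `beta`
#'   (vertices x 3), `angle_deg`, `r_squared`, `signal_sd`, `noise_sd`,
#'   `signal_correlation`.
#' @export
synthetic_truth <- function(mesh, parc, noise_level = 0.5,
                            signal_correlation = 0.3, lambda = 0.7,
                            baseline = 0.1) {
  centers <- attr(parc, "centers")
  if (is.null(centers)) centers <- primary_cap_centers()
  d <- sapply(seq_len(3L), function(k)
    great_circle_distance(mesh$coordinates, centers[k, ]))
  beta <- baseline + exp(-d^2 / (2 * lambda^2))
  colnames(beta) <- c("beta_V", "beta_S", "beta_A")
  sigma_mat <- equicorrelation_matrix(signal_correlation)
  s2 <- rowSums((beta %*% sigma_mat) * beta)
  noise_sd <- noise_level * sqrt(mean(s2))
  structure(list(beta = beta,
                 angle_deg = hue_angle(beta),
                 r_squared = true_r_squared(beta, noise_sd,
                                            signal_correlation),
                 signal_sd = sqrt(s2),
                 noise_sd = rep(noise_sd, nrow(beta)),
                 signal_correlation = signal_correlation),
            class = "synthetic_truth")
}

#' Between-state scenario: hue rotation inside designated patches
#'
#' Emulates a state contrast (e.g. movie-watching vs. rest): inside each
#' patch the mixing weights are rotated in hue space by the stated shift
#' before mixing, leaving chroma and baseline unchanged (so magnitudes
#' stay put while angles move).
#'
#' @param patches list of integer vertex-index vectors.
#' @param shift_deg angular shifts in degrees, one per patch (wrapped to
#'   (-180, 180\]).
#' @return An object of class `state_scenario`.
#' @export
state_scenario <- function(patches, shift_deg) {
  if (!is.list(patches)) patches <- list(patches)
  shift_deg <- rep_len(shift_deg, length(patches))
  shift_deg <- ((shift_deg + 180) %% 360) - 180
  structure(list(patches = patches, shift_deg = shift_deg),
            class = "state_scenario")
}

apply_scenario <- function(beta, scenario) {
  if (is.null(scenario)) return(beta)
  for (i in seq_along(scenario$patches)) {
    idx <- scenario$patches[[i]]
    b <- beta[idx, , drop = FALSE]
    cmax <- pmax(b[, 1L], b[, 2L], b[, 3L])
    cmin <- pmin(b[, 1L], b[, 2L], b[, 3L])
    ang <- hue_angle(b)
    beta[idx, ] <- beta_from_angle(ang + scenario$shift_deg[i],
                                   delta = cmax - cmin, cmin = cmin)
  }
  beta
}

#' Closed-form explained-variance truth for a mixing-weight field
#'
#' The population value of the per-vertex variance-decomposition ratio for
#' data generated as `Y_v = beta_v . t + noise` and then standardized.
#' Under the `"temporal_mean"` reference convention this is the classical
#' signal fraction `s2 / (s2 + sigma^2)` with `s2 = beta' Sigma beta`.
#' Under the `"global_mean"` convention (the pipeline default) both sums
#' of squares subtract the across-vertex mean series, giving
#' `q / (q + sigma_std^2)` where `q = (bs - g)' Sigma (bs - g)`, `bs` the
#' weights rescaled to the standardized data (`beta / sqrt(s2 + sigma^2)`),
#' `g` their across-vertex mean, and `sigma_std^2 = sigma^2 / (s2 +
#' sigma^2)` the standardized noise variance.
#'
#' @param beta vertices-by-3 matrix of non-negative mixing weights.
#' @param noise_sd Gaussian noise SD on the unstandardized scale.
#' @param signal_correlation pairwise equicorrelation of the latent
#'   signals.
#' @param ybar reference-series convention, as in [build_sensory_map()].
#' @return Numeric vector of per-vertex population ratios.
#' @export
true_r_squared <- function(beta, noise_sd, signal_correlation = 0.3,
                           ybar = c("global_mean", "temporal_mean")) {
  ybar <- match.arg(ybar)
  sigma_mat <- equicorrelation_matrix(signal_correlation)
  s2 <- rowSums((beta %*% sigma_mat) * beta)
  if (ybar == "temporal_mean") return(s2 / (s2 + noise_sd^2))
  bs <- beta / sqrt(s2 + noise_sd^2)
  g <- colMeans(bs)
  dev <- sweep(bs, 2L, g)
  q <- rowSums((dev %*% sigma_mat) * dev)
  sigma_std2 <- noise_sd^2 / (s2 + noise_sd^2)
  q / (q + sigma_std2)
}

#' Between-state scenario emulating a movie-vs-rest contrast
#'
#' Association cortex is divided into three sectors by nearest primary cap
#' and each sector's hue is rotated heterogeneously: the auditory-adjacent
#' sector anticlockwise (toward auditory dominance) and the visual- and
#' somatosensory-adjacent sectors clockwise (toward visual dominance),
#' mirroring the direction and size of the observed state-dependent
#' cluster shifts. A homogeneous rotation would be a weak contrast since
#' circular correlation is rotation-invariant.
#'
#' @param mesh the [surface_mesh()] the parcellation lives on.
#' @param parc the paired [make_parcellation()].
#' @param shifts named shifts in degrees for the sectors nearest `V1`,
#'   `S1`, `A1`.
#' @return A [state_scenario()].
#' @export
between_state_scenario <- function(mesh, parc,
                                   shifts = c(V1 = -80, S1 = -85,
                                              A1 = 100)) {
  centers <- attr(parc, "centers")
  if (is.null(centers)) centers <- primary_cap_centers()
  assoc <- which(parc$labels == 0L)
  d <- sapply(seq_len(3L), function(k)
    great_circle_distance(mesh$coordinates, centers[k, ]))
  sector <- apply(d[assoc, , drop = FALSE], 1L, which.min)
  state_scenario(list(assoc[sector == 1L], assoc[sector == 2L],
                      assoc[sector == 3L]),
                 unname(shifts[c("V1", "S1", "A1")]))
}

derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p)) %% 2147483629
  as.integer(s) + 1L
}

#' Generate multi-subject, multi-state synthetic surface datasets
#'
#' Each vertex series is the non-negative mixture of the three latent
#' primary signals plus Gaussian noise:
#' `Y_v = beta_v . t + noise`, with per-subject weight jitter
#' (elementwise lognormal, sdlog 0.1) shared across states and sessions,
#' per-subject per-state angular session noise (an independent hue
#' rotation of each vertex's weights, SD `angle_noise_sd` degrees,
#' modeling scan-level variability of functional topography), fresh
#' latent signals and noise per subject/state, and all series
#' standardized (population SD).
#'
#' @param mesh a [surface_mesh()] (one hemisphere).
#' @param parc the paired [make_parcellation()].
#' @param truth a [synthetic_truth()] for the mesh.
#' @param scenarios named list of per-state [state_scenario()] objects or
#'   `NULL` entries (no shift); one dataset is generated per state.
#' @param n_subjects number of subjects (>= 1).
#' @param n_timepoints timepoints per dataset.
#' @param seed seed for latent signals and noise (vary for a second
#'   session).
#' @param subject_seed seed for the per-subject weight jitter (keep fixed
#'   across sessions so subjects persist); derived from `seed` when
#'   `NULL`.
#' @param angle_noise_sd SD in degrees of the per-subject per-state hue
#'   rotation noise (default 20; 0 disables it).
#' @return List of subjects; each subject is a named list of per-state
#'   [surface_dataset()] objects. The effective per-subject weights are
#'   attached as attribute `subject_beta` (list of per-state matrices).
#' @export
generate_dataset <- function(mesh, parc, truth,
                             scenarios = list(state1 = NULL),
                             n_subjects = 1L, n_timepoints = 300L,
                             seed = 1L, subject_seed = NULL,
                             angle_noise_sd = 20) {
  nv <- nrow(mesh$coordinates)
  if (nrow(truth$beta) != nv)
    stop("truth is not aligned to the mesh", call. = FALSE)
  if (is.null(subject_seed)) subject_seed <- derive_seed(seed, 20000L)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("state", seq_along(scenarios))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(derive_seed(subject_seed, s))
    jitter <- matrix(stats::rlnorm(nv * 3L, meanlog = 0, sdlog = 0.1),
                     nv, 3L)
    beta_s <- truth$beta * jitter
    states <- vector("list", length(scenarios))
    names(states) <- names(scenarios)
    state_betas <- vector("list", length(scenarios))
    names(state_betas) <- names(scenarios)
    for (k in seq_along(scenarios)) {
      beta_sk <- apply_scenario(beta_s, scenarios[[k]])
      if (angle_noise_sd > 0) {
        set.seed(derive_seed(seed, s, k, 555L))
        rot <- stats::rnorm(nv, 0, angle_noise_sd)
        cmax <- pmax(beta_sk[, 1L], beta_sk[, 2L], beta_sk[, 3L])
        cmin <- pmin(beta_sk[, 1L], beta_sk[, 2L], beta_sk[, 3L])
        beta_sk <- beta_from_angle(hue_angle(beta_sk) + rot,
                                   delta = cmax - cmin, cmin = cmin)
      }
      sig <- generate_primary_signals(
        n_timepoints, truth$signal_correlation,
        seed = derive_seed(seed, s, k))
      set.seed(derive_seed(seed, s, k, 999L))
      noise <- matrix(stats::rnorm(nv * n_timepoints,
                                   sd = truth$noise_sd[1L]),
                      nv, n_timepoints)
      y <- beta_sk %*% t(signals_matrix(sig)) + noise
      ds <- surface_dataset(y)
      states[[k]] <- suppressWarnings(standardize(ds))
      state_betas[[k]] <- beta_sk
    }
    attr(states, "subject_beta") <- state_betas
    subjects[[s]] <- states
  }
  subjects
}
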