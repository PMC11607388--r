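# Shared fixtures and independent oracles, built in code at test time.

wrap_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

toy_dataset <- function(nv = 4L, nt = 10L, seed = 1L, ...) {
  set.seed(seed)
  surface_dataset(matrix(rnorm(nv * nt), nv, nt), ...)
}

# 12-vertex icosahedron mesh (smallest closed triangulation we use)
toy_icosahedron <- function() make_sphere_mesh(0L)$left

# brute-force edge set by pairwise enumeration over triangles
brute_force_edges <- function(triangles) {
  edges <- unique(do.call(rbind, lapply(seq_len(nrow(triangles)), function(t) {
    tri <- sort(triangles[t, ])
    rbind(tri[c(1, 2)], tri[c(1, 3)], tri[c(2, 3)])
  })))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

adjacency_to_edges <- function(adj) {
  edges <- do.call(rbind, lapply(seq_along(adj), function(v) {
    nb <- adj[[v]]
    nb <- nb[nb > v]
    if (length(nb) == 0L) return(NULL)
    cbind(v, nb)
  }))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  edges
}

# exact minimizer of ||y - X b||^2 over the grid b in [0, hi]^3, step h.
# Exhaustive over (b1, b2); for each pair the objective is a convex
# quadratic in b3, so the grid optimum lies at a grid neighbor of the
# clamped continuous minimizer (both neighbors evaluated).
grid_nnls_objective <- function(X, y, hi = 3, h = 0.01) {
  A <- crossprod(X)
  b <- crossprod(X, y)
  yy <- sum(y^2)
  g <- seq(0, hi, by = h)
  best <- Inf
  for (b1 in g) {
    # objective(b2, b3 | b1) = const1 + quadratic form
    const1 <- yy - 2 * b[1] * b1 + A[1, 1] * b1^2
    c2 <- -2 * b[2] + 2 * A[1, 2] * b1
    c3 <- -2 * b[3] + 2 * A[1, 3] * b1
    # continuous argmin over b3 for each b2: (-c3 - 2 A23 b2) / (2 A33)
    b3_star <- (-c3 - 2 * A[2, 3] * g) / (2 * A[3, 3])
    for (cand in list(pmin(pmax(floor(b3_star / h) * h, 0), hi),
                      pmin(pmax(ceiling(b3_star / h) * h, 0), hi))) {
      obj <- const1 + c2 * g + A[2, 2] * g^2 +
        c3 * cand + A[3, 3] * cand^2 + 2 * A[2, 3] * g * cand
      best <- min(best, min(obj))
    }
  }
  best
}

# full O(grid^3) enumeration, for validating grid_nnls_objective
grid_nnls_objective_full <- function(X, y, hi, h) {
  g <- seq(0, hi, by = h)
  best <- Inf
  for (b1 in g) for (b2 in g) {
    resid_base <- y - X[, 1] * b1 - X[, 2] * b2
    for (b3 in g) best <- min(best, sum((resid_base - X[, 3] * b3)^2))
  }
  best
}

# reference experiment used by the recovery / reliability checks
recovery_fixture <- function(seed = 11L, n_timepoints = 900L) {
  mesh <- make_sphere_mesh(3L)$left
  parc <- make_parcellation(mesh)
  truth <- synthetic_truth(mesh, parc, noise_level = 0.5)
  list(mesh = mesh, parc = parc, truth = truth,
       data = generate_dataset(mesh, parc, truth, n_subjects = 1L,
                               n_timepoints = n_timepoints, seed = seed))
}
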