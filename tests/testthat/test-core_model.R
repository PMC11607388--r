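test_that("parcel mean signals are unweighted member means", {
  mesh <- make_sphere_mesh(2)$left
  parc <- make_parcellation(mesh)
  ds <- toy_dataset(162, 20)
  for (g in c("V1", "S1", "A1")) {
    idx <- group_vertices(parc, g)
    expect_equal(mean_parcel_signal(ds, parc, g),
                 colMeans(ds$data[idx, , drop = FALSE]))
  }
  # S1 spans the union of the four somatosensory sub-parcels
  s1 <- group_vertices(parc, "S1")
  expect_setequal(parc$labels[s1], 3:6)
  # one-vertex group returns that series; s and -s average to zero
  tiny <- surface_dataset(rbind(ds$data[1, ], -ds$data[1, ]))
  p2 <- parcellation(c(1L, 2L), c("1" = "V1", "2" = "A1"),
                     list(V1 = "V1", A1 = "A1"))
  expect_equal(mean_parcel_signal(tiny, p2, "V1"), tiny$data[1, ])
  p3 <- parcellation(c(1L, 1L), c("1" = "V1"), list(V1 = "V1"))
  expect_equal(mean_parcel_signal(tiny, p3, "V1"), rep(0, 20))
  expect_error(group_vertices(p2, "S1"), "empty|unknown")
})

test_that("non-negative fit recovers exact and boundary solutions", {
  n <- 60
  X <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))   # orthonormal predictors
  fit <- fit_nnls(2 * X[, 1], X)
  expect_equal(unname(fit$beta), c(2, 0, 0), tolerance = 1e-10)
  expect_lt(max(abs(fit$residual)), 1e-10)

  fit_neg <- fit_nnls(-X[, 1], X)             # constraint binds at zero
  expect_equal(unname(fit_neg$beta), c(0, 0, 0), tolerance = 1e-10)

  expect_error(fit_nnls(rnorm(10), X), "length")
  dup <- cbind(X[, 1], X[, 1], X[, 2])
  expect_true(fit_nnls(rnorm(n), dup)$degenerate)
})

test_that("fitted objective matches the brute-force grid oracle and is
           bounded below by the unconstrained optimum", {
  # validate the reduced grid enumerator against full enumeration first
  set.seed(7)
  Xs <- matrix(rnorm(30), 10, 3)
  ys <- rnorm(10)
  expect_equal(grid_nnls_objective(Xs, ys, hi = 1, h = 0.1),
               grid_nnls_objective_full(Xs, ys, hi = 1, h = 0.1),
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- as.numeric(X %*% runif(3, 0, 2)) + rnorm(n)
    fit <- fit_nnls(y, X)
    obj <- sum(fit$residual^2)
    expect_lte(obj, grid_nnls_objective(X, y) + 1e-3)
    ols <- stats::lm.fit(X, y)
    expect_gte(obj, sum(ols$residuals^2) - 1e-10)
  }
})

test_that("variance decomposition follows the stated sums of squares", {
  ev <- explained_variance(c(1, -1, 0), c(0.5, -0.5, 0), c(0, 0, 0))
  expect_equal(ev$ss_total, 2)
  expect_equal(ev$ss_exp, 0.5)
  expect_equal(ev$r_squared, 0.25)
  expect_false(ev$flagged)

  y <- rnorm(20)
  expect_equal(explained_variance(y, y, mean(y))$r_squared, 1)
  expect_equal(explained_variance(y, rep(mean(y), 20),
                                  mean(y))$r_squared, 0)
  # ratio above 1 clips and flags; zero total flags with NA
  over <- explained_variance(c(1, -1), c(2, -2), c(0, 0))
  expect_true(over$flagged)
  expect_equal(over$r_squared, 1)
  zed <- explained_variance(c(3, 3), c(1, 2), c(3, 3))
  expect_true(zed$flagged)
  expect_true(is.na(zed$r_squared))
})

test_that("classical R-squared bridge: temporal-mean reference plus
           unconstrained fit equals the normal-equations value", {
  set.seed(99)
  for (i in 1:20) {
    n <- 40
    X <- matrix(rnorm(n * 3), n, 3)
    y <- as.numeric(X %*% runif(3)) + rnorm(n)
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    beta <- solve(crossprod(Xc), crossprod(Xc, yc))  # brute-force solve
    r2_classic <- 1 - sum((yc - Xc %*% beta)^2) / sum(yc^2)
    ev <- explained_variance(y, mean(y) + as.numeric(Xc %*% beta), mean(y))
    expect_equal(ev$r_squared, r2_classic, tolerance = 1e-10)
  }
})

test_that("magnitude is a rank rescale with average ties", {
  expect_equal(magnitude_from_r2(c(0.1, 0.5, 0.9)), c(0, 0.5, 1))
  expect_equal(magnitude_from_r2(c(0.2, 0.2, 0.8)), c(0.25, 0.25, 1))
  # a tie among 5 preserves the ordering of the others
  m <- magnitude_from_r2(c(0.3, 0.1, 0.3, 0.7, 0.9))
  expect_equal(order(c(0.1, 0.7, 0.9)), order(m[c(2, 4, 5)]))
  expect_equal(m[1], m[3])
  # NA flagged entries excluded but preserved
  mf <- magnitude_from_r2(c(0.5, NA, 0.1, 0.9))
  expect_true(is.na(mf[2]))
  expect_equal(mf[c(1, 3, 4)], c(0.5, 0, 1))
  expect_warning(magnitude_from_r2(c(0.4, 0.4, 0.4)), "identical")
  expect_error(magnitude_from_r2(c(0.4, NA)), "at least 2")
  # invariance under strictly increasing transforms
  x <- runif(50)
  expect_equal(magnitude_from_r2(x), magnitude_from_r2(exp(3 * x)))
})

test_that("hue transformation hits the anchors and derived cases", {
  expect_identical(hue_angle(1, 0, 0), 0)
  expect_identical(hue_angle(0, 1, 0), 120)
  expect_identical(hue_angle(0, 0, 1), 240)
  expect_identical(hue_angle(1, 1, 1), 0)           # delta = 0
  expect_equal(hue_angle(2, 1, 0), 30)
  expect_equal(hue_angle(0, 1, 1), 180)
  expect_equal(hue_angle(1, 0, 0.5), 330)           # wrap of -30
  expect_error(hue_angle(-1, 0, 0), "non-negative")
  expect_true(all(hue_angle(matrix(runif(300), 100, 3)) >= 0))
  expect_true(all(hue_angle(matrix(runif(300), 100, 3)) < 360))
})

test_that("hue transformation has channel symmetry and branch continuity", {
  set.seed(5)
  b <- matrix(runif(300), 100, 3)
  rotated <- hue_angle(b[, 3], b[, 1], b[, 2])  # (V,S,A) -> (A,V,S)
  expect_equal((hue_angle(b) + 120) %% 360, rotated, tolerance = 1e-10)
  # adjacent two-way ties: both applicable branches agree
  expect_equal(hue_angle(1, 1, 0), 60)   # V branch 60, S branch 120-60=60
  expect_equal(hue_angle(0, 1, 1), 180)
  expect_equal(hue_angle(1, 0, 1), 300)
})

test_that("inverse hue parameterization composes to the identity", {
  angles <- seq(0, 359.5, by = 7.3)
  b <- beta_from_angle(angles, delta = 2, cmin = 0.3)
  expect_equal(hue_angle(b), angles %% 360, tolerance = 1e-9)
  expect_equal(pmax(b[, 1], b[, 2], b[, 3]) - pmin(b[, 1], b[, 2], b[, 3]),
               rep(2, length(angles)), tolerance = 1e-12)
  expect_equal(pmin(b[, 1], b[, 2], b[, 3]), rep(0.3, length(angles)))
})

test_that("variance inflation factors match the closed forms", {
  n <- 500
  set.seed(61)
  # mean-zero orthonormal columns: orthogonalize against the intercept too
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  expect_true(all(is.infinite(vif(cbind(Q[, 1], Q[, 1], Q[, 2]))[1:2])))
  # exact pairwise correlation 0.5 -> VIF 1.5 each (equicorrelated form)
  R <- 0.5 * matrix(1, 3, 3) + 0.5 * diag(3)
  expect_equal(unname(vif(Q %*% chol(R))), rep(1.5, 3), tolerance = 1e-10)
})

test_that("full map fit equals composing the four stages by hand", {
  mesh <- make_sphere_mesh(2)$left
  parc <- make_parcellation(mesh)
  ds <- standardize(toy_dataset(162, 40, seed = 8))
  fit <- build_sensory_map(ds, parc)
  sig <- primary_signals(ds, parc)
  X <- cbind(sig$t_V, sig$t_S, sig$t_A)
  ybar <- colMeans(ds$data)
  for (v in c(1, 57, 162)) {
    f <- fit_nnls(ds$data[v, ], sig)
    expect_equal(unname(fit$parameters[v, ]), unname(f$beta),
                 tolerance = 1e-10)
    ev <- explained_variance(ds$data[v, ], X %*% f$beta, ybar)
    expect_equal(fit$r_squared[v], ev$r_squared, tolerance = 1e-10)
    expect_equal(fit$angle_deg[v], hue_angle(f$beta[1], f$beta[2],
                                             f$beta[3]))
  }
  expect_equal(fit$magnitude,
               magnitude_from_r2(replace(fit$r_squared, fit$flagged, NA)))
})

test_that("a cortex of pure visual signal yields all-zero angles and tied
           magnitudes", {
  mesh <- make_sphere_mesh(1)$left
  parc <- make_parcellation(mesh, cap_radius = 0.7)
  set.seed(2)
  t_v <- as.numeric(scale(rnorm(50)))
  ds <- surface_dataset(matrix(rep(t_v, each = 42), 42, 50))
  # with the temporal-mean reference every ratio is 1: a full tie
  suppressWarnings(fit <- build_sensory_map(standardize(ds), parc,
                                            ybar = "temporal_mean"))
  expect_true(all(fit$angle_deg == 0))
  expect_true(all(fit$magnitude == 0.5))
  # under the global-mean reference this degenerate cortex has no
  # residual variance around the mean series: every vertex is flagged
  expect_warning(g <- build_sensory_map(standardize(ds), parc),
                 "undefined|unflagged")
  expect_true(all(is.na(g$magnitude)))
})

test_that("group maps use circular means and rank-rescaled mean ratios", {
  r2 <- rbind(c(0.2, 0.8), c(0.2, 0.8))
  ang <- rbind(c(10, 90), c(350, 90))
  g <- group_level_map(r2, ang)
  expect_equal(g$angle_deg, c(0, 90), tolerance = 1e-10)
  expect_equal(g$magnitude, c(0, 1))
  # identical subjects reproduce the individual map
  same <- group_level_map(rbind(r2[1, ], r2[1, ]), rbind(ang[1, ], ang[1, ]))
  expect_equal(same$angle_deg, ang[1, ], tolerance = 1e-10)
  # antipodal pair: undefined angle flagged
  g0 <- group_level_map(r2, rbind(c(0, 90), c(180, 90)))
  expect_true(is.na(g0$angle_deg[1]))
  expect_error(group_level_map(r2[1, , drop = FALSE],
                               ang[1, , drop = FALSE]), "2 subjects")
})

test_that("color encoding is the standard hexcone at brightness 0.86", {
  expect_equal(unname(color_encode(0, 1)[1, ]), c(0.86, 0, 0))
  expect_equal(unname(color_encode(240, 1)[1, ]), c(0, 0, 0.86))
  expect_equal(unname(color_encode(123, 0)[1, ]), rep(0.86, 3))
  expect_equal(unname(color_encode(120, 0.5)[1, ]), c(0.43, 0.86, 0.43))
  # agrees with grDevices' HSV conversion on a grid (8-bit tolerance)
  for (h in seq(0, 350, by = 37)) for (s in c(0.2, 0.9)) {
    ours <- color_encode(h, s)
    ref <- as.numeric(grDevices::col2rgb(grDevices::hsv(h / 360, s,
                                                        0.86))) / 255
    expect_equal(unname(ours[1, ]), ref, tolerance = 0.01)
  }
})
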