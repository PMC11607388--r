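test_that("icosphere counts follow the subdivision arithmetic", {
  m0 <- make_sphere_mesh(0)
  expect_identical(dim(m0$left$coordinates), c(12L, 3L))
  expect_identical(nrow(m0$left$triangles), 20L)
  m1 <- make_sphere_mesh(1)
  expect_identical(nrow(m1$left$coordinates), 42L)
  expect_identical(nrow(m1$left$triangles), 80L)
  m2 <- make_sphere_mesh(2)
  expect_identical(nrow(m2$left$coordinates), 162L)
  # unit sphere, valid triangles
  expect_equal(sqrt(rowSums(m1$left$coordinates^2)), rep(1, 42))
  expect_true(all(m1$left$triangles >= 1 & m1$left$triangles <= 42))
  expect_error(make_sphere_mesh(6), "0..5")
})

test_that("hemispheres are mirror images with identical index order", {
  m <- make_sphere_mesh(2)
  expect_equal(m$right$coordinates[, 1], -m$left$coordinates[, 1])
  expect_equal(m$right$coordinates[, 2:3], m$left$coordinates[, 2:3])
  expect_identical(m$right$triangles, m$left$triangles)
  expect_identical(m$right$adjacency, m$left$adjacency)
})

test_that("parcellation caps are disjoint and match a spherical-distance
           oracle", {
  m <- make_sphere_mesh(2)$left
  parc <- make_parcellation(m)
  centers <- attr(parc, "centers")
  for (g in c("V1", "S1", "A1")) {
    k <- match(g, c("V1", "S1", "A1"))
    member <- group_vertices(parc, g)
    d <- acos(pmin(pmax(m$coordinates %*% centers[k, ], -1), 1))
    expect_setequal(member, which(d <= 0.5))
  }
  counts <- table(factor(parc$labels, levels = 0:6))
  expect_true(all(counts[c("1", "2")] > 0))
  expect_gt(sum(counts[c("3", "4", "5", "6")]), 0)
  expect_error(make_parcellation(m, cap_radius = 0), "positive")
  expect_error(make_parcellation(m, cap_radius = 1.2), "overlap")
})

test_that("latent signals hit the target correlation and are reproducible", {
  s0 <- generate_primary_signals(1000, 0, seed = 4)
  X0 <- cbind(s0$t_V, s0$t_S, s0$t_A)
  offdiag <- cor(X0)[upper.tri(diag(3))]
  expect_lt(max(abs(offdiag)), 0.1)

  s5 <- generate_primary_signals(5000, 0.5, seed = 4)
  expect_equal(unname(vif(s5)), rep(1.5, 3), tolerance = 0.12)
  off5 <- cor(cbind(s5$t_V, s5$t_S, s5$t_A))[upper.tri(diag(3))]
  expect_lt(max(abs(off5 - 0.5)), 0.1)

  again <- generate_primary_signals(1000, 0, seed = 4)
  expect_identical(s0, again)
  expect_error(generate_primary_signals(5, 0), ">= 10")
  expect_error(generate_primary_signals(100, 1), "\\[0, 1\\)")
})

test_that("latent signals carry the configured AR(1) serial structure", {
  s <- generate_primary_signals(20000, 0, seed = 10)
  ac <- acf(s$t_V, plot = FALSE, lag.max = 1)$acf[2]
  expect_equal(ac, 0.3, tolerance = 0.05)
})

test_that("truth fields are consistent with their own definitions", {
  m <- make_sphere_mesh(2)$left
  parc <- make_parcellation(m)
  tr <- synthetic_truth(m, parc, noise_level = 0.5)
  expect_equal(tr$angle_deg, hue_angle(tr$beta))
  expect_true(all(tr$beta > 0))
  expect_true(all(tr$r_squared > 0 & tr$r_squared < 1))
  expect_equal(tr$noise_sd[1], 0.5 * sqrt(mean(tr$signal_sd^2)),
               tolerance = 1e-12)
  # cap members are dominated by their own channel
  expect_true(all(apply(tr$beta[group_vertices(parc, "V1"), ], 1,
                        which.max) == 1))
  expect_true(all(apply(tr$beta[group_vertices(parc, "A1"), ], 1,
                        which.max) == 3))
})

test_that("closed-form explained variance matches a long-run simulation", {
  set.seed(88)
  nv <- 200  # the closed form neglects O(1/nv) mean-series noise terms
  beta <- matrix(runif(nv * 3, 0.05, 1.2), nv, 3)
  rho <- 0.3
  sigma <- 0.6
  nt <- 30000
  sig <- generate_primary_signals(nt, rho, seed = 17)
  X <- cbind(sig$t_V, sig$t_S, sig$t_A)
  y <- beta %*% t(X) + matrix(rnorm(nv * nt, sd = sigma), nv, nt)
  ds <- standardize(surface_dataset(y))
  # temporal-mean convention: classical signal fraction
  r2_tm <- true_r_squared(beta, sigma, rho, ybar = "temporal_mean")
  # global-mean convention against the pipeline's own decomposition
  r2_gm <- true_r_squared(beta, sigma, rho, ybar = "global_mean")
  ybar <- colMeans(ds$data)
  for (v in c(1, 61, 123, 200)) {
    fitted <- as.numeric(X %*% qr.solve(X, ds$data[v, ]))
    emp <- sum((fitted - mean(ds$data[v, ]))^2) /
      sum((ds$data[v, ] - mean(ds$data[v, ]))^2)
    expect_equal(emp, r2_tm[v], tolerance = 0.02)

    fit <- fit_nnls(ds$data[v, ], X)
    ev <- explained_variance(ds$data[v, ], fit$fitted, ybar)
    expect_equal(ev$r_squared, r2_gm[v], tolerance = 0.03)
  }
})

test_that("scenario rotation shifts hue while preserving chroma and base", {
  set.seed(19)
  beta <- matrix(runif(60, 0.1, 1.5), 20, 3)
  sc <- state_scenario(list(1:10), 60)
  m <- make_sphere_mesh(0)$left
  shifted <- sensoangle:::apply_scenario(beta, sc)
  expect_equal(hue_angle(shifted[1:10, ]),
               (hue_angle(beta[1:10, ]) + 60) %% 360, tolerance = 1e-9)
  expect_equal(shifted[11:20, ], beta[11:20, ])
  expect_equal(pmax(shifted[, 1], shifted[, 2], shifted[, 3]),
               pmax(beta[, 1], beta[, 2], beta[, 3]), tolerance = 1e-12)
  expect_equal(pmin(shifted[, 1], shifted[, 2], shifted[, 3]),
               pmin(beta[, 1], beta[, 2], beta[, 3]), tolerance = 1e-12)
})

test_that("datasets are deterministic given seeds and recover the truth
           when noise-free", {
  m <- make_sphere_mesh(2)$left
  parc <- make_parcellation(m)
  tr <- synthetic_truth(m, parc, noise_level = 0.5)
  d1 <- generate_dataset(m, parc, tr, n_subjects = 2, n_timepoints = 50,
                         seed = 3)
  d2 <- generate_dataset(m, parc, tr, n_subjects = 2, n_timepoints = 50,
                         seed = 3)
  expect_identical(d1[[1]]$state1$data, d2[[1]]$state1$data)
  expect_false(identical(d1[[1]]$state1$data, d1[[2]]$state1$data))

  # same subject_seed, different session seed: jitter persists
  s1 <- generate_dataset(m, parc, tr, n_subjects = 1, n_timepoints = 50,
                         seed = 5, subject_seed = 7, angle_noise_sd = 0)
  s2 <- generate_dataset(m, parc, tr, n_subjects = 1, n_timepoints = 50,
                         seed = 6, subject_seed = 7, angle_noise_sd = 0)
  expect_identical(attr(s1[[1]], "subject_beta")$state1,
                   attr(s2[[1]], "subject_beta")$state1)
  expect_false(identical(s1[[1]]$state1$data, s2[[1]]$state1$data))

  # noiseless generation: the fitted map reproduces the effective angles
  tr0 <- synthetic_truth(m, parc, noise_level = 0)
  d0 <- generate_dataset(m, parc, tr0, n_subjects = 1, n_timepoints = 200,
                         seed = 9, angle_noise_sd = 0)
  fit <- build_sensory_map(d0[[1]]$state1, parc)
  b_eff <- attr(d0[[1]], "subject_beta")$state1
  err <- wrap_diff(fit$angle_deg, hue_angle(b_eff))
  expect_lt(median(err), 2)
})

test_that("a scenario patch elevates the angular difference only inside
           the patch", {
  m <- make_sphere_mesh(2)$left
  parc <- make_parcellation(m)
  tr <- synthetic_truth(m, parc, noise_level = 0)
  patch <- vertices_within(m, c(0, 0, 1), 0.45)
  sc <- state_scenario(patch, 60)
  d <- generate_dataset(m, parc, tr,
                        scenarios = list(a = NULL, b = sc),
                        n_subjects = 1, n_timepoints = 400, seed = 12,
                        angle_noise_sd = 0)
  fa <- build_sensory_map(d[[1]]$a, parc)
  fb <- build_sensory_map(d[[1]]$b, parc)
  v <- angular_variance(fa$angle_deg, fb$angle_deg)$variance_v
  expect_gt(min(v[patch]), 0.1)       # V(theta, theta+60) = 0.134
  expect_lt(max(v[-patch]), 0.02)
})

test_that("the between-state scenario shifts association sectors in
           opposite directions and leaves primary caps alone", {
  m <- make_sphere_mesh(2)$left
  parc <- make_parcellation(m)
  sc <- between_state_scenario(m, parc)
  covered <- sort(unlist(sc$patches))
  expect_setequal(covered, which(parc$labels == 0L))
  expect_identical(sc$shift_deg, c(-80, -85, 100))
})
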