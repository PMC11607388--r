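test_that("ROI segmentation follows the wrapped arc and magnitude bins", {
  expect_identical(segment_rois(0, 0.9), 25L)      # 330-30 arc, 0.8-1.0 bin
  expect_identical(segment_rois(330, 0.9), 25L)    # half-open low edge
  expect_identical(segment_rois(30, 0.9), 26L)
  expect_identical(segment_rois(359, 0.05), 1L)
  expect_identical(segment_rois(1, 1), 25L)        # magnitude 1 -> top bin
  expect_identical(segment_rois(NA_real_, 0.5), 0L)

  # brute-force double loop oracle over a uniform random map
  set.seed(6)
  ang <- runif(300, 0, 360)
  mag <- runif(300)
  got <- segment_rois(ang, mag)
  arcs_low <- c(330, 30, 90, 150, 210, 270)
  for (v in seq(1, 300, by = 13)) {
    arc <- NA
    for (a in 1:6) {
      lo <- arcs_low[a]
      hi <- (lo + 60) %% 360
      inside <- if (lo < hi) ang[v] >= lo && ang[v] < hi
                else ang[v] >= lo || ang[v] < hi
      if (inside) arc <- a - 1L
    }
    bin <- min(floor(mag[v] / 0.2), 4)
    expect_identical(got[v], as.integer(6 * bin + arc + 1))
  }

  # a product-grid map covers all 30 labels
  grid <- expand.grid(angle = seq(0, 300, by = 60),
                      magnitude = seq(0.1, 0.9, by = 0.2))
  expect_setequal(segment_rois(grid$angle, grid$magnitude), 1:30)
})

test_that("weight scheme: each channel dominant in one arc, integrative in
           two, with the stated hierarchical ladder", {
  w <- roi_weights()
  arc_of_roi <- (1:30 - 1) %% 6
  for (ch in 1:3) {
    for (arc in 0:5) {
      vals <- unique(w$sensory[ch, arc_of_roi == arc])
      expect_length(vals, 1L)
    }
    expect_identical(sum(w$sensory[ch, 1:6] == 1), 1L)
    expect_identical(sum(w$sensory[ch, 1:6] == 0.5), 2L)
    expect_identical(sum(w$sensory[ch, 1:6] == 0), 3L)
  }
  # visual: dominant on the wrapped arc, integrative on both neighbors
  expect_equal(w$sensory[1, 1:6], c(1, 0.5, 0, 0, 0, 0.5))
  expect_equal(w$sensory[2, 1:6], c(0, 0.5, 1, 0.5, 0, 0))
  expect_equal(w$sensory[3, 1:6], c(0, 0, 0, 0.5, 1, 0.5))
  expect_equal(w$hierarchical[c(1, 7, 13, 19, 25)],
               c(0.1, 0.3, 0.5, 0.7, 0.9))
})

test_that("threshold keeps strictly suprathreshold z and rescales per term", {
  z <- rbind(a = c(2.327, 3, 4, 5, rep(0, 26)),
             b = c(rep(0, 29), 6),
             c = rep(1, 30))
  out <- threshold_and_rescale(z)
  expect_equal(unname(out$z_thresholded["a", 1]), 0)  # exact z excluded
  expect_equal(unname(out$z_rescaled["a", 2:4]), c(0, 0.5, 1))
  expect_equal(unname(out$z_rescaled["b", 30]), 1)  # single survivor
  expect_identical(unname(out$flagged), c(FALSE, FALSE, TRUE))
  expect_error(threshold_and_rescale(matrix(NA_real_, 1, 30)), "finite")
})

test_that("term angle and magnitude follow the weighted-mean aggregation", {
  w <- roi_weights()
  z_vis <- numeric(30)
  z_vis[25] <- 3                      # visual-dominant, top magnitude
  expect_equal(term_sensory_angle(z_vis, w), 0)
  expect_equal(term_magnitude(z_vis, w), 3 * 0.9)

  z_som <- numeric(30)
  z_som[c(3, 15)] <- 2                # somatosensory-dominant arcs
  expect_equal(term_sensory_angle(z_som, w), 120)

  z_mix <- numeric(30)
  z_mix[25] <- 1                      # visual dominant
  z_mix[26] <- 1                      # visual-somatosensory integrative
  expect_equal(term_sensory_angle(z_mix, w), 20)  # a = (0.75, 0.25, 0)

  z_one <- numeric(30)
  z_one[1] <- 1
  expect_equal(term_magnitude(z_one, w), 0.1)
  expect_equal(term_magnitude(2 * z_one, w), 0.2)  # homogeneity
  expect_equal(term_sensory_angle(5 * z_mix, w),
               term_sensory_angle(z_mix, w))       # scale invariance
  expect_true(is.na(term_sensory_angle(numeric(30), w)))
})

test_that("hexagon radius correction matches the closed form", {
  expect_equal(hexagon_radius(30, 1), 1, tolerance = 1e-12)
  expect_equal(hexagon_radius(0, 1), sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(hexagon_radius(123, 0), 0)

  D <- seq(0, 360, by = 0.25)
  ratio <- hexagon_radius(D, 1)
  expect_true(all(ratio >= sqrt(3) / 2 - 1e-12 & ratio <= 1 + 1e-12))
  expect_equal(ratio, hexagon_radius(D + 60, 1), tolerance = 1e-12)
  expect_equal(which(abs(ratio - 1) < 1e-9),
               which(D %% 60 == 30))
  expect_equal(which(abs(ratio - sqrt(3) / 2) < 1e-9),
               which(D %% 60 == 0))
  expect_lt(max(abs(diff(ratio))), 0.01)           # continuity in D
})

test_that("term projection composes the four decoding stages", {
  z <- matrix(0, 3, 30,
              dimnames = list(c("vision", "touch_vision", "listening"),
                              NULL))
  z["vision", 25] <- 3
  z["touch_vision", 13] <- 4
  z["touch_vision", 15] <- 4
  z["listening", 1] <- 2.327          # boundary: excluded
  z["listening", 3] <- 2.5
  z["listening", 23] <- 5
  got <- project_terms(z)
  expect_identical(got$term, rownames(z))

  # hand-computed expectations (weights, hue transform, Eq-of-hexagon)
  expect_equal(got$D, c(0, 60, 210), tolerance = 1e-9)
  expect_equal(got$m, c(2.7, 2, 1.875), tolerance = 1e-9)
  expect_equal(got$M, c(2.7 * sqrt(3) / 2, 2 * sqrt(3) / 2, 1.875),
               tolerance = 1e-9)
  expect_equal(got$x, got$M * cos(got$D * pi / 180), tolerance = 1e-12)
  expect_equal(got$y, got$M * sin(got$D * pi / 180), tolerance = 1e-12)

  # flagged terms are dropped from the projection
  z2 <- rbind(z, dead = numeric(30))
  expect_identical(nrow(project_terms(z2)), 3L)
})

test_that("z matrices round-trip through the TSV interface", {
  set.seed(44)
  z <- matrix(round(rnorm(60, 2, 1), 4), 2, 30,
              dimnames = list(c("alpha", "beta"), NULL))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_z_matrix(z, path)
  back <- read_z_matrix(path)
  expect_equal(back, z, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(z))
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(term = "x", t(rep(1, 10))), bad, sep = "\t",
              row.names = FALSE)
  expect_error(read_z_matrix(bad), "30")
})
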