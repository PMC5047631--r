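test_that("perfectly separable two-valued image segments exactly", {
  a <- array(0, c(8, 64, 64))
  ell <- ellipse <- array(FALSE, dim(a))
  ctr <- (dim(a) + 1) / 2
  for (z in 1:8) {
    d2 <- outer(((1:64 - ctr[2]) / 20)^2, ((1:64 - ctr[3]) / 25)^2, "+") +
      ((z - ctr[1]) / 3)^2
    ellipse[z, , ] <- d2 <= 1
  }
  a[ellipse] <- 100
  mask <- segment_cell(volume_image(a, c(200, 60, 60)),
                       segmentation_params(smooth_sigma = 0))
  expect_identical(mask, ellipse)

  expect_error(segment_cell(volume_image(array(5, c(8, 64, 64)), 60)),
               "degenerate")
})

test_that("cell segmentation recovers the generator truth (Jaccard >= 0.9)", {
  truth <- generate_ground_truth(shape = c(14, 80, 80), seed = 4)
  st <- render_quiet(truth, psf_preset("RCM"), noise_params(1, 30, 4),
                     channels = "cytoplasm")
  mask <- segment_cell(st$channels$cytoplasm)
  jac <- sum(mask & truth$cell_mask) / sum(mask | truth$cell_mask)
  expect_gte(jac, 0.9)
})

test_that("intensity clustering is shift-covariant and matches exhaustive 1D k-means", {
  set.seed(42)
  a <- array(c(stats::rnorm(2000, 10, 2), stats::rnorm(2048, 60, 5)),
             c(8, 16, 32))
  p <- segmentation_params(smooth_sigma = 0)
  m1 <- segment_cell(a, p)
  m2 <- segment_cell(a + 500, p)
  expect_identical(m1, m2)

  # against the exhaustive-search optimum on a small multiset
  x <- c(1.1, 1.3, 0.9, 5.2, 5.5, 9.9, 10.4, 10.1)
  oracle <- brute_kmeans1d(x, 3)
  got <- npreflect:::kmeans_intensity(x, 3)$cluster
  expect_identical(got, oracle)
})

test_that("nucleus segmentation labels blobs and reports physical centroids", {
  a <- array(0, c(8, 64, 64))
  a[3:5, 10:14, 10:14] <- 100
  a[3:5, 40:46, 50:56] <- 120
  seg <- segment_nuclei(volume_image(a, c(200, 60, 60)),
                        segmentation_params(smooth_sigma = 0))
  expect_identical(nrow(seg$centroids_nm), 2L)
  expect_equal(seg$centroids_nm[1, ], c(z_nm = 3 * 200, y_nm = 11 * 60,
                                        x_nm = 11 * 60))
  expect_equal(seg$centroids_nm[2, ], c(z_nm = 3 * 200, y_nm = 42 * 60,
                                        x_nm = 52 * 60))

  # double-nucleus generator scene: centroids within one voxel of truth
  tr <- generate_ground_truth(shape = c(10, 96, 96), n_nuclei = 2, seed = 9)
  st <- render_quiet(tr, psf_preset("RCM"), noise_params(1, 20, 9),
                     channels = "nucleus")
  seg2 <- segment_nuclei(st$channels$nucleus)
  expect_identical(nrow(seg2$centroids_nm), 2L)
  truth_cc <- connected_components(tr$nucleus_mask, "full",
                                   voxel_size_nm = tr$voxel_size_nm)
  got <- seg2$centroids_nm[order(seg2$centroids_nm[, "x_nm"]), ]
  want <- as.matrix(truth_cc$table[order(truth_cc$table$centroid_x_nm),
                                   c("centroid_z_nm", "centroid_y_nm",
                                     "centroid_x_nm")])
  expect_lt(max(abs(got - want)), 200)
})

test_that("empty nuclear foreground yields an empty centroid list", {
  a <- array(stats::rnorm(8 * 64 * 64, 100, 1), c(8, 64, 64))
  a[2, 5, 5] <- 200  # just enough separation for two clusters
  seg <- segment_nuclei(volume_image(a, 60), segmentation_params(0))
  expect_lte(nrow(seg$table), 1L)  # no error, at most the one bright voxel
})

test_that("NP segmentation requires controls and nulls out on control input", {
  truth <- generate_ground_truth(shape = c(8, 64, 64), control = TRUE,
                                 amplitude_range = c(800, 1200), seed = 21)
  ctrl2 <- generate_ground_truth(shape = c(8, 64, 64), control = TRUE,
                                 amplitude_range = c(800, 1200), seed = 22)
  r1 <- render_quiet(truth, psf_preset("RCM"), noise_params(1, 50, 21),
                     channels = "reflectance")$channels$reflectance
  r2 <- render_quiet(ctrl2, psf_preset("RCM"), noise_params(1, 50, 22),
                     channels = "reflectance")$channels$reflectance
  expect_error(segment_np(r1, list()), "control")

  m <- segment_np(r1, r2)[[1]]
  expect_lt(sum(m) / sum(truth$cell_mask), 0.001)

  z <- segment_np(volume_image(array(0, c(8, 64, 64)), 60), r2)[[1]]
  expect_identical(sum(z), 0L)
})

test_that("NP segmentation recovers seeded clusters against the truth", {
  truth <- generate_ground_truth(shape = c(10, 96, 96), n_clusters = 20,
                                 amplitude_range = c(800, 1200),
                                 min_separation_nm = 700, seed = 31)
  ctrl <- generate_ground_truth(shape = c(10, 96, 96), control = TRUE,
                                amplitude_range = c(800, 1200), seed = 32)
  tr <- render_quiet(truth, psf_preset("RCM"), noise_params(1, 30, 31),
                     channels = "reflectance")$channels$reflectance
  cr <- render_quiet(ctrl, psf_preset("RCM"), noise_params(1, 30, 32),
                     channels = "reflectance")$channels$reflectance
  mask <- segment_np(tr, cr)[[1]]
  vox <- truth$voxel_size_nm
  idx <- cbind(round(truth$np_clusters$z_nm / vox[1]) + 1,
               round(truth$np_clusters$y_nm / vox[2]) + 1,
               round(truth$np_clusters$x_nm / vox[3]) + 1)
  hits <- sum(mask[idx])
  expect_gte(hits, 18)
})

test_that("raising the threshold multiplier never grows the NP mask", {
  truth <- generate_ground_truth(shape = c(8, 64, 64), n_clusters = 8,
                                 seed = 41)
  ctrl <- generate_ground_truth(shape = c(8, 64, 64), control = TRUE,
                                seed = 42)
  tr <- render_quiet(truth, psf_preset("RCM"), noise_params(1, 50, 41),
                     channels = "reflectance")$channels$reflectance
  cr <- render_quiet(ctrl, psf_preset("RCM"), noise_params(1, 50, 42),
                     channels = "reflectance")$channels$reflectance
  prev <- NULL
  for (m in c(1, 2, 3, 5)) {
    cur <- segment_np(tr, cr, segmentation_params(0.7, 3, m))[[1]]
    if (!is.null(prev)) expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("background subtraction removes offsets but preserves impulses", {
  a <- array(7, c(6, 32, 32))
  expect_lt(max(abs(subtract_background(a, 4))), 1e-9)

  b <- array(50, c(6, 32, 32))
  b[3, 16, 16] <- b[3, 16, 16] + 1000
  sub <- subtract_background(b, 5)
  # closed form: blurring constant + impulse leaves the impulse minus its own
  # tiny blurred copy; peak retention >= 95%
  expect_gte(sub[3, 16, 16], 0.95 * 1000)
  expect_true(all(sub >= 0))
})
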