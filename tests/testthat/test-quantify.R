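test_that("diagonal touching and checkerboard cases match enumeration", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE
  expect_identical(connected_components(m, "full")$n, 1L)
  expect_identical(connected_components(m, "face")$n, 2L)

  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  expect_identical(connected_components(cb, "face")$n, 8L)
  expect_identical(connected_components(cb, "full")$n, 1L)

  expect_identical(connected_components(array(FALSE, c(3, 3, 3)))$n, 0L)
})

test_that("component labelling agrees with flood fill on random small masks", {
  set.seed(123)
  for (i in 1:120) {
    d <- sample(3:8, 3, replace = TRUE)
    mask <- array(stats::runif(prod(d)) < stats::runif(1, 0.2, 0.6), d)
    conn <- if (i %% 2) "full" else "face"
    oracle <- flood_fill_components(mask, conn)
    got <- connected_components(mask, conn)
    expect_identical(got$n, oracle$n)
    # same partition: labels are a bijection of the oracle's
    if (got$n > 0) {
      pairs <- unique(cbind(got$labels[mask], oracle$labels[mask]))
      expect_identical(nrow(pairs), got$n)
    }
  }
})

test_that("region table reports counts, volumes and centroids correctly", {
  m <- array(FALSE, c(4, 8, 8))
  m[2, 2:3, 2:3] <- TRUE          # 4 voxels
  m[3:4, 6:7, 6] <- TRUE          # 4 voxels
  int <- array(1, dim(m)); int[2, 2, 2] <- 9
  cc <- connected_components(m, "full", intensity = int,
                             voxel_size_nm = c(200, 60, 60))
  expect_identical(cc$n, 2L)
  expect_identical(cc$table$label, 1:2)
  expect_equal(cc$table$n_voxels, c(4L, 4L))
  expect_equal(cc$table$volume_nm3, rep(4 * 200 * 60 * 60, 2))
  expect_equal(cc$table$centroid_y_nm[1], 1.5 * 60)
  expect_equal(cc$table$max_intensity, c(9, 1))
  expect_equal(cc$table$mean_intensity, c(3, 1))
})

test_that("object co-occurrence handles identity, disjoint and nested masks", {
  a <- array(FALSE, c(1, 16, 16))
  a[1, 4:12, 4:12] <- TRUE
  co <- cooccurrence(a, a)
  expect_equal(co$pct_A_in_B, 100)
  expect_equal(co$pct_B_in_A, 100)

  b <- array(FALSE, dim(a)); b[1, 14:15, 14:15] <- TRUE
  co2 <- cooccurrence(a, b)
  expect_equal(co2$n_A_in_B, 0L)
  expect_equal(co2$pct_A_in_B, 0)
  expect_equal(co2$pct_B_in_A, 0)

  # one broad blob vs two sub-blobs inside it: the merged-structure case
  sub <- array(FALSE, dim(a))
  sub[1, 5:6, 5:6] <- TRUE
  sub[1, 9:10, 9:10] <- TRUE
  co3 <- cooccurrence(a, sub)
  expect_equal(co3$n_A, 1L)
  expect_equal(co3$n_B, 2L)
  expect_equal(co3$pct_A_in_B, 100)
  expect_equal(co3$pct_B_in_A, 100)

  expect_error(cooccurrence(a, array(FALSE, c(1, 8, 8))), "shape")
})

test_that("co-occurring component counts never exceed either side's total", {
  set.seed(7)
  for (i in 1:20) {
    a <- array(stats::runif(16 * 16) < 0.35, c(1, 16, 16))
    b <- array(stats::runif(16 * 16) < 0.35, c(1, 16, 16))
    co <- cooccurrence(a, b)
    expect_lte(co$n_A_in_B, co$n_A)
    expect_lte(co$n_B_in_A, co$n_B)
    prod_cc <- connected_components(a & b, "full")$n
    expect_lte(co$n_A_in_B, max(prod_cc, 0) + co$n_A)  # sanity bound
  }
})

test_that("axial persistence counts consecutive occupied slices", {
  m <- array(FALSE, c(8, 6, 6))
  m[3:5, 2, 2] <- TRUE
  out <- axial_persistence(m)
  expect_equal(out$persistence, 3L)
  expect_false(out$has_gap)

  # a z-gap is impossible for a 3D-connected component (every path steps at
  # most one slice), but labels imported from per-slice 2D segmentation can
  # have one; such regions are flagged
  g <- array(0L, c(6, 4, 8))
  g[2:3, 2, 2] <- 1L
  g[5, 2, 2] <- 1L       # same object id, absent on slice 4
  g[2:4, 3, 5] <- 2L
  expect_warning(out2 <- axial_persistence(g), "non-consecutive")
  expect_equal(out2$persistence, c(2L, 3L))
  expect_equal(out2$has_gap, c(TRUE, FALSE))
})

test_that("point reflectors persist across more slices in RCM than R-SIM", {
  truth <- point_scene()
  persistence_at <- function(mod, thr) {
    a <- render_quiet(truth, psf_preset(mod), NULL,
                      channels = "reflectance")$channels$reflectance$data
    axial_persistence(a >= thr * max(a))$persistence
  }
  for (thr in c(0.25, 0.3, 0.5))
    expect_gt(persistence_at("RCM", thr), persistence_at("RSIM", thr))
})

test_that("per-cell summaries count in-cell components only", {
  cell <- array(FALSE, c(4, 16, 16)); cell[2:3, 4:12, 4:12] <- TRUE
  np <- array(FALSE, dim(cell))
  np[2, 5, 5] <- TRUE; np[2, 8, 8] <- TRUE; np[3, 10, 10] <- TRUE
  np[2, 5, 6] <- TRUE  # touches the first spot -> same component
  np[1, 15, 15] <- TRUE  # outside the cell
  s <- per_cell_summary(cell, np, voxel_size_nm = c(200, 60, 60))
  expect_equal(s$n_components, 3L)
  expect_equal(s$total_volume_nm3, 4 * 200 * 60 * 60)

  outside <- array(FALSE, dim(cell)); outside[1, 15, 15] <- TRUE
  expect_equal(per_cell_summary(cell, outside)$n_components, 0L)
  expect_error(per_cell_summary(array(FALSE, dim(cell)), np), "empty cell")

  # control scene end-to-end: zero uptake
  ctrl <- generate_ground_truth(shape = c(8, 64, 64), control = TRUE, seed = 51)
  ctrl2 <- generate_ground_truth(shape = c(8, 64, 64), control = TRUE, seed = 52)
  r1 <- render_quiet(ctrl, psf_preset("RCM"), noise_params(1, 50, 51))
  r2 <- render_quiet(ctrl2, psf_preset("RCM"), noise_params(1, 50, 52),
                     channels = "reflectance")
  cellm <- segment_cell(r1$channels$cytoplasm)
  npm <- segment_np(r1$channels$reflectance, r2$channels$reflectance)[[1]]
  s2 <- per_cell_summary(cellm, npm, voxel_size_nm = c(200, 60, 60))
  expect_lte(s2$n_components, 2L)
  expect_lt(sum(npm & cellm) / sum(cellm), 0.001)
})

test_that("pooled t-test matches the textbook formula", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  r <- two_sample_ttest(a, b)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t, t_hand)
  expect_lt(r$p, 0.001)

  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  h <- c(2.1, 3.4, 2.9); g <- c(4.0, 5.2, 4.4)
  rh <- two_sample_ttest(h, g)
  sp2h <- (2 * stats::var(h) + 2 * stats::var(g)) / 4
  expect_equal(rh$t, (mean(h) - mean(g)) / sqrt(sp2h * 2 / 3))
  expect_equal(rh$df, 4)

  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "variance")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})
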