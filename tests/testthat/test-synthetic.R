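test_that("ground-truth generation is deterministic and geometrically valid", {
  p <- list(shape = c(10, 64, 64), n_clusters = 50, seed = 11)
  t1 <- generate_ground_truth(shape = p$shape, n_clusters = p$n_clusters,
                              seed = p$seed)
  t2 <- generate_ground_truth(shape = p$shape, n_clusters = p$n_clusters,
                              seed = p$seed)
  expect_identical(t1, t2)

  # every centre lies in cytoplasm (cell minus nucleus), checked by
  # point-in-mask lookup of the containing voxel
  vox <- t1$voxel_size_nm
  idx <- cbind(round(t1$np_clusters$z_nm / vox[1]) + 1,
               round(t1$np_clusters$y_nm / vox[2]) + 1,
               round(t1$np_clusters$x_nm / vox[3]) + 1)
  expect_true(all(t1$cell_mask[idx]))
  expect_true(all(!t1$nucleus_mask[idx]))

  ctrl <- generate_ground_truth(shape = p$shape, control = TRUE, seed = p$seed)
  expect_identical(nrow(ctrl$np_clusters), 0L)

  expect_error(generate_ground_truth(shape = c(8, 64, 64), n_clusters = 1e7),
               "cytoplasm")
  expect_error(generate_ground_truth(shape = c(4, 32, 32)), "at least")
})

test_that("minimum-separation placement honours the exclusion distance", {
  t <- generate_ground_truth(shape = c(12, 96, 96), n_clusters = 10,
                             min_separation_nm = 1500, seed = 3)
  p <- as.matrix(t$np_clusters[, c("z_nm", "y_nm", "x_nm")])
  dmin <- min(dist(p))
  expect_gte(dmin, 1500)
})

test_that("rendered isolated point reproduces the preset PSF width per axis", {
  truth <- point_scene()
  ctr <- as.numeric(truth$np_clusters[1, c("z_nm", "y_nm", "x_nm")])
  for (mod in c("RCM", "RSIM")) {
    psf <- psf_preset(mod)
    st <- render_quiet(truth, psf, noise = NULL, channels = "reflectance")
    img <- st$channels$reflectance
    expected <- c(x = psf$fwhm_lateral, y = psf$fwhm_lateral, z = psf$fwhm_axial)
    voxel <- c(x = 60, y = 60, z = 200)
    for (ax in c("x", "y", "z")) {
      pr <- line_profile(img, ctr, ax, half_length_nm = 1.8 * expected[[ax]])
      est <- fwhm_from_profile(pr, baseline = "zero")
      expect_lt(abs(est$fwhm_nm - expected[[ax]]), voxel[[ax]],
                label = sprintf("%s axis %s FWHM error", mod, ax))
    }
  }
})

test_that("rendering is seed-deterministic and control scenes stay dim", {
  truth <- generate_ground_truth(shape = c(8, 64, 64), n_clusters = 4,
                                 amplitude_range = c(900, 1100), seed = 7)
  nz <- noise_params(1, 30, seed = 7)
  a <- render_quiet(truth, psf_preset("RCM"), nz)
  b <- render_quiet(truth, psf_preset("RCM"), nz)
  expect_identical(a$channels$reflectance$data, b$channels$reflectance$data)

  ctrl <- generate_ground_truth(shape = c(8, 64, 64), n_clusters = 0,
                                amplitude_range = c(900, 1100),
                                control = TRUE, seed = 8)
  cs <- render_quiet(ctrl, psf_preset("RCM"), NULL, channels = "reflectance")
  # background texture tops out at 15% of the smallest treated amplitude
  expect_lt(max(cs$channels$reflectance$data), 900)
  expect_gt(max(cs$channels$reflectance$data), 0)
})

test_that("two impulses 200 nm apart are resolved by R-SIM but merged by RCM", {
  # closed form: the sum of two Gaussians separated by s is bimodal along the
  # joining line iff s > 2*sigma; here s = 200 nm, RSIM sigma = 48.8 nm
  # (bimodal), RCM sigma = 146.5 nm (unimodal)
  truth <- point_scene(shape = c(16, 64, 64))
  vox <- c(200, 25, 25)
  truth$voxel_size_nm <- vox
  ctr <- c(8, 32, 32) * vox
  truth$np_clusters <- truth$np_clusters[c(1, 1), ]
  truth$np_clusters$z_nm <- ctr[1]
  truth$np_clusters$y_nm <- ctr[2]
  truth$np_clusters$x_nm <- ctr[3] + c(-100, 100)
  count_maxima <- function(mod) {
    st <- render_quiet(truth, psf_preset(mod), NULL, channels = "reflectance")
    pr <- line_profile(st$channels$reflectance, ctr, "x", 500)
    y <- pr$intensity
    sum(diff(sign(diff(y))) < 0)
  }
  expect_identical(count_maxima("RSIM"), 2L)
  expect_identical(count_maxima("RCM"), 1L)
})

test_that("more local maxima survive the finer PSF (resolution ordering)", {
  truth <- generate_ground_truth(shape = c(10, 80, 80), n_clusters = 12,
                                 amplitude_range = c(1000, 1000),
                                 background_level = 0,
                                 min_separation_nm = 400, seed = 5)
  count_max3d <- function(mod) {
    a <- render_quiet(truth, psf_preset(mod), NULL,
                      channels = "reflectance")$channels$reflectance$data
    d <- dim(a)
    n <- 0L
    for (i in which(a > 100)) {
      co <- arrayInd(i, d)
      if (any(co == 1) || any(co == d)) next
      nb <- a[co[1] + (-1:1), co[2] + (-1:1), co[3] + (-1:1)]
      if (a[i] == max(nb) && sum(nb == a[i]) == 1L) n <- n + 1L
    }
    n
  }
  expect_gte(count_max3d("RSIM"), count_max3d("RCM"))
})

test_that("TEM sections tile the axial range and capture slab membership", {
  truth <- generate_ground_truth(shape = c(8, 64, 64),
                                 voxel_size_nm = c(60, 60, 60),
                                 n_clusters = 1, radius_range = c(20, 20),
                                 background_level = 0, seed = 2)
  truth$np_clusters$z_nm <- 220  # inside section 2 of 3 (150-300 nm)
  secs <- render_tem_sections(truth, section_thickness_nm = 150,
                              n_sections = 3)
  zr <- attr(secs, "z_ranges_nm")
  expect_equal(zr[, 2] - zr[, 1], rep(150, 3))
  expect_equal(zr[3, 2], 450)
  darkness <- vapply(secs, function(s) 1 - min(s$data), 0)
  expect_gt(darkness[2], 0.5)
  expect_lt(darkness[1], 0.05)
  expect_lt(darkness[3], 0.05)

  # two sections of 150 nm cover a 300 nm composite slab
  secs2 <- render_tem_sections(truth, 150, 2)
  zr2 <- attr(secs2, "z_ranges_nm")
  expect_equal(zr2[2, 2] - zr2[1, 1], 300)

  # empty scene: uniform background
  ctrl <- generate_ground_truth(shape = c(8, 64, 64),
                                voxel_size_nm = c(60, 60, 60),
                                control = TRUE, background_level = 0, seed = 2)
  su <- render_tem_sections(ctrl, 150, 2)
  expect_equal(max(su[[1]]$data), min(su[[1]]$data))

  expect_error(render_tem_sections(truth, 200, 4), "axial extent")
})
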