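test_that("line profiles reproduce grid rows exactly and interpolate off-grid", {
  a <- array(stats::rnorm(6 * 16 * 16), c(6, 16, 16))
  img <- volume_image(a, c(200, 60, 60))
  # axis x through a voxel row: exactly the row's values
  ctr <- c((3 - 1) * 200, (5 - 1) * 60, (8 - 1) * 60)
  pr <- line_profile(img, ctr, "x", half_length_nm = 4 * 60)
  expect_equal(pr$intensity, a[3, 5, 4:12])
  expect_equal(pr$spacing_nm, 60)

  # constant image: constant profile
  cimg <- volume_image(array(3.5, c(6, 16, 16)), c(200, 60, 60))
  expect_true(all(line_profile(cimg, ctr, "y", 240)$intensity == 3.5))

  # analytic Gaussian image sampled off-grid matches the closed form
  sig <- 150
  g <- array(0, c(6, 32, 32))
  for (x in 1:32) g[, , x] <- exp(-(((x - 1) * 60 - 940)^2) / (2 * sig^2))
  gi <- volume_image(g, c(200, 60, 60))
  prg <- line_profile(gi, c(400, 900, 940), "x", 600)
  expect_equal(prg$intensity,
               exp(-((prg$positions_nm - 940)^2) / (2 * sig^2)),
               tolerance = 1e-6)

  expect_error(line_profile(img, c(200, 60, 60), "x", 1e5), "outside")
})

test_that("FWHM of sampled Gaussians matches the closed form across widths", {
  # oracle: FWHM = 2*sqrt(2*log(2)) * sigma = 2.3548 sigma
  for (sig in c(50, 100, 200, 350, 500)) {
    x <- seq(-4 * sig, 4 * sig, by = 60)
    pr <- profile_from_values(x, exp(-x^2 / (2 * sig^2)))
    est <- fwhm_from_profile(pr, baseline = "zero")
    expect_lt(abs(est$fwhm_nm - 2.3548 * sig), 30,
              label = sprintf("sigma %g", sig))
  }
  # off-grid peaks across sub-pixel phases
  for (off in seq(-25, 25, by = 10)) {
    x <- seq(-400, 400, by = 60)
    pr <- profile_from_values(x, exp(-(x - off)^2 / (2 * 100^2)))
    est <- fwhm_from_profile(pr, baseline = "zero")
    expect_lt(abs(est$fwhm_nm - 235.48), 30)
    expect_lt(abs(est$peak_position_nm - off), 30)
  }
})

test_that("triangle peaks and baselines behave geometrically", {
  # triangle of half-width w at half height: FWHM = w
  x <- seq(-300, 300, by = 30)
  y <- pmax(1 - abs(x) / 200, 0)
  est <- fwhm_from_profile(profile_from_values(x, y), baseline = "zero")
  expect_equal(est$fwhm_nm, 200, tolerance = 1e-9)

  # a constant pedestal is absorbed by the min baseline, not by zero
  est_min <- fwhm_from_profile(profile_from_values(x, y + 0.5), "min")
  expect_equal(est_min$fwhm_nm, 200, tolerance = 1e-9)

  # scale equivariance: intensity scaling leaves FWHM unchanged; position
  # shifts move the peak equally
  est2 <- fwhm_from_profile(profile_from_values(x, 7 * y), baseline = "zero")
  expect_equal(est2$fwhm_nm, est$fwhm_nm)
  est3 <- fwhm_from_profile(profile_from_values(x + 500, y), baseline = "zero")
  expect_equal(est3$peak_position_nm - est$peak_position_nm, 500)

  expect_error(fwhm_from_profile(profile_from_values(x, x)), "boundary")
  expect_error(
    fwhm_from_profile(profile_from_values(x, pmax(1 - abs(x) / 2000, 0.7)),
                      baseline = "zero"),
    "left|right")
})

test_that("double peaks split at the interior minimum into two estimates", {
  # sum of two Gaussians 400 nm apart, sigma 49: closed-form bimodal
  x <- seq(-600, 1000, by = 30)
  y <- exp(-x^2 / (2 * 49^2)) + exp(-(x - 400)^2 / (2 * 49^2))
  parts <- split_at_minima(profile_from_values(x, y))
  expect_length(parts, 2)
  ests <- vapply(parts, function(p)
    fwhm_from_profile(p, baseline = "zero")$fwhm_nm, 0)
  expect_true(all(abs(ests - 2.3548 * 49) < 16))
  pos <- vapply(parts, function(p)
    fwhm_from_profile(p, baseline = "zero")$peak_position_nm, 0)
  expect_lt(abs(pos[1] - 0), 16)
  expect_lt(abs(pos[2] - 400), 16)

  expect_length(split_at_minima(profile_from_values(
    x, exp(-x^2 / (2 * 200^2)))), 1)
})

test_that("estimated FWHM increases strictly with the preset width", {
  truth <- point_scene()
  ctr <- as.numeric(truth$np_clusters[1, c("z_nm", "y_nm", "x_nm")])
  got <- vapply(c(150, 250, 345, 500), function(fw) {
    st <- render_quiet(truth, psf_preset("RCM", fwhm_lateral = fw,
                                         fwhm_axial = 3 * fw),
                       NULL, channels = "reflectance")
    pr <- line_profile(st$channels$reflectance, ctr, "x", 2 * fw)
    fwhm_from_profile(pr, baseline = "zero")$fwhm_nm
  }, 0)
  expect_true(all(diff(got) > 0))
})

test_that("measure_regions profiles detected points and skips bad geometry", {
  truth <- generate_ground_truth(shape = c(14, 128, 128), n_clusters = 6,
                                 amplitude_range = c(1000, 1000),
                                 radius_range = c(0, 0),
                                 min_separation_nm = c(2400, 800, 800),
                                 seed = 61)
  st <- render_quiet(truth, psf_preset("RCM"), noise_params(1, 50, 61),
                     channels = "reflectance")
  ctrl <- generate_ground_truth(shape = c(14, 128, 128), control = TRUE,
                                amplitude_range = c(1000, 1000), seed = 62)
  sc <- render_quiet(ctrl, psf_preset("RCM"), noise_params(1, 50, 62),
                     channels = "reflectance")
  mask <- segment_np(st$channels$reflectance, sc$channels$reflectance)[[1]]
  cc <- connected_components(mask, "full", voxel_size_nm = truth$voxel_size_nm)
  sub <- subtract_background(st$channels$reflectance, 6)
  meas <- measure_regions(sub, cc, axes = c("x", "y"),
                          half_length_nm = 520, baseline = "zero")
  lat <- lateral_fwhm(meas)
  expect_gte(nrow(lat), 4)
  expect_true(all(abs(lat$fwhm_nm - 345) < 80))

  empty <- connected_components(array(FALSE, c(14, 128, 128)),
                                voxel_size_nm = truth$voxel_size_nm)
  expect_identical(nrow(measure_regions(sub, empty)), 0L)
})

test_that("FWHM summaries report sample statistics and a normal fit", {
  s <- summarize_fwhm(c(300, 400))
  expect_equal(s$mean, 350)
  expect_equal(s$sd, 70.71068, tolerance = 1e-6)
  expect_identical(s$n, 2L)
  expect_equal(s$fit$mean, 350)

  expect_error(summarize_fwhm(100), "at least 2")
  s2 <- summarize_fwhm(data.frame(fwhm_nm = c(100, 100, 100)))
  expect_equal(s2$mean, 100)
  expect_equal(s2$sd, 0)
})
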