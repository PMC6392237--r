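# Reflectance calibration: panel fit, PVC transfer, height-resolved
# conversion factors, and forward/inverse consistency with the generator.

make_flat_cube <- function(values, wl = c(450, 550, 650)) {
  # 8 x 6 image in which every pixel has spectrum `values`
  arr <- array(rep(values, each = 8 * 6), c(8, 6, length(wl)))
  spectral_cube(arr, wl)
}

test_that("panel calibration: identity, linearity, saturation handling", {
  r_spec <- c(0.9, 0.95, 1.0)
  cube <- make_flat_cube(r_spec)
  mask <- matrix(TRUE, 8, 6)
  cal <- fit_spectralon(cube, mask, r_spec)
  expect_equal(unname(as.vector(cal$a_spec)), rep(1, 3 * 6), tolerance = 1e-12)
  expect_equal(cal$n_spec, 48L)

  cube2 <- make_flat_cube(2 * r_spec)
  cal2 <- fit_spectralon(cube2, mask, r_spec)
  expect_equal(as.vector(cal2$a_spec), rep(2, 18), tolerance = 1e-12)

  # saturated pixels are excluded and counted; all-saturated fails
  cube$saturated[1:4, ] <- TRUE
  cal3 <- fit_spectralon(cube, mask, r_spec)
  expect_equal(cal3$n_saturated_excluded, 24L)
  expect_equal(cal3$n_spec, 24L)
  cube$saturated[] <- TRUE
  expect_error(fit_spectralon(cube, mask, r_spec), "saturated")
  expect_error(fit_spectralon(cube, mask, c(0, 1, 1)), "positive")
})

test_that("panel conversion factor matches the generator forward model", {
  fx <- tiny_scene()
  spec <- fx$spec
  cal <- fx$cal$panel
  wl <- spec$wavelengths
  a <- seawater_attenuation(wl); E <- halogen_illumination(wl)
  path <- 2 * (spec$camera_altitude_m - spec$panel_height_cm / 100)
  cols <- ncol(fx$scene$cube$data)
  u <- (2 * (cal$x - 1) / (cols - 1)) - 1
  G <- 1 - spec$geometry_falloff * u^2
  expected <- outer(G, E * exp(-a * path))
  expect_equal(cal$a_spec, expected, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("PVC reflectance: identity, generator oracle, illumination invariance", {
  r_spec <- c(0.9, 0.95, 1.0)
  cube <- make_flat_cube(r_spec)
  mask_top <- matrix(FALSE, 8, 6); mask_top[1:4, ] <- TRUE
  mask_bot <- matrix(FALSE, 8, 6); mask_bot[5:8, ] <- TRUE
  cal <- fit_spectralon(cube, mask_top, r_spec)
  # PVC intensity equal to the panel's: R_PVC = R_spec
  expect_equal(derive_pvc_reflectance(cube, mask_bot, cal), r_spec,
               tolerance = 1e-12)
  expect_error(derive_pvc_reflectance(cube, matrix(FALSE, 8, 6), cal),
               "empty")

  # synthetic scene: recovered PVC spectrum matches the generator truth
  fx <- tiny_scene()
  pvc_true <- fx$spec$pvc_reflectance +
    0.03 * plogis((fx$spec$wavelengths - 500) / 100)
  expect_equal(fx$cal$r_pvc, pvc_true, tolerance = 0.02)

  # doubling the illumination cancels in the ratio
  bright <- fx$scene$cube
  bright$data <- bright$data * 2
  cal_b <- fit_spectralon(bright, fx$masks$spectralon,
                          fx$spec$spectralon_reflectance)
  r_b <- derive_pvc_reflectance(bright, fx$masks$pvc_at_panel_height, cal_b)
  expect_equal(r_b, fx$cal$r_pvc, tolerance = 1e-10)
})

test_that("height calibration: constant without attenuation, increasing with it", {
  # no attenuation, flat illumination: A constant in z
  spec0 <- tiny_spec(attenuation = "none", illumination = "none",
                     geometry_falloff = 0, noise_sd_relative = 0)
  sc0 <- render_beaker(spec0, tiny_design())
  m0 <- scene_masks(sc0$truth)
  cal0 <- calibrate_scene(sc0$cube, m0, spec0$spectralon_reflectance)
  a0 <- cal0$height$a
  for (k in 2:dim(a0)[2]) expect_equal(a0[, k, ], a0[, 1, ], tolerance = 1e-10)

  # with attenuation: higher object = shorter path = larger A (generator
  # sign convention); checked noiseless, where monotonicity is strict
  sc1 <- render_beaker(tiny_spec(noise_sd_relative = 0), tiny_design())
  cal1 <- calibrate_scene(sc1$cube, scene_masks(sc1$truth),
                          tiny_spec()$spectralon_reflectance)
  a1 <- cal1$height$a
  mid_x <- dim(a1)[1] %/% 2
  profile <- a1[mid_x, , dim(a1)[3] %/% 2]
  expect_true(all(diff(profile) > 0))
  fx <- tiny_scene()

  # querying a sampled height returns the exact grid value
  z <- fx$cal$height$height_grid_cm[3]
  expect_identical(conversion_at_height(fx$cal$height, z),
                   fx$cal$height$a[, 3, ])
  expect_error(conversion_at_height(fx$cal$height, 99), "outside")
})

test_that("to_reflectance: identity pixels, round trip, error bounds", {
  fx <- tiny_scene()
  refl <- fx$cal$reflectance
  truth <- fx$scene$truth
  np <- prod(dim(refl$data)[1:2])
  R <- flat_pixels(refl$data); Rt <- flat_pixels(truth$r_true)
  coral <- which(!(truth$label %in% c("background", "pvc", "spectralon")))
  rel <- abs(R[coral, ] - Rt[coral, ]) / pmax(Rt[coral, ], 1e-6)
  # median relative error within 3x the configured noise floor
  expect_lt(median(rel), 3 * fx$spec$noise_sd_relative)

  # wavelength-grid mismatch fails
  other <- fx$scene$cube
  other$wavelengths <- other$wavelengths + 1
  expect_error(to_reflectance(other, fx$cal$height), "wavelength grids")
})

test_that("whole-scene intensity scaling leaves reflectance unchanged", {
  fx <- tiny_scene()
  scaled <- fx$scene$cube
  scaled$data <- scaled$data * 3.7
  cal <- calibrate_scene(scaled, fx$masks, fx$spec$spectralon_reflectance,
                         fx$spec$panel_height_cm, fx$spec$sample_height_cm)
  expect_equal(cal$reflectance$data, fx$cal$reflectance$data,
               tolerance = 1e-10)
})

test_that("noiseless round trip is exact and wrong height inflates error", {
  spec0 <- tiny_spec(noise_sd_relative = 0)
  design <- tiny_design()
  sc <- render_beaker(spec0, design)
  masks <- scene_masks(sc$truth)
  cal <- calibrate_scene(sc$cube, masks, spec0$spectralon_reflectance)
  Rt <- flat_pixels(sc$truth$r_true); R <- flat_pixels(cal$reflectance$data)
  coral <- which(!(sc$truth$label %in% c("background", "pvc", "spectralon")))
  expect_lt(max(abs(R[coral, ] - Rt[coral, ]) / pmax(Rt[coral, ], 1e-9)),
            1e-10)

  # calibrating the same corals at the wrong height gives larger error
  wrong <- to_reflectance(sc$cube, cal$height, sample_height_cm = 2)
  Rw <- flat_pixels(wrong$data)
  err_right <- median(abs(R[coral, ] - Rt[coral, ]))
  err_wrong <- median(abs(Rw[coral, ] - Rt[coral, ]))
  expect_gt(err_wrong, err_right)
})

test_that("saturated pixels propagate to the reflectance mask", {
  fx <- tiny_scene()
  spec_sat <- fx$spec
  # saturate the brightest pixels only
  spec_sat$saturation_level <-
    stats::quantile(fx$scene$cube$data, 0.999)
  sc <- render_scene(spec_sat, fx$design, experiment = fx$experiment,
                     sample_ids = fx$experiment$samples$sample_id[1:3])
  expect_gt(sum(sc$cube$saturated), 0)
  masks <- scene_masks(sc$truth)
  cal <- calibrate_scene(sc$cube, masks, spec_sat$spectralon_reflectance)
  expect_identical(cal$reflectance$saturated, sc$cube$saturated)
})

test_that("calibration HDF5 container round-trips", {
  fx <- tiny_scene()
  path <- file.path(withr::local_tempdir(), "calib.h5")
  calibration_write(fx$cal$panel, fx$cal$height, path)
  back <- calibration_read(path)
  expect_equal(back$panel$a_spec, fx$cal$panel$a_spec, ignore_attr = TRUE)
  expect_equal(back$height$a, fx$cal$height$a, ignore_attr = TRUE)
  expect_equal(back$height$height_grid_cm, fx$cal$height$height_grid_cm)
  # reflectance computed from the re-read calibration is identical
  r2 <- to_reflectance(fx$scene$cube, back$height,
                       fx$spec$sample_height_cm)
  expect_equal(r2$data, fx$cal$reflectance$data, tolerance = 1e-12)
})
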