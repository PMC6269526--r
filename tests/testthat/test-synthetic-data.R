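test_that("phantom construction validates its inputs", {
  expect_error(make_vessel_phantom(list()), "non-empty")
  pl <- rbind(c(10, 50), c(200, 50))
  expect_error(vessel(pl, diameter_um = -5, so2 = 0.9, speed_mm_s = 1),
               "> 0")
  expect_error(vessel(pl, diameter_um = 20, so2 = 1.2, speed_mm_s = 1),
               "\\[0, 1\\]")
  expect_error(vessel(pl, diameter_um = 20, so2 = 0.9, speed_mm_s = -1),
               ">= 0")
  expect_error(make_vessel_phantom(
    list(vessel(pl, 20, 0.9, 1)), oxygen_field = matrix(-1, 4, 4)),
    "oxygen_field")
})

test_that("phantom stores the programmed truth verbatim", {
  ph <- make_vessel_phantom(list(
    vessel(rbind(c(10, 50), c(200, 50)), diameter_um = 50, so2 = 0.95,
           speed_mm_s = 1, class = "arterial")),
    dim = c(64L, 128L), pixel_size_um = 2)
  tt <- phantom_truth_table(ph)
  expect_equal(nrow(tt), 1)
  expect_equal(tt$diameter_um, 50)
  expect_equal(tt$so2, 0.95)
  expect_equal(tt$speed_mm_s, 1)
  expect_equal(tt$class, "arterial")
})

test_that("bifurcation truth conserves volumetric flow", {
  ph <- bifurcation_phantom(dp = 40, dd1 = 30, dd2 = 24, v1 = 1, v2 = 1.5)
  tt <- phantom_truth_table(ph)
  # evaluate F = v * pi * d^2 / 4 by hand for all three branches (uL/min)
  f_hand <- tt$speed_mm_s * 1e-3 * pi * (tt$diameter_um * 1e-6)^2 / 4 *
    1e9 * 60
  expect_equal(tt$flow_ul_min, f_hand, tolerance = 1e-12)
  expect_lt(abs(f_hand[1] - sum(f_hand[2:3])) / f_hand[1], 1e-9)
})

test_that("simulated amplitudes follow the hemoglobin spectra", {
  ph <- straight_phantom(30, so2 = 1, speed = 1)
  sc <- simulate_pam_scan(ph, fluence_ratio = 1.7, noise_sd = 0, seed = 1,
                          aline_n = 64)
  a532 <- project_amplitude(sc, 532, "max")
  a559 <- project_amplitude(sc, 559, "max")
  inside <- a559 > 0
  expect_true(any(inside))
  ext <- hb_extinction()
  want <- 1.7 * ext$eps_hbo2[ext$wavelength_nm == 532] /
    ext$eps_hbo2[ext$wavelength_nm == 559]
  expect_equal(unique(round(a532[inside] / a559[inside], 10)), want,
               tolerance = 1e-9)
  # doubling the fluence at 532 nm doubles that channel only
  sc2 <- simulate_pam_scan(ph, fluence_ratio = 3.4, noise_sd = 0, seed = 1,
                           aline_n = 64)
  expect_equal(project_amplitude(sc2, 532, "max"), 2 * a532)
  expect_equal(project_amplitude(sc2, 559, "max"), a559)
})

test_that("scan generation is bit-reproducible and seed-sensitive", {
  ph <- straight_phantom(20, so2 = 0.8, speed = 1.5)
  s1 <- simulate_pam_scan(ph, noise_sd = 0.05, seed = 7, aline_n = 256)
  s2 <- simulate_pam_scan(ph, noise_sd = 0.05, seed = 7, aline_n = 256)
  s3 <- simulate_pam_scan(ph, noise_sd = 0.05, seed = 8, aline_n = 256)
  expect_identical(s1$amp, s2$amp)
  expect_identical(s1$flow_stacks[[1]]$stack, s2$flow_stacks[[1]]$stack)
  expect_false(identical(s1$amp, s3$amp))
})

test_that("a stationary absorber pattern gives correlation 1", {
  ph <- straight_phantom(20, so2 = 0.8, speed = 0)
  sc <- simulate_pam_scan(ph, noise_sd = 0, seed = 2, aline_n = 512)
  stk <- sc$flow_stacks[[1]]$stack
  expect_equal(max(abs(sweep(stk, 1, stk[, 1]))), 0)
  cors <- vapply(2:ncol(stk), function(k) stats::cor(stk[, 1], stk[, k]),
                 numeric(1))
  expect_true(all(abs(cors - 1) < 1e-12))
})

test_that("ratiometric forward model quenches only the red channel", {
  po2 <- matrix(0, 16, 16)
  pair <- simulate_ratiometric_images(po2, ksv = 2, backgrounds = c(0, 0),
                                      noise_sd = 0)
  expect_equal(pair$blue, pair$red)

  po2 <- matrix(0.5, 16, 16)   # pO2 = 1/ksv
  pair <- simulate_ratiometric_images(po2, ksv = 2, backgrounds = c(0, 0),
                                      noise_sd = 0)
  expect_equal(pair$red, pair$blue / 2)

  expect_error(simulate_ratiometric_images(po2, ksv = -1), "ksv")

  pair_bg <- simulate_ratiometric_images(po2, ksv = 2,
                                         backgrounds = c(0.2, 0.3),
                                         noise_sd = 0)
  corr <- subtract_background(pair_bg)
  expect_equal(corr$blue, pair$blue)
  expect_equal(corr$red, pair$red)
})

test_that("wound mask series shrinks geometrically", {
  same <- simulate_wound_series(1, per_day_shrink = 0, days = c(0, 3, 6),
                                pixel_size_mm = 0.01)
  expect_identical(same[["0"]], same[["6"]])

  # halving the radius quarters the pixel-count area (disc >= 100 px radius)
  m <- simulate_wound_series(2, per_day_shrink = 1 - 0.5^(1 / 6),
                             days = c(0, 6), pixel_size_mm = 0.01)
  ratio <- sum(m[["6"]]) / sum(m[["0"]])
  expect_lt(abs(ratio - 0.25) / 0.25, 0.01)

  empty <- simulate_wound_series(0, 0.1, days = c(0, 1))
  expect_true(all(!empty[["0"]]))
  expect_error(simulate_wound_series(-1, 0.1, days = 0), "r0_mm")
  expect_error(simulate_wound_series(1, 1.5, days = 0), "per_day_shrink")
})

test_that("Bateman PK generator matches its closed form", {
  pk <- simulate_pk_profile(ka = 0.5, ke = 0.1, scale = 40,
                            times = c(0, 2, 4, 8, 16), noise_sd = 0)
  expect_equal(pk$conc[1], 0)
  expect_equal(pk$conc, 40 * (exp(-0.1 * pk$time_h) - exp(-0.5 * pk$time_h)))

  zero <- simulate_pk_profile(scale = 0, noise_sd = 0)
  expect_true(all(zero$conc == 0))

  expect_error(simulate_pk_profile(ka = 0.3, ke = 0.3), "degenerate")
  expect_error(simulate_pk_profile(times = c(0, 2, 1)), "increasing")

  # noiseless peak time is log(ka/ke)/(ka - ke)
  tt <- seq(0, 48, by = 0.25)
  pk2 <- simulate_pk_profile(ka = 0.4205, ke = 0.0439, scale = 52.31,
                             times = tt, noise_sd = 0)
  expect_equal(pk2$time_h[which.max(pk2$conc)],
               tt[which.min(abs(tt - bateman_tmax(0.4205, 0.0439)))])
})

test_that("default PK conditions reproduce the targeted exposure profile", {
  pk <- simulate_pk_profile(noise_sd = 0)
  s <- pk_summary(pk)
  expect_equal(s$tmax_h, 6)
  expect_equal(s$cmax, 36, tolerance = 1e-3)
  expect_equal(s$auc, 1081, tolerance = 0.01)
})
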