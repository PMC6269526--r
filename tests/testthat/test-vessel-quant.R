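test_that("segmentation counts match the phantom topology", {
  blank <- segment_vessels(matrix(0, 64, 64))
  expect_equal(blank$n_segments, 0L)
  expect_length(blank$centerlines, 0)

  ph <- straight_phantom(20, n = 160L)   # 10 px wide tube
  sc <- simulate_pam_scan(ph, noise_sd = 0, seed = 1, aline_n = 64)
  seg <- segment_vessels(structure_map(sc))
  expect_equal(seg$n_segments, 1L)

  # two crossing tubes split into >= 2 segments at the junction
  n <- 160L; px <- 2; ext <- n * px; c0 <- ext / 2 + 0.5
  ph2 <- make_vessel_phantom(list(
    vessel(rbind(c(0.1 * ext, c0), c(0.9 * ext, c0)), 20, 0.9, 1),
    vessel(rbind(c(c0, 0.1 * ext), c(c0, 0.9 * ext)), 20, 0.7, 1)
  ), dim = c(n, n), pixel_size_um = px)
  sc2 <- simulate_pam_scan(ph2, noise_sd = 0, seed = 1, aline_n = 64)
  seg2 <- segment_vessels(structure_map(sc2))
  expect_gte(seg2$n_segments, 2L)
})

test_that("diameter estimate agrees with the perpendicular-profile oracle", {
  px <- 2
  ph <- straight_phantom(20, ang_deg = 35, n = 160L, px = px)  # 10 px wide
  sc <- simulate_pam_scan(ph, noise_sd = 0, seed = 1, aline_n = 64)
  seg <- segment_vessels(structure_map(sc))
  tab <- vessel_metrics(seg, pixel_size_um = px)
  expect_equal(nrow(tab), 1)
  expect_lt(abs(tab$diameter_um - 20), 2)
  fwhm <- profile_fwhm_oracle(seg$mask * 1, seg$centerlines[[1]], px)
  expect_lt(abs(tab$diameter_um - fwhm) / fwhm, 0.1)
})

test_that("volumetric flow follows the hand-converted formula", {
  # v = 1 mm/s, d = 50 um: F = v pi d^2/4 = 1.9635e-12 m^3/s = 0.11781 uL/min
  expect_equal(volumetric_flow(1, 50), 1.9634954085e-12 * 1e9 * 60,
               tolerance = 1e-9)
  expect_equal(volumetric_flow(1, 50), 0.117809724510, tolerance = 1e-9)
  expect_equal(volumetric_flow(2, 0), 0)
  # table rows satisfy F = v pi d^2 / 4 to 1e-9 relative
  ph <- av_pair_phantom()
  q <- quantify_phantom(ph, seed = 2)
  with(q$table, expect_equal(
    flow_ul_min, speed_mm_s * 1e-3 * pi * (diameter_um * 1e-6)^2 / 4 * 6e10,
    tolerance = 1e-9))
})

test_that("vessels without valid sO2 pixels report missing, not zero", {
  ph <- straight_phantom(20)
  sc <- simulate_pam_scan(ph, noise_sd = 0, seed = 1, aline_n = 64)
  seg <- segment_vessels(structure_map(sc))
  so2 <- unmix_so2(project_amplitude(sc, 532), project_amplitude(sc, 559),
                   noise_floor = 10)   # everything below the floor
  tab <- vessel_metrics(seg, so2, NULL, pixel_size_um = 2)
  expect_true(is.na(tab$so2[1]))
  expect_true(is.na(tab$flow_ul_min[1]))
})

test_that("arterial/venous classification applies the threshold and ties", {
  tab <- data.frame(vessel_id = 1:3, diameter_um = c(20, 30, 25),
                    so2 = c(0.95, 0.95, 0.95),
                    speed_mm_s = 1, flow_ul_min = 0.1,
                    class = "unclassified", n_pixels = 100)
  expect_true(all(classify_av(tab)$class == "arterial"))
  tab$so2 <- c(0.75, 0.7499999, NA)
  cl <- classify_av(tab, so2_threshold = 0.75)
  expect_equal(cl$class, c("arterial", "venous", "unclassified"))
  tab$so2 <- NA_real_
  expect_error(classify_av(tab), "missing")
  expect_error(classify_av(tab[0, ]), "empty")
})

test_that("classification matches programmed truth through the pipeline", {
  ph <- av_pair_phantom(so2_a = 0.95, so2_v = 0.65)
  q <- quantify_phantom(ph, seed = 3, with_flow = FALSE)
  tab <- classify_av(q$table)
  truth <- phantom_truth_table(ph)
  # match by sO2 proximity: each segment inherits its vessel's class
  want <- truth$class[vapply(tab$so2, function(s)
    which.min(abs(truth$so2 - s)), integer(1))]
  expect_equal(tab$class, want)
})

test_that("OEF arithmetic matches direct substitution and flags inversion", {
  mk <- function(so2, cls, flow = rep(1, length(so2)))
    data.frame(vessel_id = seq_along(so2), diameter_um = 30, so2 = so2,
               speed_mm_s = 1, flow_ul_min = flow, class = cls,
               n_pixels = 100)
  eq <- compute_oef(mk(c(0.8, 0.8), c("arterial", "venous")))
  expect_equal(eq$oef, 0)

  r <- compute_oef(mk(c(1.0, 0.6), c("arterial", "venous")))
  expect_equal(r$oef, 0.4)

  expect_error(compute_oef(mk(c(0, 0.1), c("arterial", "venous"))),
               "saO2")
  expect_warning(inv <- compute_oef(mk(c(0.6, 0.9),
                                       c("arterial", "venous"))),
                 "inverted")
  expect_lt(inv$oef, 0)
  expect_true(inv$inverted)

  # flow weighting: exact agreement with spreadsheet-style recomputation
  set.seed(11)
  for (i in 1:5) {
    tab <- mk(runif(6, 0.4, 1),
              sample(c("arterial", "venous"), 6, replace = TRUE,
                     prob = c(0.5, 0.5)),
              flow = runif(6, 0.01, 0.2))
    if (!any(tab$class == "arterial") || !any(tab$class == "venous")) next
    got <- suppressWarnings(compute_mro2(tab, compute_oef(tab)))
    want <- oef_mro2_oracle(tab)
    expect_equal(got$sao2, want$sao2, tolerance = 1e-12)
    expect_equal(got$oef, want$oef, tolerance = 1e-12)
    expect_equal(got$mro2, want$mro2, tolerance = 1e-12)
  }
})

test_that("MRO2 is arterial inflow times OEF", {
  tab <- data.frame(vessel_id = 1:2, diameter_um = 30,
                    so2 = c(0.9, 0.6), speed_mm_s = 1,
                    flow_ul_min = c(0.12, 0.10),
                    class = c("arterial", "venous"), n_pixels = 100)
  oef <- compute_oef(tab)
  r <- compute_mro2(tab, oef)
  expect_equal(r$mro2, 0.12 * oef$oef)
  oef0 <- oef; oef0$oef <- 0
  expect_equal(compute_mro2(tab, oef0)$mro2, 0)
  oef1 <- oef; oef1$oef <- 1
  expect_equal(compute_mro2(tab, oef1)$mro2, 0.12)
  ven_only <- tab[tab$class == "venous", ]
  expect_error(compute_mro2(ven_only, oef), "arterial")
})

test_that("longitudinal summary normalizes to baseline percent", {
  d <- expand.grid(metric = c("diameter", "flow"), timepoint = c(0, 7, 14),
                   group = "g", replicate = 1:3)
  d$value <- 2
  s <- longitudinal_summary(d, baseline = 0)
  expect_true(all(s$mean_pct == 100))
  expect_equal(unique(s$n), 3)

  one <- d[d$replicate == 1, ]
  s1 <- longitudinal_summary(one, baseline = 0)
  expect_true(all(is.na(s1$sem_pct)))

  d$value[1] <- 0
  expect_error(longitudinal_summary(d, baseline = 0), "zero baseline")
  expect_error(longitudinal_summary(d, baseline = 99), "baseline")
})

test_that("a programmed 1.5x diameter change reads out as 150%", {
  q0 <- quantify_phantom(straight_phantom(20, ang_deg = 20, n = 160L),
                         seed = 4, with_flow = FALSE)
  q1 <- quantify_phantom(straight_phantom(30, ang_deg = 20, n = 160L),
                         seed = 4, with_flow = FALSE)
  d <- data.frame(metric = "diameter", timepoint = c(0, 7), group = "g",
                  replicate = 1,
                  value = c(q0$table$diameter_um, q1$table$diameter_um))
  s <- longitudinal_summary(d, baseline = 0)
  expect_equal(s$mean_pct[s$timepoint == 7], 150, tolerance = 0.02)
})
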