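# Phantom builders shared across tests.

# Straight vessel through the image centre at angle `ang_deg`. The centre is
# offset by a quarter pixel so integer pixel widths rasterize to exactly
# that many pixel rows (no boundary ties on pixel centres).
straight_phantom <- function(diameter_um, so2 = 0.9, speed = 1, ang_deg = 0,
                             n = 128L, px = 2, frac_len = 0.4) {
  ext <- n * px
  c0 <- ext / 2 + px / 4
  L <- frac_len * ext
  dirv <- c(cos(ang_deg * pi / 180), sin(ang_deg * pi / 180))
  make_vessel_phantom(list(
    vessel(rbind(c(c0 - L * dirv[1], c0 - L * dirv[2]),
                 c(c0 + L * dirv[1], c0 + L * dirv[2])),
           diameter_um = diameter_um, so2 = so2, speed_mm_s = speed)
  ), dim = c(n, n), pixel_size_um = px)
}

# Oblique Y bifurcation with flow-conserving parent speed:
# parent at 45 deg, daughters at 15 and 75 deg, F_parent = F_d1 + F_d2.
bifurcation_phantom <- function(dp = 40, dd1 = 30, dd2 = 24,
                                v1 = 1.0, v2 = 1.5, n = 200L, px = 2) {
  ext <- n * px
  j <- c(ext / 2, ext / 2)
  dirp <- c(cos(pi / 4), sin(pi / 4))
  dir1 <- c(cos(pi / 12), sin(pi / 12))
  dir2 <- c(cos(5 * pi / 12), sin(5 * pi / 12))
  L <- 0.3 * ext
  vp <- (v1 * dd1^2 + v2 * dd2^2) / dp^2
  make_vessel_phantom(list(
    vessel(rbind(j - L * dirp, j), dp, 0.95, vp, class = "arterial"),
    vessel(rbind(j, j + L * dir1), dd1, 0.65, v1, class = "venous"),
    vessel(rbind(j, j + L * dir2), dd2, 0.65, v2, class = "venous")
  ), dim = c(n, n), pixel_size_um = px)
}

# Arterial/venous pair of parallel straight vessels.
av_pair_phantom <- function(so2_a = 0.95, so2_v = 0.65, speed_a = 2,
                            speed_v = 1.2, d_a = 24, d_v = 30,
                            n = 128L, px = 2) {
  ext <- n * px
  make_vessel_phantom(list(
    vessel(rbind(c(0.1 * ext, 0.3 * ext + 0.5), c(0.9 * ext, 0.3 * ext + 0.5)),
           d_a, so2_a, speed_a, class = "arterial"),
    vessel(rbind(c(0.1 * ext, 0.7 * ext + 0.5), c(0.9 * ext, 0.7 * ext + 0.5)),
           d_v, so2_v, speed_v, class = "venous")
  ), dim = c(n, n), pixel_size_um = px)
}

# Run the map-level pipeline (scan -> segmentation -> metrics) on a phantom.
quantify_phantom <- function(phantom, noise_sd = 0, seed = 1,
                             noise_floor = 0.05, with_flow = TRUE,
                             aline_n = if (with_flow) 16384L else 64L) {
  scan <- simulate_pam_scan(phantom, noise_sd = noise_sd, seed = seed,
                            aline_n = aline_n)
  seg <- segment_vessels(structure_map(scan))
  so2 <- unmix_so2(project_amplitude(scan, 532),
                   project_amplitude(scan, 559),
                   noise_floor = noise_floor)
  fm <- if (with_flow) flow_map(scan) else NULL
  tab <- vessel_metrics(seg, so2, fm,
                        pixel_size_um = phantom$pixel_size_um)
  list(scan = scan, seg = seg, so2 = so2, flow = fm, table = tab)
}
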