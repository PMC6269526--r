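#' Simulate a dual-wavelength PAM scan of a phantom
#'
#' Forward model for optical-resolution PAM acquisition. Inside each vessel
#' the expected (post-envelope) amplitude at wavelength lambda is
#' `fluence(lambda) * [so2 * epsHbO2(lambda) + (1 - so2) * epsHb(lambda)]`
#' (normalised by epsHbO2 at 532 nm), zero outside; a Gaussian depth profile
#' spreads it into a 3-D volume. For flowmetry, each vessel additionally gets
#' a repeated-A-line stack at 532 nm: a frozen 1-D random absorber pattern is
#' advected along the vessel axis by `speed / prf` per repeat (sub-pixel shift
#' by linear interpolation on a periodic fine grid), so the inter-repeat
#' decorrelation is a monotone function of speed. Noise is additive Gaussian
#' post-envelope.
#'
#' @param phantom a `PhantomTruth` from [make_vessel_phantom()].
#' @param fluence_ratio fluence(532)/fluence(559) (> 0); fluence at 559 nm is
#'   taken as 1.
#' @param noise_sd additive Gaussian noise sd, in the same arbitrary units as
#'   the amplitudes (peak blood amplitude is O(1)).
#' @param seed integer seed; the frozen absorber pattern of vessel i depends
#'   only on `seed` and `i`, never on its speed, so scans of the same phantom
#'   geometry at different programmed speeds share patterns.
#' @param n_depth depth samples per A-line in the volume.
#' @param depth_sigma_px Gaussian depth-profile sigma in depth samples.
#' @param prf A-line repetition rate in Hz.
#' @param n_repeats repeated A-lines per flow stack (100 as acquired).
#' @param w beam-waist parameter in um shared with [flow_speed()].
#' @param aline_n samples per flow A-line.
#' @param aline_dx sample spacing of the flow A-line along the vessel axis, um.
#' @param extinction extinction table, see [hb_extinction()].
#' @return A list of class `PAMScan` with elements `amp` (named list of 3-D
#'   arrays `[row, col, depth]` for "532" and "559"), `flow_stacks` (per
#'   vessel: `stack` matrix `aline_n x n_repeats`, footprint `mask`),
#'   `wavelengths`, `prf`, `w`, `n_repeats`, `pixel_size_um`, `params`.
#' @export
simulate_pam_scan <- function(phantom, fluence_ratio = 1, noise_sd = 0,
                              seed = 1L, n_depth = 16L, depth_sigma_px = 3,
                              prf = 2000, n_repeats = 100L, w = 3,
                              aline_n = 16384L, aline_dx = 0.5,
                              extinction = hb_extinction()) {
  stopifnot(inherits(phantom, "PhantomTruth"))
  stopifnot_scalar(fluence_ratio, "fluence_ratio", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(prf, "prf", positive = TRUE)
  stopifnot_scalar(w, "w", positive = TRUE)
  wavelengths <- c(532, 559)
  for (wl in wavelengths) extinction_at(wl, extinction)  # errors early

  dim <- phantom$dim
  fluence <- c(`532` = fluence_ratio, `559` = 1)
  depth_prof <- exp(-((seq_len(n_depth) - (n_depth + 1) / 2)^2) /
                      (2 * depth_sigma_px^2))

  local_seed(seed, {
    # frozen absorber patterns, drawn before any noise so they are invariant
    # to noise_sd and to per-vessel speeds
    patterns <- lapply(seq_along(phantom$vessels), function(i)
      frozen_pattern(w = w, cv = 0.25))

    peak <- lapply(wavelengths, function(wl) {
      m <- matrix(0, dim[1], dim[2])
      for (i in seq_along(phantom$vessels)) {
        v <- phantom$vessels[[i]]
        a <- fluence[[as.character(wl)]] *
          blood_absorption(v$so2, wl, extinction)
        mk <- vessel_mask(phantom, i)
        m[mk] <- pmax(m[mk], a)
      }
      m
    })
    names(peak) <- as.character(wavelengths)

    amp <- lapply(peak, function(m) {
      vol <- outer(m, depth_prof)
      if (noise_sd > 0)
        vol <- vol + array(stats::rnorm(length(vol), sd = noise_sd), dim(vol))
      vol
    })

    flow_stacks <- lapply(seq_along(phantom$vessels), function(i) {
      v <- phantom$vessels[[i]]
      a532 <- fluence[["532"]] * blood_absorption(v$so2, 532, extinction)
      stk <- advect_stack(patterns[[i]], speed_um_s = v$speed_mm_s * 1000,
                          prf = prf, n_repeats = n_repeats,
                          aline_n = aline_n, aline_dx = aline_dx) * a532
      if (noise_sd > 0)
        stk <- stk + matrix(stats::rnorm(length(stk), sd = noise_sd),
                            nrow(stk), ncol(stk))
      list(vessel_id = i, stack = stk, mask = vessel_mask(phantom, i))
    })

    structure(list(
      amp = amp,
      wavelengths = wavelengths,
      flow_stacks = flow_stacks,
      prf = prf, w = w, n_repeats = as.integer(n_repeats),
      pixel_size_um = phantom$pixel_size_um,
      params = list(fluence_ratio = fluence_ratio, noise_sd = noise_sd,
                    seed = as.integer(seed), n_depth = as.integer(n_depth),
                    depth_sigma_px = depth_sigma_px, aline_n = aline_n,
                    aline_dx = aline_dx)
    ), class = "PAMScan")
  })
}

# Frozen 1-D absorber pattern on a periodic fine grid. White noise smoothed
# with a circular Gaussian of sigma = w/2 gives pattern autocorrelation
# exp(-(shift/w)^2), the decay model the flow estimator fits. Mean 1, sd cv,
# clipped at 0 (cv << 1 keeps clipping negligible).
frozen_pattern <- function(w, len_um = 8192, dx = 0.25, cv = 0.25) {
  n <- as.integer(round(len_um / dx))
  z <- stats::rnorm(n)
  sigma <- (w / 2) / dx
  pos <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  kern <- exp(-pos^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  s <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / n
  s <- (s - mean(s)) / stats::sd(s)
  list(values = pmax(1 + cv * s, 0), dx = dx, len_um = len_um)
}

# Sample the frozen pattern at aline positions shifted by speed/prf per
# repeat, with linear interpolation on the periodic fine grid.
advect_stack <- function(pattern, speed_um_s, prf, n_repeats, aline_n,
                         aline_dx) {
  delta <- speed_um_s / prf
  x0 <- (seq_len(aline_n) - 1) * aline_dx
  vapply(seq_len(n_repeats), function(k) {
    circular_interp(pattern, x0 + (k - 1) * delta)
  }, numeric(aline_n))
}

circular_interp <- function(pattern, x) {
  n <- length(pattern$values)
  u <- (x / pattern$dx) %% n      # fractional index on [0, n)
  i0 <- floor(u)
  frac <- u - i0
  i0 <- as.integer(i0 %% n) + 1L
  i1 <- i0 %% n + 1L
  (1 - frac) * pattern$values[i0] + frac * pattern$values[i1]
}

#' Simulate a ratiometric fluorescence/phosphorescence channel pair
#'
#' Forward model of the boron-nanoparticle oxygen sensor: the blue
#' (fluorescence) channel is oxygen-independent, the red (phosphorescence)
#' channel is quenched by oxygen following Stern-Volmer kinetics,
#' `red = gain * B0 / (1 + ksv * pO2)`, with emitter brightness `B0` constant
#' across the field. Backgrounds model the pre-injection images and are
#' returned noiselessly.
#'
#' @param oxygen_field non-negative matrix of relative pO2 (arbitrary units).
#' @param ksv Stern-Volmer constant (>= 0), in inverse pO2 units.
#' @param backgrounds numeric c(blue, red) background levels (scalars).
#' @param gain common detector gain.
#' @param noise_sd additive Gaussian noise sd on the signal channels.
#' @param seed integer seed.
#' @param b0 emitter brightness (constant across the field).
#' @return A list of class `ChannelPair` with matrices `blue`, `red`,
#'   `blue_bg`, `red_bg` and the scalar `gain`.
#' @export
simulate_ratiometric_images <- function(oxygen_field, ksv,
                                        backgrounds = c(0, 0), gain = 1,
                                        noise_sd = 0, seed = 1L, b0 = 1) {
  oxygen_field <- as.matrix(oxygen_field)
  if (any(!is.finite(oxygen_field)) || any(oxygen_field < 0))
    stop("'oxygen_field' must be finite and >= 0", call. = FALSE)
  stopifnot_scalar(ksv, "ksv", nonneg = TRUE)
  stopifnot_scalar(gain, "gain", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot(length(backgrounds) == 2, all(backgrounds >= 0))
  d <- dim(oxygen_field)
  blue_bg <- matrix(backgrounds[1], d[1], d[2])
  red_bg <- matrix(backgrounds[2], d[1], d[2])
  local_seed(seed, {
    blue <- gain * b0 + blue_bg
    red <- gain * b0 / (1 + ksv * oxygen_field) + red_bg
    if (noise_sd > 0) {
      blue <- blue + matrix(stats::rnorm(length(blue), sd = noise_sd), d[1], d[2])
      red <- red + matrix(stats::rnorm(length(red), sd = noise_sd), d[1], d[2])
    }
    structure(list(blue = pmax(blue, 0), red = pmax(red, 0),
                   blue_bg = blue_bg, red_bg = red_bg, gain = gain),
              class = "ChannelPair")
  })
}

#' Simulate a shrinking-wound mask series
#'
#' The open wound on day d is a disc of radius `r0 * (1 - per_day_shrink)^d`,
#' rasterized at `pixel_size_mm`. The default shrink rate of 0.05/day leaves
#' about 54% of the original area open on day 6, the closure level reported
#' for treated wounds in the study this package models.
#'
#' @param r0_mm day-0 wound radius in mm (>= 0).
#' @param per_day_shrink fractional radius shrink per day, in \[0, 1\].
#' @param days integer vector of days to rasterize.
#' @param pixel_size_mm raster pixel size (mm/px).
#' @param dim optional c(rows, cols); default fits the day-0 disc.
#' @param seed accepted for generator-interface uniformity; rasterization is
#'   deterministic.
#' @return Named list (by day) of logical matrices (TRUE = open wound).
#' @export
simulate_wound_series <- function(r0_mm, per_day_shrink = 0.05,
                                  days = c(0, 3, 6, 10, 14),
                                  pixel_size_mm = 0.02, dim = NULL,
                                  seed = 1L) {
  stopifnot_scalar(r0_mm, "r0_mm", nonneg = TRUE)
  stopifnot_scalar(per_day_shrink, "per_day_shrink")
  if (per_day_shrink < 0 || per_day_shrink > 1)
    stop("'per_day_shrink' must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar(pixel_size_mm, "pixel_size_mm", positive = TRUE)
  if (is.null(dim)) {
    n <- max(8L, as.integer(ceiling(2.4 * r0_mm / pixel_size_mm)))
    dim <- c(n, n)
  }
  cx <- dim[2] / 2 * pixel_size_mm
  cy <- dim[1] / 2 * pixel_size_mm
  ctr <- pixel_centers(dim, pixel_size_mm)
  px <- matrix(rep(ctr$x, each = dim[1]), dim[1], dim[2])
  py <- matrix(rep(ctr$y, times = dim[2]), dim[1], dim[2])
  rr2 <- (px - cx)^2 + (py - cy)^2
  masks <- lapply(days, function(d) {
    r <- r0_mm * (1 - per_day_shrink)^d
    rr2 <= r^2
  })
  names(masks) <- as.character(days)
  masks
}

#' Simulate a one-compartment skin concentration-time profile
#'
#' Bateman function `C(t) = scale * (exp(-ke t) - exp(-ka t))` with additive
#' Gaussian noise, negative draws clipped to 0. The defaults (`ka` 0.4205/h,
#' `ke` 0.0439/h, `scale` 52.31 pg/mg) emulate the intradermal VEGF-A mRNA
#' kinetics the package targets: peak 36 pg/mg tissue at 6 h and 144-h
#' exposure (trapezoidal AUC) of about 1065 pg*h/mg.
#'
#' @param ka absorption rate constant, 1/h (> 0).
#' @param ke elimination rate constant, 1/h (> 0, != ka).
#' @param scale concentration scale, pg/mg tissue.
#' @param times sampling times in hours, strictly increasing.
#' @param noise_sd additive Gaussian noise sd, pg/mg.
#' @param seed integer seed.
#' @return A data.frame of class `PKProfile` with columns `time_h`, `conc`;
#'   the Bateman parameters are stored in `attr(x, "pk_params")`.
#' @export
simulate_pk_profile <- function(ka = 0.4205, ke = 0.0439, scale = 52.31,
                                times = c(0, 1, 2, 4, 6, 9, 12, 18, 24, 36, 48, 72,
                                          96, 120, 144),
                                noise_sd = 0, seed = 1L) {
  stopifnot_scalar(ka, "ka", positive = TRUE)
  stopifnot_scalar(ke, "ke", positive = TRUE)
  if (isTRUE(all.equal(ka, ke)))
    stop("'ka' must differ from 'ke' (degenerate Bateman form)", call. = FALSE)
  stopifnot_scalar(scale, "scale", nonneg = TRUE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  local_seed(seed, {
    conc <- scale * (exp(-ke * times) - exp(-ka * times))
    if (noise_sd > 0) conc <- conc + stats::rnorm(length(times), sd = noise_sd)
    conc <- pmax(conc, 0)
    out <- data.frame(time_h = times, conc = conc)
    attr(out, "pk_params") <- list(ka = ka, ke = ke, scale = scale,
                                   noise_sd = noise_sd, seed = as.integer(seed))
    class(out) <- c("PKProfile", "data.frame")
    out
  })
}

#' Closed-form peak time of the Bateman function
#'
#' @param ka,ke absorption and elimination rate constants (1/h).
#' @return Tmax in hours, `log(ka/ke) / (ka - ke)`.
#' @export
bateman_tmax <- function(ka, ke) log(ka / ke) / (ka - ke)
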