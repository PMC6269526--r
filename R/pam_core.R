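#' Envelope of a raw photoacoustic A-line
#'
#' Magnitude of the analytic signal, computed by the frequency-domain Hilbert
#' construction (zeroing negative frequencies, doubling positive ones). This
#' is the standard envelope detector used to turn raw bipolar PAM pressure
#' traces into non-negative amplitude profiles from which vascular structure
#' is rendered.
#'
#' @param raw_aline finite real numeric vector, length >= 8.
#' @return Non-negative numeric vector of the same length.
#' @examples
#' t <- seq(0, 1, length.out = 256)
#' env <- envelope(3 * cos(2 * pi * 40 * t))
#' range(env[26:230])  # ~3 away from the edges
#' @export
envelope <- function(raw_aline) {
  x <- as.numeric(raw_aline)
  if (length(x) < 8) stop("A-line must have length >= 8", call. = FALSE)
  if (all(is.na(x))) stop("A-line is all NA", call. = FALSE)
  if (any(!is.finite(x))) stop("A-line must be finite", call. = FALSE)
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Lateral projection of a PAM amplitude volume
#'
#' Collapses the depth axis of one wavelength's amplitude volume into the 2-D
#' en-face map the downstream stages work on. `"max"` is the
#' maximum-amplitude projection used for structure; `"mean"` averages over
#' depth, which suppresses additive noise and is the default input to
#' spectral unmixing.
#'
#' @param scan a `PAMScan`.
#' @param wavelength 532 or 559.
#' @param method "mean" or "max".
#' @return Numeric matrix.
#' @export
project_amplitude <- function(scan, wavelength,
                              method = c("mean", "max")) {
  stopifnot(inherits(scan, "PAMScan"))
  method <- match.arg(method)
  vol <- scan$amp[[as.character(wavelength)]]
  if (is.null(vol)) stop(sprintf("scan has no %s nm volume", wavelength),
                         call. = FALSE)
  f <- if (method == "max") function(v) apply(v, c(1, 2), max)
       else function(v) apply(v, c(1, 2), mean)
  f(vol)
}

#' Vascular structure map (maximum-amplitude projection)
#'
#' @param scan a `PAMScan`.
#' @param wavelength wavelength to project (default 532 nm, near-isosbestic,
#'   so the map reflects total hemoglobin rather than oxygenation).
#' @return list of class `StructureMap`: `map` (non-negative matrix, clipped
#'   at 0) and `pixel_size_um`.
#' @export
structure_map <- function(scan, wavelength = 532) {
  m <- pmax(project_amplitude(scan, wavelength, "max"), 0)
  structure(list(map = m, pixel_size_um = scan$pixel_size_um),
            class = "StructureMap")
}

#' Dual-wavelength spectral unmixing of hemoglobin oxygen saturation
#'
#' Per valid pixel, solves the 2x2 linear system
#' `amp(lambda) = fluence(lambda) * (cHbO2 * epsHbO2(lambda) + cHb * epsHb(lambda))`
#' for the two hemoglobin concentrations and returns
#' `sO2 = cHbO2 / (cHbO2 + cHb)`. A negative component of the unconstrained
#' solution is clipped to the boundary of the non-negative quadrant before
#' normalising (the constrained least-squares solution in 2-D), so sO2 is
#' always in \[0, 1\]. Pixels whose 532-nm amplitude is below `noise_floor`
#' are flagged invalid, not zero-filled.
#'
#' @param amp532,amp559 co-registered 2-D amplitude maps.
#' @param extinction extinction table with rows for 532 and 559 nm.
#' @param fluence_ratio fluence(532)/fluence(559) (> 0).
#' @param noise_floor amplitude validity threshold on the 532-nm map.
#' @return list of class `SO2Map`: `so2` (matrix in \[0,1\], NA where
#'   invalid), `valid` (logical matrix), `params`.
#' @export
unmix_so2 <- function(amp532, amp559, extinction = hb_extinction(),
                      fluence_ratio = 1, noise_floor = 0) {
  amp532 <- as.matrix(amp532); amp559 <- as.matrix(amp559)
  if (!identical(dim(amp532), dim(amp559)))
    stop("amplitude maps must be co-registered (same dimensions)",
         call. = FALSE)
  stopifnot_scalar(fluence_ratio, "fluence_ratio", positive = TRUE)
  e532 <- extinction_at(532, extinction)
  e559 <- extinction_at(559, extinction)
  det <- e532$eps_hbo2 * e559$eps_hb - e559$eps_hbo2 * e532$eps_hb
  scale <- max(abs(c(e532$eps_hbo2, e532$eps_hb, e559$eps_hbo2, e559$eps_hb)))
  if (abs(det) < 1e-12 * scale^2)
    stop("extinction spectra are collinear; unmixing is singular",
         call. = FALSE)
  b1 <- amp532 / fluence_ratio
  b2 <- amp559
  c_hbo2 <- (e559$eps_hb * b1 - e532$eps_hb * b2) / det
  c_hb <- (e532$eps_hbo2 * b2 - e559$eps_hbo2 * b1) / det
  # boundary solution of the non-negative constrained problem
  c_hbo2_c <- pmax(c_hbo2, 0)
  c_hb_c <- pmax(c_hb, 0)
  tot <- c_hbo2_c + c_hb_c
  so2 <- ifelse(tot > 0, c_hbo2_c / tot, NA_real_)
  so2 <- clamp(so2, 0, 1)
  valid <- amp532 >= noise_floor & !is.na(so2)
  so2[!valid] <- NA_real_
  structure(list(so2 = so2, valid = valid,
                 params = list(fluence_ratio = fluence_ratio,
                               noise_floor = noise_floor)),
            class = "SO2Map")
}

#' Flow speed from the decorrelation of repeated A-lines
#'
#' Computes the normalized (Pearson) correlation `C(k)` between repeated
#' A-lines separated by lag `k` (averaged over all pairs at each lag, on
#' mean-subtracted A-lines) and fits the Gaussian decorrelation model
#' `C(k) = exp(-(v * k / (prf * w))^2)`, where `w` is the beam-waist
#' parameter shared with the simulator. The fit is a no-intercept linear
#' regression of `-log C(k)` on `k^2` over lags 1..`max_lag`, restricted to
#' lags with `C(k)` above a small positive floor (excludes the noise
#' plateau). Speed is reported in mm/s; quality is the R^2 between observed
#' and fitted `C(k)`, clipped to \[0, 1\].
#'
#' @param flow_stack matrix, samples x repeats (>= 10 repeats).
#' @param prf A-line repetition rate, Hz.
#' @param w beam-waist parameter, um.
#' @param max_lag largest lag used in the fit.
#' @param c_floor lags with mean correlation below this are excluded.
#' @return list: `speed_mm_s` (>= 0), `quality` in \[0,1\], `degenerate`
#'   (TRUE for a constant stack, reported as speed 0).
#' @export
flow_speed <- function(flow_stack, prf, w, max_lag = 10L, c_floor = 0.05) {
  flow_stack <- as.matrix(flow_stack)
  n_rep <- ncol(flow_stack)
  if (n_rep < 10) stop("need >= 10 repeated A-lines", call. = FALSE)
  stopifnot_scalar(prf, "prf", positive = TRUE)
  stopifnot_scalar(w, "w", positive = TRUE)
  sds <- apply(flow_stack, 2, stats::sd)
  if (all(sds < 1e-14 * max(abs(flow_stack), 1)))
    return(list(speed_mm_s = 0, quality = 0, degenerate = TRUE))
  x <- sweep(flow_stack, 2, colMeans(flow_stack))
  x <- sweep(x, 2, pmax(sds, .Machine$double.eps), "/")
  cc <- crossprod(x) / (nrow(x) - 1)            # repeat-by-repeat Pearson
  max_lag <- min(max_lag, n_rep - 1L)
  ck <- vapply(seq_len(max_lag), function(k) {
    i <- seq_len(n_rep - k)
    mean(cc[cbind(i, i + k)])
  }, numeric(1))
  # truncate at the first drop below the floor: beyond it the true
  # correlation is gone and finite-pattern noise can produce spurious
  # revivals that would dominate the k^4-weighted slope
  below <- which(ck <= c_floor)
  use <- if (length(below)) seq_len(below[1] - 1L) else seq_len(max_lag)
  if (!length(use)) {
    # decorrelated already at lag 1: bound the speed from C(1)
    a <- -log(max(ck[1], 1e-6))
    v <- prf * w * sqrt(a) / 1000
    return(list(speed_mm_s = v, quality = 0, degenerate = FALSE))
  }
  k <- use
  y <- -log(ck[use])
  # no-intercept WLS of y = a k^2; weights C^2 are the delta-method inverse
  # variance of log C, which keeps the noisy small-C lags from dominating
  wts <- ck[use]^2
  a <- sum(wts * k^2 * y) / sum(wts * k^4)
  a <- max(a, 0)
  v <- prf * w * sqrt(a) / 1000                 # um/s -> mm/s
  fit <- exp(-a * k^2)
  ss_tot <- sum((ck[use] - mean(ck[use]))^2)
  qual <- if (ss_tot > 0) 1 - sum((ck[use] - fit)^2) / ss_tot else 1
  list(speed_mm_s = v, quality = clamp(qual, 0, 1), degenerate = FALSE)
}

#' Per-pixel flow-speed map from a scan's repeated-A-line stacks
#'
#' Runs [flow_speed()] on every flow stack of a `PAMScan` and paints the
#' estimate over the stack's acquisition footprint. Where footprints overlap
#' (e.g. around a junction) the smaller footprint wins: an acquisition
#' focused on a thin vessel is specific to it, while a large vessel's
#' footprint merely brushes the junction.
#'
#' @param scan a `PAMScan`.
#' @param prf,w override the scan's stored acquisition parameters.
#' @param ... passed to [flow_speed()].
#' @return list of class `FlowMap`: `speed` (matrix, mm/s, NA where no stack
#'   covers the pixel), `quality` (matrix in \[0,1\]), `per_stack`
#'   (data.frame vessel_id, speed_mm_s, quality, degenerate).
#' @export
flow_map <- function(scan, prf = scan$prf, w = scan$w, ...) {
  stopifnot(inherits(scan, "PAMScan"))
  d <- dim(scan$amp[[1]])[1:2]
  speed <- matrix(NA_real_, d[1], d[2])
  qual <- matrix(0, d[1], d[2])
  owner_size <- matrix(Inf, d[1], d[2])
  ord <- order(vapply(scan$flow_stacks, function(fs) sum(fs$mask),
                      numeric(1)), decreasing = TRUE)
  per <- lapply(scan$flow_stacks[ord], function(fs) {
    est <- flow_speed(fs$stack, prf = prf, w = w, ...)
    sz <- sum(fs$mask)
    upd <- fs$mask & (is.na(speed) | sz < owner_size)
    speed[upd] <<- est$speed_mm_s
    qual[upd] <<- est$quality
    owner_size[upd] <<- sz
    data.frame(vessel_id = fs$vessel_id, speed_mm_s = est$speed_mm_s,
               quality = est$quality, degenerate = est$degenerate)
  })
  per <- per[order(vapply(per, `[[`, numeric(1), "vessel_id"))]
  structure(list(speed = speed, quality = qual,
                 per_stack = do.call(rbind, per)),
            class = "FlowMap")
}
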