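# Independent oracles kept deliberately separate from the implementation
# paths they check.

# Full width of a tube measured by perpendicular intensity profiles: at
# `n_points` positions along the centerline, step along the perpendicular in
# both directions at fine subpixel increments until the (binary, noiseless)
# image drops below half its plateau, and average the full widths.
profile_fwhm_oracle <- function(img, centerline, pixel_size_um,
                                n_points = 20, step = 0.1) {
  half <- max(img) / 2
  n <- nrow(centerline)
  use <- round(seq(0.2 * n, 0.8 * n, length.out = n_points))
  widths <- vapply(use, function(i) {
    a <- centerline[max(1, i - 5), ]
    b <- centerline[min(n, i + 5), ]
    tang <- b - a
    tang <- tang / sqrt(sum(tang^2))
    perp <- c(-tang[2], tang[1])
    extent <- function(sgn) {
      t <- 0
      repeat {
        t <- t + step
        p <- centerline[i, ] + sgn * t * perp
        r <- round(p[1]); c_ <- round(p[2])
        if (r < 1 || c_ < 1 || r > nrow(img) || c_ > ncol(img)) break
        if (img[r, c_] < half) break
      }
      t - step / 2
    }
    extent(1) + extent(-1)
  }, numeric(1))
  mean(widths) * pixel_size_um
}

# Plain-arithmetic recomputation of OEF and MRO2 from a vessel table, the
# way one would do it in a spreadsheet.
oef_mro2_oracle <- function(tab, weights = "flow") {
  art <- tab[tab$class == "arterial", ]
  ven <- tab[tab$class == "venous", ]
  wa <- if (weights == "flow") art$flow_ul_min else rep(1, nrow(art))
  wv <- if (weights == "flow") ven$flow_ul_min else rep(1, nrow(ven))
  sao2 <- sum(art$so2 * wa) / sum(wa)
  svo2 <- sum(ven$so2 * wv) / sum(wv)
  oef <- (sao2 - svo2) / sao2
  list(sao2 = sao2, svo2 = svo2, oef = oef,
       mro2 = sum(art$flow_ul_min) * oef)
}

# Exact two-sided permutation test for a difference in group means
# (complete enumeration of the C(n, nx) group assignments). At n = 8 + 8 the
# smallest attainable two-sided p is 2/12870, reached when only the observed
# assignment and its mirror produce as extreme a difference.
permutation_p_oracle <- function(x, y) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pool), nx)
  diffs <- apply(idx, 2, function(i)
    abs(mean(pool[i]) - mean(pool[-i])))
  mean(diffs >= obs - 1e-12)
}

# Smallest p the exact test can report for given group sizes.
permutation_p_floor <- function(nx, ny) 2 / choose(nx + ny, nx)

# Grid search for the saturation minimizing the dual-wavelength residual.
so2_grid_oracle <- function(amp532, amp559, fluence_ratio = 1,
                            grid = seq(0, 1, by = 1e-4)) {
  ext <- hb_extinction()
  e532 <- ext[ext$wavelength_nm == 532, ]
  e559 <- ext[ext$wavelength_nm == 559, ]
  resid <- vapply(grid, function(s) {
    m532 <- s * e532$eps_hbo2 + (1 - s) * e532$eps_hb
    m559 <- s * e559$eps_hbo2 + (1 - s) * e559$eps_hb
    # best total hemoglobin for this saturation, then residual norm
    b <- c(amp532 / fluence_ratio, amp559)
    a <- c(m532, m559)
    chb <- sum(a * b) / sum(a * a)
    sum((b - chb * a)^2)
  }, numeric(1))
  grid[which.min(resid)]
}

# Independent decorrelation fit: empirical lag correlations computed with
# stats::cor column pairs, then a nonlinear least-squares fit of the
# Gaussian decay (optimize over v).
flow_nls_oracle <- function(stack, prf, w, max_lag = 6) {
  n_rep <- ncol(stack)
  ck <- vapply(seq_len(max_lag), function(k) {
    mean(vapply(seq_len(n_rep - k), function(i)
      stats::cor(stack[, i], stack[, i + k]), numeric(1)))
  }, numeric(1))
  keep <- seq_len(max(which(ck > 0.05)[1], 1))
  keep <- keep[ck[keep] > 0]
  obj <- function(v_um_s)
    sum((ck[keep] - exp(-(v_um_s * keep / (prf * w))^2))^2)
  stats::optimize(obj, c(0, 10000))$minimum / 1000
}
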