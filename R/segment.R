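# Vessel segmentation: tubeness filtering, hysteresis thresholding,
# skeletonization and branch splitting.

#' Multiscale Frangi vesselness of a 2-D image
#'
#' Hessian-eigenvalue tubeness filter for bright curvilinear structures.
#' At each scale the image is convolved with scale-normalised Gaussian
#' second-derivative kernels; the vesselness response combines the eigenvalue
#' ratio (blobness) and the Hessian norm (structure strength) and is
#' maximised over scales.
#'
#' @param img non-negative numeric matrix.
#' @param scales Gaussian sigmas in pixels (roughly vessel radius).
#' @param beta blobness sensitivity (default 0.5).
#' @param c structure-strength sensitivity; default half the maximum Hessian
#'   norm, per scale.
#' @return matrix of the same size, >= 0.
#' @export
frangi_vesselness <- function(img, scales = c(1.5, 2.5, 4, 6), beta = 0.5,
                              c = NULL) {
  img <- as.matrix(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    h <- hessian_gauss(img, s)
    tmp <- sqrt(((h$xx - h$yy) / 2)^2 + h$xy^2)
    m <- (h$xx + h$yy) / 2
    l1 <- m + tmp   # larger algebraic value
    l2 <- m - tmp   # smaller (most negative for bright ridges)
    big <- ifelse(abs(l1) >= abs(l2), l1, l2)
    small <- ifelse(abs(l1) >= abs(l2), l2, l1)
    rb2 <- (small / ifelse(big == 0, .Machine$double.eps, big))^2
    s2 <- l1^2 + l2^2
    cs <- if (is.null(c)) sqrt(max(s2)) / 2 else c
    if (cs <= 0) cs <- .Machine$double.eps
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cs^2)))
    v[big >= 0] <- 0   # bright tube: principal curvature negative
    out <- pmax(out, v)
  }
  out
}

# Scale-normalised Gaussian Hessian via separable kernels (EBImage::filter2,
# zero-padded boundary).
hessian_gauss <- function(img, sigma) {
  r <- max(2L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- (-x / sigma^2) * g
  g2 <- ((x^2 - sigma^2) / sigma^4) * g
  f <- function(kr, kc) EBImage::filter2(img, outer(kr, kc), boundary = 0)
  list(xx = sigma^2 * f(g, g2),   # d2/dx2, x = columns
       yy = sigma^2 * f(g2, g),
       xy = sigma^2 * f(g1, g1))
}

# One Zhang-Suen thinning pass (vectorized); sub = 1 or 2 selects the
# directional deletion conditions.
zs_pass <- function(mask, sub) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ctr <- function(dr, dc) p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  # neighbours clockwise from north (P2..P9)
  n2 <- ctr(-1, 0); n3 <- ctr(-1, 1); n4 <- ctr(0, 1); n5 <- ctr(1, 1)
  n6 <- ctr(1, 0); n7 <- ctr(1, -1); n8 <- ctr(0, -1); n9 <- ctr(-1, -1)
  b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
  seqs <- list(n2, n3, n4, n5, n6, n7, n8, n9, n2)
  a <- matrix(0L, nr, nc)
  for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
  cond <- mask & b >= 2 & b <= 6 & a == 1
  if (sub == 1L)
    cond <- cond & !(n2 & n4 & n6) & !(n4 & n6 & n8)
  else
    cond <- cond & !(n2 & n4 & n8) & !(n2 & n6 & n8)
  mask & !cond
}

#' Morphological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' @param mask logical matrix.
#' @return logical matrix of the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  mask <- mask > 0
  repeat {
    m1 <- zs_pass(mask, 1L)
    m2 <- zs_pass(m1, 2L)
    if (identical(m2, mask)) break
    mask <- m2
  }
  mask
}

#' Segment vessels from a structure map
#'
#' Detects vessels by Frangi tubeness filtering, builds the binary vessel
#' mask by hysteresis thresholding of the amplitude image (seeds must exceed
#' the high threshold *and* carry tubeness response; the mask grows to all
#' amplitude pixels above the low threshold connected to a seed, which
#' preserves the full vessel width), skeletonizes the mask, splits the
#' skeleton at junction points and discards branches shorter than
#' `min_length` pixels. Thresholds are fractions of the 99th-percentile
#' amplitude. A blank image yields an empty result, not an error.
#'
#' @param structure a `StructureMap` or non-negative matrix.
#' @param hi_frac,lo_frac hysteresis thresholds as fractions of the
#'   99th-percentile amplitude.
#' @param scales tubeness scales in pixels, see [frangi_vesselness()].
#' @param vesselness_frac seed gate as a fraction of the maximum tubeness.
#' @param min_length minimum branch length in skeleton pixels.
#' @return list of class `VesselSegmentation`: `labels` (integer matrix, 0 =
#'   background), `centerlines` (list of ordered (row, col) matrices per
#'   segment), `mask` (logical), `skeleton` (logical), `n_segments`.
#' @export
segment_vessels <- function(structure, hi_frac = 0.5, lo_frac = 0.25,
                            scales = c(1.5, 2.5, 4, 6),
                            vesselness_frac = 0.05, min_length = 10L) {
  m <- if (inherits(structure, "StructureMap")) structure$map
       else as.matrix(structure)
  if (any(m < 0)) stop("structure map must be non-negative", call. = FALSE)
  empty <- list(labels = matrix(0L, nrow(m), ncol(m)),
                centerlines = list(), mask = m > Inf,
                skeleton = m > Inf, n_segments = 0L)
  class(empty) <- "VesselSegmentation"
  if (all(m == 0)) return(empty)
  q99 <- stats::quantile(m, 0.99, names = FALSE)
  if (q99 <= 0) return(empty)
  vs <- frangi_vesselness(m, scales = scales)
  seeds <- m >= hi_frac * q99 & vs >= vesselness_frac * max(vs)
  low <- m >= lo_frac * q99
  if (!any(seeds)) return(empty)
  low_lab <- label8(low)
  keep <- unique(low_lab[seeds])
  keep <- keep[keep > 0]
  mask <- matrix(low_lab %in% keep, nrow(m), ncol(m))
  skel <- skeletonize(mask)
  junction <- skel & crossing_number(skel) >= 3
  # removing a lone junction pixel leaves its neighbours 8-connected, so cut
  # out the junction's 1-px neighbourhood as well
  junction_zone <- junction | (neighbor_count8(junction) > 0)
  branches <- label8(skel & !junction_zone)
  sizes <- tabulate(branches[branches > 0])
  keep_b <- which(sizes >= min_length)
  if (!length(keep_b)) return(empty)
  centerlines <- vector("list", length(keep_b))
  relabel <- integer(max(branches))
  relabel[keep_b] <- seq_along(keep_b)
  for (j in seq_along(keep_b)) {
    idx <- which(branches == keep_b[j])
    rc <- cbind(row = ((idx - 1L) %% nrow(m)) + 1L,
                col = ((idx - 1L) %/% nrow(m)) + 1L)
    centerlines[[j]] <- order_branch(rc)
  }
  labels <- assign_labels(mask, branches, relabel)
  structure(list(labels = labels, centerlines = centerlines, mask = mask,
                 skeleton = skel, n_segments = length(keep_b)),
            class = "VesselSegmentation")
}

# Rutovitz crossing number: 0->1 transitions in the 8-neighbour ring. 2 for
# a pixel interior to a curve, 3+ at junctions; robust on diagonal staircase
# skeletons where a plain neighbour count over-triggers.
crossing_number <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ctr <- function(dr, dc) p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  ring <- list(ctr(-1, 0), ctr(-1, 1), ctr(0, 1), ctr(1, 1), ctr(1, 0),
               ctr(1, -1), ctr(0, -1), ctr(-1, -1), ctr(-1, 0))
  a <- matrix(0L, nr, nc)
  for (i in 1:8) a <- a + (!ring[[i]] & ring[[i + 1]])
  a
}

# Reduce a branch's (row, col) pixel set to its longest geodesic path: two
# Dijkstra sweeps (endpoint-to-farthest-endpoint) over the 8-neighbour graph
# with 1/sqrt(2) step weights. Short side spurs left by thinning are dropped
# from the polyline (they stay in the mask).
order_branch <- function(rc) {
  n <- nrow(rc)
  if (n <= 2) return(rc)
  nbrs <- lapply(seq_len(n), function(i) {
    j <- which(abs(rc[, 1] - rc[i, 1]) <= 1 & abs(rc[, 2] - rc[i, 2]) <= 1)
    j[j != i]
  })
  dijkstra <- function(src) {
    dist <- rep(Inf, n); prev <- integer(n)
    dist[src] <- 0
    done <- logical(n)
    for (it in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (v2 in nbrs[[u]]) {
        if (done[v2]) next
        wgt <- if (abs(rc[u, 1] - rc[v2, 1]) + abs(rc[u, 2] - rc[v2, 2]) == 2)
          sqrt(2) else 1
        if (dist[u] + wgt < dist[v2]) {
          dist[v2] <- dist[u] + wgt
          prev[v2] <- u
        }
      }
    }
    list(dist = dist, prev = prev)
  }
  a <- which.max(dijkstra(1L)$dist)
  da <- dijkstra(a)
  b <- which.max(da$dist)
  path <- b
  while (path[1] != a) path <- c(da$prev[path[1]], path)
  rc[path, , drop = FALSE]
}

# Assign every mask pixel to the nearest retained skeleton branch.
assign_labels <- function(mask, branches, relabel) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  sk_idx <- which(branches > 0)
  sk_idx <- sk_idx[relabel[branches[sk_idx]] > 0]
  if (!length(sk_idx)) return(labels)
  sk_r <- ((sk_idx - 1L) %% nrow(mask)) + 1L
  sk_c <- ((sk_idx - 1L) %/% nrow(mask)) + 1L
  sk_lab <- relabel[branches[sk_idx]]
  m_idx <- which(mask)
  m_r <- ((m_idx - 1L) %% nrow(mask)) + 1L
  m_c <- ((m_idx - 1L) %/% nrow(mask)) + 1L
  best_d <- rep(Inf, length(m_idx))
  best_l <- integer(length(m_idx))
  chunk <- 2000L
  for (s in seq(1L, length(sk_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(sk_idx))
    d <- outer(m_r, sk_r[s:e], "-")^2 + outer(m_c, sk_c[s:e], "-")^2
    j <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_along(m_idx), j)]
    upd <- dmin < best_d
    best_d[upd] <- dmin[upd]
    best_l[upd] <- sk_lab[s:e][j[upd]]
  }
  labels[m_idx] <- best_l
  labels
}
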