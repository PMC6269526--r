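# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a fixed RNG state, restoring the caller's state afterwards so
# generators are bit-reproducible without clobbering the session RNG.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# 8-connected labelling of a logical matrix by breadth-first flood fill.
# EBImage::bwlabel is 4-connected, which splits diagonal skeleton runs, so
# skeleton branches need their own labeller. Pixel counts here are small
# (skeletons, masks of desk-scale phantoms), so plain R is adequate.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  cur <- 0L
  off <- as.integer(c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1))
  row_of <- function(i) ((i - 1L) %% nr) + 1L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- row_of(p)
      nb <- p + off
      # drop neighbours that wrap across matrix columns
      keep <- nb >= 1L & nb <= nr * nc & abs(row_of(nb) - r) <= 1L
      nb <- nb[keep]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

# Count of 8-neighbours that are TRUE, for each pixel of a logical matrix.
neighbor_count8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  s <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s + p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  s
}
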