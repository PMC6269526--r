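# Ratiometric boron-nanoparticle oxygen mapping of wound images.

#' Subtract pre-injection backgrounds from a channel pair
#'
#' Background images are taken before the nanoparticle solution is added;
#' their values are subtracted per pixel and per channel, clipping at zero.
#' Multiple background images per channel (3-D arrays or lists) are averaged.
#'
#' @param pair a `ChannelPair`, or any list with `blue`, `red`, `blue_bg`,
#'   `red_bg` matrices.
#' @return list with corrected `blue` and `red` matrices.
#' @export
subtract_background <- function(pair) {
  avg_bg <- function(bg) {
    if (is.list(bg)) Reduce(`+`, bg) / length(bg)
    else if (length(dim(bg)) == 3) apply(bg, c(1, 2), mean)
    else bg
  }
  blue_bg <- avg_bg(pair$blue_bg)
  red_bg <- avg_bg(pair$red_bg)
  if (!identical(dim(pair$blue), dim(pair$red)) ||
      !identical(dim(pair$blue), dim(blue_bg)) ||
      !identical(dim(pair$blue), dim(red_bg)))
    stop("channel and background images must share one shape", call. = FALSE)
  list(blue = pmax(pair$blue - blue_bg, 0),
       red = pmax(pair$red - red_bg, 0))
}

#' Per-pixel blue/red ratio map with grayscale rendering
#'
#' The oxygen-sensitive ratio is blue (oxygen-independent fluorescence) over
#' red (oxygen-quenched phosphorescence), computed where the red channel is
#' at or above `red_floor`; other pixels are flagged invalid, not
#' zero-filled. The grayscale rendering maps ratio affinely onto \[0, 1\]
#' (low oxygen: black; high oxygen: white) between `gray_bounds`; with the
#' default `NULL` the per-image valid ratio range is used, but a fixed range
#' shared across a study is what makes day-to-day gray values comparable
#' (the pipeline configuration sets one).
#'
#' @param blue_corr,red_corr background-corrected channel images.
#' @param red_floor red-channel validity floor (> 0).
#' @param gray_bounds c(lo, hi) ratio bounds for the gray rendering, or NULL
#'   for the per-image range.
#' @return list of class `RatioImage`: `ratio` (NA where invalid), `valid`,
#'   `gray` (in \[0,1\], NA where invalid), `bounds`.
#' @export
ratio_map <- function(blue_corr, red_corr, red_floor, gray_bounds = NULL) {
  blue_corr <- as.matrix(blue_corr); red_corr <- as.matrix(red_corr)
  if (!identical(dim(blue_corr), dim(red_corr)))
    stop("corrected images must share one shape", call. = FALSE)
  stopifnot_scalar(red_floor, "red_floor", positive = TRUE)
  valid <- red_corr >= red_floor
  ratio <- matrix(NA_real_, nrow(red_corr), ncol(red_corr))
  ratio[valid] <- blue_corr[valid] / red_corr[valid]
  if (is.null(gray_bounds)) {
    rng <- range(ratio[valid])
    if (!any(valid)) rng <- c(0, 1)
    gray_bounds <- rng
  }
  if (gray_bounds[2] <= gray_bounds[1]) gray_bounds[2] <- gray_bounds[1] + 1
  gray <- clamp((ratio - gray_bounds[1]) / diff(gray_bounds), 0, 1)
  structure(list(ratio = ratio, valid = valid, gray = gray,
                 bounds = gray_bounds),
            class = "RatioImage")
}

#' Invert the Stern-Volmer relation to relative pO2
#'
#' With a constant-brightness emitter, the blue/red ratio equals
#' `ratio0 * (1 + ksv * pO2)`; relative pO2 is recovered as
#' `(ratio/ratio0 - 1) / ksv`. `ratio0` is the zero-oxygen ratio (1 for the
#' forward model used by [simulate_ratiometric_images()]).
#'
#' @param ratio a `RatioImage` or ratio matrix.
#' @param ksv Stern-Volmer constant (> 0).
#' @param ratio0 zero-oxygen ratio (> 0), default 1.
#' @return matrix of relative pO2 (NA where the ratio is invalid).
#' @export
invert_stern_volmer <- function(ratio, ksv, ratio0 = 1) {
  stopifnot_scalar(ksv, "ksv", positive = TRUE)
  stopifnot_scalar(ratio0, "ratio0", positive = TRUE)
  r <- if (inherits(ratio, "RatioImage")) ratio$ratio else as.matrix(ratio)
  (r / ratio0 - 1) / ksv
}

#' Mean gray value over a region of interest
#'
#' Mean of the grayscale rendering over the intersection of the ROI with the
#' image's valid pixels — the wound-bed oxygenation readout.
#'
#' @param ratio a `RatioImage`.
#' @param roi logical matrix, same shape.
#' @return scalar mean gray value in \[0, 1\].
#' @export
mean_gray <- function(ratio, roi) {
  stopifnot(inherits(ratio, "RatioImage"))
  roi <- roi > 0
  if (!identical(dim(roi), dim(ratio$gray)))
    stop("ROI shape does not match the image", call. = FALSE)
  sel <- roi & ratio$valid
  if (!any(sel))
    stop("ROI does not overlap any valid pixel", call. = FALSE)
  mean(ratio$gray[sel])
}

#' Relative oxygenation time course
#'
#' Expresses mean-gray readouts as percent of a reference value and
#' summarises mean and SEM per day and group. The reference (for example the
#' day-0 control mean) must be supplied explicitly.
#'
#' @param series data.frame with columns `day`, `group`, `replicate`,
#'   `value`.
#' @param reference positive scalar reference value (= 100%).
#' @return data.frame `day`, `group`, `mean_pct`, `sem_pct`, `n`.
#' @export
relative_oxygenation <- function(series, reference) {
  need <- c("day", "group", "replicate", "value")
  if (!all(need %in% names(series)))
    stop("series must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  stopifnot_scalar(reference, "reference")
  if (reference <= 0) stop("'reference' must be > 0", call. = FALSE)
  sp <- split(series, list(series$day, series$group), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    pct <- 100 * d$value / reference
    data.frame(day = d$day[1], group = d$group[1], mean_pct = mean(pct),
               sem_pct = sem(pct), n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$day), ]
}

#' Default red-channel validity floor from background noise
#'
#' Three standard deviations of the red background image: below this the
#' phosphorescence signal is indistinguishable from background and the ratio
#' would blow up.
#'
#' @param red_bg red background image (matrix).
#' @param k multiplier (default 3).
#' @return positive scalar floor.
#' @export
default_red_floor <- function(red_bg, k = 3) {
  s <- stats::sd(as.numeric(red_bg))
  max(k * s, .Machine$double.eps)
}
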