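#' Describe one vessel of a phantom
#'
#' Convenience constructor for the vessel records consumed by
#' [make_vessel_phantom()]. Coordinates are in micrometres in the phantom
#' plane; a straight vessel can be given as a two-point polyline.
#'
#' @param polyline numeric matrix with columns (x, y) in um; at least two
#'   points.
#' @param diameter_um vessel diameter in um (> 0).
#' @param so2 hemoglobin oxygen saturation as a fraction in \[0, 1\].
#' @param speed_mm_s mean blood flow speed in mm/s (>= 0).
#' @param class one of "arterial", "venous", "capillary".
#' @return A list of class `mpam_vessel`.
#' @export
vessel <- function(polyline, diameter_um, so2, speed_mm_s,
                   class = c("capillary", "arterial", "venous")) {
  class <- match.arg(class)
  polyline <- as.matrix(polyline)
  if (ncol(polyline) != 2 || nrow(polyline) < 2 || !all(is.finite(polyline)))
    stop("'polyline' must be a finite matrix with >= 2 rows and columns (x, y)",
         call. = FALSE)
  stopifnot_scalar(diameter_um, "diameter_um", positive = TRUE)
  stopifnot_scalar(so2, "so2")
  if (so2 < 0 || so2 > 1) stop("'so2' must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar(speed_mm_s, "speed_mm_s", nonneg = TRUE)
  structure(list(polyline = polyline, diameter_um = diameter_um, so2 = so2,
                 speed_mm_s = speed_mm_s, class = class),
            class = "mpam_vessel")
}

#' Build a vascular phantom with known ground truth
#'
#' Assembles the ground-truth object every simulator in the package draws
#' from: vessel geometry (centerline polylines, diameters), per-vessel sO2,
#' flow speed and arterial/venous class, plus optional companions for the
#' other assays (a relative tissue-oxygen field, a shrinking-wound radius
#' schedule and one-compartment PK parameters).
#'
#' @param vessels list of [vessel()] records; must be non-empty.
#' @param dim integer c(rows, cols) of the phantom raster.
#' @param pixel_size_um lateral pixel size in um/pixel (default 2).
#' @param oxygen_field optional non-negative matrix of relative pO2
#'   (arbitrary units).
#' @param wound_radii_mm optional named numeric vector of wound radii per day.
#' @param pk_params optional list(ka, ke, scale) of Bateman parameters.
#' @param seed integer seed recorded with the phantom.
#' @return A list of class `PhantomTruth`.
#' @seealso [simulate_pam_scan()], [phantom_truth_table()]
#' @export
make_vessel_phantom <- function(vessels, dim = c(128L, 128L),
                                pixel_size_um = 2,
                                oxygen_field = NULL,
                                wound_radii_mm = NULL,
                                pk_params = NULL,
                                seed = 1L) {
  if (!is.list(vessels) || length(vessels) == 0)
    stop("'vessels' must be a non-empty list of vessel() records",
         call. = FALSE)
  vessels <- lapply(vessels, function(v) {
    if (!inherits(v, "mpam_vessel")) do.call(vessel, v) else v
  })
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  dim <- as.integer(dim)
  stopifnot(length(dim) == 2, all(dim >= 4))
  if (!is.null(oxygen_field)) {
    oxygen_field <- as.matrix(oxygen_field)
    if (any(!is.finite(oxygen_field)) || any(oxygen_field < 0))
      stop("'oxygen_field' must be finite and >= 0 everywhere", call. = FALSE)
  }
  if (!is.null(wound_radii_mm) && any(wound_radii_mm < 0))
    stop("wound radii must be non-negative", call. = FALSE)
  phantom <- structure(list(
    vessels = vessels,
    dim = dim,
    pixel_size_um = pixel_size_um,
    oxygen_field = oxygen_field,
    wound_radii_mm = wound_radii_mm,
    pk_params = pk_params,
    seed = as.integer(seed)
  ), class = "PhantomTruth")
  phantom
}

#' Ground-truth vessel table of a phantom
#'
#' @param phantom a `PhantomTruth`.
#' @return data.frame with columns vessel_id, diameter_um, so2, speed_mm_s,
#'   flow_ul_min (volumetric flow v*pi*d^2/4, unit-converted) and class.
#' @export
phantom_truth_table <- function(phantom) {
  stopifnot(inherits(phantom, "PhantomTruth"))
  v <- phantom$vessels
  data.frame(
    vessel_id = seq_along(v),
    diameter_um = vapply(v, `[[`, numeric(1), "diameter_um"),
    so2 = vapply(v, `[[`, numeric(1), "so2"),
    speed_mm_s = vapply(v, `[[`, numeric(1), "speed_mm_s"),
    flow_ul_min = vapply(v, function(x)
      volumetric_flow(x$speed_mm_s, x$diameter_um), numeric(1)),
    class = vapply(v, `[[`, character(1), "class"),
    stringsAsFactors = FALSE
  )
}

#' Volumetric flow from speed and diameter
#'
#' F = v * pi * d^2 / 4, converted from (mm/s, um) to uL/min:
#' d\[m\] = d_um * 1e-6, v\[m/s\] = v_mm_s * 1e-3, 1 m^3 = 1e9 uL.
#'
#' @param speed_mm_s mean speed in mm/s.
#' @param diameter_um diameter in um.
#' @return flow in uL/min.
#' @examples
#' volumetric_flow(1, 50)  # 0.11781 uL/min
#' @export
volumetric_flow <- function(speed_mm_s, diameter_um) {
  area_m2 <- pi * (diameter_um * 1e-6)^2 / 4
  q_m3_s <- area_m2 * speed_mm_s * 1e-3
  q_m3_s * 1e9 * 60
}

# Pixel-centre coordinates (um) of a raster of size dim = c(nr, nc).
pixel_centers <- function(dim, pixel_size_um) {
  nr <- dim[1]; nc <- dim[2]
  list(x = (seq_len(nc) - 0.5) * pixel_size_um,
       y = (seq_len(nr) - 0.5) * pixel_size_um)
}

# Distance (um) of every pixel centre to a polyline (min over its segments).
polyline_distance <- function(dim, pixel_size_um, polyline) {
  ctr <- pixel_centers(dim, pixel_size_um)
  px <- matrix(rep(ctr$x, each = dim[1]), dim[1], dim[2])
  py <- matrix(rep(ctr$y, times = dim[2]), dim[1], dim[2])
  d2 <- matrix(Inf, dim[1], dim[2])
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- pmin(d2, (px - a[1])^2 + (py - a[2])^2)
      next
    }
    t <- clamp(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0, 1)
    d2 <- pmin(d2, (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2)
  }
  sqrt(d2)
}

# Logical occupancy mask of one vessel (pixel centre within d/2 of the
# centerline).
vessel_mask <- function(phantom, i) {
  v <- phantom$vessels[[i]]
  polyline_distance(phantom$dim, phantom$pixel_size_um, v$polyline) <=
    v$diameter_um / 2
}

#' @export
print.PhantomTruth <- function(x, ...) {
  cat(sprintf("PhantomTruth: %d vessel(s), %dx%d px at %g um/px\n",
              length(x$vessels), x$dim[1], x$dim[2], x$pixel_size_um))
  print(phantom_truth_table(x))
  invisible(x)
}
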