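# Format plumbing: 32-bit float TIFF with JSON sidecars, CSV tables.
#
# TIFF storage is normalised to [0, 1]; the physical scale factor is recorded
# in the sidecar and restored on read, so round trips are exact to float
# precision and files stay portable.

#' Write a matrix or image stack as 32-bit TIFF with a JSON sidecar
#'
#' @param img matrix, 3-D array (pages = third dim) or list of matrices.
#' @param path output `.tif` path; the sidecar goes to `<path>.json`.
#' @param meta named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, meta = list()) {
  pages <- if (is.list(img)) img
  else if (length(dim(img)) == 3)
    lapply(seq_len(dim(img)[3]), function(k) img[, , k])
  else list(img)
  pages <- lapply(pages, function(m) {
    m <- as.matrix(m * 1)       # logical -> numeric
    m[is.na(m)] <- 0
    m
  })
  mx <- max(vapply(pages, max, numeric(1)), 0)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(lapply(pages, function(m) clamp(m / scale, 0, 1)),
                  path, bits.per.sample = 32L)
  sidecar <- c(list(scale = scale, n_pages = length(pages),
                    package = "mpam",
                    version = as.character(utils::packageVersion("mpam"))),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path `.tif` path.
#' @return matrix (one page) or 3-D array (several pages), rescaled to
#'   physical units via the sidecar; the sidecar metadata is attached as
#'   `attr(x, "meta")`.
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list(scale = 1)
  scale <- meta$scale %||% 1
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]   # greyscale stored; be tolerant
    m * scale
  })
  out <- if (length(pages) == 1) pages[[1]]
  else array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  attr(out, "meta") <- meta
  out
}

# MD5 of the canonical JSON rendering of a config list, for provenance.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Provenance sidecar naming the inputs, the full config and its hash. No
# timestamps: identical config + seed must reproduce outputs byte-for-byte.
write_provenance <- function(path, config, seed, inputs = character()) {
  jsonlite::write_json(
    list(config = config, config_hash = config_hash(config),
         seed = seed, inputs = as.character(inputs),
         package = "mpam",
         version = as.character(utils::packageVersion("mpam"))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
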