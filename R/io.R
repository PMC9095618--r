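# File I/O: grayscale images (PNG/TIFF), phase holograms (8-bit PNG for
# display, 32-bit TIFF, exact JSON), complex fields (two-plane 32-bit TIFF
# with a JSON geometry sidecar), and core maps (JSON/CSV).

file_ext <- function(path) tolower(sub(".*\\.", "", path))

#' Read / write a grayscale image
#'
#' PNG and TIFF are dispatched on the file extension; color images are
#' averaged to grayscale. Values are in `[0, 1]`.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param img numeric matrix in `[0, 1]` (values are clipped).
#' @return `read_image` returns a numeric matrix; `write_image` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- file_ext(path)
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])),
                                               drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- file_ext(path)
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read / write a phase hologram
#'
#' Three containers, dispatched on extension:
#' \describe{
#'   \item{`.png`}{8-bit quantized display copy: `[0, 2*pi)` is mapped to
#'     `{0, ..., 255}` by floor quantization, so the per-pixel round-trip
#'     error is below `2*pi/256`.}
#'   \item{`.tif`/`.tiff`}{32-bit samples storing `phase / (2*pi)`; the
#'     quantization error is below `2*pi * 2^-32` radians per pixel.}
#'   \item{`.json`}{exact double precision (the lossless container).}
#' }
#'
#' @param phase numeric phase matrix; wrapped to `[0, 2*pi)` on write.
#' @param path file path.
#' @return `read_hologram` returns the phase matrix; `write_hologram`
#'   returns `path` invisibly.
#' @export
write_hologram <- function(phase, path) {
  stopifnot(is.matrix(phase), all(is.finite(phase)))
  phase <- wrap_phase(phase)
  ext <- file_ext(path)
  switch(ext,
    png = {
      q <- pmin(floor(phase / (2 * pi) * 256), 255)
      png::writePNG(q / 255, path)
    },
    tif = , tiff = tiff::writeTIFF(phase / (2 * pi), path,
                                   bits.per.sample = 32L),
    json = jsonlite::write_json(
      list(kind = "phase_hologram", units = "radians", dim = dim(phase),
           phase = as.numeric(phase)),
      path, auto_unbox = TRUE, digits = I(17)),
    stop("unsupported hologram format: .", ext))
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  ext <- file_ext(path)
  switch(ext,
    png = {
      q <- round(png::readPNG(path) * 255)
      q * (2 * pi / 256)
    },
    tif = , tiff = tiff::readTIFF(path) * (2 * pi),
    json = {
      j <- jsonlite::read_json(path, simplifyVector = TRUE)
      if (is.null(j$phase) || is.null(j$dim))
        stop("malformed hologram JSON: missing field 'phase' or 'dim'")
      matrix(j$phase, j$dim[1], j$dim[2])
    },
    stop("unsupported hologram format: .", ext))
}

#' Read / write a complex field
#'
#' The field is stored as a two-plane (real, imaginary) 32-bit TIFF, affinely
#' mapped to the container's unit range, with the sampling geometry and the
#' affine map in a JSON sidecar (`<path>.json`). The per-sample quantization
#' error is `2^-32` of the field's dynamic range.
#'
#' @param field a [complex_field()].
#' @param path TIFF file path.
#' @return `read_field` returns a [complex_field()]; `write_field` returns
#'   `path` invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  re <- Re(field$values); im <- Im(field$values)
  # the TIFF container stores 32-bit samples in [0, 1]; the affine map back
  # to physical values lives in the sidecar
  rng <- range(re, im)
  scale <- max(rng[2] - rng[1], .Machine$double.xmin)
  planes <- array(c((re - rng[1]) / scale, (im - rng[1]) / scale),
                  dim = c(field$geom$ny, field$geom$nx, 2L))
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  g <- field$geom
  jsonlite::write_json(list(kind = "complex_field", units = "um",
                            nx = g$nx, ny = g$ny, pitch_x = g$pitch_x,
                            pitch_y = g$pitch_y, wavelength = g$wavelength,
                            offset = rng[1], scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  # libtiff flags the second (imaginary) plane as a non-color extra sample;
  # that classification is irrelevant here
  planes <- suppressWarnings(tiff::readTIFF(path, all = FALSE))
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  for (f in c("nx", "ny", "pitch_x", "pitch_y", "wavelength", "offset",
              "scale"))
    if (is.null(j[[f]])) stop("malformed field sidecar: missing field '", f, "'")
  geom <- field_geometry(j$nx, j$ny, j$pitch_x, j$pitch_y, j$wavelength)
  re <- planes[, , 1] * j$scale + j$offset
  im <- planes[, , 2] * j$scale + j$offset
  complex_field(matrix(complex(real = re, imaginary = im), geom$ny, geom$nx),
                geom)
}

#' Read / write a core map
#'
#' JSON is the native format and carries all metadata (units, core radius,
#' facet diameter, minimum spacing, centres). CSV carries one `x,y` centre
#' per row — header names may be any of `x`/`X`/`x_um` (same for y) — with
#' the remaining metadata supplied as arguments.
#'
#' @param map a [core_map()].
#' @param path file path (`.json` or `.csv`).
#' @param core_radius,facet_diameter,min_spacing metadata for CSV input;
#'   ignored for JSON.
#' @return `read_core_map` returns a [core_map()]; `write_core_map` returns
#'   `path` invisibly.
#' @export
write_core_map <- function(map, path) {
  stopifnot(inherits(map, "core_map"))
  ext <- file_ext(path)
  switch(ext,
    json = jsonlite::write_json(
      list(kind = "core_map", units = "um", core_radius = map$core_radius,
           facet_diameter = map$facet_diameter, min_spacing = map$min_spacing,
           centers = unname(map$centers)),
      path, auto_unbox = TRUE, digits = NA),
    csv = utils::write.csv(data.frame(x = map$centers[, 1],
                                      y = map$centers[, 2]),
                           path, row.names = FALSE),
    stop("unsupported core map format: .", ext))
  invisible(path)
}

#' @rdname write_core_map
#' @export
read_core_map <- function(path, core_radius = 1, facet_diameter = 350,
                          min_spacing = 3.3) {
  ext <- file_ext(path)
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("core_radius", "facet_diameter", "min_spacing", "centers"))
      if (is.null(j[[f]])) stop("malformed core map JSON: missing field '", f, "'")
    centers <- matrix(unlist(j$centers), ncol = 2,
                      byrow = !is.matrix(j$centers))
    if (is.matrix(j$centers)) centers <- j$centers
    return(core_map(centers, j$core_radius, j$facet_diameter, j$min_spacing))
  }
  if (ext == "csv") {
    d <- utils::read.csv(path)
    nm <- tolower(gsub("_?um$", "", names(d)))
    xi <- match("x", nm); yi <- match("y", nm)
    if (is.na(xi) || is.na(yi))
      stop("malformed core map CSV: need columns named x and y ",
           "(x_um/y_um accepted); found: ", paste(names(d), collapse = ", "))
    return(core_map(cbind(d[[xi]], d[[yi]]), core_radius, facet_diameter,
                    min_spacing))
  }
  stop("unsupported core map format: .", ext)
}
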