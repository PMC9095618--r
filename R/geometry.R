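#' Sampling geometry of a scalar field
#'
#' A `field_geometry` fixes the regular grid on which complex scalar fields are
#' sampled: the grid size, the physical pixel pitch, and the optical
#' wavelength. All physical quantities are in micrometres. Pixel centres are
#' placed symmetrically about the optical axis, so the grid spans
#' `nx * pitch_x` by `ny * pitch_y` centred on (0, 0).
#'
#' Defaults describe the desk-scale profile used throughout the package:
#' a 64 x 64 grid with 2 um pitch at 532 nm.
#'
#' @param nx,ny grid size in pixels (columns, rows); both must be >= 2.
#' @param pitch_x,pitch_y physical pixel pitch (um); `pitch_y` defaults to
#'   `pitch_x`.
#' @param wavelength optical wavelength (um).
#' @return an object of class `field_geometry`.
#' @export
field_geometry <- function(nx = 64L, ny = nx, pitch_x = 2, pitch_y = pitch_x,
                           wavelength = 0.532) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("invalid geometry: grid must be at least 2 x 2")
  if (!is.finite(pitch_x) || !is.finite(pitch_y) || pitch_x <= 0 || pitch_y <= 0)
    stop("invalid geometry: pixel pitch must be positive")
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("invalid geometry: wavelength must be positive")
  structure(list(nx = nx, ny = ny, pitch_x = pitch_x, pitch_y = pitch_y,
                 wavelength = wavelength),
            class = "field_geometry")
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("<field_geometry> %d x %d px, pitch %.3g x %.3g um, lambda %.4g um\n",
              x$nx, x$ny, x$pitch_x, x$pitch_y, x$wavelength))
  invisible(x)
}

# physical x (resp. y) coordinate of each pixel centre, centred on the axis
grid_coords <- function(geom) {
  list(x = (seq_len(geom$nx) - (geom$nx + 1) / 2) * geom$pitch_x,
       y = (seq_len(geom$ny) - (geom$ny + 1) / 2) * geom$pitch_y)
}

#' Complex scalar field on a regular grid
#'
#' Bundles a complex-valued `ny x nx` matrix (rows index y, columns index x)
#' with its sampling geometry. Fields are the currency passed between the
#' facet plane and the target plane by [propagate()].
#'
#' @param values complex (or numeric) matrix of field samples.
#' @param geom a [field_geometry()]; its grid size must match `values`.
#' @return an object of class `complex_field` with elements `values` and `geom`.
#' @export
complex_field <- function(values, geom) {
  if (!is.matrix(values)) stop("values must be a matrix")
  stopifnot(inherits(geom, "field_geometry"))
  if (nrow(values) != geom$ny || ncol(values) != geom$nx)
    stop("field/geometry size mismatch: values are ", nrow(values), " x ",
         ncol(values), " but geometry is ", geom$ny, " x ", geom$nx)
  if (!is.complex(values)) values <- values + 0i
  if (!all(is.finite(Re(values)) & is.finite(Im(values))))
    stop("field values must be finite")
  structure(list(values = values, geom = geom), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px, energy %.6g\n",
              x$geom$ny, x$geom$nx, field_energy(x)))
  invisible(x)
}

#' Total energy of a field
#'
#' Sum of `|U|^2` over all grid samples.
#'
#' @param field a [complex_field()].
#' @return a non-negative scalar.
#' @export
field_energy <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  sum(Mod(field$values)^2)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

#' Desk-scale study profile
#'
#' The package's default working point for simulation, testing and method
#' comparison: a 64 x 64 grid at 2 um pitch (532 nm), z = 700 um, and an
#' 85 um facet. The facet diameter follows from matching the number of
#' far-field resolution cells across the working area to the degrees of
#' freedom of the phased array at the same ratio as a full-scale instrument
#' (about 4 cells per core): with N cores on a facet of diameter D, the
#' far-field speckle grain is lambda*z/D, and D = 85 um gives ~540 cells
#' over the 48 x 48-pixel working area for a 128-core array.
#'
#' @param n_cores number of cores of the profile's core map.
#' @param seed seed for the core-map draw.
#' @return a list with `geom` ([field_geometry()]), `z`, `core_map`,
#'   `work_size` and `slm_size`.
#' @export
desk_profile <- function(n_cores = 128L, seed = 1L) {
  list(geom = field_geometry(64L, 64L, 2, 2, 0.532), z = 700,
       core_map = make_synthetic_core_map(n_cores, core_radius = 1,
                                          min_spacing = 3.3,
                                          facet_diameter = 85, seed = seed),
       work_size = c(48L, 48L), slm_size = c(64L, 64L))
}
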