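#' Band-limited angular spectrum transfer function
#'
#' Computes the transfer function H(u, v) of free-space propagation over a
#' signed distance `z`, band-limited to suppress the frequencies whose
#' sampled phase would alias at that distance:
#' \deqn{H(u,v) = \exp\!\big(i\,2\pi z \sqrt{1/\lambda^2 - u^2 - v^2}\big)
#'   \,\mathrm{rect}\!\big(u / 2u_{lim}\big)\,\mathrm{rect}\!\big(v / 2v_{lim}\big)}
#' with \eqn{u_{lim} = [(2\Delta u z)^2 + 1]^{-1/2}/\lambda} (and likewise for
#' v), where \eqn{\Delta u = 1/(n_x\,\mathrm{pitch}_x)} is the frequency-domain
#' sample interval. Inside the window every propagating frequency has unit
#' modulus, so in-band propagation is unitary. Evanescent frequencies
#' (\eqn{1/\lambda^2 - u^2 - v^2 < 0}) are set to zero rather than decayed:
#' at the far-field distances this model targets their transmission is
#' negligible and zeroing avoids exponential overflow for negative `z`.
#'
#' @param geom a [field_geometry()].
#' @param z signed propagation distance (um); may be zero.
#' @return a complex `ny x nx` matrix in unshifted FFT frequency order
#'   (DC at element [1, 1]).
#' @seealso [band_limits()], [propagate()]
#' @export
transfer_function <- function(geom, z) {
  stopifnot(inherits(geom, "field_geometry"))
  if (!is.finite(z)) stop("z must be finite")
  f <- freq_grids(geom)
  lim <- band_limits(geom, z)
  w2 <- 1 / geom$wavelength^2 - outer(f$v^2, f$u^2, `+`)
  inband <- (abs(outer(rep(1, geom$ny), f$u)) <= lim$u_limit) &
    (abs(outer(f$v, rep(1, geom$nx))) <= lim$v_limit) & (w2 >= 0)
  H <- matrix(0i, geom$ny, geom$nx)
  H[inband] <- exp(2i * pi * z * sqrt(w2[inband]))
  H
}

#' Band limits of the angular spectrum transfer function
#'
#' Frequency half-widths \eqn{u_{lim}, v_{lim}} of the anti-aliasing window at
#' distance `z`. As `z -> 0` both limits tend to \eqn{1/\lambda}, i.e. the
#' full propagating band.
#'
#' @inheritParams transfer_function
#' @return a list with elements `u_limit`, `v_limit`, `du`, `dv` (cycles/um).
#' @export
band_limits <- function(geom, z) {
  stopifnot(inherits(geom, "field_geometry"))
  du <- 1 / (geom$nx * geom$pitch_x)
  dv <- 1 / (geom$ny * geom$pitch_y)
  list(u_limit = 1 / (geom$wavelength * sqrt((2 * du * z)^2 + 1)),
       v_limit = 1 / (geom$wavelength * sqrt((2 * dv * z)^2 + 1)),
       du = du, dv = dv)
}

# frequency sample positions in unshifted FFT order (cycles/um)
freq_grids <- function(geom) {
  fftfreq <- function(n, d) {
    k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
    k / (n * d)
  }
  list(u = fftfreq(geom$nx, geom$pitch_x), v = fftfreq(geom$ny, geom$pitch_y))
}

# core spectral step shared by propagate/backpropagate; H is ny x nx in
# fft order. Linear in the field, so its adjoint is the same step with Conj(H).
apply_transfer <- function(values, H) {
  stats::fft(stats::fft(values) * H, inverse = TRUE) / length(values)
}

#' Propagate a field by the band-limited angular spectrum method
#'
#' Advances a sampled complex field over a signed distance `z` by
#' \eqn{U_o = F^{-1}\{H_{lim} \cdot F\{U_i\}\}}. The operation is a composition
#' of FFTs and an elementwise complex multiply, so it is linear and its
#' adjoint (used for gradient propagation during network training) is
#' multiplication by the conjugate transfer function, see [backpropagate()].
#' Within the band the transfer function has unit modulus, so in-band energy
#' is conserved.
#'
#' @param field a [complex_field()].
#' @param z signed propagation distance (um).
#' @param H optional precomputed transfer function from [transfer_function()]
#'   for this geometry and `z` (an optimization for iterative callers).
#' @return the propagated [complex_field()] on the same grid.
#' @export
propagate <- function(field, z, H = NULL) {
  stopifnot(inherits(field, "complex_field"))
  if (is.null(H)) H <- transfer_function(field$geom, z)
  complex_field(apply_transfer(field$values, H), field$geom)
}

#' Back-propagate a field or an intensity image to the facet plane
#'
#' Returns the field at distance `-z`, implemented as multiplication by the
#' complex conjugate of the `+z` transfer function so that
#' `propagate(backpropagate(U, z), z)` reproduces the in-band component of `U`
#' exactly. When given a plain numeric matrix it is interpreted as an
#' intensity image: the amplitude is its square root with zero phase.
#'
#' @param x a [complex_field()], or a non-negative numeric matrix of
#'   intensities (requires `geom`).
#' @param z signed propagation distance (um) of the forward pass being undone.
#' @param geom geometry for matrix input; ignored for `complex_field` input.
#' @param H optional precomputed `+z` transfer function.
#' @return a [complex_field()] at the source plane.
#' @export
backpropagate <- function(x, z, geom = NULL, H = NULL) {
  if (!inherits(x, "complex_field")) {
    if (!is.matrix(x) || is.complex(x))
      stop("x must be a complex_field or a numeric intensity matrix")
    if (any(x < 0)) stop("intensity values must be non-negative")
    if (is.null(geom)) stop("geom is required for intensity input")
    x <- complex_field(sqrt(x), geom)
  }
  if (is.null(H)) H <- transfer_function(x$geom, z)
  complex_field(apply_transfer(x$values, Conj(H)), x$geom)
}

#' Reconstructed intensity at the target plane
#'
#' Propagates a facet-plane field forward by `z` and returns `|U|^2`,
#' max-normalized when the peak is positive (the convention used before
#' correlation-based comparison and for display).
#'
#' @param field facet-plane [complex_field()].
#' @param z propagation distance (um).
#' @param H optional precomputed transfer function.
#' @param normalize max-normalize the intensity (default `TRUE`).
#' @return a numeric `ny x nx` intensity matrix.
#' @export
reconstruct_intensity <- function(field, z, H = NULL, normalize = TRUE) {
  I <- Mod(propagate(field, z, H = H)$values)^2
  if (normalize && max(I) > 0) I <- I / max(I)
  I
}
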