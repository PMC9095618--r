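#' Fiber core map
#'
#' A `core_map` describes the distal facet of a multi-core fiber as a phased
#' array: the physical centre coordinates of every single-mode core, a common
#' core radius, the facet diameter, and the minimum centre-to-centre spacing
#' the map is guaranteed to respect. Coordinates are in micrometres, centred
#' on the fiber axis.
#'
#' @param centers numeric `n x 2` matrix of (x, y) core centres (um).
#' @param core_radius core radius (um).
#' @param facet_diameter facet diameter (um); all cores must lie inside the
#'   facet disk with their full radius. The default matches a 350 um
#'   high-count imaging bundle; the package's desk-scale profile uses 85 um
#'   (see [desk_profile()]).
#' @param min_spacing minimum centre spacing the map respects (um); checked.
#' @param check validate invariants (default `TRUE`).
#' @return an object of class `core_map`.
#' @export
core_map <- function(centers, core_radius = 1, facet_diameter = 350,
                     min_spacing = 3.3, check = TRUE) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || nrow(centers) < 1L)
    stop("centers must be an n x 2 matrix with n >= 1")
  storage.mode(centers) <- "double"
  colnames(centers) <- c("x", "y")
  m <- structure(list(centers = centers, core_radius = core_radius,
                      facet_diameter = facet_diameter,
                      min_spacing = min_spacing,
                      n_cores = nrow(centers)),
                 class = "core_map")
  if (check) validate_core_map(m)
  m
}

#' @export
print.core_map <- function(x, ...) {
  cat(sprintf("<core_map> %d cores, radius %.3g um, facet %.4g um, min spacing %.3g um\n",
              x$n_cores, x$core_radius, x$facet_diameter, x$min_spacing))
  invisible(x)
}

validate_core_map <- function(m) {
  if (!all(is.finite(m$centers))) stop("core centres must be finite")
  if (m$core_radius <= 0 || m$facet_diameter <= 0 || m$min_spacing <= 0)
    stop("core_radius, facet_diameter and min_spacing must be positive")
  r <- sqrt(rowSums(m$centers^2))
  if (any(r + m$core_radius > m$facet_diameter / 2 + 1e-9))
    stop("core map invariant violated: cores extend outside the facet disk")
  if (m$n_cores > 1L && min_pair_distance(m$centers) < m$min_spacing - 1e-9)
    stop("core map invariant violated: centre spacing below min_spacing")
  invisible(m)
}

# minimum pairwise distance; cell-hashed for large n, exact in both branches
min_pair_distance <- function(p) {
  n <- nrow(p)
  if (n <= 2000L) return(min(stats::dist(p)))
  cell <- max(diff(range(p[, 1])), diff(range(p[, 2]))) / ceiling(sqrt(n))
  ix <- floor(p[, 1] / cell); iy <- floor(p[, 2] / cell)
  key <- paste(ix, iy)
  idx <- split(seq_len(n), key)
  lookup <- new.env(parent = emptyenv())
  for (k in names(idx)) assign(k, idx[[k]], envir = lookup)
  best <- Inf
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(ix[i] + dx, iy[i] + dy)
      js <- if (exists(k, envir = lookup, inherits = FALSE))
        get(k, envir = lookup, inherits = FALSE) else next
      js <- js[js > i]
      if (length(js))
        best <- min(best, sqrt(min((p[js, 1] - p[i, 1])^2 + (p[js, 2] - p[i, 2])^2)))
    }
  }
  best
}

#' Generate a synthetic random core map
#'
#' Places `n_cores` core centres inside the facet disk with a guaranteed
#' minimum centre spacing. At low packing density the centres are drawn by
#' random darts with rejection, giving the irregular distribution typical of
#' imaging fiber bundles. Above roughly 45% of the hexagonal packing limit a
#' pure rejection sampler stalls well short of the target count, so placement
#' switches to a randomly rotated, jittered triangular lattice — the jammed
#' quasi-lattice regime real high-count bundles (e.g. 10,000 cores on a
#' 350 um facet) actually occupy. Both regimes respect `min_spacing` exactly
#' and are reproducible for a fixed seed.
#'
#' @param n_cores number of cores (>= 1). A single core is placed on the axis.
#' @param core_radius core radius (um).
#' @param min_spacing minimum centre-to-centre spacing (um).
#' @param facet_diameter facet diameter (um).
#' @param seed optional integer seed for reproducible placement.
#' @param max_attempts dart budget before the sampler reports the packing as
#'   infeasible.
#' @return a [core_map()].
#' @export
make_synthetic_core_map <- function(n_cores, core_radius = 1, min_spacing = 3.3,
                                    facet_diameter = 350, seed = NULL,
                                    max_attempts = 200L * n_cores + 10000L) {
  n_cores <- as.integer(n_cores)
  if (n_cores < 1L) stop("n_cores must be >= 1")
  R <- facet_diameter / 2 - core_radius
  if (R < 0) stop("packing infeasible: core radius exceeds the facet radius")
  if (n_cores == 1L)
    return(core_map(matrix(0, 1, 2), core_radius, facet_diameter, min_spacing))
  hex_capacity <- 2 * pi * R^2 / (sqrt(3) * min_spacing^2)
  if (n_cores > hex_capacity)
    stop("packing infeasible: ", n_cores, " cores at spacing ", min_spacing,
         " um exceed the hexagonal limit (~", floor(hex_capacity),
         ") of a ", facet_diameter, " um facet")
  with_seed_if(seed, {
    if (n_cores <= 0.45 * hex_capacity)
      centers <- place_darts(n_cores, R, min_spacing, max_attempts)
    else
      centers <- place_jittered_hex(n_cores, R, min_spacing)
  })
  core_map(centers, core_radius, facet_diameter, min_spacing)
}

place_darts <- function(n, R, spacing, max_attempts) {
  pts <- matrix(NA_real_, n, 2)
  cell <- spacing
  occ <- new.env(parent = emptyenv(), hash = TRUE)
  placed <- 0L
  sp2 <- spacing^2
  for (att in seq_len(max_attempts)) {
    r <- R * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
    cx <- floor(x / cell); cy <- floor(y / cell)
    ok <- TRUE
    for (dx in -1:1) {
      for (dy in -1:1) {
        k <- paste(cx + dx, cy + dy)
        js <- if (exists(k, envir = occ, inherits = FALSE))
          get(k, envir = occ, inherits = FALSE) else next
        if (any((pts[js, 1] - x)^2 + (pts[js, 2] - y)^2 < sp2)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    pts[placed, ] <- c(x, y)
    k <- paste(cx, cy)
    prev <- if (exists(k, envir = occ, inherits = FALSE))
      get(k, envir = occ, inherits = FALSE) else integer()
    assign(k, c(prev, placed), envir = occ)
    if (placed == n) return(pts)
  }
  stop("packing infeasible: placed ", placed, " of ", n,
       " cores before exhausting the dart budget; violated constraint: ",
       "min_spacing = ", spacing, " um within the facet disk")
}

place_jittered_hex <- function(n, R, spacing) {
  # lattice constant: as loose as the requested count allows
  a_max <- sqrt(2 * pi * R^2 / (sqrt(3) * n))
  a <- max(spacing, 0.995 * a_max)
  jitter <- (a - spacing) / 2
  rot <- runif(1, 0, pi / 3)
  m <- ceiling(2 * R / a) + 2
  i <- rep(-m:m, each = 2 * m + 1); j <- rep(-m:m, times = 2 * m + 1)
  x0 <- a * (i + j / 2); y0 <- a * j * sqrt(3) / 2
  x <- cos(rot) * x0 - sin(rot) * y0 + runif(1, -a / 2, a / 2)
  y <- sin(rot) * x0 + cos(rot) * y0 + runif(1, -a / 2, a / 2)
  if (jitter > 0) {
    rr <- jitter * sqrt(runif(length(x))); tt <- runif(length(x), 0, 2 * pi)
    x <- x + rr * cos(tt); y <- y + rr * sin(tt)
  }
  keep <- which(x^2 + y^2 <= R^2)
  if (length(keep) < n)
    stop("packing infeasible: jittered lattice offers ", length(keep),
         " sites inside the facet for ", n, " cores at spacing ", spacing, " um")
  sel <- sample(keep, n)
  cbind(x[sel], y[sel])
}

# --- physical <-> pixel mapping -------------------------------------------

# nearest pixel (row iy, col jx) of each core centre; linear index into the
# ny x nx matrix
core_pixel_indices <- function(core_map, geom) {
  jx <- round(core_map$centers[, 1] / geom$pitch_x + (geom$nx + 1) / 2)
  iy <- round(core_map$centers[, 2] / geom$pitch_y + (geom$ny + 1) / 2)
  if (any(jx < 1 | jx > geom$nx | iy < 1 | iy > geom$ny))
    stop("core centre falls outside the sampling grid")
  list(iy = as.integer(iy), jx = as.integer(jx),
       linear = as.integer(iy + (jx - 1) * geom$ny))
}

#' Precompute the pixel footprint of every core on a grid
#'
#' Rasterizes each core as the set of pixels whose centres lie within
#' `core_radius` of the core centre (hard-edged disks). A core whose disk
#' covers no pixel centre — possible when the pitch is comparable to the core
#' radius — paints its single nearest pixel instead, so every core always has
#' support on the grid. The returned plan caches the per-core pixel indices
#' used by [render_core_field()] and [sample_core_phases()]; callers that
#' render many holograms on a fixed geometry should build it once.
#'
#' @param core_map a [core_map()].
#' @param geom a [field_geometry()].
#' @return a list with the nearest-pixel sampling index per core
#'   (`sample_idx`), concatenated disk pixel indices (`disk_idx`), the core id
#'   of each disk pixel (`disk_core`), and per-core pixel counts (`n_px`).
#' @export
core_render_plan <- function(core_map, geom) {
  px <- core_pixel_indices(core_map, geom)
  co <- grid_coords(geom)
  r <- core_map$core_radius
  wx <- ceiling(r / geom$pitch_x) + 1L
  wy <- ceiling(r / geom$pitch_y) + 1L
  disk_idx <- vector("list", core_map$n_cores)
  for (c in seq_len(core_map$n_cores)) {
    js <- max(1L, px$jx[c] - wx):min(geom$nx, px$jx[c] + wx)
    is <- max(1L, px$iy[c] - wy):min(geom$ny, px$iy[c] + wy)
    dx2 <- (co$x[js] - core_map$centers[c, 1])^2
    dy2 <- (co$y[is] - core_map$centers[c, 2])^2
    d2 <- outer(dy2, dx2, `+`)
    hit <- which(d2 <= r^2)
    if (length(hit) == 0L) {
      disk_idx[[c]] <- px$linear[c]
    } else {
      ii <- is[(hit - 1L) %% length(is) + 1L]
      jj <- js[(hit - 1L) %/% length(is) + 1L]
      disk_idx[[c]] <- as.integer(ii + (jj - 1L) * geom$ny)
    }
  }
  n_px <- lengths(disk_idx)
  all_idx <- unlist(disk_idx, use.names = FALSE)
  if (anyDuplicated(all_idx))
    stop("overlapping core disks: two cores paint the same pixel")
  list(sample_idx = px$linear, disk_idx = all_idx,
       disk_core = rep.int(seq_len(core_map$n_cores), n_px), n_px = n_px,
       ny = geom$ny, nx = geom$nx)
}

# --- holograms -------------------------------------------------------------

#' Per-core phase state of the phased array
#'
#' A `core_hologram` is the vector of piston phases, one per fiber core,
#' wrapped to `[0, 2*pi)`. An `offset` slot accumulates additional per-core
#' phase layers (simulated optical-path-difference distortion and its
#' conjugate compensation); the effective phase of core `c` is
#' `wrap(phases[c] + offset[c])`, evaluated when the hologram is rendered or
#' sampled. Keeping the layers separate lets exact conjugate compensation
#' cancel a distortion bit-for-bit.
#'
#' @param phases numeric vector of per-core phases (radians); wrapped on
#'   construction.
#' @param offset optional accumulated phase-layer vector (default all zero).
#' @return an object of class `core_hologram`.
#' @export
core_hologram <- function(phases, offset = NULL) {
  phases <- as.numeric(phases)
  if (length(phases) < 1L || !all(is.finite(phases)))
    stop("phases must be a non-empty finite numeric vector")
  if (is.null(offset)) offset <- numeric(length(phases))
  if (length(offset) != length(phases)) stop("offset length must match phases")
  structure(list(phases = wrap_phase(phases), offset = offset),
            class = "core_hologram")
}

#' @export
print.core_hologram <- function(x, ...) {
  cat(sprintf("<core_hologram> %d cores, phase range [%.3f, %.3f)\n",
              length(x$phases), min(x$phases), max(x$phases)))
  invisible(x)
}

# effective per-core phase including accumulated offset layers
effective_phases <- function(holo) wrap_phase(holo$phases + holo$offset)

#' Sample per-core phases from a full-resolution phase image
#'
#' Reads one phase per core at the pixel nearest each core centre
#' (nearest-neighbour sampling) and wraps it to `[0, 2*pi)`. This is the
#' spatial sampling a multi-core fiber applies to any hologram displayed on
#' the modulator: only the values at the core positions matter.
#'
#' @param phase_image numeric `ny x nx` matrix of phases (radians).
#' @param core_map a [core_map()].
#' @param geom the [field_geometry()] of `phase_image`.
#' @param plan optional cached [core_render_plan()].
#' @return a [core_hologram()].
#' @export
sample_core_phases <- function(phase_image, core_map, geom, plan = NULL) {
  if (!is.matrix(phase_image) || nrow(phase_image) != geom$ny ||
      ncol(phase_image) != geom$nx)
    stop("phase_image size does not match geometry")
  idx <- if (is.null(plan)) core_pixel_indices(core_map, geom)$linear
         else plan$sample_idx
  core_hologram(phase_image[idx])
}

#' Render a core hologram as a complex facet field
#'
#' Paints every core as a hard-edged disk of unit amplitude and uniform
#' (piston) phase equal to its hologram entry; the cladding between cores has
#' zero amplitude. The disk footprints are fixed by the geometry, so the
#' field depends on the phases only through `exp(i * phase)` and the
#' operation is differentiable with respect to them.
#'
#' @param holo a [core_hologram()] with one phase per core.
#' @param core_map a [core_map()].
#' @param geom a [field_geometry()].
#' @param plan optional cached [core_render_plan()].
#' @return a [complex_field()] at the facet plane.
#' @export
render_core_field <- function(holo, core_map, geom, plan = NULL) {
  stopifnot(inherits(holo, "core_hologram"))
  if (length(holo$phases) != core_map$n_cores)
    stop("hologram length does not match core count")
  if (is.null(plan)) plan <- core_render_plan(core_map, geom)
  phi <- effective_phases(holo)
  values <- matrix(0i, geom$ny, geom$nx)
  values[plan$disk_idx] <- exp(1i * phi[plan$disk_core])
  complex_field(values, geom)
}

# --- OPD distortion and digital phase conjugation --------------------------

#' Apply per-core optical-path-difference phase offsets
#'
#' Adds a per-core phase layer to a hologram, simulating the intrinsic
#' optical path differences between the cores of a real fiber (or, with the
#' negated layer from [conjugate_compensation()], their pre-compensation on
#' the modulator). Layers accumulate in the hologram's `offset` slot, so a
#' distortion followed by its exact conjugate cancels identically.
#'
#' @param x a [core_hologram()], or a full-grid numeric phase matrix
#'   (requires `core_map` and `geom`, offsets are added over each core's disk).
#' @param opd numeric per-core phase offsets (radians), one per core.
#' @param core_map,geom required only for matrix input.
#' @return same type as `x`.
#' @export
apply_opd <- function(x, opd, core_map = NULL, geom = NULL) {
  opd <- as.numeric(opd)
  if (inherits(x, "core_hologram")) {
    if (length(opd) != length(x$phases))
      stop("OPD length does not match core count")
    x$offset <- x$offset + opd
    return(x)
  }
  if (is.matrix(x)) {
    if (is.null(core_map) || is.null(geom))
      stop("core_map and geom are required for matrix input")
    if (length(opd) != core_map$n_cores)
      stop("OPD length does not match core count")
    plan <- core_render_plan(core_map, geom)
    x[plan$disk_idx] <- x[plan$disk_idx] + opd[plan$disk_core]
    return(x)
  }
  stop("x must be a core_hologram or a phase matrix")
}

#' Conjugate compensation layer for a measured OPD map
#'
#' Digital optical phase conjugation: returns the negated per-core offsets,
#' which applied on top of the distortion cancel it exactly.
#'
#' @param opd numeric per-core phase offsets (radians).
#' @return the negated offsets.
#' @export
conjugate_compensation <- function(opd) -as.numeric(opd)

#' Transmit a hologram through a (possibly distorted) fiber
#'
#' Renders the facet field of `holo` with optional distortion and
#' compensation layers. The layers are summed before being added to the
#' hologram phase, mirroring how a real system stacks the conjugation layer
#' and the intrinsic OPD: with `compensation = conjugate_compensation(opd)`
#' the two layers sum to exactly zero and the transmitted field is
#' bit-for-bit identical to the undistorted one.
#'
#' @param holo a [core_hologram()].
#' @param core_map a [core_map()].
#' @param geom a [field_geometry()].
#' @param opd optional per-core distortion layer (radians).
#' @param compensation optional per-core compensation layer (radians).
#' @param plan optional cached [core_render_plan()].
#' @return the facet-plane [complex_field()].
#' @export
mcf_transmit <- function(holo, core_map, geom, opd = NULL, compensation = NULL,
                         plan = NULL) {
  extra <- numeric(core_map$n_cores)
  if (!is.null(opd)) extra <- extra + as.numeric(opd)
  if (!is.null(compensation)) extra <- extra + as.numeric(compensation)
  if (any(extra != 0)) holo <- apply_opd(holo, extra)
  render_core_field(holo, core_map, geom, plan = plan)
}
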