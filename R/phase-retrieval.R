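#' Gerchberg-Saxton phase retrieval
#'
#' Classic two-plane alternating projection for a phase-only hologram: the
#' source plane is constrained to unit amplitude (phase freedom only), the
#' target plane to the desired amplitude `sqrt(target)`. Each iteration
#' propagates forward by `z`, records the reconstruction fidelity, imposes
#' the target amplitude, propagates back with the conjugate transfer
#' function, and re-imposes unit amplitude.
#'
#' @param target numeric target intensity matrix in `[0, 1]` on the grid of
#'   `geom`; must not be constant.
#' @param z propagation distance (um).
#' @param geom a [field_geometry()].
#' @param iters number of iterations (>= 0); with 0 the initial phase is
#'   returned unchanged.
#' @param seed seed for random initialization.
#' @param init `"zero"` (default) or `"random"` uniform initial phase.
#' @param trace record the per-iteration correlation trace (default `TRUE`).
#' @return a `retrieval_result`: list with `hologram` (full-grid phase matrix
#'   wrapped to `[0, 2*pi)`), `trace` (CC per iteration; `NA` where the
#'   reconstruction is constant and correlation is undefined), `iterations`.
#' @export
gs_retrieve <- function(target, z, geom, iters = 100L, seed = NULL,
                        init = c("zero", "random"), trace = TRUE) {
  init <- match.arg(init)
  check_target(target, geom)
  iters <- as.integer(iters)
  stopifnot(iters >= 0L)
  amp <- sqrt(target)
  H <- transfer_function(geom, z)
  phi <- init_phase(init, geom$ny, geom$nx, seed)
  U <- exp(1i * phi)
  cc <- numeric(iters)
  for (it in seq_len(iters)) {
    Ut <- apply_transfer(U, H)
    if (trace) cc[it] <- safe_cc(Mod(Ut)^2, target)
    Ut <- amp * phasor(Ut)
    Ub <- apply_transfer(Ut, Conj(H))
    phi <- Arg(Ub)
    U <- exp(1i * phi)
  }
  retrieval_result(wrap_phase(phi), if (trace) cc else numeric(0), iters)
}

#' Core-constrained Gerchberg-Saxton (Core-GS)
#'
#' Gerchberg-Saxton tailored to a multi-core fiber phased array: every
#' iteration additionally projects the source plane onto the fiber
#' constraint — piston phase per core, zero amplitude between cores — by
#' sampling the back-propagated phase at the core centres and re-rendering
#' the disk field. The result is a per-core hologram rather than a full-grid
#' phase image.
#'
#' @inheritParams gs_retrieve
#' @param core_map a [core_map()].
#' @param plan optional cached [core_render_plan()].
#' @return a `retrieval_result` whose `hologram` is a [core_hologram()].
#' @export
core_gs_retrieve <- function(target, core_map, z, geom, iters = 100L,
                             seed = NULL, init = c("zero", "random"),
                             trace = TRUE, plan = NULL) {
  init <- match.arg(init)
  check_target(target, geom)
  iters <- as.integer(iters)
  stopifnot(iters >= 0L)
  if (is.null(plan)) plan <- core_render_plan(core_map, geom)
  amp <- sqrt(target)
  H <- transfer_function(geom, z)
  phi0 <- init_phase(init, geom$ny, geom$nx, seed)
  holo <- sample_core_phases(phi0, core_map, geom, plan = plan)
  U <- render_core_field(holo, core_map, geom, plan = plan)$values
  cc <- numeric(iters)
  for (it in seq_len(iters)) {
    Ut <- apply_transfer(U, H)
    if (trace) cc[it] <- safe_cc(Mod(Ut)^2, target)
    Ut <- amp * phasor(Ut)
    Ub <- apply_transfer(Ut, Conj(H))
    holo <- core_hologram(Arg(Ub)[plan$sample_idx])
    U <- render_core_field(holo, core_map, geom, plan = plan)$values
  }
  retrieval_result(holo, if (trace) cc else numeric(0), iters)
}

# trace-only correlation: a degenerate (constant) reconstruction, e.g. at the
# first iteration from a uniform zero-phase start, has no defined CC
safe_cc <- function(I, target) {
  tryCatch(correlation_coefficient(I, target), error = function(e) NA_real_)
}

retrieval_result <- function(hologram, trace, iterations) {
  structure(list(hologram = hologram, trace = trace,
                 iterations = as.integer(iterations)),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  kind <- if (inherits(x$hologram, "core_hologram")) "core" else "SLM"
  cat(sprintf("<retrieval_result> %s hologram, %d iterations%s\n", kind,
              x$iterations,
              if (length(x$trace)) sprintf(", final CC = %.4f",
                                           x$trace[length(x$trace)]) else ""))
  invisible(x)
}

check_target <- function(target, geom) {
  if (!is.matrix(target) || nrow(target) != geom$ny || ncol(target) != geom$nx)
    stop("target size does not match geometry")
  if (any(target < 0)) stop("target intensities must be non-negative")
  invisible(target)
}

init_phase <- function(init, ny, nx, seed) {
  if (init == "zero") matrix(0, ny, nx)
  else with_seed_if(seed, matrix(runif(ny * nx, 0, 2 * pi), ny, nx))
}

# unit phasor, safe at zero amplitude
phasor <- function(U) {
  m <- Mod(U)
  m[m == 0] <- 1
  U / m
}
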