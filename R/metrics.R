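#' Two-dimensional correlation coefficient
#'
#' Pearson correlation between two images of equal shape,
#' \deqn{CC = \frac{\sum_i (X_i - \bar X)(Y_i - \bar Y)}
#'   {\{\sum_i (X_i - \bar X)^2 \sum_i (Y_i - \bar Y)^2\}^{1/2}},}
#' the fidelity measure used throughout the package to compare a numerically
#' reconstructed intensity with its target. Symmetric in its arguments and
#' invariant to positive affine rescaling of either image.
#'
#' @param x,y numeric matrices (or vectors) of identical shape; neither may
#'   be constant.
#' @return a scalar in `[-1, 1]`.
#' @export
correlation_coefficient <- function(x, y) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("images must have identical shape")
  xc <- as.numeric(x) - mean(x)
  yc <- as.numeric(y) - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0)
    stop("correlation undefined for a constant image")
  sum(xc * yc) / sqrt(sxx * syy)
}

#' Negative Pearson correlation loss
#'
#' The training loss of the phase-encoder network: `-CC(x, y)`. Being a
#' similarity measure rather than a pixel-wise error, it constrains only the
#' linear correlation between reconstruction and target, which leaves the
#' overall intensity scale free and eases convergence.
#'
#' @inheritParams correlation_coefficient
#' @return a scalar in `[-1, 1]`.
#' @export
npcc_loss <- function(x, y) -correlation_coefficient(x, y)

# gradient of npcc_loss(x, y) with respect to x (same shape as x)
npcc_loss_grad <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (sxx == 0 || syy == 0) stop("correlation undefined for a constant image")
  -(yc - (sxy / sxx) * xc) / sqrt(sxx * syy)
}

#' Evaluate a hologram-generation method over a set of targets
#'
#' Runs a method per target, reconstructs the far field numerically through
#' the shared fiber + propagation model (sample at the cores, render the disk
#' field, propagate by `z`, take `|U|^2`), and scores each reconstruction
#' against its target with [correlation_coefficient()]. Every method is
#' reconstructed through the same forward model, so the comparison is fair
#' by construction.
#'
#' Built-in methods:
#' \describe{
#'   \item{`"gs"`}{plain Gerchberg-Saxton hologram, subsequently sampled
#'     through the cores (the aliasing-afflicted baseline).}
#'   \item{`"core_gs"`}{core-constrained Gerchberg-Saxton.}
#'   \item{`"corenet"`}{single forward pass of a trained phase-encoder model
#'     (supply `model`).}
#'   \item{`"random"`}{seeded uniform random core phases (null baseline).}
#' }
#' A function `function(target) -> core_hologram | phase matrix` may be
#' supplied instead.
#'
#' @param method method label or function (see Details).
#' @param targets non-empty list of target intensity matrices in `[0, 1]`.
#' @param core_map a [core_map()].
#' @param geom a [field_geometry()].
#' @param z propagation distance (um).
#' @param iters iteration budget for the iterative methods.
#' @param model trained model for `method = "corenet"`.
#' @param seed seed for stochastic methods.
#' @return a `fidelity_report`: list with per-target `cc`, the `method`
#'   label, and a `summary` list (mean, median, quartiles, 1.5 IQR whiskers).
#' @export
evaluate_method <- function(method, targets, core_map, geom, z = 700,
                            iters = 100L, model = NULL, seed = NULL) {
  if (!length(targets)) stop("targets must be a non-empty list")
  if (is.matrix(targets)) targets <- list(targets)
  plan <- core_render_plan(core_map, geom)
  H <- transfer_function(geom, z)
  label <- if (is.function(method)) "custom" else match.arg(
    method, c("gs", "core_gs", "corenet", "random"))
  holo_fun <- if (is.function(method)) method else switch(label,
    gs = function(tg) gs_retrieve(tg, z, geom, iters = iters, seed = seed)$hologram,
    core_gs = function(tg) core_gs_retrieve(tg, core_map, z, geom, iters = iters,
                                            seed = seed, plan = plan)$hologram,
    corenet = {
      if (is.null(model)) stop("method 'corenet' requires a trained model")
      function(tg) infer_hologram(model, tg, z, geom)
    },
    random = function(tg) core_hologram(runif(core_map$n_cores, 0, 2 * pi)))
  cc <- vapply(targets, function(tg) {
    h <- holo_fun(tg)
    if (is.matrix(h)) h <- sample_core_phases(h, core_map, geom, plan = plan)
    I <- reconstruct_intensity(render_core_field(h, core_map, geom, plan = plan),
                               z, H = H)
    correlation_coefficient(I, tg)
  }, numeric(1))
  fidelity_report(cc, label)
}

#' Assemble a fidelity report from per-target correlation coefficients
#'
#' @param cc numeric vector of per-target correlation coefficients.
#' @param method method label.
#' @return a `fidelity_report` with box-plot style summary statistics
#'   (median, quartiles, 1.5 IQR whiskers clamped to the data range).
#' @export
fidelity_report <- function(cc, method = "unknown") {
  stopifnot(length(cc) >= 1, all(is.finite(cc)), all(abs(cc) <= 1 + 1e-12))
  q <- unname(stats::quantile(cc, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  structure(list(
    cc = as.numeric(cc), method = method,
    summary = list(n = length(cc), mean = mean(cc), median = q[2],
                   q1 = q[1], q3 = q[3],
                   whisker_low = min(cc[cc >= q[1] - 1.5 * iqr]),
                   whisker_high = max(cc[cc <= q[3] + 1.5 * iqr]))),
    class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<fidelity_report> %s: n = %d, mean CC = %.4f, median = %.4f, IQR = [%.4f, %.4f]\n",
    x$method, s$n, s$mean, s$median, s$q1, s$q3))
  invisible(x)
}

#' Write a fidelity report to CSV (per target) and JSON (summary)
#'
#' @param report a `fidelity_report`.
#' @param csv_path path of the per-target CSV (`target`, `cc`).
#' @param json_path path of the JSON summary.
#' @return the report, invisibly.
#' @export
write_fidelity_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "fidelity_report"))
  utils::write.csv(data.frame(target = seq_along(report$cc),
                              method = report$method, cc = report$cc),
                   csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(c(list(method = report$method), report$summary),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
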