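#' Configuration of the phase-encoder network
#'
#' The encoder is a modified U-Net with two independent downsampling paths —
#' one for the real part and one for the imaginary part of the
#' back-propagated target field — joined at the bottleneck by channel
#' concatenation and upsampled to the modulator resolution. Every
#' down/upsampling block is a pair of pre-activation residual sub-blocks
#' (BN, ReLU, convolution twice per sub-block); the first convolution (or
#' transposed convolution) of each block has stride (2, 2).
#'
#' @param input_size side of the (square) input grid in pixels; must be
#'   divisible by `2^depth`.
#' @param output_size side of the output phase image; must be
#'   `input_size * 2^k` for an integer `k >= 0` (extra upsampling blocks
#'   carry the bottleneck past the input resolution when the modulator grid
#'   is finer).
#' @param depth number of downsampling levels (>= 1).
#' @param base_width channel width of the first level; doubled per level.
#' @param seed integer seed for weight initialization; the same
#'   configuration and seed always produce identical parameters.
#' @return an object of class `corenet_config`.
#' @export
corenet_config <- function(input_size = 64L, output_size = input_size,
                           depth = 3L, base_width = 8L, seed = 1L) {
  input_size <- as.integer(input_size); output_size <- as.integer(output_size)
  depth <- as.integer(depth); base_width <- as.integer(base_width)
  if (depth < 1L) stop("depth must be >= 1")
  if (input_size %% 2L^depth != 0L)
    stop("input_size must be divisible by 2^depth")
  if (output_size < input_size)
    stop("output_size must be >= input_size")
  k <- log2(output_size / input_size)
  if (abs(k - round(k)) > 1e-9)
    stop("output_size must be input_size times a power of two")
  structure(list(input_size = input_size, output_size = output_size,
                 depth = depth, base_width = base_width,
                 extra_up = as.integer(round(k)), seed = as.integer(seed)),
            class = "corenet_config")
}

#' Build an untrained phase-encoder network
#'
#' Instantiates the dual-input encoder of [corenet_config()]: per input
#' plane, `depth` downsampling blocks (each two residual sub-blocks, the
#' first strided); a concatenation bottleneck with a mixing residual block;
#' `depth` upsampling blocks whose outputs are concatenated with the skip
#' features of *both* downsampling paths at the matching resolution; then a
#' BN-ReLU-conv head producing a single unwrapped-phase plane, wrapped to
#' `[0, 2*pi)` downstream of the network.
#'
#' @param cfg a [corenet_config()].
#' @return an object of class `corenet_model`.
#' @export
build_corenet <- function(cfg) {
  stopifnot(inherits(cfg, "corenet_config"))
  with_seed_if(cfg$seed, {
    ch <- cfg$base_width * 2L^(seq_len(cfg$depth) - 1L)
    make_path <- function() {
      lapply(seq_len(cfg$depth), function(l) {
        cin <- if (l == 1L) 1L else ch[l - 1L]
        list(sub1 = new_resblock(cin, ch[l], stride = 2L),
             sub2 = new_resblock(ch[l], ch[l]))
      })
    }
    path_a <- make_path()
    path_b <- make_path()
    cbot <- 2L * ch[cfg$depth]
    bottleneck <- new_resblock(cbot, cbot)
    up <- vector("list", cfg$depth + cfg$extra_up)
    cin <- cbot
    for (l in seq(cfg$depth, 1L)) {
      cout <- if (l >= 2L) ch[l - 1L] else cfg$base_width
      skip_ch <- if (l >= 2L) 2L * ch[l - 1L] else 0L
      up[[cfg$depth - l + 1L]] <- list(
        sub1 = new_resblock(cin, cout, up = TRUE),
        sub2 = new_resblock(cout + skip_ch, cout),
        skip_level = if (l >= 2L) l - 1L else 0L)
      cin <- cout
    }
    if (cfg$extra_up > 0L) {
      for (j in seq_len(cfg$extra_up)) {
        up[[cfg$depth + j]] <- list(
          sub1 = new_resblock(cin, cfg$base_width, up = TRUE),
          sub2 = new_resblock(cfg$base_width, cfg$base_width),
          skip_level = 0L)
        cin <- cfg$base_width
      }
    }
    head_bn <- new_bn(cfg$base_width)
    head_conv <- new_conv(3L, 3L, cfg$base_width, 1L)
    model <- new_layer("corenet", cfg = cfg, path_a = path_a, path_b = path_b,
                       bottleneck = bottleneck, up = up,
                       head_bn = head_bn, head_conv = head_conv)
    leaves <- list()
    for (p in list(path_a, path_b)) for (bl in p)
      leaves <- c(leaves, resblock_leaves(bl$sub1), resblock_leaves(bl$sub2))
    leaves <- c(leaves, resblock_leaves(bottleneck))
    for (bl in up)
      leaves <- c(leaves, resblock_leaves(bl$sub1), resblock_leaves(bl$sub2))
    model$leaves <- c(leaves, list(head_bn, head_conv))
    model
  })
}

#' Number of learnable parameters of a model
#' @param model a `corenet_model` from [build_corenet()].
#' @return integer parameter count.
#' @export
corenet_n_params <- function(model) {
  sum(vapply(model$leaves,
             function(l) sum(vapply(l$params, function(p) length(l[[p]]),
                                    numeric(1))), numeric(1)))
}

# forward pass; xa, xb: (H, W, 1, N). Returns (H', W', 1, N) unwrapped phase.
corenet_fwd <- function(model, xa, xb, train = FALSE) {
  if (length(dim(xa)) != 4L || length(dim(xb)) != 4L)
    stop("network inputs must be 4-D (H, W, 1, N) arrays")
  if (!identical(dim(xa), dim(xb)))
    stop("the two input planes must have identical shape")
  if (dim(xa)[1] != model$cfg$input_size || dim(xa)[2] != model$cfg$input_size)
    stop("input size does not match the configured grid")
  run_path <- function(path, x) {
    skips <- vector("list", length(path))
    for (l in seq_along(path)) {
      x <- resblock_fwd(path[[l]]$sub1, x, train)
      x <- resblock_fwd(path[[l]]$sub2, x, train)
      skips[[l]] <- x
    }
    skips
  }
  sa <- run_path(model$path_a, xa)
  sb <- run_path(model$path_b, xb)
  model$skip_dims <- lapply(sa, dim)
  z <- resblock_fwd(model$bottleneck, concat_ch(sa[[length(sa)]],
                                                sb[[length(sb)]]), train)
  for (bl in model$up) {
    z <- resblock_fwd(bl$sub1, z, train)
    if (bl$skip_level > 0L)
      z <- concat_ch(z, concat_ch(sa[[bl$skip_level]], sb[[bl$skip_level]]))
    z <- resblock_fwd(bl$sub2, z, train)
  }
  h <- layer_fwd(model$head_bn, z, train)
  model$head_mask <- h > 0
  layer_fwd(model$head_conv, h * model$head_mask, train)
}

# backward pass for corenet_fwd(train = TRUE); gy: gradient w.r.t. the
# unwrapped-phase output. Accumulates parameter gradients in the leaves.
corenet_bwd <- function(model, gy) {
  gh <- layer_bwd(model$head_conv, gy) * model$head_mask
  gz <- layer_bwd(model$head_bn, gh)
  ga_skips <- lapply(model$skip_dims, function(d) array(0, dim = d))
  gb_skips <- lapply(model$skip_dims, function(d) array(0, dim = d))
  for (i in rev(seq_along(model$up))) {
    bl <- model$up[[i]]
    gz <- resblock_bwd(bl$sub2, gz)
    if (bl$skip_level > 0L) {
      cs <- model$skip_dims[[bl$skip_level]][3]
      cz <- dim(gz)[3] - 2L * cs
      sp <- split_ch(gz, cz)
      sk <- split_ch(sp$b, cs)
      ga_skips[[bl$skip_level]] <- ga_skips[[bl$skip_level]] + sk$a
      gb_skips[[bl$skip_level]] <- gb_skips[[bl$skip_level]] + sk$b
      gz <- sp$a
    }
    gz <- resblock_bwd(bl$sub1, gz)
  }
  gz <- resblock_bwd(model$bottleneck, gz)
  d <- length(model$path_a)
  sp <- split_ch(gz, dim(gz)[3] %/% 2L)
  ga_skips[[d]] <- ga_skips[[d]] + sp$a
  gb_skips[[d]] <- gb_skips[[d]] + sp$b
  back_path <- function(path, gskips) {
    g <- 0
    for (l in rev(seq_along(path))) {
      g <- g + gskips[[l]]
      g <- resblock_bwd(path[[l]]$sub2, g)
      g <- resblock_bwd(path[[l]]$sub1, g)
    }
    g
  }
  list(gxa = back_path(model$path_a, ga_skips),
       gxb = back_path(model$path_b, gb_skips))
}

#' Prepare the dual network inputs from a target image
#'
#' Back-propagates the target amplitude `sqrt(target)` from the target plane
#' to the facet plane and splits the resulting complex field into its real
#' and imaginary parts — the two input planes of the encoder. Feeding the
#' field at the facet plane (rather than the raw image at the target plane)
#' keeps input and output of the network at the same plane, which makes the
#' feature mapping easier to learn. Both planes are jointly scaled by the
#' peak field magnitude so input statistics do not depend on target
#' brightness.
#'
#' @param target numeric target intensity matrix in `[0, 1]`.
#' @param z propagation distance (um).
#' @param geom a [field_geometry()].
#' @param H optional precomputed `+z` transfer function.
#' @return list with matrices `re` and `im` and the applied `scale`.
#' @export
prepare_inputs <- function(target, z, geom, H = NULL) {
  check_target(target, geom)
  U <- backpropagate(target, z, geom = geom, H = H)$values
  s <- max(Mod(U))
  if (s > 0) U <- U / s
  list(re = Re(U), im = Im(U), scale = s)
}

#' Full differentiable pipeline: network output to reconstructed intensity
#'
#' Runs a single target through the trained (or untrained) network and the
#' embedded physical model: infer the full-grid phase, sample it at the core
#' positions, render the disk field, propagate to the target plane, and take
#' the squared modulus. Every stage is differentiable; the training loop
#' uses the same code path.
#'
#' @param model a `corenet_model`.
#' @param target numeric target intensity matrix.
#' @param core_map a [core_map()].
#' @param geom a [field_geometry()] of the modulator grid.
#' @param z propagation distance (um).
#' @param plan,H optional cached render plan / transfer function.
#' @return list with `slm` (wrapped full-grid phase), `hologram`
#'   ([core_hologram()]), and `intensity` (max-normalized reconstruction).
#' @export
forward_pipeline <- function(model, target, core_map, geom, z = 700,
                             plan = NULL, H = NULL) {
  if (is.null(plan)) plan <- core_render_plan(core_map, geom)
  if (is.null(H)) H <- transfer_function(geom, z)
  phase <- infer_hologram(model, target, z, geom, H = H)
  holo <- sample_core_phases(phase, core_map, geom, plan = plan)
  I <- reconstruct_intensity(render_core_field(holo, core_map, geom,
                                               plan = plan), z, H = H)
  list(slm = phase, hologram = holo, intensity = I)
}

#' Infer a modulator hologram for a target with a single forward pass
#'
#' @param model a trained `corenet_model`.
#' @param target numeric target intensity matrix on the input grid.
#' @param z propagation distance (um).
#' @param geom a [field_geometry()].
#' @param H optional precomputed transfer function.
#' @return the full-resolution phase hologram, wrapped to `[0, 2*pi)`.
#' @export
infer_hologram <- function(model, target, z = 700, geom, H = NULL) {
  inp <- prepare_inputs(target, z, geom, H = H)
  n <- model$cfg$input_size
  xa <- array(inp$re, dim = c(n, n, 1L, 1L))
  xb <- array(inp$im, dim = c(n, n, 1L, 1L))
  out <- corenet_fwd(model, xa, xb, train = FALSE)
  wrap_phase(matrix(out, model$cfg$output_size, model$cfg$output_size))
}

#' Train the phase-encoder network, unsupervised
#'
#' Minimizes the mean negative Pearson correlation between each target and
#' its own reconstruction through the embedded fiber + propagation model
#' with the Adam optimizer. The target is simultaneously the input (after
#' back-propagation to the facet) and the label, so no precomputed hologram
#' enters the loop at any point.
#'
#' @param model a `corenet_model` (modified in place and returned).
#' @param targets non-empty list of target intensity matrices on the
#'   modulator grid.
#' @param core_map a [core_map()].
#' @param geom a [field_geometry()].
#' @param z propagation distance (um).
#' @param epochs number of epochs (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param lr Adam learning rate.
#' @param seed seed controlling shuffling (weight initialization is fixed by
#'   the model's own config seed).
#' @param verbose print per-epoch mean loss.
#' @return the model, with `$loss_history` set to the per-epoch mean NPCC
#'   loss.
#' @export
train_corenet <- function(model, targets, core_map, geom, z = 700,
                          epochs = 5L, batch_size = 8L, lr = 1e-3,
                          seed = 1L, verbose = FALSE) {
  if (!length(targets)) stop("targets must be a non-empty list")
  stopifnot(epochs >= 1L, batch_size >= 1L)
  n <- model$cfg$input_size
  if (geom$nx != n || geom$ny != n)
    stop("geometry does not match the configured input size")
  plan <- core_render_plan(core_map, geom)
  H <- transfer_function(geom, z)
  nt <- length(targets)
  Xre <- array(0, dim = c(n, n, nt)); Xim <- array(0, dim = c(n, n, nt))
  for (i in seq_len(nt)) {
    inp <- prepare_inputs(targets[[i]], z, geom, H = H)
    Xre[, , i] <- inp$re; Xim[, , i] <- inp$im
  }
  loss_hist <- numeric(epochs)
  step <- 0L
  with_seed_if(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nt)
      ep_loss <- 0
      for (b0 in seq(1L, nt, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, nt)]
        B <- length(idx)
        xa <- array(Xre[, , idx], dim = c(n, n, 1L, B))
        xb <- array(Xim[, , idx], dim = c(n, n, 1L, B))
        phase <- corenet_fwd(model, xa, xb, train = TRUE)
        gy <- array(0, dim = dim(phase))
        bl <- 0
        for (k in seq_len(B)) {
          phi <- matrix(phase[, , 1L, k], model$cfg$output_size)
          r <- pipeline_loss_grad(phi, targets[[idx[k]]], plan, H)
          bl <- bl + r$loss
          gy[, , 1L, k] <- r$gphi / B
        }
        corenet_bwd(model, gy)
        step <- step + 1L
        adam_step(model$leaves, lr = lr, t = step)
        ep_loss <- ep_loss + bl
      }
      loss_hist[ep] <- ep_loss / nt
      if (verbose)
        message(sprintf("epoch %d/%d: mean NPCC loss %.4f", ep, epochs,
                        loss_hist[ep]))
    }
  })
  model$loss_history <- loss_hist
  model
}

# loss and gradient of NPCC(|propagate(render(sample(phi)))|^2, target)
# with respect to the full-grid unwrapped phase phi
pipeline_loss_grad <- function(phi, target, plan, H) {
  v <- exp(1i * phi[plan$sample_idx])
  values <- matrix(0i, plan$ny, plan$nx)
  values[plan$disk_idx] <- v[plan$disk_core]
  Ut <- apply_transfer(values, H)
  I <- Mod(Ut)^2
  loss <- npcc_loss(I, target)
  gI <- npcc_loss_grad(I, target)
  g <- 2 * Ut * gI
  gfac <- apply_transfer(g, Conj(H))
  gv <- gfac[plan$disk_idx]
  sre <- rowsum(Re(gv), plan$disk_core, reorder = TRUE)
  sim <- rowsum(Im(gv), plan$disk_core, reorder = TRUE)
  s <- complex(real = sre, imaginary = sim)
  dphi <- Im(Conj(v) * s)
  gphi <- matrix(0, plan$ny, plan$nx)
  gphi[plan$sample_idx] <- dphi
  list(loss = loss, gphi = gphi)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, all learnable parameters, the
#' BatchNorm running statistics, and the loss history.
#'
#' @param model a `corenet_model`.
#' @param path checkpoint file path (RDS).
#' @return `save_corenet` returns `path` invisibly; `load_corenet` returns
#'   the restored model.
#' @export
save_corenet <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), state = leaves_state(model$leaves),
               loss_history = model$loss_history), path)
  invisible(path)
}

#' @rdname save_corenet
#' @export
load_corenet <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(corenet_config, ck$cfg[c("input_size", "output_size", "depth",
                                          "base_width", "seed")])
  model <- build_corenet(cfg)
  restore_leaves(model$leaves, ck$state)
  model$loss_history <- ck$loss_history
  model
}
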