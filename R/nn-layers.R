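# Minimal layer framework for the phase-encoder network.
#
# Layers are environments holding parameter arrays, gradient slots, optimizer
# state, and forward caches; `layer_fwd()`/`layer_bwd()` dispatch on $type.
# Tensors are R arrays in (H, W, C, N) layout. Convolution inner loops live in
# src/conv_ops.cpp; everything else is vectorized R. Environments give the
# mutable state (BatchNorm running statistics, Adam moments) without
# reassembling a nested parameter list on every update.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

new_conv <- function(kh, kw, cin, cout, stride = 1L, pad = (kh - 1L) %/% 2L) {
  new_layer("conv", w = he_init(c(kh, kw, cin, cout), kh * kw * cin),
            b = numeric(cout), s = as.integer(stride), p = as.integer(pad),
            params = c("w", "b"))
}

# transposed conv doubling the spatial size; weights (kh, kw, cout, cin)
new_tconv <- function(kh, kw, cin, cout, stride = 2L, pad = (kh - 1L) %/% 2L) {
  new_layer("tconv", w = he_init(c(kh, kw, cout, cin), kh * kw * cin),
            b = numeric(cout), s = as.integer(stride), p = as.integer(pad),
            params = c("w", "b"))
}

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", gamma = rep(1, c), beta = numeric(c),
            rm = numeric(c), rv = rep(1, c), momentum = momentum, eps = eps,
            params = c("gamma", "beta"))
}

layer_fwd <- function(l, x, train) {
  switch(l$type,
    conv = {
      r <- conv2d_fwd_cpp(x, l$w, l$b, l$s, l$s, l$p, l$p, l$cols)
      l$cols <- r$cols
      if (train) l$xdim <- dim(x)
      r$y
    },
    tconv = {
      if (train) l$x <- x
      d <- dim(x)
      tconv2d_fwd_cpp(x, l$w, l$b, l$s, l$s, l$p, l$p,
                      d[1] * l$s, d[2] * l$s)
    },
    bn = bn_fwd(l, x, train),
    stop("unknown layer type: ", l$type))
}

layer_bwd <- function(l, gy) {
  switch(l$type,
    conv = {
      r <- conv2d_bwd_cpp(l$cols, l$w, gy, l$xdim, l$s, l$s, l$p, l$p)
      l$gw <- r$gw; l$gb <- r$gb
      r$gx
    },
    tconv = {
      r <- tconv2d_bwd_cpp(l$x, l$w, gy, l$s, l$s, l$p, l$p)
      l$gw <- r$gw; l$gb <- r$gb
      r$gx
    },
    bn = bn_bwd(l, gy),
    stop("unknown layer type: ", l$type))
}

# per-channel sums over (H, W, N) without materializing a transposed copy
channel_stats <- function(x, d) {
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  list(s1 = rowSums(matrix(.colSums(x, hw, C * N), C, N)),
       s2 = rowSums(matrix(.colSums(x * x, hw, C * N), C, N)), count = hw * N)
}

bn_fwd <- function(l, x, train) {
  d <- dim(x)
  hw <- d[1] * d[2]
  if (train) {
    st <- channel_stats(x, d)
    mu <- st$s1 / st$count
    v <- st$s2 / st$count - mu^2
    l$rm <- (1 - l$momentum) * l$rm + l$momentum * mu
    l$rv <- (1 - l$momentum) * l$rv + l$momentum * v
    istd <- 1 / sqrt(v + l$eps)
    xhat <- (x - rep(mu, each = hw)) * rep(istd, each = hw)
    l$xhat <- xhat
    l$istd <- istd
    l$d <- d
    xhat * rep(l$gamma, each = hw) + rep(l$beta, each = hw)
  } else {
    # inference: fold normalization and affine into one multiply-add
    istd <- 1 / sqrt(l$rv + l$eps)
    a <- l$gamma * istd
    bn_eval_cpp(x, a, l$beta - l$rm * a)
  }
}

bn_bwd <- function(l, gy) {
  d <- l$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]; M <- hw * N
  xhat <- l$xhat
  s1 <- rowSums(matrix(.colSums(gy, hw, C * N), C, N))
  s2 <- rowSums(matrix(.colSums(gy * xhat, hw, C * N), C, N))
  l$ggamma <- s2
  l$gbeta <- s1
  gx <- rep(l$gamma * l$istd, each = hw) *
    (gy - rep(s1 / M, each = hw) - xhat * rep(s2 / M, each = hw))
  array(gx, dim = d)
}

# --- pre-activation residual sub-block ------------------------------------
# y = main(x) + shortcut(x) with main = conv2(relu(bn2(conv1(relu(bn1(x))))));
# conv1 is strided (2,2) in "down" blocks and a strided transposed
# convolution in "up" blocks; the shortcut matches shape with a 1x1 strided
# conv (down) or a 2x2 stride-2 transposed conv (up), and is the identity
# when the shapes already agree.
new_resblock <- function(cin, cout, stride = 1L, up = FALSE) {
  b <- new_layer("res")
  b$bn1 <- new_bn(cin)
  b$conv1 <- if (up) new_tconv(3L, 3L, cin, cout) else
    new_conv(3L, 3L, cin, cout, stride = stride)
  b$bn2 <- new_bn(cout)
  b$conv2 <- new_conv(3L, 3L, cout, cout)
  b$shortcut <- if (up) new_tconv(2L, 2L, cin, cout, pad = 0L)
    else if (stride != 1L || cin != cout)
      new_conv(1L, 1L, cin, cout, stride = stride, pad = 0L)
    else NULL
  b
}

resblock_fwd <- function(b, x, train) {
  a1 <- layer_fwd(b$bn1, x, train)
  b$mask1 <- a1 > 0
  h <- layer_fwd(b$conv1, a1 * b$mask1, train)
  a2 <- layer_fwd(b$bn2, h, train)
  b$mask2 <- a2 > 0
  h2 <- layer_fwd(b$conv2, a2 * b$mask2, train)
  sc <- if (is.null(b$shortcut)) x else layer_fwd(b$shortcut, x, train)
  h2 + sc
}

resblock_bwd <- function(b, gy) {
  gr2 <- layer_bwd(b$conv2, gy) * b$mask2
  gh <- layer_bwd(b$bn2, gr2)
  gr1 <- layer_bwd(b$conv1, gh) * b$mask1
  gx <- layer_bwd(b$bn1, gr1)
  gx + (if (is.null(b$shortcut)) gy else layer_bwd(b$shortcut, gy))
}

resblock_leaves <- function(b) {
  out <- list(b$bn1, b$conv1, b$bn2, b$conv2)
  if (!is.null(b$shortcut)) out <- c(out, list(b$shortcut))
  out
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , (c1 + 1):d[3], , drop = FALSE])
}

# --- Adam ------------------------------------------------------------------

adam_step <- function(leaves, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (l in leaves) {
    for (pn in l$params) {
      g <- l[[paste0("g", pn)]]
      if (is.null(g)) next
      mk <- paste0("m_", pn); vk <- paste0("v_", pn)
      if (is.null(l[[mk]])) { l[[mk]] <- g * 0; l[[vk]] <- g * 0 }
      l[[mk]] <- beta1 * l[[mk]] + (1 - beta1) * g
      l[[vk]] <- beta2 * l[[vk]] + (1 - beta2) * g * g
      l[[pn]] <- l[[pn]] - lr * (l[[mk]] / c1) / (sqrt(l[[vk]] / c2) + eps)
    }
  }
}

# serialize/restore leaf parameters (used by checkpoints)
leaves_state <- function(leaves) {
  lapply(leaves, function(l) {
    s <- lapply(l$params, function(pn) l[[pn]])
    names(s) <- l$params
    if (l$type == "bn") { s$rm <- l$rm; s$rv <- l$rv }
    s
  })
}

restore_leaves <- function(leaves, state) {
  stopifnot(length(leaves) == length(state))
  for (i in seq_along(leaves)) {
    for (nm in names(state[[i]])) leaves[[i]][[nm]] <- state[[i]][[nm]]
  }
  invisible(leaves)
}
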