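test_that("network configuration enforces size and depth invariants", {
  expect_error(corenet_config(60L, depth = 3L), "divisible")
  expect_error(corenet_config(64L, output_size = 32L), ">= input")
  expect_error(corenet_config(64L, output_size = 96L), "power of two")
  expect_error(corenet_config(64L, depth = 0L), "depth")
  cfg <- corenet_config(64L, output_size = 128L, depth = 3L, base_width = 4L)
  expect_equal(cfg$extra_up, 1L)
})

test_that("identical config and seed give identical parameters; the output covers the SLM grid", {
  cfg <- corenet_config(16L, depth = 2L, base_width = 4L, seed = 11L)
  m1 <- build_corenet(cfg)
  m2 <- build_corenet(cfg)
  s1 <- mcfholo:::leaves_state(m1$leaves)
  s2 <- mcfholo:::leaves_state(m2$leaves)
  expect_identical(s1, s2)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  out <- mcfholo:::corenet_fwd(m1, x, x, train = FALSE)
  expect_equal(dim(out), c(16L, 16L, 1L, 1L))
  # upsampling configuration reaches a finer SLM grid than the input
  cfg2 <- corenet_config(16L, output_size = 32L, depth = 2L, base_width = 4L,
                         seed = 1L)
  m3 <- build_corenet(cfg2)
  out2 <- mcfholo:::corenet_fwd(m3, x, x, train = FALSE)
  expect_equal(dim(out2)[1:2], c(32L, 32L))
})

test_that("the network requires two conformable input planes", {
  m <- build_corenet(corenet_config(16L, depth = 2L, base_width = 4L))
  x <- array(rnorm(256), c(16, 16, 1, 1))
  expect_error(mcfholo:::corenet_fwd(m, x, array(rnorm(64), c(8, 8, 1, 1))),
               "identical shape")
  expect_error(mcfholo:::corenet_fwd(m, matrix(0, 16, 16), x), "4-D")
})

test_that("prepared inputs live at the facet plane and re-propagate to the target", {
  g <- desk_geom(64)
  zero <- matrix(0, 64, 64)
  inp0 <- prepare_inputs(zero, 700, g)
  expect_true(all(inp0$re == 0) && all(inp0$im == 0))
  tg <- generate_targets(1, 64, "disks", seed = 14)[[1]]
  # z = 0: no propagation phase, so the imaginary plane vanishes
  inp_z0 <- prepare_inputs(tg, 0, g)
  expect_lt(max(abs(inp_z0$im)), 1e-12)
  # smooth in-band target: round trip preserves the image
  tgs <- mcfholo:::gaussian_blur(tg, 2)
  tgs <- tgs / max(tgs)
  inp <- prepare_inputs(tgs, 700, g)
  U <- (inp$re + 1i * inp$im) * inp$scale
  rec <- Mod(propagate(complex_field(U, g), 700)$values)^2
  expect_gte(correlation_coefficient(rec, tgs), 0.99)
})

test_that("the forward pipeline is deterministic and consistent with its stages", {
  g <- desk_geom(32)
  cm <- make_synthetic_core_map(40, facet_diameter = 60, seed = 3)
  m <- build_corenet(corenet_config(32L, depth = 2L, base_width = 4L,
                                    seed = 2L))
  tg <- generate_targets(1, 32, "disks", seed = 15)[[1]]
  r1 <- forward_pipeline(m, tg, cm, g, z = 700)
  r2 <- forward_pipeline(m, tg, cm, g, z = 700)
  expect_identical(r1$intensity, r2$intensity)
  expect_true(all(r1$slm >= 0 & r1$slm < 2 * pi))
  # replacing the network output with a Core-GS hologram reproduces the
  # Core-GS reconstruction exactly
  cgs <- core_gs_retrieve(tg, cm, 700, g, iters = 20)
  I_pipe <- reconstruct_intensity(render_core_field(cgs$hologram, cm, g), 700)
  rep <- evaluate_method(function(t) cgs$hologram, list(tg), cm, g, z = 700)
  expect_equal(rep$cc[1], correlation_coefficient(I_pipe, tg))
})

test_that("loss gradients flow through the full pipeline (finite differences)", {
  g <- field_geometry(16, 16, 2, 2, 0.532)
  cm <- make_synthetic_core_map(8, facet_diameter = 28, seed = 5)
  plan <- core_render_plan(cm, g)
  H <- transfer_function(g, 700)
  m <- build_corenet(corenet_config(16L, depth = 2L, base_width = 4L,
                                    seed = 3L))
  tg <- generate_targets(1, 16, "disks", seed = 9)[[1]]
  # evaluate at a generic parameter point: a freshly initialized network has
  # BN outputs sitting exactly on the ReLU kink (beta = 0), where the loss is
  # genuinely non-differentiable and central differences see the kink
  withr::with_seed(91, for (l in m$leaves) for (pn in l$params)
    l[[pn]] <- l[[pn]] + rnorm(length(l[[pn]]), sd = 1e-3))
  inp <- prepare_inputs(tg, 700, g, H = H)
  xa <- array(inp$re, c(16, 16, 1, 1))
  xb <- array(inp$im, c(16, 16, 1, 1))
  run <- function() {
    ph <- mcfholo:::corenet_fwd(m, xa, xb, train = TRUE)
    mcfholo:::pipeline_loss_grad(matrix(ph, 16, 16), tg, plan, H)
  }
  r0 <- run()
  expect_true(is.finite(r0$loss))
  mcfholo:::corenet_bwd(m, array(r0$gphi, c(16, 16, 1, 1)))
  withr::with_seed(21, {
    checked <- 0
    while (checked < 12) {
      l <- m$leaves[[sample(length(m$leaves), 1)]]
      pn <- sample(l$params, 1)
      idx <- sample(length(l[[pn]]), 1)
      ana <- l[[paste0("g", pn)]][idx]
      v0 <- l[[pn]][idx]
      eps <- 1e-5
      l[[pn]][idx] <- v0 + eps; lp <- run()$loss
      l[[pn]][idx] <- v0 - eps; lm <- run()$loss
      l[[pn]][idx] <- v0
      fd <- (lp - lm) / (2 * eps)
      if (abs(fd) > 1e-8) {
        expect_lt(abs(ana - fd) / abs(fd), 1e-3)
        checked <- checked + 1
      }
    }
  })
})

test_that("training is unsupervised, reduces the loss, and can overfit one sample", {
  g <- desk_geom(32)
  # enough cores that the array can represent the disk target well: the
  # capacity check is about the optimizer, not the physical ceiling
  cm <- make_synthetic_core_map(80, facet_diameter = 60, seed = 3)
  tg <- generate_targets(1, 32, "disks", seed = 16)
  m <- build_corenet(corenet_config(32L, depth = 2L, base_width = 6L,
                                    seed = 4L))
  expect_error(train_corenet(m, list(), cm, g), "non-empty")
  m <- train_corenet(m, tg, cm, g, z = 700, epochs = 80, batch_size = 1,
                     lr = 2e-3, seed = 2)
  expect_length(m$loss_history, 80)
  expect_lt(m$loss_history[80], m$loss_history[1])
  out <- forward_pipeline(m, tg[[1]], cm, g, z = 700)
  expect_gte(correlation_coefficient(out$intensity, tg[[1]]), 0.9)
})

test_that("inference is deterministic and beats a random-phase null baseline", {
  g <- desk_geom(32)
  cm <- make_synthetic_core_map(40, facet_diameter = 60, seed = 3)
  plan <- core_render_plan(cm, g)
  H <- transfer_function(g, 700)
  tg <- generate_targets(1, 32, "disks", seed = 17)
  m <- build_corenet(corenet_config(32L, depth = 2L, base_width = 6L,
                                    seed = 5L))
  m <- train_corenet(m, tg, cm, g, z = 700, epochs = 40, batch_size = 1,
                     lr = 2e-3, seed = 3)
  h1 <- infer_hologram(m, tg[[1]], 700, g)
  h2 <- infer_hologram(m, tg[[1]], 700, g)
  expect_identical(h1, h2)
  cc_net <- reconstruct_cc(sample_core_phases(h1, cm, g, plan = plan),
                           tg[[1]], cm, g, 700, plan, H)
  withr::with_seed(7, rnd <- core_hologram(runif(40, 0, 2 * pi)))
  cc_rnd <- reconstruct_cc(rnd, tg[[1]], cm, g, 700, plan, H)
  expect_gt(cc_net, cc_rnd)
})

test_that("checkpoints restore configuration, weights and BN statistics", {
  g <- desk_geom(32)
  cm <- make_synthetic_core_map(40, facet_diameter = 60, seed = 3)
  tg <- generate_targets(2, 32, "disks", seed = 18)
  m <- build_corenet(corenet_config(32L, depth = 2L, base_width = 4L,
                                    seed = 6L))
  m <- train_corenet(m, tg, cm, g, z = 700, epochs = 2, batch_size = 2,
                     seed = 4)
  p <- withr::local_tempfile(fileext = ".rds")
  save_corenet(m, p)
  m2 <- load_corenet(p)
  expect_equal(m2$loss_history, m$loss_history)
  expect_identical(infer_hologram(m2, tg[[1]], 700, g),
                   infer_hologram(m, tg[[1]], 700, g))
})
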