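test_that("transfer function obeys the analytic on-axis, z = 0 and window limits", {
  g <- desk_geom(32)
  for (z in c(-350, 0, 123.4, 700)) {
    H <- transfer_function(g, z)
    # DC bin sits at [1, 1] in fft order: H(0,0) = exp(i 2 pi z / lambda)
    expect_equal(H[1, 1], exp(2i * pi * z / g$wavelength), tolerance = 1e-12)
  }
  H0 <- transfer_function(g, 0)
  f <- mcfholo:::freq_grids(g)
  rho2 <- outer(f$v^2, f$u^2, `+`)
  propagating <- rho2 <= 1 / g$wavelength^2
  expect_true(all(H0[propagating] == 1))
  expect_true(all(H0[!propagating] == 0))
  # beyond the band limit the window forces exact zeros
  Hz <- transfer_function(g, 700)
  lim <- band_limits(g, 700)
  outside <- abs(outer(rep(1, g$ny), f$u)) > lim$u_limit
  expect_true(all(Hz[outside] == 0))
  # unit modulus on every propagating in-window frequency
  expect_true(all(abs(Mod(Hz[Mod(Hz) > 0]) - 1) < 1e-14))
})

test_that("band limits tend to 1/lambda as z tends to 0 and shrink with z", {
  g <- desk_geom(32)
  expect_equal(band_limits(g, 0)$u_limit, 1 / g$wavelength)
  expect_lt(band_limits(g, 700)$u_limit, band_limits(g, 100)$u_limit)
  expect_equal(band_limits(g, 0)$du, 1 / (g$nx * g$pitch_x))
})

test_that("geometry validation rejects degenerate grids and bad physics", {
  expect_error(field_geometry(1, 8), "at least 2 x 2")
  expect_error(field_geometry(8, 8, pitch_x = 0), "pitch")
  expect_error(field_geometry(8, 8, wavelength = -1), "wavelength")
  g <- desk_geom(8)
  expect_error(complex_field(matrix(0i, 4, 4), g), "mismatch")
})

test_that("z = 0 propagation is the identity on band-limited input", {
  g <- desk_geom(32)
  f <- inband_field(g, 0, seed = 2)
  out <- propagate(f, 0)
  expect_lt(rel_err(out$values, f$values), 1e-10)
})

test_that("propagate conserves in-band energy and inverts exactly within the band", {
  g <- desk_geom(32)
  for (z in c(150, 700)) {
    f <- inband_field(g, z, seed = 3)
    fz <- propagate(f, z)
    expect_lt(abs(field_energy(fz) - field_energy(f)) / field_energy(f), 1e-8)
    back <- propagate(fz, -z)
    expect_lt(rel_err(back$values, f$values), 1e-8)
  }
})

test_that("FFT propagation matches the direct frequency-summation oracle", {
  g <- desk_geom(32)
  z <- 50 * g$wavelength
  # single on-axis point emitter
  U <- matrix(0i, 32, 32); U[16, 16] <- 1
  f <- complex_field(U, g)
  got <- propagate(f, z)$values
  want <- propagate_loop_oracle(f, z)
  expect_lt(max(Mod(got - want)), 1e-6)
  expect_lt(max(abs(Mod(got)^2 - Mod(want)^2)), 1e-6)
  # and on a random band-limited field
  f2 <- inband_field(g, z, seed = 4)
  expect_lt(max(Mod(propagate(f2, z)$values - propagate_loop_oracle(f2, z))),
            1e-6)
})

test_that("backpropagate is the conjugate-transfer inverse and validates input", {
  g <- desk_geom(32)
  expect_error(backpropagate(matrix(-1, 32, 32), 700, geom = g),
               "non-negative")
  zero <- backpropagate(matrix(0, 32, 32), 700, geom = g)
  expect_true(all(zero$values == 0))
  # in-band amplitude image round trip
  amp <- Mod(inband_field(g, 700, seed = 5)$values)
  Hb <- transfer_function(g, 700)
  amp_ib <- Re(stats::fft(stats::fft(amp) * (Mod(Hb) > 0), inverse = TRUE) /
                 length(amp))
  f <- backpropagate(complex_field(amp_ib, g), 700)
  rec <- propagate(f, 700)
  expect_lt(rel_err(rec$values, amp_ib), 1e-6)
})

test_that("an off-centre point source re-focuses at its pixel after a round trip", {
  g <- desk_geom(32)
  z <- 100 * g$wavelength
  I <- matrix(0, 32, 32); I[12, 21] <- 1
  fb <- backpropagate(I, z, geom = g)
  rec <- Mod(propagate(fb, z)$values)^2
  expect_equal(which.max(rec), which.max(I))
})

test_that("on-axis intensity agrees with single-term Fresnel propagation in the paraxial limit", {
  g <- field_geometry(32, 32, 1, 1, 0.532)
  co <- mcfholo:::grid_coords(g)
  sigma <- 6
  U <- exp(-outer(co$y^2, co$x^2, `+`) / (2 * sigma^2))
  z <- 240  # z = 7.5x the grid extent; Gaussian spectrum well inside the band
  out <- propagate(complex_field(U, g), z)
  # direct Fresnel-kernel summation (single quadratic-phase term)
  k <- 2 * pi / g$wavelength
  on_axis <- 0i
  for (m in 1:32) for (n2 in 1:32)
    on_axis <- on_axis + U[m, n2] *
      exp(1i * k * (co$x[n2]^2 + co$y[m]^2) / (2 * z))
  on_axis <- on_axis * exp(1i * k * z) / (1i * g$wavelength * z) *
    g$pitch_x * g$pitch_y
  centre <- Mod(out$values[17, 17])^2
  expect_lt(abs(centre - Mod(on_axis)^2) / Mod(on_axis)^2, 0.01)
})

test_that("a scalar loss through propagate has adjoint-consistent gradients", {
  g <- field_geometry(8, 8, 2, 2, 0.532)
  z <- 40
  withr::with_seed(11, {
    phi <- matrix(runif(64, 0, 2 * pi), 8, 8)
    Wt <- matrix(rnorm(64), 8, 8)
  })
  H <- transfer_function(g, z)
  loss <- function(phi) {
    out <- mcfholo:::apply_transfer(exp(1i * phi), H)
    sum(Wt * Mod(out)^2)
  }
  # analytic gradient via the conjugate-transfer adjoint
  out <- mcfholo:::apply_transfer(exp(1i * phi), H)
  gU <- mcfholo:::apply_transfer(2 * out * Wt, Conj(H))
  gphi <- Im(Conj(exp(1i * phi)) * gU)
  eps <- 1e-6
  for (idx in c(1, 13, 40, 64)) {
    pp <- phi; pp[idx] <- pp[idx] + eps
    pm <- phi; pm[idx] <- pm[idx] - eps
    fd <- (loss(pp) - loss(pm)) / (2 * eps)
    expect_lt(abs(fd - gphi[idx]) / max(abs(fd), 1e-10), 1e-4)
  }
})

test_that("fields serialize to the two-plane container and back", {
  g <- desk_geom(16)
  f <- inband_field(g, 700, seed = 6)
  path <- withr::local_tempfile(fileext = ".tif")
  write_field(f, path)
  back <- read_field(path)
  expect_equal(back$geom, f$geom)
  # container is 32-bit float; match at single precision
  expect_lt(rel_err(back$values, f$values), 1e-6)
})
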