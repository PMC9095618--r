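test_that("synthetic core maps honour spacing, facet and determinism", {
  cm <- make_synthetic_core_map(60, core_radius = 1, min_spacing = 3.3,
                                facet_diameter = 85, seed = 42)
  expect_s3_class(cm, "core_map")
  expect_equal(cm$n_cores, 60L)
  # brute-force all-pairs verification, independent of the generator
  d <- as.matrix(dist(cm$centers))
  diag(d) <- Inf
  expect_gte(min(d), 3.3)
  expect_true(all(sqrt(rowSums(cm$centers^2)) + 1 <= 85 / 2 + 1e-9))
  cm2 <- make_synthetic_core_map(60, core_radius = 1, min_spacing = 3.3,
                                 facet_diameter = 85, seed = 42)
  expect_identical(cm$centers, cm2$centers)
})

test_that("a single core sits on the facet centre", {
  cm <- make_synthetic_core_map(1, seed = 1)
  expect_equal(unname(cm$centers), matrix(0, 1, 2))
})

test_that("the full-scale bundle geometry (10,000 cores, 350 um) is placeable", {
  cm <- make_synthetic_core_map(10000, core_radius = 1, min_spacing = 3.3,
                                facet_diameter = 350, seed = 7)
  expect_equal(cm$n_cores, 10000L)
  expect_gte(mcfholo:::min_pair_distance(cm$centers), 3.3 - 1e-9)
})

test_that("infeasible packings fail with an informative constraint message", {
  expect_error(make_synthetic_core_map(500, min_spacing = 3.3,
                                       facet_diameter = 30, seed = 1),
               "packing infeasible")
  expect_error(core_map(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE),
                        min_spacing = 3.3),
               "spacing")
  expect_error(core_map(matrix(c(0, 200), 1, 2), facet_diameter = 100),
               "facet")
})

test_that("sampling a phase image reads the nearest pixel per core and wraps", {
  g <- desk_geom(32)
  cm <- make_synthetic_core_map(20, facet_diameter = 50, seed = 3)
  # constant image: every core reads the constant
  holo <- sample_core_phases(matrix(1.5, 32, 32), cm, g)
  expect_true(all(holo$phases == 1.5))
  # linear ramp: verified by an independent nearest-pixel lookup
  co <- mcfholo:::grid_coords(g)
  ramp <- outer(0.01 * co$y, 0.02 * co$x, `+`)
  holo2 <- sample_core_phases(ramp, cm, g)
  for (c in seq_len(cm$n_cores)) {
    iy <- round(cm$centers[c, 2] / g$pitch_y + (g$ny + 1) / 2)
    jx <- round(cm$centers[c, 1] / g$pitch_x + (g$nx + 1) / 2)
    expect_equal(holo2$phases[c], mcfholo:::wrap_phase(ramp[iy, jx]))
  }
  # phases outside [0, 2 pi) are wrapped
  holo3 <- sample_core_phases(matrix(-pi, 32, 32), cm, g)
  expect_true(all(holo3$phases >= 0 & holo3$phases < 2 * pi))
})

test_that("cores outside the grid are rejected", {
  g <- desk_geom(16)  # 32 um extent
  cm <- core_map(matrix(c(40, 0), 1, 2), facet_diameter = 100, check = TRUE)
  expect_error(sample_core_phases(matrix(0, 16, 16), cm, g), "outside")
})

test_that("rendering paints unit-amplitude piston disks with the expected energy", {
  g <- desk_geom(32)
  cm <- make_synthetic_core_map(15, facet_diameter = 50, seed = 9)
  holo <- core_hologram(rep(0, 15))
  f <- render_core_field(holo, cm, g)
  expect_true(all(Im(f$values) == 0))
  expect_true(all(Re(f$values) %in% c(0, 1)))
  # energy equals the independently counted disk pixel total
  co <- mcfholo:::grid_coords(g)
  n_px <- 0L
  for (c in seq_len(cm$n_cores)) {
    d2 <- outer((co$y - cm$centers[c, 2])^2, (co$x - cm$centers[c, 1])^2, `+`)
    n_px <- n_px + max(1L, sum(d2 <= cm$core_radius^2))
  }
  expect_equal(field_energy(f), n_px)
})

test_that("sampling after rendering recovers the hologram exactly", {
  g <- desk_geom(64)
  cm <- make_synthetic_core_map(128, facet_diameter = 85, seed = 5)
  withr::with_seed(8, phases <- runif(128, 0, 2 * pi))
  holo <- core_hologram(phases)
  f <- render_core_field(holo, cm, g)
  back <- sample_core_phases(Arg(f$values), cm, g)
  expect_equal(back$phases, mcfholo:::wrap_phase(phases), tolerance = 1e-12)
})

test_that("far-field intensity is invariant under a global phase shift", {
  g <- desk_geom(32)
  cm <- make_synthetic_core_map(30, facet_diameter = 60, seed = 6)
  withr::with_seed(10, phases <- runif(30, 0, 2 * pi))
  I1 <- reconstruct_intensity(render_core_field(core_hologram(phases), cm, g),
                              700)
  I2 <- reconstruct_intensity(render_core_field(core_hologram(phases + 1.23),
                                                cm, g), 700)
  expect_equal(I1, I2, tolerance = 1e-9)
  # single core: intensity independent of its (only, hence global) phase
  cm1 <- make_synthetic_core_map(1, seed = 1)
  g1 <- desk_geom(32)
  Ia <- reconstruct_intensity(render_core_field(core_hologram(0), cm1, g1), 700)
  Ib <- reconstruct_intensity(render_core_field(core_hologram(2.5), cm1, g1), 700)
  expect_equal(Ia, Ib, tolerance = 1e-9)
})

test_that("overlapping disks are rejected at render time", {
  cm <- core_map(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE), core_radius = 2,
                 facet_diameter = 80, min_spacing = 0.5, check = FALSE)
  expect_error(render_core_field(core_hologram(c(0, 1)), cm, desk_geom(32)),
               "overlap")
})

test_that("OPD layers add, wrap, and cancel exactly under conjugation", {
  withr::with_seed(3, {
    phases <- runif(40, 0, 2 * pi)
    opd <- runif(40, 0, 2 * pi)
  })
  holo <- core_hologram(phases)
  expect_error(apply_opd(holo, opd[1:10]), "length")
  distorted <- apply_opd(holo, opd)
  expect_equal(mcfholo:::effective_phases(distorted),
               mcfholo:::wrap_phase(phases + opd))
  # zero OPD is the identity
  expect_identical(apply_opd(holo, rep(0, 40))$offset + holo$phases,
                   holo$phases)
  # distortion then conjugate compensation restores the object exactly
  restored <- apply_opd(distorted, conjugate_compensation(opd))
  expect_identical(restored, holo)
})

test_that("conjugate compensation makes the transmitted field bit-for-bit identical", {
  g <- desk_geom(64)
  cm <- make_synthetic_core_map(128, facet_diameter = 85, seed = 5)
  withr::with_seed(4, {
    phases <- runif(128, 0, 2 * pi)
    opd <- runif(128, 0, 2 * pi)
  })
  holo <- core_hologram(phases)
  clean <- mcf_transmit(holo, cm, g)
  distorted <- mcf_transmit(holo, cm, g, opd = opd)
  compensated <- mcf_transmit(holo, cm, g, opd = opd,
                              compensation = conjugate_compensation(opd))
  expect_false(isTRUE(all.equal(distorted$values, clean$values)))
  expect_identical(compensated$values, clean$values)
})

test_that("uncompensated OPD strictly degrades a focused reconstruction", {
  g <- desk_geom(64)
  z <- 700
  tg <- generate_targets(1, 64, "disks", seed = 21)[[1]]
  H <- transfer_function(g, z)
  worse <- logical(10)
  for (s in 1:10) {
    cm <- make_synthetic_core_map(128, facet_diameter = 85, seed = s)
    plan <- core_render_plan(cm, g)
    U <- backpropagate(tg, z, geom = g, H = H)$values
    holo <- sample_core_phases(Arg(U), cm, g, plan = plan)
    withr::with_seed(100 + s, opd <- runif(128, 0, 2 * pi))
    cc_clean <- reconstruct_cc(holo, tg, cm, g, z, plan, H)
    cc_dist <- correlation_coefficient(
      reconstruct_intensity(mcf_transmit(holo, cm, g, opd = opd, plan = plan),
                            z, H = H), tg)
    worse[s] <- cc_dist < cc_clean
  }
  expect_true(all(worse))
})

test_that("core maps round-trip through JSON and CSV equivalently", {
  cm <- make_synthetic_core_map(25, facet_diameter = 60, seed = 11)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_core_map(cm, jp)
  write_core_map(cm, cp)
  from_json <- read_core_map(jp)
  from_csv <- read_core_map(cp, core_radius = cm$core_radius,
                            facet_diameter = cm$facet_diameter,
                            min_spacing = cm$min_spacing)
  expect_equal(unname(from_json$centers), unname(cm$centers))
  expect_equal(unname(from_csv$centers), unname(from_json$centers))
  expect_equal(from_json$core_radius, cm$core_radius)
  # header variants
  d <- utils::read.csv(cp)
  names(d) <- c("X_um", "Y_um")
  cp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, cp2, row.names = FALSE)
  expect_equal(unname(read_core_map(cp2, facet_diameter = 60)$centers),
               unname(cm$centers))
})

test_that("malformed core map files name the offending field", {
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(kind = "core_map", units = "um"), bad,
                       auto_unbox = TRUE)
  expect_error(read_core_map(bad), "core_radius")
  badcsv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1, b = 2), badcsv, row.names = FALSE)
  expect_error(read_core_map(badcsv), "columns named x and y")
})
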