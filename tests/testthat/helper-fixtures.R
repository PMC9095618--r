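# Shared fixtures: small geometries, fields and oracles used across tests.

desk_geom <- function(n = 32L, pitch = 2) field_geometry(n, n, pitch, pitch, 0.532)

# a field whose spectrum is confined to the band limit at distance z
inband_field <- function(geom, z, seed = 1) {
  withr::with_seed(seed, {
    U <- matrix(complex(real = rnorm(geom$nx * geom$ny),
                        imaginary = rnorm(geom$nx * geom$ny)),
                geom$ny, geom$nx)
  })
  H <- transfer_function(geom, z)
  complex_field(stats::fft(stats::fft(U) * (Mod(H) > 0), inverse = TRUE) /
                  length(U), geom)
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / max(sum(Mod(b)^2), .Machine$double.eps))
}

# direct angular-spectrum propagation: explicit double loop over frequency
# bins, no FFT anywhere. O(N^4); keep grids small.
propagate_loop_oracle <- function(field, z) {
  U <- field$values
  ny <- nrow(U); nx <- ncol(U)
  H <- transfer_function(field$geom, z)
  A <- matrix(0i, ny, nx)
  for (q in seq_len(ny)) for (p in seq_len(nx)) {
    s <- 0i
    for (m in seq_len(ny)) for (n2 in seq_len(nx))
      s <- s + U[m, n2] *
        exp(-2i * pi * ((q - 1) * (m - 1) / ny + (p - 1) * (n2 - 1) / nx))
    A[q, p] <- s
  }
  O <- matrix(0i, ny, nx)
  for (m in seq_len(ny)) for (n2 in seq_len(nx)) {
    s <- 0i
    for (q in seq_len(ny)) for (p in seq_len(nx))
      s <- s + H[q, p] * A[q, p] *
        exp(2i * pi * ((q - 1) * (m - 1) / ny + (p - 1) * (n2 - 1) / nx))
    O[m, n2] <- s / (nx * ny)
  }
  O
}

# independent direct evaluation of the correlation-coefficient formula,
# written without reusing any package code path
cc_direct <- function(X, Y) {
  X <- as.numeric(X); Y <- as.numeric(Y)
  n <- length(X)
  mx <- sum(X) / n; my <- sum(Y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (X[i] - mx) * (Y[i] - my)
    dx <- dx + (X[i] - mx)^2
    dy <- dy + (Y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# reconstruction of a core hologram through the shared forward model
reconstruct_cc <- function(holo, target, cm, geom, z = 700, plan = NULL,
                           H = NULL) {
  I <- reconstruct_intensity(render_core_field(holo, cm, geom, plan = plan),
                             z, H = H)
  correlation_coefficient(I, target)
}
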