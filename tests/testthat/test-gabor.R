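# Atom synthesis, inner products, optimal phase and the fast-path
# machinery of the core module.

test_that("synthesized atoms are unit-norm and phase-antisymmetric", {
  set.seed(101)
  for (i in 1:20) {
    g <- rand_gabor(512)
    v <- synthesize_gabor(g, 512)
    expect_lt(abs(sum(v^2) - 1), 1e-12)
    g2 <- gabor_params(g$u, g$omega, g$s, g$phi + pi)
    expect_lt(max(abs(synthesize_gabor(g2, 512) + v)), 1e-13)
  }
  # border-clipped atom is renormalized on the clipped support
  vb <- synthesize_gabor(gabor_params(3, 2.5, 40, 1), 256)
  expect_lt(abs(sum(vb^2) - 1), 1e-12)
  # at the Nyquist frequency the waveform alternates in sign
  vn <- synthesize_gabor(gabor_params(256, pi, 128, 0), 512)
  nz <- which(abs(vn) > 1e-6)
  expect_true(all(diff(sign(vn[nz])) %in% c(-2, 2)))
  expect_lt(abs(sum(vn^2) - 1), 1e-12)
})

test_that("recurrence-generated tables match direct evaluation over 4096 samples", {
  g <- gabor_params(2048.3, pi / 3, 500, 0.7)
  rng <- gaborpursuit:::.support_range(g$u, g$s, 4096)
  tb <- gaborpursuit:::.gabor_tables(g$u, g$omega, g$s, rng[1], rng[2], g$phi)
  tau <- (rng[1]:rng[2]) - g$u
  expect_lt(max(abs(tb$cosv - cos(g$omega * tau + g$phi))), 1e-9)
  expect_lt(max(abs(tb$sinv - sin(g$omega * tau + g$phi))), 1e-9)
  expect_lt(max(abs(tb$env - exp(-pi * (tau / g$s)^2))), 1e-9)
})

test_that("invalid and degenerate atoms are rejected", {
  expect_error(gabor_params(0, 0, 10), "omega")
  expect_error(gabor_params(0, 3.5, 10), "omega")
  expect_error(gabor_params(0, 1, -1), "scale")
  expect_error(gabor_params(NaN, 1, 1), "finite")
  # envelope underflows everywhere on the epoch
  expect_error(synthesize_gabor(gabor_params(-100, 1, 0.5), 64),
               "degenerate")
})

test_that("product constants follow the closed forms", {
  g <- function(u, s) gabor_params(u, 1, s)
  pc <- product_constants(g(0, 8), g(0, 8))
  expect_equal(pc$A, 2 * pi / 64)
  expect_equal(pc$B, 0)
  expect_equal(pc$C, 0)
  pc <- product_constants(g(-5, 10), g(5, 10))   # position case, du = 10
  expect_equal(pc$C, -pi * 100 / (2 * 100))
  expect_equal(pc$B, 0)
  pc <- product_constants(g(7, 3), g(7, 41))
  expect_equal(pc$C, 0)
  # B always lies between the two centers, A positive, C nonpositive
  set.seed(7)
  for (i in 1:20) {
    a <- rand_gabor(1024); b <- rand_gabor(1024)
    pc <- product_constants(a, b)
    expect_gt(pc$A, 0)
    expect_lte(pc$C, 0)
    expect_true(pc$B >= min(a$u, b$u) - 1e-9 && pc$B <= max(a$u, b$u) + 1e-9)
  }
})

test_that("analytic product: self-normalization, symmetry and the quadrature oracle", {
  set.seed(11)
  for (i in 1:10) {
    g <- rand_gabor(1024, s_range = c(8, 128), w_range = c(0.2, 2.9))
    expect_lt(abs(analytic_gabor_product(g, g) - 1), 1e-6)
  }
  for (i in 1:50) {
    a <- rand_gabor(1024); b <- rand_gabor(1024)
    expect_identical(analytic_gabor_product(a, b),
                     analytic_gabor_product(b, a))
  }
  for (i in 1:100) {
    a <- rand_gabor(1024, s_range = c(8, 96), w_range = c(0.2, 2.9),
                    u_range = c(300, 700))
    b <- gabor_params(a$u + stats::runif(1, -80, 80),
                      stats::runif(1, 0.2, 2.9),
                      stats::runif(1, 8, 96), stats::runif(1, 0, 2 * pi))
    expect_lt(abs(analytic_gabor_product(a, b) - quad_gabor_product(a, b)),
              1e-8)
  }
})

test_that("discrete product matches the analytic formula in the well-sampled regime", {
  expect_error(discrete_product(1:3, 1:4), "length")
  v <- synthesize_gabor(gabor_params(100, 1, 16), 256)
  expect_equal(discrete_product(v, v), 1, tolerance = 1e-12)
  d1 <- numeric(64); d1[10] <- 1
  d2 <- numeric(64); d2[40] <- 1
  expect_identical(discrete_product(d1, d2), 0)
  set.seed(13)
  for (i in 1:30) {
    a <- gabor_params(stats::runif(1, 300, 700), stats::runif(1, 0.3, 2.7),
                      stats::runif(1, 16, 80), stats::runif(1, 0, 2 * pi))
    b <- gabor_params(a$u + stats::runif(1, -40, 40),
                      stats::runif(1, 0.3, 2.7),
                      stats::runif(1, 16, 80), stats::runif(1, 0, 2 * pi))
    expect_lt(abs(discrete_product(synthesize_gabor(a, 1024),
                                   synthesize_gabor(b, 1024)) -
                    analytic_gabor_product(a, b)), 1e-4)
  }
})

test_that("optimal phase equals brute-force grid maximization", {
  set.seed(17)
  n <- 512
  for (i in 1:30) {
    x <- stats::rnorm(n)
    u <- stats::runif(1, 50, n - 50)
    w <- stats::runif(1, 0.1, 3.0)
    s <- stats::runif(1, 5, 80)
    op <- optimal_phase(x, u, w, s)
    ps <- phase_split(x, u, w, s)
    brute <- phase_grid_max(ps$xc, ps$xs, ps$cc, ps$ss, ps$cs)
    expect_lt(abs(op$product_max - brute) / max(brute, 1e-12), 1e-8)
    # the returned atom realizes the reported product
    expect_lt(abs(sum(x * op$atom) - op$product_max), 1e-9)
  }
})

test_that("optimal phase: aligned input, known-phase recovery, minimum root", {
  n <- 512
  # signal equal to the zero-phase component C -> phi_max = 0
  ps0 <- phase_split(numeric(n), 200, 0.9, 30)
  op <- optimal_phase(ps0$C_vec, 200, 0.9, 30)
  expect_lt(min(op$phi_max, abs(op$phi_max - pi), abs(op$phi_max - 2 * pi)),
            1e-10)
  # planted phase 1.1 is recovered with the exhaustive-grid product
  x <- 3 * synthesize_gabor(gabor_params(200, 0.9, 30, 1.1), n)
  op <- optimal_phase(x, 200, 0.9, 30)
  expect_lt(abs(op$product_max - 3) / 3, 1e-10)
  expect_lt(abs(op$phi_max - 1.1), 1e-8)
  # substituting tan(phi) = <x,C>/<x,S> gives the zero of the product
  set.seed(19)
  x <- stats::rnorm(n)
  ps <- phase_split(x, 200, 0.9, 30)
  phi1 <- atan2(ps$xc, ps$xs)   # tan(phi1) = xc / xs
  num <- ps$xc * cos(phi1) - ps$xs * sin(phi1)
  expect_lt(abs(num), 1e-9 * sqrt(ps$xc^2 + ps$xs^2))
})

test_that("windowed-FFT products equal direct dot products", {
  set.seed(23)
  n <- 512
  x <- stats::rnorm(n)
  dw <- 2 * pi / 1024
  wf <- windowed_fft_products(x, 200, 64, dw)
  expect_length(wf$omega, 512)
  scale <- sqrt(sum(x^2))
  for (m in seq(1, 512, by = 7)) {
    ps <- phase_split(x, 200, wf$omega[m], 64)
    expect_lt(abs(ps$xc - wf$xc[m]), 1e-9 * scale)
    expect_lt(abs(ps$xs - wf$xs[m]), 1e-9 * scale)
  }
  # zero signal -> exactly zero products
  wf0 <- windowed_fft_products(numeric(n), 200, 64, dw)
  expect_identical(max(abs(wf0$xc), abs(wf0$xs)), 0)
  # pure cosine at a grid frequency, window at its antinode
  m0 <- 64L
  xc_sig <- cos(wf$omega[m0] * ((0:(n - 1)) - 128))
  wfc <- windowed_fft_products(xc_sig, 128, 24, dw)
  expect_equal(which.max(abs(wfc$xc)), m0)
  expect_lt(abs(wfc$xs[m0]), 1e-9 * sqrt(sum(xc_sig^2)))
  # incompatible grids are explicit errors, never silently regridded
  expect_error(windowed_fft_products(x, 200, 64, 0.01), "integer")
  expect_error(windowed_fft_products(x, 200, 64, 2 * pi / 64),
               "shorter than the window")
})

test_that("fast orthogonality screening is conservative", {
  g0 <- gabor_params(100, 1, 8)
  g1 <- gabor_params(100 + 40 * 8, 1, 8)
  expect_true(is_orthogonal_fast(g0, g1, 0.1))
  expect_identical(discrete_product(synthesize_gabor(g0, 1024),
                                    synthesize_gabor(g1, 1024)), 0)
  expect_false(is_orthogonal_fast(g0, g0, 0.1))
  set.seed(29)
  n_flagged <- 0L
  for (i in 1:200) {
    a <- rand_gabor(1024, s_range = c(4, 40))
    b <- rand_gabor(1024, s_range = c(4, 40))
    if (is_orthogonal_fast(a, b, 0.1, eta = 1e-12)) {
      n_flagged <- n_flagged + 1L
      expect_lt(abs(discrete_product(synthesize_gabor(a, 1024),
                                     synthesize_gabor(b, 1024))), 1e-12)
    }
  }
  expect_gt(n_flagged, 0L)   # the screen does fire on distant pairs
})

test_that("bounded-domain integration: truncation below eta, monotone in eta", {
  set.seed(31)
  kf <- function(g) 2^(3 / 4) / sqrt(g$s) /
    sqrt(1 + cos(2 * g$phi) * exp(-g$s^2 * g$omega^2 / (2 * pi)))
  for (i in 1:30) {
    a <- rand_gabor(1024, s_range = c(8, 60), u_range = c(300, 700))
    b <- gabor_params(a$u + stats::runif(1, -30, 30),
                      stats::runif(1, 0.1, 3), stats::runif(1, 8, 60),
                      stats::runif(1, 0, 2 * pi))
    if (is_orthogonal_fast(a, b, 0.1, eta = 1e-12)) next
    dl <- integration_halfwidth(a, b, 1e-12, 0.1)
    cst <- product_constants(a, b)
    f <- function(t)
      kf(a) * kf(b) *
      exp(-pi * ((t - a$u) / a$s)^2 - pi * ((t - b$u) / b$s)^2) *
      cos(a$omega * (t - a$u) + a$phi) * cos(b$omega * (t - b$u) + b$phi)
    full <- quad_gabor_product(a, b)
    trunc <- stats::integrate(f, cst$B - dl, cst$B + dl, rel.tol = 1e-12,
                              abs.tol = 1e-14, subdivisions = 4000L,
                              stop.on.error = FALSE)$value
    expect_lt(abs(full - trunc), 1e-12)
    expect_lt(integration_halfwidth(a, b, 1e-4, 0.1), dl)
  }
  # identical atoms: finite interval spanning several envelope sigmas
  g <- gabor_params(500, 1.5, 40)
  dl <- integration_halfwidth(g, g, 1e-12, 0.1)
  expect_true(is.finite(dl))
  expect_gte(2 * dl, 6 * g$s / sqrt(2 * pi))
  # orthogonal pairs signal that no interval is needed
  expect_error(integration_halfwidth(gabor_params(0, 1, 4),
                                     gabor_params(1000, 1, 4), 1e-12, 0.1),
               "no interval")
})
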