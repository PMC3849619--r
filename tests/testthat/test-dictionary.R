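# Metric, maximal products of adjacent atoms, and the optimal /
# stochastic dictionary construction.

test_that("d0 metric: identity, orthogonality, antipodal maximum, triangle axiom", {
  n <- 1024
  g <- gabor_params(300, 1.2, 24, 0.5)
  expect_equal(metric_d0(g, g, n), 0, tolerance = 1e-7)
  far <- gabor_params(900, 1.2, 24, 0.5)
  expect_equal(metric_d0(g, far, n), 1, tolerance = 1e-12)
  anti <- gabor_params(300, 1.2, 24, 0.5 + pi)
  expect_equal(metric_d0(g, anti, n), sqrt(2), tolerance = 1e-12)
  set.seed(37)
  for (i in 1:30) {
    a <- rand_gabor(n); b <- rand_gabor(n); c <- rand_gabor(n)
    expect_lte(metric_d0(a, c, n),
               metric_d0(a, b, n) + metric_d0(b, c, n) + 1e-12)
    expect_lte(metric_d0(a, b, n), sqrt(2) + 1e-12)
  }
})

test_that("class metric: identity, separation, and the 2-D phase brute force", {
  n <- 512
  c0 <- list(u = 200, omega = 1.1, s = 30)
  expect_equal(metric_d(c0, c0, n), 0, tolerance = 1e-7)
  # frequencies far apart at the same (s, u): numerically orthogonal classes
  expect_equal(metric_d(list(u = 200, omega = 0.5, s = 30),
                        list(u = 200, omega = 2.5, s = 30), n),
               1, tolerance = 1e-6)
  set.seed(41)
  for (i in 1:4) {
    a <- list(u = stats::runif(1, 150, 350), omega = stats::runif(1, 0.4, 2.6),
              s = stats::runif(1, 8, 40))
    b <- list(u = a$u + stats::runif(1, -6, 6),
              omega = a$omega + stats::runif(1, -0.1, 0.1),
              s = a$s * stats::runif(1, 0.85, 1.2))
    dm <- metric_d(a, b, n)
    # brute force over a phase grid, then local refinement
    prod_fn <- function(p) discrete_product(
      synthesize_gabor(gabor_params(a$u, a$omega, a$s, p[1]), n),
      synthesize_gabor(gabor_params(b$u, b$omega, b$s, p[2]), n))
    ph <- seq(0, 2 * pi, length.out = 61)[-61]
    grid <- outer(ph, ph, Vectorize(function(p, q) prod_fn(c(p, q))))
    i0 <- which(grid == max(grid), arr.ind = TRUE)[1, ]
    ref <- stats::optim(c(ph[i0[1]], ph[i0[2]]),
                        function(p) -prod_fn(p), method = "Nelder-Mead",
                        control = list(reltol = 1e-14))
    expect_lt(abs(dm - sqrt(max(0, 1 + ref$value))), 1e-6)
  }
})

test_that("maximal products of adjacent atoms: limits and Nyquist reductions", {
  # scale case
  expect_equal(max_product_scale(10, 1.3, 1), 1, tolerance = 1e-12)
  expect_equal(max_product_scale(10, pi, 1.2), sqrt(2 * 1.2 / (1.2^2 + 1)),
               tolerance = 1e-10)
  av <- seq(1.05, 3, length.out = 40)
  vals <- vapply(av, function(a) max_product_scale(10, pi, a), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(max_product_scale(10, 1, 0.9), "dilation")
  # frequency case
  expect_equal(max_product_freq(10, 2.0, 0), 1, tolerance = 1e-12)
  expect_equal(max_product_freq(10, pi, 0.05),
               exp(-0.05^2 * 100 / (8 * pi)), tolerance = 1e-6)
  expect_error(max_product_freq(10, 1, -0.1), "negative")
  # position case
  expect_equal(max_product_pos(10, 2.0, 0), 1, tolerance = 1e-12)
  expect_equal(max_product_pos(10, pi, 1.5),
               exp(-pi * 1.5^2 / (2 * 100)), tolerance = 1e-6)
  expect_gte(max_product_pos(10, 0.8, 2), exp(-pi * 4 / (2 * 100)) - 1e-12)
  expect_error(max_product_pos(10, 1, -1), "negative")
  # position case against the discrete 2-phase maximum at large scale
  dm <- metric_d(list(u = 250, omega = 1.4, s = 40),
                 list(u = 253, omega = 1.4, s = 40), 512)
  expect_lt(abs((1 - dm^2) - max_product_pos(40, 1.4, 3)), 1e-4)
})

test_that("dilation factor: closed form, root property, and metric closure", {
  expect_equal(dilation_factor(0.1), 1.22285, tolerance = 1e-5)
  expect_lt(dilation_factor(1e-4) - 1, 1e-3)
  expect_gt(dilation_factor(1e-4), 1)
  expect_error(dilation_factor(1.2), "epsilon")
  for (eps in c(0.05, 0.1, 0.2, 0.4)) {
    a <- dilation_factor(eps)
    expect_lt(abs((1 - eps^2)^2 * (a^2 + 1) - 2 * a), 1e-12)
    # adjacent scales at the Nyquist frequency sit at distance epsilon
    expect_lt(abs(sqrt(1 - max_product_scale(20, pi, a)) - eps), 1e-6)
  }
})

test_that("per-scale steps: printed values, s-invariance, metric closure", {
  st <- steps_for_scale(10, 0.1)
  expect_equal(st$delta_omega * 10, 0.502586, tolerance = 1e-5)
  expect_equal(st$delta_u / 10, 0.079989, tolerance = 1e-5)
  p1 <- steps_for_scale(5, 0.17); p2 <- steps_for_scale(200, 0.17)
  expect_equal(p1$delta_omega * p1$delta_u, p2$delta_omega * p2$delta_u,
               tolerance = 1e-12)
  for (eps in c(0.05, 0.2)) {
    st <- steps_for_scale(20, eps)
    expect_lt(abs(sqrt(1 - max_product_freq(20, pi, st$delta_omega)) - eps),
              1e-6)
    expect_lt(abs(sqrt(1 - max_product_pos(20, pi, st$delta_u)) - eps),
              1e-6)
  }
})

test_that("layout: exact scale count, conservative step snapping, epsilon monotonicity", {
  for (eps in c(0.05, 0.1, 0.2)) {
    lay <- dictionary_layout(dictionary_config(eps, 512,
                                               include_families = "gabor"))
    a <- dilation_factor(eps)
    expect_identical(lay$N_s, floor(log(512) / log(a)))
    expect_true(all(lay$scales$delta_omega <= lay$scales$delta_omega_nominal + 1e-12))
    expect_true(all(lay$scales$delta_omega > 0 & lay$scales$delta_u > 0))
  }
  counts <- vapply(c(0.05, 0.1, 0.2), function(eps)
    dictionary_layout(dictionary_config(eps, 512,
                                        include_families = "gabor"))$counts[["gabor"]],
    0)
  expect_true(all(diff(counts) < 0))
  expect_warning(dictionary_config(0.6, 256), "0.5")
})

test_that("epsilon-audit: adjacent classes stay within the metric bound", {
  eps <- 0.1
  lay <- dictionary_layout(dictionary_config(eps, 512,
                                             include_families = "gabor"))
  a <- lay$a
  set.seed(43)
  for (i in 1:40) {
    r <- sample(nrow(lay$scales), 1)
    s <- lay$scales$s[r]
    w <- stats::runif(1, 0.9 * pi, pi)
    u <- stats::runif(1, 100, 400)
    dsc <- metric_d(list(u = u, omega = w, s = s),
                    list(u = u, omega = w, s = a * s), 512)
    wf <- min(w + lay$scales$delta_omega[r], pi)
    dfr <- metric_d(list(u = u, omega = w, s = s),
                    list(u = u, omega = wf, s = s), 512)
    dpo <- metric_d(list(u = u, omega = w, s = s),
                    list(u = u + lay$scales$delta_u[r], omega = w, s = s),
                    512)
    expect_lte(dsc, eps + 1e-6)
    expect_lte(dfr, eps + 1e-6)
    expect_lte(dpo, eps + 1e-6)
  }
})

test_that("built dictionary Gram tables match direct phase splits", {
  d <- dict_256()
  n <- d$n
  set.seed(47)
  for (i in 1:12) {
    r <- sample(length(d$scales), 1)
    sc <- d$scales[[r]]
    mi <- sample(sc$n_omega, 1); ci <- sample(length(sc$u), 1)
    ps <- phase_split(numeric(n), sc$u[ci], sc$omega[mi], sc$s)
    expect_lt(abs(ps$cc - sc$cc[mi, ci]), 1e-9)
    expect_lt(abs(ps$ss - sc$ss[mi, ci]), 1e-9)
    expect_lt(abs(ps$cs - sc$cs[mi, ci]), 1e-9)
  }
})

test_that("stochastic subsampling is reproducible and unbiased", {
  cfg <- function(seed, pct = 60)
    dictionary_config(0.35, 128, dict_type = "stochastic",
                      percentage_chosen = pct, seed = seed,
                      include_families = "gabor")
  d1 <- build_dictionary(cfg(5)); d2 <- build_dictionary(cfg(5))
  masks <- function(d) lapply(d$scales, `[[`, "mask")
  expect_identical(masks(d1), masks(d2))
  # percentage_chosen = 100 is the fixed dictionary atom-for-atom
  d100 <- build_dictionary(cfg(5, pct = 100))
  dfix <- build_dictionary(dictionary_config(0.35, 128,
                                             include_families = "gabor"))
  x <- stats::rnorm(128)
  b1 <- mp_decompose(x, d100, stopping_rule(5, 100))
  b2 <- mp_decompose(x, dfix, stopping_rule(5, 100))
  expect_identical(b1$params[, -1], b2$params[, -1])
  expect_identical(b1$weights, b2$weights)
  # removed sets from different seeds overlap as hypergeometric draws
  rm_set <- function(d) which(!unlist(masks(d)))
  r1 <- rm_set(d1); r2 <- rm_set(build_dictionary(cfg(6)))
  total <- sum(vapply(d1$scales, function(s) length(s$mask), 0L))
  m <- length(r1)
  mu <- m^2 / total
  sd_h <- sqrt(m * (m / total) * (1 - m / total) * (total - m) / (total - 1))
  expect_lt(abs(length(intersect(r1, r2)) - mu), 3 * sd_h)
  # full removal is rejected
  expect_error(build_dictionary(cfg(1, pct = 1e-6)), "empty")
})
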