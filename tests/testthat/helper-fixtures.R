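# Shared fixtures, built lazily and cached for the whole run.

.fx <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

dict_256 <- function() fixture("dict_256", function()
  build_dictionary(dictionary_config(0.2, 256)))

dict_512 <- function() fixture("dict_512", function()
  build_dictionary(dictionary_config(0.2, 512)))

dict_256_gabor <- function() fixture("dict_256_gabor", function()
  build_dictionary(dictionary_config(0.2, 256, include_families = "gabor")))

# dense recovery dictionary (the parameter-recovery study condition)
dict_256_eps05 <- function() fixture("dict_256_eps05", function()
  build_dictionary(dictionary_config(0.05, 256, include_families = "gabor")))

# sleep-like preset at 20 dB SNR (the recovery fixture)
sleep_sim_20db <- function() fixture("sleep20", function() {
  spec <- sleep_preset_spec()
  spec$noise_sigma <- noise_sigma_for_snr(spec, 20)
  generate_synthetic(spec)
})

rand_gabor <- function(n, s_range = c(4, n / 4), w_range = c(0.05, pi),
                       u_range = c(0, n - 1)) {
  gabor_params(stats::runif(1, u_range[1], u_range[2]),
               stats::runif(1, w_range[1], w_range[2]),
               stats::runif(1, s_range[1], s_range[2]),
               stats::runif(1, 0, 2 * pi))
}

# independent continuous-product oracle: adaptive quadrature of the
# continuous integrand with the analytic normalization written out
quad_gabor_product <- function(g0, g1) {
  kf <- function(g) 2^(3 / 4) / sqrt(g$s) /
    sqrt(1 + cos(2 * g$phi) * exp(-g$s^2 * g$omega^2 / (2 * pi)))
  f <- function(t)
    kf(g0) * kf(g1) *
    exp(-pi * ((t - g0$u) / g0$s)^2 - pi * ((t - g1$u) / g1$s)^2) *
    cos(g0$omega * (t - g0$u) + g0$phi) *
    cos(g1$omega * (t - g1$u) + g1$phi)
  lo <- min(g0$u - 8 * g0$s, g1$u - 8 * g1$s)
  hi <- max(g0$u + 8 * g0$s, g1$u + 8 * g1$s)
  stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-13,
                   subdivisions = 4000L)$value
}

# brute-force maximal product over a single phase from the raw scalars
phase_grid_max <- function(xc, xs, cc, ss, cs, n_grid = 1e5) {
  phi <- seq(0, 2 * pi, length.out = n_grid)
  den2 <- cc * cos(phi)^2 - 2 * cs * sin(phi) * cos(phi) + ss * sin(phi)^2
  p <- (xc * cos(phi) - xs * sin(phi)) / sqrt(pmax(den2, 1e-300))
  max(abs(p))
}
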