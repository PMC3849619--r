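# Multivariate pursuit: variant catalog, reductions, selection rules,
# ground-truth recovery.

test_that("variant validation follows the catalog", {
  expect_identical(mmp_variant("MMP23"), "mmp23")
  expect_error(mmp_variant("mmp13"), "not implemented in reference engine")
  expect_error(mmp_variant("mmp31"), "not implemented in reference engine")
  expect_error(mmp_variant("mmp99"), "unknown")
})

test_that("every variant reduces to monochannel MP on 1x1 data", {
  set.seed(73)
  x <- stats::rnorm(256)
  d <- dict_256()
  mpd <- mp_decompose(x, d, stopping_rule(5, 100))
  for (v in c("mmp1", "mmp2", "mmp3", "mmp11", "mmp12", "mmp21",
              "mmp23", "mmp32", "mmp33")) {
    md <- mmp_decompose(trial_matrix(x), d, stopping_rule(5, 100),
                        variant = v)
    expect_identical(md$params$family, mpd$params$family)
    expect_equal(as.matrix(md$params[, 3:5]),
                 as.matrix(mpd$params[, 3:5]))
    expect_lt(max(abs(abs(md$weights) - abs(mpd$weights))), 1e-8)
  }
})

test_that("identical channels reproduce the monochannel atom sequence", {
  set.seed(79)
  x <- stats::rnorm(256)
  d <- dict_256()
  mpd <- mp_decompose(x, d, stopping_rule(5, 100))
  for (v in c("mmp1", "mmp2", "mmp3")) {
    md <- mmp_decompose(trial_matrix(rbind(x, x, x)), d,
                        stopping_rule(5, 100), variant = v)
    expect_identical(md$params$family, mpd$params$family)
    expect_equal(as.matrix(md$params[, 3:5]), as.matrix(mpd$params[, 3:5]))
    # equal weights across channels
    expect_lt(max(abs(md$weights[, 1, 1] - md$weights[, 2, 1]),
                  abs(md$weights[, 1, 1] - md$weights[, 3, 1])), 1e-9)
  }
})

test_that("MMP1 recovers a shared atom with per-channel amplitudes", {
  set.seed(83)
  n <- 256
  d <- dict_256()
  g <- gabor_params(128, 1.2, 24, 0.4)
  atom <- synthesize_gabor(g, n)
  amps <- c(10, 5, -8)
  X <- t(vapply(amps, function(a) a * atom + stats::rnorm(n, sd = 0.0625),
                numeric(n)))
  m1 <- mmp_decompose(trial_matrix(X), d, stopping_rule(1, 100),
                      variant = "mmp1")
  p <- m1$params[1, ]
  sc <- d$scales[[which(vapply(d$scales, `[[`, 0, "s") == p$s)]]
  expect_lte(abs(p$u - g$u), sc$delta_u + 1e-9)
  expect_lte(abs(p$omega - g$omega), sc$delta_omega + 1e-9)
  expect_lte(max(p$s / g$s, g$s / p$s), d$a + 1e-9)
  expect_lt(max(abs(m1$weights[1, , 1] - amps) / abs(amps)), 0.05)
  # single common phase across channels
  expect_identical(max(abs(diff(m1$phases[1, , 1]))), 0)
})

test_that("MMP2 selects on the channel average and warns on average-referenced data", {
  set.seed(89)
  n <- 256
  d <- dict_256()
  X <- rbind(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n)) +
    5 * matrix(rep(synthesize_gabor(gabor_params(100, 1, 30), n), 3),
               3, byrow = TRUE)
  m2 <- mmp_decompose(trial_matrix(X), d, stopping_rule(4, 100),
                      variant = "mmp2")
  mavg <- mp_decompose(colMeans(X), d, stopping_rule(4, 100))
  expect_identical(m2$params$family, mavg$params$family)
  expect_equal(as.matrix(m2$params[, 3:5]), as.matrix(mavg$params[, 3:5]))
  # channel-mean weight equals the average-signal weight (linearity)
  expect_lt(max(abs(rowMeans(m2$weights[, , 1]) - mavg$weights[, 1, 1])),
            1e-9)
  # exactly opposite channels: average carries nothing of the atom
  g <- synthesize_gabor(gabor_params(128, 1.4, 20), n)
  set.seed(90)
  Xo <- rbind(8 * g + stats::rnorm(n, sd = 0.5),
              -8 * g + stats::rnorm(n, sd = 0.5))
  e2 <- explained_energy(mmp_decompose(trial_matrix(Xo), d,
                                       stopping_rule(5, 100),
                                       variant = "mmp2"))
  e1 <- explained_energy(mmp_decompose(trial_matrix(Xo), d,
                                       stopping_rule(5, 100),
                                       variant = "mmp1"))
  expect_lt(e2, e1)
  # strictly zero average is a hard error
  Xz <- rbind(g, -g)
  expect_error(mmp_decompose(trial_matrix(Xz), d, stopping_rule(2, 100),
                             variant = "mmp2"),
               "average")
})

test_that("MMP3: free phases recovered and squared-sum objective dominates MMP1", {
  set.seed(97)
  n <- 256
  # phase recovery needs a dense grid: a coarse (u, omega) cell offsets
  # both recovered phases by the same grid-mismatch term
  dd <- dict_256_eps05()
  a1 <- synthesize_gabor(gabor_params(128, 1.2, 24, 0.3), n)
  a2 <- synthesize_gabor(gabor_params(128, 1.2, 24, 2.1), n)
  # 20 dB SNR per channel
  X <- rbind(10 * a1 + stats::rnorm(n, sd = 0.0625),
             10 * a2 + stats::rnorm(n, sd = 0.0625))
  m3 <- mmp_decompose(trial_matrix(X), dd, stopping_rule(1, 100),
                      variant = "mmp3")
  # the stored phase is referenced to the selected atom center; compare
  # carrier phases at the true center (invariant to sub-step u offsets)
  p <- m3$params[1, ]
  at_center <- (m3$phases[1, , 1] + p$omega * (128 - p$u)) %% (2 * pi)
  wrap <- function(x) abs(((x + pi) %% (2 * pi)) - pi)
  expect_lt(wrap(at_center[1] - 0.3), 0.05)
  expect_lt(wrap(at_center[2] - 2.1), 0.05)
  expect_lt(wrap(diff(m3$phases[1, , 1]) - 1.8), 0.05)
  d <- dict_256()
  # free phases can only increase the squared-sum objective relative to
  # a common phase, from the same residual state
  step_sq <- function(state, v)
    sum(mmp_decompose(trial_matrix(state), d, stopping_rule(1, 100),
                      variant = v)$weights[1, , 1]^2)
  state <- X
  for (q in 1:3) {
    expect_gte(step_sq(state, "mmp3"), step_sq(state, "mmp1") - 1e-9)
    state <- mmp_decompose(trial_matrix(state), d, stopping_rule(1, 100),
                           variant = "mmp3")$residuals[, 1, ]
  }
})

test_that("trial-axis compositions collapse and order correctly", {
  set.seed(101)
  n <- 256
  d <- dict_256()
  # all trials identical: MMP12 is MMP11 on one trial per channel
  X <- rbind(stats::rnorm(n), stats::rnorm(n))
  arr <- array(0, c(2, 3, n))
  for (k in 1:3) arr[, k, ] <- X
  m12 <- mmp_decompose(trial_matrix(arr), d, stopping_rule(4, 100),
                       variant = "mmp12")
  m11_1 <- mmp_decompose(trial_matrix(X), d, stopping_rule(4, 100),
                         variant = "mmp11")
  expect_identical(m12$params$family, m11_1$params$family)
  expect_equal(as.matrix(m12$params[, 3:5]),
               as.matrix(m11_1$params[, 3:5]))
  expect_equal(m12$weights[, , 1], m11_1$weights[, , 1], tolerance = 1e-9)
  # free phase can only help the squared-sum objective: mmp33 >= mmp11
  arr2 <- array(0, c(2, 2, n))
  set.seed(102)
  for (i in 1:2) for (k in 1:2)
    arr2[i, k, ] <- 8 * synthesize_gabor(
      gabor_params(128, 1.2, 24, 0.3 + 0.6 * (i + k)), n) +
      stats::rnorm(n, sd = 0.3)
  e33 <- explained_energy(mmp_decompose(trial_matrix(arr2), d,
                                        stopping_rule(5, 100),
                                        variant = "mmp33"))
  e11 <- explained_energy(mmp_decompose(trial_matrix(arr2), d,
                                        stopping_rule(5, 100),
                                        variant = "mmp11"))
  expect_gte(e33, e11)
})

test_that("per-channel energy conservation holds in every variant", {
  set.seed(103)
  n <- 256
  d <- dict_256()
  arr <- array(stats::rnorm(2 * 2 * n), c(2, 2, n))
  arr[1, 1, ] <- arr[1, 1, ] + 6 * synthesize_gabor(gabor_params(90, 0.8, 30), n)
  for (v in c("mmp11", "mmp23", "mmp32", "mmp33")) {
    md <- mmp_decompose(trial_matrix(arr), d, stopping_rule(4, 100),
                        variant = v)
    for (i in 1:2) for (k in 1:2) {
      e0 <- sum(arr[i, k, ]^2)
      er <- sum(md$residuals[i, k, ]^2)
      expect_lt(abs(e0 - er - sum(md$weights[, i, k]^2)) / e0, 1e-9)
    }
    expect_true(all(diff(md$residual_energy) <= 0))
  }
})

test_that("decompositions are deterministic for fixed dictionary, seed and data", {
  set.seed(107)
  arr <- array(stats::rnorm(2 * 2 * 128), c(2, 2, 128))
  cfg <- dictionary_config(0.3, 128, dict_type = "stochastic",
                           percentage_chosen = 80, seed = 9,
                           include_families = "gabor")
  d1 <- build_dictionary(cfg); d2 <- build_dictionary(cfg)
  b1 <- mmp_decompose(trial_matrix(arr), d1, stopping_rule(5, 100),
                      variant = "mmp33")
  b2 <- mmp_decompose(trial_matrix(arr), d2, stopping_rule(5, 100),
                      variant = "mmp33")
  expect_identical(b1$params, b2$params)
  expect_identical(b1$weights, b2$weights)
  expect_identical(b1$phases, b2$phases)
})
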