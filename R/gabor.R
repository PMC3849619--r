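# Gabor atoms: parameterization, discrete synthesis, inner products
# (analytic and numerical), optimal phase, and the fast-computation
# machinery (recursive trig/exp tables, windowed-FFT products,
# orthogonality screening, bounded-domain integration).

# Envelope support cutoff: samples are generated only where the Gaussian
# envelope exp(-pi (tau/s)^2) exceeds 1e-16 of its peak, i.e. for
# |tau| <= s * sqrt(16 log(10) / pi).
.support_factor <- sqrt(16 * log(10) / pi)

#' Gabor atom parameters
#'
#' A real Gabor function is a cosine with a Gaussian envelope,
#' \deqn{g(t) = K \exp(-\pi ((t-u)/s)^2) \cos(\omega (t-u) + \phi),}
#' parameterized by time center \code{u} (samples), angular frequency
#' \code{omega} (radians/sample, in (0, pi]), scale \code{s} (samples,
#' the width of the envelope) and phase \code{phi} (radians, stored in
#' [0, 2*pi)).  \code{K} normalizes the atom to unit norm.
#'
#' @param u time center in samples (0-based sample coordinates).
#' @param omega angular frequency in radians per sample, in (0, pi].
#' @param s scale (envelope width) in samples, positive.
#' @param phi phase in radians; reduced modulo 2*pi.
#' @return An object of class \code{"gabor_params"}: a list with fields
#'   \code{u}, \code{omega}, \code{s}, \code{phi}.
#' @examples
#' g <- gabor_params(u = 128, omega = pi / 4, s = 32)
#' v <- synthesize_gabor(g, 256)
#' sum(v^2)  # 1 by construction
#' @export
gabor_params <- function(u, omega, s, phi = 0) {
  stopifnot(is.numeric(u), is.numeric(omega), is.numeric(s), is.numeric(phi),
            length(u) == 1L, length(omega) == 1L, length(s) == 1L,
            length(phi) == 1L)
  if (!all(is.finite(c(u, omega, s, phi))))
    stop("gabor_params: all parameters must be finite")
  if (omega <= 0 || omega > pi)
    stop("gabor_params: omega must lie in (0, pi] (Nyquist bound)")
  if (s <= 0)
    stop("gabor_params: scale s must be positive")
  phi <- phi %% (2 * pi)
  structure(list(u = u, omega = omega, s = s, phi = phi),
            class = "gabor_params")
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf("Gabor atom: u = %.6g samples, omega = %.6g rad/sample, s = %.6g samples, phi = %.6g rad\n",
              x$u, x$omega, x$s, x$phi))
  invisible(x)
}

# Integer sample window [lo, hi] (0-based) on which the envelope of an
# atom centered at u with scale s exceeds the support cutoff, clipped to
# the epoch [0, n-1].  Returns NULL when empty.
.support_range <- function(u, s, n) {
  h <- s * .support_factor
  lo <- max(0, ceiling(u - h))
  hi <- min(n - 1, floor(u + h))
  if (lo > hi) return(NULL)
  c(lo, hi)
}

# Recursive sin/cos and exp tables.  Computes cos(omega*tau + phi),
# sin(omega*tau + phi) and exp(-alpha*tau^2) for tau = (t - u),
# t = t_lo..t_hi, using one direct transcendental call per quantity per
# direction and recurrences elsewhere.  The recurrences run center-out
# (from the sample nearest u towards both edges), which keeps the
# exponent recursion strictly decreasing (no overflow) and exploits the
# even/odd symmetry of the envelope and of sine/cosine about u.
.gabor_tables <- function(u, omega, s, t_lo, t_hi, phi = 0) {
  n <- t_hi - t_lo + 1L
  alpha <- pi / s^2
  tc <- min(max(round(u), t_lo), t_hi)      # start near the center
  ic <- tc - t_lo + 1L
  tau_c <- tc - u
  # trig rotation recurrence z_{k+1} = z_k * e^{i omega}, run as a
  # cumulative product; one direct sin/cos evaluation per direction.
  # exp recurrence e_{k+1} = e_k * q_k * e^{-alpha}, q_{k+1} = q_k *
  # e^{-2 alpha}, likewise cumulative.  Running center-out keeps every
  # factor <= 1 (no overflow) and exploits the symmetry of the
  # envelope about u.
  z0 <- complex(modulus = 1, argument = omega * tau_c + phi)
  e0 <- exp(-alpha * tau_c^2)
  right <- function(m) {                     # tau_c .. tau_c + m - 1
    if (m == 1L) return(list(z = z0, e = e0))
    rot <- cumprod(c(z0, rep(complex(modulus = 1, argument = omega),
                             m - 1L)))
    fac <- exp(-alpha * (2 * tau_c + 1)) *
      cumprod(c(1, rep(exp(-2 * alpha), m - 2L)))
    list(z = rot, e = e0 * c(1, cumprod(fac)))
  }
  left <- function(m) {                      # tau_c - 1 .. tau_c - m (outward)
    rot <- cumprod(c(z0 * complex(modulus = 1, argument = -omega),
                     rep(complex(modulus = 1, argument = -omega),
                         m - 1L)))
    fac <- exp(alpha * (2 * tau_c - 1)) *
      cumprod(c(1, rep(exp(-2 * alpha), m - 1L)))
    e <- e0 * cumprod(fac[seq_len(m)])
    list(z = rot, e = e)
  }
  r <- right(n - ic + 1L)
  if (ic > 1L) {
    l <- left(ic - 1L)
    z <- c(rev(l$z), r$z)
    e <- c(rev(l$e), r$e)
  } else { z <- r$z; e <- r$e }
  list(cosv = Re(z), sinv = Im(z), env = e)
}

#' Synthesize the discrete waveform of a Gabor atom
#'
#' Generates the envelope-times-cosine sample vector of a Gabor atom on
#' the integer grid t = 0..n_samples-1 and normalizes it to unit
#' Euclidean norm computed on the discrete samples (atoms clipped by the
#' epoch border are renormalized on the clipped support).  Samples where
#' the envelope falls below 1e-16 of its peak are exact zeros.
#' Internally the cosine and exponential values are filled in by
#' one-step recurrences seeded by a single direct call each.
#'
#' @param params a \code{\link{gabor_params}} object.
#' @param n_samples epoch length (>= 2).
#' @return Numeric vector of length \code{n_samples} with unit norm.
#' @export
synthesize_gabor <- function(params, n_samples) {
  stopifnot(inherits(params, "gabor_params"),
            is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 2)
  n <- as.integer(n_samples)
  rng <- .support_range(params$u, params$s, n)
  if (is.null(rng))
    stop("degenerate atom: envelope underflows everywhere on the epoch")
  tb <- .gabor_tables(params$u, params$omega, params$s, rng[1], rng[2],
                      phi = params$phi)
  w <- tb$env * tb$cosv
  nrm <- sqrt(sum(w^2))
  if (nrm == 0)
    stop("degenerate atom: zero norm on the discrete grid")
  out <- numeric(n)
  out[(rng[1]:rng[2]) + 1L] <- w / nrm
  out
}

#' Constants of the analytic Gabor product
#'
#' For two Gabor atoms with centers \code{u0}, \code{u1} and scales
#' \code{s0}, \code{s1}, the Gaussian part of their continuous product
#' collapses to \code{exp(-A (t-B)^2 + C)} with
#' \deqn{A = \pi (1/s_0^2 + 1/s_1^2),\quad
#'       B = (\pi/A) (u_0/s_0^2 + u_1/s_1^2),\quad
#'       C = -\pi (u_0-u_1)^2 / (s_0^2 + s_1^2).}
#'
#' @param g0,g1 \code{\link{gabor_params}} objects.
#' @return List with components \code{A} (1/samples^2), \code{B}
#'   (samples; lies between the two centers) and \code{C}
#'   (dimensionless, <= 0).
#' @export
product_constants <- function(g0, g1) {
  stopifnot(inherits(g0, "gabor_params"), inherits(g1, "gabor_params"))
  A <- pi * (1 / g0$s^2 + 1 / g1$s^2)
  B <- (pi / A) * (g0$u / g0$s^2 + g1$u / g1$s^2)
  C <- -pi * (g0$u - g1$u)^2 / (g0$s^2 + g1$s^2)
  list(A = A, B = B, C = C)
}

# Continuous-time normalization factor K(gamma): the atom
# K exp(-pi (t/s)^2) cos(omega t + phi) has unit L2 norm on the real line.
.k_continuous <- function(omega, s, phi) {
  2^(3 / 4) / sqrt(s) / sqrt(1 + cos(2 * phi) * exp(-s^2 * omega^2 / (2 * pi)))
}

#' Closed-form continuous inner product of two Gabor atoms
#'
#' Evaluates the analytic formula for the continuous-time inner product
#' of two real Gabor functions normalized on the real line: the sum of
#' the (omega0+omega1) and (omega0-omega1) cosine terms weighted by
#' Gaussian factors and scaled by \code{K0 K1 sqrt(pi/(4A)) exp(C)}.
#' The continuous value approximates, but does not exactly equal, the
#' dot product of the discretized unit-norm atoms; the discrete product
#' (\code{\link{discrete_product}}) is authoritative in the engine, and
#' this formula is used for fast approximate screening.
#'
#' @param g0,g1 \code{\link{gabor_params}} objects.
#' @return The continuous inner product (a real number).
#' @export
analytic_gabor_product <- function(g0, g1) {
  cst <- product_constants(g0, g1)
  k0 <- .k_continuous(g0$omega, g0$s, g0$phi)
  k1 <- .k_continuous(g1$omega, g1$s, g1$phi)
  wp <- g0$omega + g1$omega
  wm <- g0$omega - g1$omega
  term_p <- cos(wp * cst$B + (g0$phi + g1$phi) -
                  (g0$omega * g0$u + g1$omega * g1$u)) * exp(-wp^2 / (4 * cst$A))
  term_m <- cos(wm * cst$B + (g0$phi - g1$phi) -
                  (g0$omega * g0$u - g1$omega * g1$u)) * exp(-wm^2 / (4 * cst$A))
  val <- k0 * k1 * sqrt(pi / (4 * cst$A)) * exp(cst$C) * (term_p + term_m)
  if (!is.finite(val)) val <- 0   # deep underflow of the Gaussian factors
  val
}

#' Euclidean dot product of two sample vectors
#'
#' The plain discrete inner product; this is the authoritative product
#' used by the pursuit engines.
#'
#' @param v0,v1 numeric vectors of equal length.
#' @return \code{sum(v0 * v1)}.
#' @export
discrete_product <- function(v0, v1) {
  if (length(v0) != length(v1))
    stop("discrete_product: length mismatch")
  sum(v0 * v1)
}

#' Phase decomposition of a Gabor atom against a signal
#'
#' Splits the atom into its zero-phase cosine component
#' \code{C = env * cos(omega (t-u))} and quadrature sine component
#' \code{S = env * sin(omega (t-u))} on the discrete support, and
#' returns the products needed for closed-form phase optimization:
#' \code{xc = <x, C>}, \code{xs = <x, S>}, and the discrete Gram entries
#' \code{cc = <C, C>}, \code{ss = <S, S>} and \code{cs = <C, S>}.  In
#' discrete time \code{<C, S>} is only approximately zero, so it is
#' carried explicitly.
#'
#' @param signal numeric sample vector (the epoch).
#' @param u,omega,s atom parameters (see \code{\link{gabor_params}}).
#' @return List with \code{C_vec}, \code{S_vec} (full-length vectors),
#'   \code{xc}, \code{xs}, \code{cc}, \code{ss}, \code{cs}, and the
#'   support \code{range} (0-based, inclusive).
#' @export
phase_split <- function(signal, u, omega, s) {
  n <- length(signal)
  stopifnot(n >= 2)
  rng <- .support_range(u, s, n)
  if (is.null(rng))
    stop("degenerate atom: envelope underflows everywhere on the epoch")
  tb <- .gabor_tables(u, omega, s, rng[1], rng[2])
  cvec <- tb$env * tb$cosv
  svec <- tb$env * tb$sinv
  idx <- (rng[1]:rng[2]) + 1L
  x <- signal[idx]
  Cf <- numeric(n); Sf <- numeric(n)
  Cf[idx] <- cvec; Sf[idx] <- svec
  list(C_vec = Cf, S_vec = Sf,
       xc = sum(x * cvec), xs = sum(x * svec),
       cc = sum(cvec^2), ss = sum(svec^2), cs = sum(cvec * svec),
       range = rng)
}

# Solve the Gram-corrected phase maximization given the five scalars.
# Maximizes (xc cos(phi) - xs sin(phi)) / sqrt(w' G w) with
# w = (cos(phi), sin(phi)) and G = [[cc, -cs], [-cs, ss]].  Reduces to
# the textbook arctan formula when cs = 0.  Returns phi in [0, 2 pi)
# with a nonnegative product.
.optimal_phase_scalars <- function(xc, xs, cc, ss, cs) {
  det <- cc * ss - cs * cs
  scale <- cc * ss + cs * cs + .Machine$double.xmin
  if (!(det > 1e-14 * scale)) {
    # G numerically rank one: the phase family spans a single direction
    if (cc >= ss) {
      prod <- xc / sqrt(cc)
      phi <- if (prod >= 0) 0 else pi
      return(list(phi = phi, product = abs(prod)))
    } else {
      prod <- xs / sqrt(ss)
      # g(phi = 3 pi / 2) = +S/||S||
      phi <- if (prod >= 0) 3 * pi / 2 else pi / 2
      return(list(phi = phi, product = abs(prod)))
    }
  }
  b1 <- xc; b2 <- -xs
  # w* = G^{-1} b (up to scale)
  w1 <- (ss * b1 + cs * b2) / det
  w2 <- (cs * b1 + cc * b2) / det
  den <- sqrt(cc * w1^2 - 2 * cs * w1 * w2 + ss * w2^2)
  if (den == 0) return(list(phi = 0, product = 0))
  prod <- (b1 * w1 + b2 * w2) / den
  phi <- atan2(w2, w1)
  if (prod < 0) { phi <- phi + pi; prod <- -prod }
  list(phi = phi %% (2 * pi), product = prod)
}

#' Optimal phase of a Gabor atom for a given signal
#'
#' Finds, in closed form, the phase that maximizes the inner product of
#' the signal with the unit-norm Gabor atom of given (u, omega, s).
#' The solver uses the exact 2x2 Gram system of the discrete C and S
#' components (which are not exactly orthogonal in discrete time) and
#' reduces to
#' \code{atan((xs/ss) / (xc/cc))} when \code{<C,S> = 0}.
#'
#' @inheritParams phase_split
#' @return List with \code{phi_max} (radians, in [0, 2*pi)),
#'   \code{product_max} (>= 0), and \code{atom}, the unit-norm waveform
#'   synthesized at \code{phi_max}.
#' @export
optimal_phase <- function(signal, u, omega, s) {
  ps <- phase_split(signal, u, omega, s)
  sol <- .optimal_phase_scalars(ps$xc, ps$xs, ps$cc, ps$ss, ps$cs)
  atom <- synthesize_gabor(gabor_params(u, omega, s, sol$phi), length(signal))
  list(phi_max = sol$phi, product_max = sol$product, atom = atom)
}

# Smallest even 5-smooth integer >= x (FFT-friendly transform length).
.nice_even_length <- function(x) {
  x <- max(2, ceiling(x))
  n <- x + x %% 2
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(as.integer(n))
    n <- n + 2
  }
}

#' Windowed-FFT inner products over a uniform frequency grid
#'
#' Computes \code{<x, C>} and \code{<x, S>} (see
#' \code{\link{phase_split}}) for all frequencies \code{omega = m *
#' delta_omega}, m = 1..L/2, in a single discrete Fourier transform of
#' the signal windowed by the Gaussian envelope centered at \code{u}:
#' the real part of the transform of \code{x * env * exp(-i omega
#' (t-u))} gives \code{<x,C>} and minus the imaginary part gives
#' \code{<x,S>}.  The grid step must correspond to an integer transform
#' length \code{L = 2*pi/delta_omega} at least as long as the window
#' support; otherwise an explicit error is raised (no silent
#' regridding).
#'
#' @param signal numeric sample vector.
#' @param u window center in samples.
#' @param s envelope scale in samples.
#' @param delta_omega frequency grid step in radians/sample.
#' @return List with \code{omega} (grid, radians/sample, in (0, pi]),
#'   \code{xc} and \code{xs}.
#' @export
windowed_fft_products <- function(signal, u, s, delta_omega) {
  n <- length(signal)
  stopifnot(delta_omega > 0)
  Lr <- 2 * pi / delta_omega
  L <- round(Lr)
  if (abs(Lr - L) > 1e-6 * Lr)
    stop("windowed_fft_products: delta_omega incompatible with an integer transform length (2*pi/delta_omega must be an integer)")
  rng <- .support_range(u, s, n)
  if (is.null(rng))
    stop("degenerate atom: envelope underflows everywhere on the epoch")
  len <- rng[2] - rng[1] + 1L
  if (L < len)
    stop("windowed_fft_products: transform length 2*pi/delta_omega shorter than the window support")
  tb <- .gabor_tables(u, 1, s, rng[1], rng[2])  # only env is used
  y <- numeric(L)
  y[seq_len(len)] <- signal[(rng[1]:rng[2]) + 1L] * tb$env
  Fy <- stats::fft(y)
  m <- seq_len(floor(L / 2))
  wg <- 2 * pi * m / L
  rot <- exp(1i * wg * (u - rng[1]))   # re-center the transform at u
  z <- Fy[m + 1L] * rot
  list(omega = wg, xc = Re(z), xs = -Im(z))
}

#' Fast screening for numerically orthogonal Gabor atoms
#'
#' Factorizes the analytic product as X*Y*Z with |X| < 2 and, for atoms
#' drawn from an epsilon-dictionary, |Y| <= 2^{3/2} / (eps^2 (2-eps^2))
#' ~ 2/eps^2.  The remaining factor
#' \code{Z = sqrt(pi/A) (s0 s1)^{-1/2} exp(C)} depends only on the
#' scales and center separation, so
#' \code{(2 sqrt(2)/eps^2) Z < eta} guarantees \code{|<g0,g1>| < eta};
#' the engine then substitutes 0 for the product in the update formula.
#'
#' @param g0,g1 \code{\link{gabor_params}} objects.
#' @param epsilon the dictionary metric bound in (0,1).
#' @param eta threshold; defaults to double-precision accuracy 1e-16.
#' @return Logical.
#' @export
is_orthogonal_fast <- function(g0, g1, epsilon, eta = 1e-16) {
  stopifnot(epsilon > 0, epsilon < 1, eta > 0)
  cst <- product_constants(g0, g1)
  Z <- sqrt(pi / cst$A) / sqrt(g0$s * g1$s) * exp(cst$C)
  (2 * sqrt(2) / epsilon^2) * Z < eta
}

#' Half-width of the truncated product integration interval
#'
#' Bounds the tails of the continuous Gabor-product integral so that
#' restricting integration to \code{[B - delta, B + delta]} changes the
#' product by less than \code{eta}.  The half-width is obtained from the
#' Gaussian tail bound of the integrand together with the
#' epsilon-dictionary bound on the normalization factors:
#' \deqn{\Delta' = \sqrt{\left(C - \log\left(\frac{\eta \epsilon^2}{2}
#'   \sqrt{s_0/s_1 + s_1/s_0}\right)\right) / A}.}
#'
#' @inheritParams is_orthogonal_fast
#' @param eta absolute truncation error bound.
#' @return Half-width in samples (positive).
#' @export
integration_halfwidth <- function(g0, g1, eta, epsilon) {
  stopifnot(eta > 0, epsilon > 0, epsilon < 1)
  if (is_orthogonal_fast(g0, g1, epsilon, eta))
    stop("integration_halfwidth: atoms orthogonal to the requested precision; no interval needed")
  cst <- product_constants(g0, g1)
  ratio <- g0$s / g1$s + g1$s / g0$s
  arg <- cst$C - log(eta * epsilon^2 / 2 * sqrt(ratio))
  if (arg <= 0)
    stop("integration_halfwidth: atoms orthogonal to the requested precision; no interval needed")
  sqrt(arg / cst$A)
}
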