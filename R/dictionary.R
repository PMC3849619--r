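# Product-related metric between Gabor atoms, maximal products of
# adjacent atoms, and construction of the metric-optimal (and
# stochastic) dictionary with per-scale sampling steps.

#' Inner-product metric between two unit-norm atoms
#'
#' \code{d0(g0, g1) = sqrt(1 - <g0|g1>)}, computed from the discrete
#' product of the synthesized unit-norm waveforms.  Orthogonal atoms are
#' at distance 1; antipodal atoms (phases differing by pi) reach the
#' algebraic maximum sqrt(2).
#'
#' @param g0,g1 \code{\link{gabor_params}} objects.
#' @param n_samples epoch length on which the atoms are discretized.
#' @return A number in [0, sqrt(2)].
#' @export
metric_d0 <- function(g0, g1, n_samples) {
  p <- discrete_product(synthesize_gabor(g0, n_samples),
                        synthesize_gabor(g1, n_samples))
  sqrt(max(0, 1 - p))
}

# Full-length C and S component vectors of a phase class (see
# phase_split), plus the support index range.
.cs_vectors <- function(u, omega, s, n) {
  rng <- .support_range(u, s, n)
  if (is.null(rng)) return(NULL)
  tb <- .gabor_tables(u, omega, s, rng[1], rng[2])
  idx <- (rng[1]:rng[2]) + 1L
  C <- numeric(n); S <- numeric(n)
  C[idx] <- tb$env * tb$cosv
  S[idx] <- tb$env * tb$sinv
  list(C = C, S = S, lo = rng[1], hi = rng[2])
}

# inverse square root of a symmetric psd 2x2 Gram matrix, dropping
# numerically null directions; returns a 2 x r matrix.
.gram_invsqrt <- function(G, tol = 1e-12) {
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, .Machine$double.xmin)
  if (!any(keep)) return(NULL)
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), nrow = sum(keep))
}

#' Phase-free metric between two Gabor parameter classes
#'
#' Distance between the equivalence classes of atoms sharing (s, omega,
#' u) but free phase: \code{d = sqrt(1 - <G0|G1>_max)} where the
#' maximal scalar product runs over both phases.  The maximum is
#' computed in closed form as the largest generalized singular value of
#' the 2x2 cross-Gram of the discrete C/S components of the two
#' classes, whitened by their own Gram matrices.
#'
#' @param c0,c1 lists (or \code{\link{gabor_params}}) with fields
#'   \code{u}, \code{omega}, \code{s}; phase is ignored.
#' @param n_samples epoch length.
#' @return A number in [0, 1].
#' @export
metric_d <- function(c0, c1, n_samples) {
  n <- as.integer(n_samples)
  a <- .cs_vectors(c0$u, c0$omega, c0$s, n)
  b <- .cs_vectors(c1$u, c1$omega, c1$s, n)
  if (is.null(a) || is.null(b))
    stop("degenerate atom: envelope underflows everywhere on the epoch")
  if (a$hi < b$lo || b$hi < a$lo) return(1)   # disjoint supports
  G0 <- matrix(c(sum(a$C^2), sum(a$C * a$S), sum(a$C * a$S), sum(a$S^2)), 2)
  G1 <- matrix(c(sum(b$C^2), sum(b$C * b$S), sum(b$C * b$S), sum(b$S^2)), 2)
  M <- matrix(c(sum(a$C * b$C), sum(a$S * b$C),
                sum(a$C * b$S), sum(a$S * b$S)), 2)
  W0 <- .gram_invsqrt(G0); W1 <- .gram_invsqrt(G1)
  if (is.null(W0) || is.null(W1))
    stop("degenerate atom: zero norm on the discrete grid")
  smax <- max(svd(t(W0) %*% M %*% W1)$d)
  sqrt(max(0, 1 - min(1, smax)))
}

#' Maximal product of two atoms adjacent in scale
#'
#' Closed-form maximum over both phases of the continuous inner product
#' of classes (s, omega, u) and (a*s, omega, u): the larger of the two
#' branches (both phases 0 or both pi/2) of the exact expression.  Near
#' the Nyquist frequency it reduces to \code{sqrt(2a/(a^2+1))}.
#'
#' @param s scale in samples.
#' @param omega frequency in radians/sample.
#' @param a dilation factor (> 1, or 1 for identical scales).
#' @return The maximal scalar product (a number in (0, 1]).
#' @export
max_product_scale <- function(s, omega, a) {
  if (a < 1) stop("max_product_scale: dilation factor a must be >= 1")
  E  <- exp(-a^2 * s^2 * omega^2 / ((a^2 + 1) * pi))
  e0 <- exp(-s^2 * omega^2 / (2 * pi))
  e1 <- exp(-a^2 * s^2 * omega^2 / (2 * pi))
  br_minus <- (1 - E) / sqrt((1 - e0) * (1 - e1))
  br_plus  <- (1 + E) / sqrt((1 + e0) * (1 + e1))
  sqrt(2 * a / (a^2 + 1)) * max(br_minus, br_plus)
}

#' Maximal product of two atoms adjacent in frequency
#'
#' Closed-form maximum over phases for classes (s, omega, u) and
#' (s, omega + delta_omega, u); attained at both phases pi/2.  Near
#' Nyquist it reduces to \code{exp(-delta_omega^2 s^2 / (8 pi))}.
#'
#' @param s scale in samples.
#' @param omega frequency in radians/sample.
#' @param delta_omega frequency step (>= 0), radians/sample.
#' @return The maximal scalar product.
#' @export
max_product_freq <- function(s, omega, delta_omega) {
  if (delta_omega < 0) stop("max_product_freq: negative step")
  w1 <- omega + delta_omega
  em <- exp(-s^2 * omega * w1 / (2 * pi))
  e0 <- exp(-s^2 * omega^2 / (2 * pi))
  e1 <- exp(-s^2 * w1^2 / (2 * pi))
  exp(-delta_omega^2 * s^2 / (8 * pi)) * (1 - em) / sqrt((1 - e0) * (1 - e1))
}

#' Maximal product of two atoms adjacent in position
#'
#' Closed-form maximum over phases for classes (s, omega, u) and
#' (s, omega, u + delta_u); the phases satisfy phi0 = -phi1 and the
#' remaining one-dimensional maximization over phi of
#' \code{(cos(2 phi + omega delta_u) + E) / (1 + cos(2 phi) E)} with
#' \code{E = exp(-s^2 omega^2/(2 pi))} is solved numerically.  Near
#' Nyquist the value reduces to \code{exp(-pi delta_u^2 / (2 s^2))}.
#'
#' @param s scale in samples.
#' @param omega frequency in radians/sample.
#' @param delta_u position step (>= 0), samples.
#' @return The maximal scalar product.
#' @export
max_product_pos <- function(s, omega, delta_u) {
  if (delta_u < 0) stop("max_product_pos: negative step")
  E <- exp(-s^2 * omega^2 / (2 * pi))
  f <- function(phi) (cos(2 * phi + omega * delta_u) + E) /
    (1 + cos(2 * phi) * E)
  grid <- seq(0, pi, length.out = 721L)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)
  inner <- max(vals[i], opt$objective)
  exp(-pi * delta_u^2 / (2 * s^2)) * inner
}

#' Dilation factor of the optimal dictionary
#'
#' The ratio between consecutive dictionary scales is chosen so that
#' scale-adjacent classes at the Nyquist frequency are at metric
#' distance exactly epsilon; equivalently \code{a} is the > 1 root of
#' \code{2a/(a^2+1) = (1-eps^2)^2}:
#' \deqn{a = \frac{1 + \epsilon\sqrt{(2-\epsilon^2)(\epsilon^4 -
#'   2\epsilon^2 + 2)}}{(1-\epsilon^2)^2}.}
#'
#' @param epsilon metric bound in (0, 1).
#' @return Dilation factor a > 1.
#' @export
dilation_factor <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 1)
    stop("dilation_factor: epsilon must lie in (0, 1)")
  e2 <- epsilon^2
  (1 + epsilon * sqrt((2 - e2) * (e2^2 - 2 * e2 + 2))) / (1 - e2)^2
}

#' Frequency and position steps for one scale
#'
#' Per-scale sampling steps of the optimal dictionary, chosen so that
#' frequency- and position-adjacent classes at the Nyquist frequency
#' are at metric distance epsilon:
#' \deqn{\Delta\omega = \frac{1}{s}\sqrt{-8\pi\log(1-\epsilon^2)},\quad
#'       \Delta u = s\sqrt{-\frac{2}{\pi}\log(1-\epsilon^2)}.}
#'
#' @param s scale in samples.
#' @param epsilon metric bound in (0, 1).
#' @return List with \code{delta_omega} (radians/sample) and
#'   \code{delta_u} (samples).
#' @export
steps_for_scale <- function(s, epsilon) {
  if (epsilon <= 0 || epsilon >= 1)
    stop("steps_for_scale: epsilon must lie in (0, 1)")
  lg <- -log(1 - epsilon^2)
  list(delta_omega = sqrt(8 * pi * lg) / s,
       delta_u = s * sqrt(2 / pi * lg))
}

.families_all <- c("gabor", "harmonic", "delta", "gaussian")

#' Dictionary configuration
#'
#' @param epsilon metric bound ("energy error") in (0, 1); the distance
#'   between neighboring dictionary atoms never exceeds it.  Values
#'   above 0.5 produce very sparse dictionaries and trigger a warning.
#' @param n_samples epoch length N.
#' @param dict_type \code{"fixed"} or \code{"stochastic"} (random
#'   removal of a fraction of atoms from the fixed dictionary).
#' @param percentage_chosen percentage of atoms kept in stochastic
#'   mode, in (0, 100]; \code{100 - percentage_chosen} percent of the
#'   atoms are removed.
#' @param seed RNG seed for the stochastic removal (reproducible).
#' @param include_families subset of
#'   \code{c("gabor", "harmonic", "delta", "gaussian")}.
#' @return Object of class \code{"dictionary_config"}.
#' @export
dictionary_config <- function(epsilon = 0.1, n_samples,
                              dict_type = c("fixed", "stochastic"),
                              percentage_chosen = 100, seed = 1L,
                              include_families = .families_all) {
  dict_type <- match.arg(dict_type)
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("dictionary_config: epsilon must lie in (0, 1)")
  if (epsilon > 0.5)
    warning("dictionary_config: epsilon above 0.5 gives a very coarse dictionary; the construction assumes epsilon << 1")
  n_samples <- as.integer(n_samples)
  if (n_samples < 4) stop("dictionary_config: n_samples must be >= 4")
  if (percentage_chosen <= 0 || percentage_chosen > 100)
    stop("dictionary_config: percentage_chosen must lie in (0, 100]")
  include_families <- match.arg(include_families, .families_all,
                                several.ok = TRUE)
  structure(list(epsilon = epsilon, n_samples = n_samples,
                 dict_type = dict_type,
                 percentage_chosen = percentage_chosen,
                 seed = as.integer(seed),
                 include_families = include_families),
            class = "dictionary_config")
}

#' Dictionary layout: scales, steps and atom counts
#'
#' Computes the per-scale sampling of the optimal dictionary without
#' building the (potentially large) product tables: the dilation
#' factor, the geometric scale set \code{s_j = a^j} for j = 1 ..
#' floor(log_a N), and for each scale the frequency step (snapped to an
#' FFT-compatible value \code{2*pi/L <= } the nominal step of
#' \code{\link{steps_for_scale}}, never coarser) and the position step.
#' Scales with envelope width below 4 samples alias on the integer
#' sample grid (the discrete inner products deviate from their
#' continuous values by Poisson-summation terms of order
#' \code{exp(-pi s^2/2)}, which breaks the metric guarantee near the
#' Nyquist frequency), so they carry no atoms; they still count towards
#' \code{N_s}.
#'
#' @param config a \code{\link{dictionary_config}}.
#' @return Object of class \code{"dictionary_layout"}: list with the
#'   dilation factor \code{a}, \code{N_s = floor(log_a(N))}, a
#'   per-scale data frame \code{scales}, harmonic-grid parameters, and
#'   atom counts per family.
#' @export
dictionary_layout <- function(config) {
  stopifnot(inherits(config, "dictionary_config"))
  eps <- config$epsilon; n <- config$n_samples
  a <- dilation_factor(eps)
  n_s <- floor(log(n) / log(a))
  if (n_s < 1) stop("dictionary_layout: epsilon too large for this epoch (no scales)")
  j <- seq_len(n_s)
  s <- a^j
  # Representability cutoff: below s ~ 4 samples the discrete atoms alias
  # (Poisson-summation terms ~ exp(-pi s^2/2)) strongly enough to break
  # the metric guarantee near Nyquist, so those scales carry no atoms.
  keep <- s >= 4
  sc <- data.frame(j = j[keep], s = s[keep])
  st <- steps_for_scale(sc$s, eps)
  # transform length: covers both the nominal frequency step and the
  # envelope support window (the window must fit in the transform)
  need <- pmax(2 * pi / st$delta_omega, floor(2 * sc$s * .support_factor) + 2)
  L <- vapply(need, .nice_even_length, integer(1))
  sc$delta_omega_nominal <- st$delta_omega
  sc$L <- L
  sc$delta_omega <- 2 * pi / L
  sc$n_omega <- L %/% 2L
  sc$delta_u <- st$delta_u
  sc$n_u <- floor((n - 1) / sc$delta_u) + 1L
  sc$n_gabor <- sc$n_omega * sc$n_u
  # harmonic grid: frequency step evaluated at the largest scale
  s_max <- a^n_s
  dwh <- steps_for_scale(s_max, eps)$delta_omega
  Lh <- .nice_even_length(max(2 * pi / dwh, n))
  counts <- c(
    gabor = if ("gabor" %in% config$include_families) sum(sc$n_gabor) else 0L,
    harmonic = if ("harmonic" %in% config$include_families) Lh %/% 2L else 0L,
    delta = if ("delta" %in% config$include_families) n else 0L,
    gaussian = if ("gaussian" %in% config$include_families) sum(sc$n_u) else 0L)
  # rough build-size estimate: Gram triplet + complex rotation per Gabor
  # class, envelope matrices, plus one xc/xs table per decomposition
  bytes <- sum(sc$n_gabor) * (5 * 8 + 16) +
    sum((sc$n_u) * (floor(2 * sc$s * .support_factor) + 2)) * 8 +
    counts["harmonic"] * 5 * 8
  structure(list(config = config, a = a, N_s = n_s, scales = sc,
                 harmonic = list(L = Lh, delta_omega = 2 * pi / Lh,
                                 n_omega = Lh %/% 2L, s_ref = s_max),
                 counts = counts, total_atoms = sum(counts),
                 est_bytes = unname(bytes)),
            class = "dictionary_layout")
}

#' @export
print.dictionary_layout <- function(x, ...) {
  cat(sprintf("Optimal Gabor dictionary layout: epsilon = %g, N = %d\n",
              x$config$epsilon, x$config$n_samples))
  cat(sprintf("  dilation factor a = %.6f, N_s = %d scales (s >= 4 kept: %d)\n",
              x$a, x$N_s, nrow(x$scales)))
  cat(sprintf("  families: %s; type: %s",
              paste(x$config$include_families, collapse = ", "),
              x$config$dict_type))
  if (x$config$dict_type == "stochastic")
    cat(sprintf(" (%.1f%% chosen, seed %d)", x$config$percentage_chosen,
                x$config$seed))
  cat("\n  atoms:", paste(sprintf("%s = %d", names(x$counts), x$counts),
                          collapse = ", "),
      sprintf("(total %d)\n", x$total_atoms))
  cat(sprintf("  estimated build size: %.1f MB\n", x$est_bytes / 2^20))
  tab <- x$scales[, c("j", "s", "delta_omega", "delta_u", "n_omega",
                      "n_u", "n_gabor")]
  print(format(tab, digits = 5), row.names = FALSE)
  invisible(x)
}

#' Export the dictionary layout as a text table
#'
#' Writes the per-scale audit table (scale, frequency step, position
#' step, atom count) as tab-separated text.
#'
#' @param layout a \code{\link{dictionary_layout}} (or built
#'   dictionary).
#' @param path output file; \code{""} prints to the console.
#' @export
write_layout <- function(layout, path = "") {
  if (inherits(layout, "mp_dictionary")) layout <- layout$layout
  stopifnot(inherits(layout, "dictionary_layout"))
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  writeLines(sprintf("# epsilon\t%.17g", layout$config$epsilon), con)
  writeLines(sprintf("# a\t%.17g", layout$a), con)
  writeLines(sprintf("# N\t%d", layout$config$n_samples), con)
  utils::write.table(layout$scales, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(layout)
}

# run expr with a private RNG stream seeded by `seed`
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Build the optimal (or stochastic) dictionary
#'
#' Constructs the full dictionary: per-scale envelope matrices,
#' FFT rotation factors, and the discrete Gram entries (cc, ss, cs) of
#' every Gabor phase class (border-clipped columns included), the
#' harmonic frequency grid, Kronecker deltas at every sample, and pure
#' Gaussians on the (scale, delta_u) grid.  In stochastic mode a
#' uniformly drawn fraction of atoms is removed, reproducibly from the
#' configured seed.  Atom enumeration order is (family, scale
#' ascending, u ascending, omega ascending) and is part of the stable
#' API (deterministic argmax tie-breaking downstream).
#'
#' @param config a \code{\link{dictionary_config}}.
#' @param mem_limit_mb refuse to build when the estimated size exceeds
#'   this budget (the estimate and atom counts are reported first).
#' @return Object of class \code{"mp_dictionary"}.
#' @export
build_dictionary <- function(config, mem_limit_mb = 4096) {
  layout <- dictionary_layout(config)
  if (layout$est_bytes / 2^20 > mem_limit_mb)
    stop(sprintf(
      "build_dictionary: estimated size %.1f MB (%d atoms) exceeds the %.0f MB budget",
      layout$est_bytes / 2^20, layout$total_atoms, mem_limit_mb))
  n <- config$n_samples
  fam <- config$include_families
  sc <- layout$scales
  scales <- vector("list", nrow(sc))
  for (r in seq_len(nrow(sc))) {
    s <- sc$s[r]; L <- sc$L[r]; n_omega <- sc$n_omega[r]
    u <- seq(0, by = sc$delta_u[r], length.out = sc$n_u[r])
    h <- s * .support_factor
    len <- min(floor(2 * h) + 1L, n + ceiling(h))  # never longer than needed
    t_lo <- as.integer(ceiling(u - h))
    tmat <- outer(0:(len - 1L), t_lo, "+")
    tau <- sweep(tmat, 2L, u)
    env <- exp(-pi * (tau / s)^2)
    env[abs(tau) > h | tmat < 0 | tmat > (n - 1L)] <- 0
    omega <- 2 * pi * seq_len(n_omega) / L
    rot <- exp(1i * outer(omega, u - t_lo))
    # Gram of every (omega, u) class from the transform of env^2
    pad <- matrix(0, L, length(u))
    pad[seq_len(len), ] <- env^2
    F2 <- stats::mvfft(pad)
    E2 <- Re(F2[1L, ])
    bins2 <- (2L * seq_len(n_omega)) %% L
    G <- F2[bins2 + 1L, , drop = FALSE] * rot^2
    E2m <- matrix(E2, n_omega, length(u), byrow = TRUE)
    cc <- pmax((E2m + Re(G)) / 2, 0)
    ss <- pmax((E2m - Re(G)) / 2, 0)
    cs <- -Im(G) / 2
    scales[[r]] <- list(j = sc$j[r], s = s, L = L, n_omega = n_omega,
                        delta_omega = sc$delta_omega[r], omega = omega,
                        delta_u = sc$delta_u[r], u = u, t_lo = t_lo,
                        len = len, env = env, rot = rot,
                        cc = cc, ss = ss, cs = cs, E2 = E2,
                        mask = NULL, gmask = NULL)
  }
  harmonic <- NULL
  if ("harmonic" %in% fam) {
    Lh <- layout$harmonic$L
    n_omega <- layout$harmonic$n_omega
    F2 <- stats::fft(c(rep(1, n), rep(0, Lh - n)))
    bins2 <- (2L * seq_len(n_omega)) %% Lh
    G <- F2[bins2 + 1L]
    cc <- pmax((n + Re(G)) / 2, 0)
    ss <- pmax((n - Re(G)) / 2, 0)
    cs <- -Im(G) / 2
    harmonic <- list(L = Lh, n_omega = n_omega,
                     delta_omega = layout$harmonic$delta_omega,
                     omega = 2 * pi * seq_len(n_omega) / Lh,
                     cc = cc, ss = ss, cs = cs, mask = NULL)
  }
  dict <- structure(list(config = config, layout = layout, a = layout$a,
                         N_s = layout$N_s, n = n,
                         families = fam, scales = scales,
                         harmonic = harmonic,
                         has_delta = "delta" %in% fam,
                         has_gabor = "gabor" %in% fam,
                         has_gaussian = "gaussian" %in% fam,
                         delta_mask = NULL),
                    class = "mp_dictionary")
  if (config$dict_type == "stochastic") dict <- .apply_stochastic_mask(dict)
  dict
}

# enumerate atom counts per block in the stable order and apply the
# random removal mask
.apply_stochastic_mask <- function(dict) {
  cfg <- dict$config
  blocks <- list()   # list of c(kind, scale_index, count)
  if (dict$has_gabor)
    for (r in seq_along(dict$scales))
      blocks[[length(blocks) + 1L]] <-
        list(kind = "gabor", r = r,
             count = dict$scales[[r]]$n_omega * length(dict$scales[[r]]$u))
  if (!is.null(dict$harmonic))
    blocks[[length(blocks) + 1L]] <-
      list(kind = "harmonic", r = NA, count = dict$harmonic$n_omega)
  if (dict$has_delta)
    blocks[[length(blocks) + 1L]] <- list(kind = "delta", r = NA,
                                          count = dict$n)
  if (dict$has_gaussian)
    for (r in seq_along(dict$scales))
      blocks[[length(blocks) + 1L]] <-
        list(kind = "gaussian", r = r, count = length(dict$scales[[r]]$u))
  total <- sum(vapply(blocks, `[[`, numeric(1), "count"))
  n_remove <- round((100 - cfg$percentage_chosen) / 100 * total)
  if (n_remove >= total)
    stop("build_dictionary: empty dictionary after stochastic subsampling")
  removed <- .with_seed(cfg$seed, sample.int(total, n_remove))
  kept <- rep(TRUE, total)
  kept[removed] <- FALSE
  off <- 0L
  for (b in blocks) {
    k <- kept[(off + 1L):(off + b$count)]
    off <- off + b$count
    if (b$kind == "gabor") {
      # column-major (omega fastest within u) matches (u asc, omega asc)
      dict$scales[[b$r]]$mask <-
        matrix(k, dict$scales[[b$r]]$n_omega, length(dict$scales[[b$r]]$u))
    } else if (b$kind == "harmonic") {
      dict$harmonic$mask <- k
    } else if (b$kind == "delta") {
      dict$delta_mask <- k
    } else {
      dict$scales[[b$r]]$gmask <- k
    }
  }
  dict
}

#' @export
print.mp_dictionary <- function(x, ...) {
  print(x$layout)
  invisible(x)
}
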