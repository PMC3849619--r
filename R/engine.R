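# Monochannel matching pursuit: product tables over the dictionary,
# the product-update formula, stopping rules and the decomposition
# ("book") container.

#' Stopping rule for the pursuit iteration
#'
#' The two continuation conditions work in logical conjunction: the
#' iteration proceeds while the iteration count is below
#' \code{max_iterations} AND the explained energy is below
#' \code{energy_percent}.  Defaults are 50 iterations and 99 percent.
#'
#' @param max_iterations maximum number of selected atoms (>= 1).
#' @param energy_percent stop once this percentage of the signal energy
#'   is explained, in (0, 100].
#' @return Object of class \code{"stopping_rule"}.
#' @export
stopping_rule <- function(max_iterations = 50L, energy_percent = 99) {
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("stopping_rule: max_iterations must be >= 1")
  if (energy_percent <= 0 || energy_percent > 100)
    stop("stopping_rule: energy_percent must lie in (0, 100]")
  structure(list(max_iterations = max_iterations,
                 energy_percent = energy_percent),
            class = "stopping_rule")
}

# Unit-norm waveform of any dictionary atom family on the epoch grid.
.atom_waveform <- function(family, u, omega, s, phi, n) {
  if (family == "gabor")
    return(synthesize_gabor(gabor_params(u, omega, s, phi), n))
  if (family == "harmonic") {
    w <- cos(omega * (0:(n - 1)) + phi)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) stop("degenerate atom: zero-norm harmonic")
    return(w / nrm)
  }
  if (family == "delta") {
    w <- numeric(n)
    w[round(u) + 1L] <- 1
    return(w)
  }
  if (family == "gaussian") {
    rng <- .support_range(u, s, n)
    if (is.null(rng)) stop("degenerate atom: envelope underflows everywhere")
    tau <- (rng[1]:rng[2]) - u
    e <- exp(-pi * (tau / s)^2)
    w <- numeric(n)
    w[(rng[1]:rng[2]) + 1L] <- e / sqrt(sum(e^2))
    return(w)
  }
  stop("unknown atom family: ", family)
}

# One windowed-transform pass of vector x over the Gabor grid of
# dictionary scale block `sc`, restricted to columns `cols` (NULL =
# all).  Returns xc, xs (n_omega x |cols|) and the envelope products gp
# (<x, env>/||env||, per column) shared with the Gaussian family.
.scale_pass <- function(x, sc, cols = NULL) {
  if (is.null(cols)) cols <- seq_along(sc$u)
  n <- length(x)
  idx <- outer(0:(sc$len - 1L), sc$t_lo[cols], "+")
  idx[idx < 0L | idx >= n] <- 0L           # clipped samples; env is 0 there
  Y <- matrix(x[idx + 1L], sc$len, length(cols)) * sc$env[, cols, drop = FALSE]
  pad <- matrix(0, sc$L, length(cols))
  pad[seq_len(sc$len), ] <- Y
  Fy <- stats::mvfft(pad)
  z <- Fy[2:(sc$n_omega + 1L), , drop = FALSE] * sc$rot[, cols, drop = FALSE]
  list(xc = Re(z), xs = -Im(z), gp = Re(Fy[1L, ]) / sqrt(sc$E2[cols]))
}

# Harmonic-grid products of x: zero-padded FFT over the epoch.
.harmonic_pass <- function(x, hm) {
  Fy <- stats::fft(c(x, rep(0, hm$L - length(x))))
  z <- Fy[2:(hm$n_omega + 1L)]
  list(xc = Re(z), xs = -Im(z))
}

# Full product-table pass: <x, C> and <x, S> for every phase class of
# every family.
.compute_tables <- function(x, dict) {
  gabor <- NULL; gaussian <- NULL
  if (dict$has_gabor || dict$has_gaussian) {
    gabor <- vector("list", length(dict$scales))
    gaussian <- vector("list", length(dict$scales))
    for (r in seq_along(dict$scales)) {
      p <- .scale_pass(x, dict$scales[[r]])
      gabor[[r]] <- list(xc = p$xc, xs = p$xs)
      gaussian[[r]] <- p$gp
    }
  }
  harmonic <- if (!is.null(dict$harmonic)) .harmonic_pass(x, dict$harmonic)
  list(gabor = gabor, harmonic = harmonic, gaussian = gaussian)
}

# Closed-form squared maximal product over the phase for whole tables
# (Gram-corrected; falls back to the dominant single component where
# the 2x2 Gram is numerically singular).
.phase_score <- function(xc, xs, cc, ss, cs) {
  det <- cc * ss - cs * cs
  good <- det > 1e-12 * (cc * ss + cs * cs + .Machine$double.xmin)
  sc <- (ss * xc^2 - 2 * cs * xc * xs + cc * xs^2) / ifelse(good, det, 1)
  if (!all(good)) {
    fb <- ifelse(cc >= ss,
                 ifelse(cc > 0, xc^2 / cc, 0),
                 ifelse(ss > 0, xs^2 / ss, 0))
    sc[!good] <- fb[!good]
  }
  sc
}

# Argmax of the squared-product score over all families in the stable
# enumeration order (family, scale asc, u asc, omega asc); the first
# maximum encountered wins.
.select_best <- function(tables, residual, dict) {
  best <- list(score = -Inf)
  if (dict$has_gabor) {
    for (r in seq_along(dict$scales)) {
      sc <- dict$scales[[r]]
      tb <- tables$gabor[[r]]
      score <- .phase_score(tb$xc, tb$xs, sc$cc, sc$ss, sc$cs)
      if (!is.null(sc$mask)) score[!sc$mask] <- -Inf
      i <- which.max(score)
      if (score[i] > best$score) {
        mi <- (i - 1L) %% sc$n_omega + 1L
        ci <- (i - 1L) %/% sc$n_omega + 1L
        best <- list(score = score[i], family = "gabor", r = r,
                     mi = mi, ci = ci,
                     u = sc$u[ci], omega = sc$omega[mi], s = sc$s)
      }
    }
  }
  if (!is.null(dict$harmonic)) {
    hm <- dict$harmonic
    score <- .phase_score(tables$harmonic$xc, tables$harmonic$xs,
                          hm$cc, hm$ss, hm$cs)
    if (!is.null(hm$mask)) score[!hm$mask] <- -Inf
    i <- which.max(score)
    if (score[i] > best$score)
      best <- list(score = score[i], family = "harmonic", r = NA,
                   mi = i, ci = NA, u = NA_real_, omega = hm$omega[i],
                   s = Inf)
  }
  if (dict$has_delta) {
    score <- residual^2
    if (!is.null(dict$delta_mask)) score[!dict$delta_mask] <- -Inf
    i <- which.max(score)
    if (score[i] > best$score)
      best <- list(score = score[i], family = "delta", r = NA, mi = NA,
                   ci = i, u = i - 1, omega = NA_real_, s = 0)
  }
  if (dict$has_gaussian) {
    for (r in seq_along(dict$scales)) {
      sc <- dict$scales[[r]]
      score <- tables$gaussian[[r]]^2
      if (!is.null(sc$gmask)) score[!sc$gmask] <- -Inf
      i <- which.max(score)
      if (score[i] > best$score)
        best <- list(score = score[i], family = "gaussian", r = r,
                     mi = NA, ci = i, u = sc$u[i], omega = 0, s = sc$s)
    }
  }
  if (!is.finite(best$score))
    stop("empty dictionary: no selectable atom")
  best
}

# columns of scale block `sc` whose windows overlap the support
# [rng[1], rng[2]] of the selected waveform and survive the fast
# orthogonality screening (the X*Y*Z factorization's Z threshold) against a
# selected Gabor of scale s_sel centered at u_sel.
.affected_cols <- function(sc, rng, u_sel = NULL, s_sel = NULL,
                           epsilon = NULL, eta = 1e-16) {
  lo <- sc$t_lo; hi <- sc$t_lo + sc$len - 1L
  cols <- which(hi >= rng[1] & lo <= rng[2])
  if (length(cols) && !is.null(s_sel) && is.finite(s_sel) && s_sel > 0) {
    A <- pi * (1 / s_sel^2 + 1 / sc$s^2)
    zc <- (2 * sqrt(2) / epsilon^2) * sqrt(pi / A) / sqrt(s_sel * sc$s)
    # exp(-pi du^2/(s0^2+s1^2)) * zc < eta  =>  du^2 > thr2
    if (zc > eta) {
      thr2 <- (s_sel^2 + sc$s^2) / pi * log(zc / eta)
      cols <- cols[(sc$u[cols] - u_sel)^2 <= thr2]
    } else cols <- integer(0)
  }
  cols
}

#' Update the product table after an atom selection
#'
#' Applies the product-update formula of greedy pursuit: for every
#' dictionary element \code{g_i},
#' \code{<R^{n+1} x, g_i> = <R^n x, g_i> - weight * <g_n, g_i>},
#' where the cross products \code{<g_n, g_i>} are computed numerically
#' on the (truncated) support of the selected waveform; elements
#' flagged by the fast orthogonality screening get 0 substituted for
#' the cross product and their table entries are left untouched.
#'
#' @param prev_products product tables as produced by the engine (the
#'   \code{<R^n x, C>} / \code{<R^n x, S>} tables for every family).
#' @param selected list describing the selected atom: fields
#'   \code{family}, \code{u}, \code{omega}, \code{s}, \code{phi}.
#' @param weight the selected product \code{<R^n x, g_n>}.
#' @param dictionary an \code{mp_dictionary}.
#' @return Updated product tables.
#' @export
update_products <- function(prev_products, selected, weight, dictionary) {
  n <- dictionary$n
  wave <- .atom_waveform(selected$family, selected$u, selected$omega,
                         selected$s, selected$phi %||% 0, n)
  supp <- range(which(wave != 0)) - 1L
  change <- weight * wave
  is_gab <- selected$family == "gabor"
  tables <- prev_products
  if (dictionary$has_gabor || dictionary$has_gaussian) {
    for (r in seq_along(dictionary$scales)) {
      sc <- dictionary$scales[[r]]
      cols <- .affected_cols(sc, supp,
                             u_sel = if (is_gab) selected$u,
                             s_sel = if (is_gab) selected$s,
                             epsilon = dictionary$config$epsilon)
      if (!length(cols)) next
      p <- .scale_pass(change, sc, cols)
      tables$gabor[[r]]$xc[, cols] <- tables$gabor[[r]]$xc[, cols] - p$xc
      tables$gabor[[r]]$xs[, cols] <- tables$gabor[[r]]$xs[, cols] - p$xs
      tables$gaussian[[r]][cols] <- tables$gaussian[[r]][cols] - p$gp
    }
  }
  if (!is.null(dictionary$harmonic)) {
    p <- .harmonic_pass(change, dictionary$harmonic)
    tables$harmonic$xc <- tables$harmonic$xc - p$xc
    tables$harmonic$xs <- tables$harmonic$xs - p$xs
  }
  tables
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact weight and phase of the selected class against the residual,
# plus a drift check of the maintained table entry (tables and residual
# are maintained independently; disagreement signals numerical decay).
.fit_selected <- function(best, residual, tables, dict, drift_tol = 1e-6) {
  n <- length(residual)
  if (best$family == "gabor") {
    ps <- phase_split(residual, best$u, best$omega, best$s)
    tb <- tables$gabor[[best$r]]
    drift <- max(abs(ps$xc - tb$xc[best$mi, best$ci]),
                 abs(ps$xs - tb$xs[best$mi, best$ci]))
    sol <- .optimal_phase_scalars(ps$xc, ps$xs, ps$cc, ps$ss, ps$cs)
    return(list(weight = sol$product, phi = sol$phi, drift = drift))
  }
  if (best$family == "harmonic") {
    t <- 0:(n - 1)
    xc <- sum(residual * cos(best$omega * t))
    xs <- sum(residual * sin(best$omega * t))
    hm <- dict$harmonic
    drift <- max(abs(xc - tables$harmonic$xc[best$mi]),
                 abs(xs - tables$harmonic$xs[best$mi]))
    sol <- .optimal_phase_scalars(xc, xs, hm$cc[best$mi], hm$ss[best$mi],
                                  hm$cs[best$mi])
    return(list(weight = sol$product, phi = sol$phi, drift = drift))
  }
  if (best$family == "delta")
    return(list(weight = residual[best$ci], phi = 0, drift = 0))
  # gaussian
  wave <- .atom_waveform("gaussian", best$u, 0, best$s, 0, n)
  w <- sum(residual * wave)
  drift <- abs(w - tables$gaussian[[best$r]][best$ci])
  list(weight = w, phi = 0, drift = drift)
}

.new_decomposition <- function(params, weights, phases, residual_energy,
                               energy0, config, residuals) {
  structure(list(params = params, weights = weights, phases = phases,
                 residual_energy = residual_energy, energy0 = energy0,
                 config = config, residuals = residuals),
            class = "mp_decomposition")
}

.empty_params <- function() {
  data.frame(iteration = integer(0), family = character(0),
             u = numeric(0), omega = numeric(0), s = numeric(0),
             stringsAsFactors = FALSE)
}

#' Matching pursuit decomposition of a single epoch
#'
#' Greedy iteration: each step selects the dictionary element
#' maximizing the absolute product with the current residual (the phase
#' of every Gabor and harmonic candidate is optimized in closed form),
#' subtracts the weighted atom, and repeats until the stopping rule is
#' met.  Product bookkeeping uses windowed-FFT product tables, the
#' product-update formula between iterations, and fast orthogonality
#' screening; the residual is maintained explicitly alongside the
#' tables and the selected entry is re-evaluated against it (drift
#' guard, tolerance 1e-6).
#'
#' @param signal numeric vector (one calibrated epoch), or a 1-channel,
#'   1-trial \code{\link{trial_matrix}}.
#' @param dictionary an \code{mp_dictionary} built for the same epoch
#'   length.
#' @param stop a \code{\link{stopping_rule}}.
#' @param fs sampling rate in Hz (used for reporting only).
#' @param calibration microvolts per sample unit (reporting only).
#' @param verbose log per-iteration residual energy to standard error.
#' @return Object of class \code{"mp_decomposition"}: the ordered atom
#'   parameters, weights (nonnegative for phase-carrying families; the
#'   sign lives in the phase), the residual-energy trace and full
#'   provenance.
#' @export
mp_decompose <- function(signal, dictionary, stop = stopping_rule(),
                         fs = 1, calibration = 1, verbose = FALSE) {
  if (inherits(signal, "trial_matrix")) {
    stopifnot(dim(signal$data)[1] == 1L, dim(signal$data)[2] == 1L)
    fs <- signal$fs; calibration <- signal$calibration
    signal <- as.numeric(signal$data[1, 1, ])
  }
  stopifnot(inherits(dictionary, "mp_dictionary"),
            inherits(stop, "stopping_rule"))
  if (length(signal) != dictionary$n)
    stop("mp_decompose: signal length does not match the dictionary epoch length")
  if (!all(is.finite(signal))) stop("mp_decompose: non-finite samples")
  n <- dictionary$n
  e0 <- sum(signal^2)
  cfg <- .decomp_config(dictionary, stop, fs, calibration, "mp",
                        n_channels = 1L, n_trials = 1L)
  if (e0 == 0)
    return(.new_decomposition(.empty_params(),
                              array(0, c(0, 1, 1)), array(0, c(0, 1, 1)),
                              residual_energy = e0, energy0 = e0,
                              config = cfg,
                              residuals = array(signal, c(1, 1, n))))
  r <- signal
  tables <- .compute_tables(r, dictionary)
  params <- vector("list", stop$max_iterations)
  weights <- numeric(stop$max_iterations)
  phases <- numeric(stop$max_iterations)
  res_energy <- numeric(stop$max_iterations + 1L)
  res_energy[1L] <- e0
  m <- 0L
  repeat {
    best <- .select_best(tables, r, dictionary)
    fit <- .fit_selected(best, r, tables, dictionary)
    if (fit$drift > 1e-6 * sqrt(max(e0, 1)))
      warning("mp_decompose: product-table drift above tolerance; recomputing tables")
    if (fit$drift > 1e-6 * sqrt(max(e0, 1)))
      tables <- .compute_tables(r, dictionary)
    m <- m + 1L
    params[[m]] <- list(iteration = m, family = best$family, u = best$u,
                        omega = best$omega, s = best$s)
    weights[m] <- fit$weight
    phases[m] <- fit$phi
    sel <- list(family = best$family, u = best$u, omega = best$omega,
                s = best$s, phi = fit$phi)
    wave <- .atom_waveform(sel$family, sel$u, sel$omega, sel$s, sel$phi, n)
    r <- r - fit$weight * wave
    if (!all(is.finite(r)))
      stop(sprintf("mp_decompose: non-finite residual at iteration %d", m))
    res_energy[m + 1L] <- sum(r^2)
    if (verbose)
      message(sprintf("iter %3d: %-8s u=%8.2f omega=%7.4f s=%8.2f w=%10.4g residual %6.2f%%",
                      m, best$family,
                      ifelse(is.na(best$u), -1, best$u),
                      ifelse(is.na(best$omega), -1, best$omega), best$s,
                      fit$weight, 100 * res_energy[m + 1L] / e0))
    done <- m >= stop$max_iterations ||
      100 * (1 - res_energy[m + 1L] / e0) >= stop$energy_percent
    if (done) break
    tables <- update_products(tables, sel, fit$weight, dictionary)
  }
  pdf <- do.call(rbind, lapply(params[seq_len(m)], function(p)
    data.frame(p, stringsAsFactors = FALSE)))
  .new_decomposition(pdf,
                     array(weights[seq_len(m)], c(m, 1, 1)),
                     array(phases[seq_len(m)], c(m, 1, 1)),
                     res_energy[seq_len(m + 1L)], e0, cfg,
                     array(r, c(1, 1, n)))
}

.decomp_config <- function(dictionary, stop, fs, calibration, variant,
                           n_channels, n_trials) {
  cfg <- dictionary$config
  list(epsilon = cfg$epsilon, a = dictionary$a,
       dict_type = cfg$dict_type,
       percentage_chosen = cfg$percentage_chosen, seed = cfg$seed,
       include_families = cfg$include_families,
       n_samples = cfg$n_samples,
       max_iterations = stop$max_iterations,
       energy_percent = stop$energy_percent,
       fs = fs, calibration = calibration, variant = variant,
       n_channels = n_channels, n_trials = n_trials)
}

#' Percentage of signal energy explained by a decomposition
#'
#' \code{100 * (1 - ||R^M x||^2 / ||x||^2)} from the residual-energy
#' trace; by orthogonality of each residual to the atom selected from
#' it, this equals \code{100 * sum(weights^2) / ||x||^2} for
#' monochannel decompositions.
#'
#' @param decomposition an \code{mp_decomposition}.
#' @return Percentage in [0, 100].
#' @export
explained_energy <- function(decomposition) {
  stopifnot(inherits(decomposition, "mp_decomposition"))
  e0 <- decomposition$energy0
  if (e0 == 0) return(0)
  ne <- length(decomposition$residual_energy)
  100 * (1 - decomposition$residual_energy[ne] / e0)
}

#' @export
print.mp_decomposition <- function(x, ...) {
  m <- nrow(x$params)
  cat(sprintf("MP decomposition (%s): %d atoms, %d channel(s) x %d trial(s), N = %d, fs = %g Hz\n",
              x$config$variant, m, x$config$n_channels, x$config$n_trials,
              x$config$n_samples, x$config$fs))
  cat(sprintf("  dictionary: epsilon = %g (%s), explained energy %.2f%%\n",
              x$config$epsilon, x$config$dict_type, explained_energy(x)))
  if (m > 0) {
    df <- utils::head(x$params, 10L)
    df$weight <- utils::head(x$weights[, 1, 1], 10L)
    print(format(df, digits = 4), row.names = FALSE)
    if (m > 10L) cat(sprintf("  ... and %d more\n", m - 10L))
  }
  invisible(x)
}
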