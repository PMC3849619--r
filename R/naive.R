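# Exhaustive reference engine: recomputes every dictionary product
# directly from the residual in every iteration, with all waveform
# values obtained by per-sample transcendental calls and all products
# by explicit dot products on the full atom support.  No product-update
# formula, no FFT, no orthogonality screening, no truncated
# integration.  Serves as the independent cross-check for the
# optimized engine on small instances.

# direct (transcendental) per-scale machinery built once per run
.naive_prepare <- function(dict) {
  n <- dict$n
  pre <- list(scales = vector("list", length(dict$scales)))
  for (r in seq_along(dict$scales)) {
    sc <- dict$scales[[r]]
    idx <- outer(0:(sc$len - 1L), sc$t_lo, "+")
    tau <- sweep(idx, 2L, sc$u)
    env <- exp(-pi * (tau / sc$s)^2)
    h <- sc$s * .support_factor
    env[abs(tau) > h | idx < 0L | idx >= n] <- 0
    n_u <- length(sc$u); n_w <- sc$n_omega
    cc <- matrix(0, n_w, n_u); ss <- matrix(0, n_w, n_u)
    cs <- matrix(0, n_w, n_u)
    for (c in seq_len(n_u)) {
      ph <- outer(tau[, c], sc$omega)
      CE <- cos(ph) * env[, c]
      SE <- sin(ph) * env[, c]
      cc[, c] <- colSums(CE^2)
      ss[, c] <- colSums(SE^2)
      cs[, c] <- colSums(CE * SE)
    }
    idx[idx < 0L | idx >= n] <- 0L
    pre$scales[[r]] <- list(idx = idx + 1L, tau = tau, env = env,
                            cc = cc, ss = ss, cs = cs,
                            gnorm = sqrt(colSums(env^2)))
  }
  if (!is.null(dict$harmonic)) {
    t <- 0:(n - 1)
    Ch <- cos(outer(t, dict$harmonic$omega))
    Sh <- sin(outer(t, dict$harmonic$omega))
    pre$harmonic <- list(C = Ch, S = Sh, cc = colSums(Ch^2),
                         ss = colSums(Sh^2), cs = colSums(Ch * Sh))
  }
  pre
}

.naive_tables <- function(x, dict, pre) {
  gabor <- vector("list", length(dict$scales))
  gaussian <- vector("list", length(dict$scales))
  for (r in seq_along(dict$scales)) {
    ps <- pre$scales[[r]]
    sc <- dict$scales[[r]]
    n_u <- length(sc$u)
    xc <- matrix(0, sc$n_omega, n_u); xs <- matrix(0, sc$n_omega, n_u)
    X <- matrix(x[ps$idx], nrow(ps$idx), n_u)
    for (c in seq_len(n_u)) {
      ph <- outer(ps$tau[, c], sc$omega)
      xe <- X[, c] * ps$env[, c]
      xc[, c] <- crossprod(cos(ph), xe)
      xs[, c] <- crossprod(sin(ph), xe)
    }
    gabor[[r]] <- list(xc = xc, xs = xs)
    gaussian[[r]] <- colSums(X * ps$env) / ps$gnorm
  }
  harmonic <- if (!is.null(dict$harmonic))
    list(xc = as.numeric(crossprod(pre$harmonic$C, x)),
         xs = as.numeric(crossprod(pre$harmonic$S, x)))
  list(gabor = gabor, harmonic = harmonic, gaussian = gaussian)
}

#' Matching pursuit with exhaustive per-iteration recomputation
#'
#' Functionally identical to \code{\link{mp_decompose}} but recomputes
#' every product directly from the residual in every iteration via
#' explicit dot products with per-sample-evaluated waveforms.  Orders
#' of magnitude slower; intended as an independent reference for
#' validating the optimized engine.
#'
#' @inheritParams mp_decompose
#' @return An \code{mp_decomposition}.
#' @export
mp_decompose_naive <- function(signal, dictionary, stop = stopping_rule(),
                               fs = 1, calibration = 1) {
  if (inherits(signal, "trial_matrix")) {
    stopifnot(dim(signal$data)[1] == 1L, dim(signal$data)[2] == 1L)
    fs <- signal$fs; calibration <- signal$calibration
    signal <- as.numeric(signal$data[1, 1, ])
  }
  stopifnot(inherits(dictionary, "mp_dictionary"))
  if (length(signal) != dictionary$n)
    stop("mp_decompose_naive: signal length does not match the dictionary epoch length")
  n <- dictionary$n
  e0 <- sum(signal^2)
  cfg <- .decomp_config(dictionary, stop, fs, calibration, "mp-naive",
                        n_channels = 1L, n_trials = 1L)
  if (e0 == 0)
    return(.new_decomposition(.empty_params(),
                              array(0, c(0, 1, 1)), array(0, c(0, 1, 1)),
                              e0, e0, cfg, array(signal, c(1, 1, n))))
  pre <- .naive_prepare(dictionary)
  # shadow dictionary carrying the directly computed Gram entries
  ndict <- dictionary
  for (r in seq_along(ndict$scales)) {
    ndict$scales[[r]]$cc <- pre$scales[[r]]$cc
    ndict$scales[[r]]$ss <- pre$scales[[r]]$ss
    ndict$scales[[r]]$cs <- pre$scales[[r]]$cs
  }
  if (!is.null(ndict$harmonic)) {
    ndict$harmonic$cc <- pre$harmonic$cc
    ndict$harmonic$ss <- pre$harmonic$ss
    ndict$harmonic$cs <- pre$harmonic$cs
  }
  r_ <- signal
  params <- list(); weights <- numeric(0); phases <- numeric(0)
  res_energy <- e0
  m <- 0L
  repeat {
    tables <- .naive_tables(r_, ndict, pre)
    best <- .select_best(tables, r_, ndict)
    fit <- .fit_selected(best, r_, tables, ndict)
    m <- m + 1L
    params[[m]] <- list(iteration = m, family = best$family, u = best$u,
                        omega = best$omega, s = best$s)
    weights[m] <- fit$weight
    phases[m] <- fit$phi
    wave <- .atom_waveform(best$family, best$u, best$omega, best$s,
                           fit$phi, n)
    r_ <- r_ - fit$weight * wave
    res_energy[m + 1L] <- sum(r_^2)
    if (m >= stop$max_iterations ||
        100 * (1 - res_energy[m + 1L] / e0) >= stop$energy_percent) break
  }
  pdf <- do.call(rbind, lapply(params, function(p)
    data.frame(p, stringsAsFactors = FALSE)))
  .new_decomposition(pdf, array(weights, c(m, 1, 1)),
                     array(phases, c(m, 1, 1)), res_energy, e0, cfg,
                     array(r_, c(1, 1, n)))
}
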