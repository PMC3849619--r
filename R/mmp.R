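# Multivariate matching pursuit across channels and trials: MMP1
# (common phase, max sum of absolute products), MMP2 (selection on the
# channel average), MMP3 (free phase, max sum of squared products) and
# the MMPXY compositions over a channels x trials data matrix.

#' Channels x trials x time signal block
#'
#' @param data numeric vector (one epoch), matrix (channels x time) or
#'   3-d array (channels x trials x time).
#' @param fs sampling rate in Hz.
#' @param calibration microvolts per sample unit; samples are stored
#'   calibrated (data * calibration).
#' @param labels optional channel labels.
#' @param montage free-form montage tag (e.g. "common reference").
#' @return Object of class \code{"trial_matrix"}.
#' @export
trial_matrix <- function(data, fs = 1, calibration = 1, labels = NULL,
                         montage = "unspecified") {
  if (is.vector(data) && is.numeric(data))
    data <- array(data, c(1, 1, length(data)))
  if (is.matrix(data))
    data <- array(data, c(nrow(data), 1, ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("trial_matrix: non-finite samples")
  if (fs <= 0) stop("trial_matrix: fs must be positive")
  nc <- dim(data)[1]
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nc))
  stopifnot(length(labels) == nc)
  structure(list(data = data * calibration, fs = fs,
                 calibration = calibration, labels = labels,
                 montage = montage),
            class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_matrix: %d channel(s) x %d trial(s) x %d samples, fs = %g Hz, calibration = %g uV/unit\n",
              d[1], d[2], d[3], x$fs, x$calibration))
  invisible(x)
}

.mmp_variants <- c("mp", "mmp1", "mmp2", "mmp3", "mmp11", "mmp12",
                   "mmp21", "mmp23", "mmp32", "mmp33")

#' Validate an MMP variant specification
#'
#' Variant names follow the MMPXY convention: X is the rule applied
#' across channels, Y across trials; rule 1 fits each signal with a
#' common phase (sum of absolute products), rule 2 averages the signals
#' before fitting, rule 3 allows a free phase per signal (sum of
#' squared products).  MMP13 and MMP31 are rejected (not implemented in
#' the reference engine).
#'
#' @param variant character, e.g. \code{"mmp23"}.
#' @return The normalized variant string.
#' @export
mmp_variant <- function(variant) {
  v <- tolower(as.character(variant)[1])
  if (v %in% c("mmp13", "mmp31"))
    stop("not implemented in reference engine: ", v)
  if (!v %in% .mmp_variants)
    stop("unknown MMP variant: ", v, " (expected one of ",
         paste(.mmp_variants, collapse = ", "), ")")
  v
}

# selection signals for one iteration: a list of numeric vectors,
# plus the phase-assignment rule
.selection_signals <- function(res, variant) {
  nc <- dim(res)[1]; nk <- dim(res)[2]
  pair_sig <- function() {
    out <- vector("list", nc * nk)
    for (k in seq_len(nk)) for (i in seq_len(nc))
      out[[(k - 1L) * nc + i]] <- res[i, k, ]
    out
  }
  ch_avg <- function()  # one signal per trial
    lapply(seq_len(nk), function(k) {
      m <- res[, k, , drop = FALSE][, 1, ]
      if (nc == 1L) as.numeric(m) else colMeans(m)
    })
  tr_avg <- function()  # one signal per channel
    lapply(seq_len(nc), function(i) {
      m <- res[i, , , drop = FALSE][1, , ]
      if (nk == 1L) as.numeric(m) else colMeans(m)
    })
  switch(variant,
    mmp1 = , mmp11 = , mmp33 = , mmp3 = pair_sig(),
    mmp12 = , mmp32 = tr_avg(),
    mmp21 = , mmp23 = ch_avg(),
    mmp2 = list(colMeans(matrix(res, nc * nk, dim(res)[3]))))
}

# exact common-phase objective for one class given per-signal scalars
.common_phi_objective <- function(xc, xs, cc, ss, cs) {
  function(phi) {
    cph <- cos(phi); sph <- sin(phi)
    den <- sqrt(max(cc * cph^2 - 2 * cs * cph * sph + ss * sph^2, 0))
    if (den == 0) return(0)
    sum(abs(xc * cph - xs * sph)) / den
  }
}

.golden_max <- function(f, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2
                   c2 <- a + gr * (b - a); f2 <- f(c2) }
    else { b <- c2; c2 <- c1; f2 <- f1
           c1 <- b - gr * (b - a); f1 <- f(c1) }
  }
  phi <- (a + b) / 2
  list(phi = phi, value = f(phi))
}

# free-phase (sum of squared maximal products) selection over a list of
# per-signal tables
.select_free <- function(tabs, rlist, dict) {
  nsig <- length(tabs)
  best <- list(score = -Inf)
  if (dict$has_gabor) {
    for (r in seq_along(dict$scales)) {
      sc <- dict$scales[[r]]
      score <- 0
      for (t in tabs)
        score <- score + .phase_score(t$gabor[[r]]$xc, t$gabor[[r]]$xs,
                                      sc$cc, sc$ss, sc$cs)
      if (!is.null(sc$mask)) score[!sc$mask] <- -Inf
      i <- which.max(score)
      if (score[i] > best$score) {
        mi <- (i - 1L) %% sc$n_omega + 1L; ci <- (i - 1L) %/% sc$n_omega + 1L
        best <- list(score = score[i], family = "gabor", r = r, mi = mi,
                     ci = ci, u = sc$u[ci], omega = sc$omega[mi], s = sc$s)
      }
    }
  }
  if (!is.null(dict$harmonic)) {
    hm <- dict$harmonic
    score <- 0
    for (t in tabs)
      score <- score + .phase_score(t$harmonic$xc, t$harmonic$xs,
                                    hm$cc, hm$ss, hm$cs)
    if (!is.null(hm$mask)) score[!hm$mask] <- -Inf
    i <- which.max(score)
    if (score[i] > best$score)
      best <- list(score = score[i], family = "harmonic", r = NA, mi = i,
                   ci = NA, u = NA_real_, omega = hm$omega[i], s = Inf)
  }
  if (dict$has_delta) {
    score <- 0
    for (x in rlist) score <- score + x^2
    if (!is.null(dict$delta_mask)) score[!dict$delta_mask] <- -Inf
    i <- which.max(score)
    if (score[i] > best$score)
      best <- list(score = score[i], family = "delta", r = NA, mi = NA,
                   ci = i, u = i - 1, omega = NA_real_, s = 0)
  }
  if (dict$has_gaussian) {
    for (r in seq_along(dict$scales)) {
      sc <- dict$scales[[r]]
      score <- 0
      for (t in tabs) score <- score + t$gaussian[[r]]^2
      if (!is.null(sc$gmask)) score[!sc$gmask] <- -Inf
      i <- which.max(score)
      if (score[i] > best$score)
        best <- list(score = score[i], family = "gaussian", r = r, mi = NA,
                     ci = i, u = sc$u[i], omega = 0, s = sc$s)
    }
  }
  best
}

# common-phase (sum of absolute products, one phase for all signals)
# selection: 64-point phase grid scan, exact golden-section refinement
# of the top candidates.
.select_common <- function(tabs, rlist, dict, n_grid = 64L, top_k = 32L) {
  nsig <- length(tabs)
  if (nsig == 1L) {
    # single signal: the exact closed form is available
    best <- .select_free(tabs, rlist, dict)
    best$score <- sqrt(max(best$score, 0))
    best$phi <- .fit_class_signal(rlist[[1]], best, dict)$phi
    return(best)
  }
  ph <- seq(0, pi, length.out = n_grid + 1L)[seq_len(n_grid)]
  cands <- list()
  grid_scan <- function(xc_list, xs_list, cc, ss, cs) {
    bestv <- NULL
    for (j in seq_along(ph)) {
      cph <- cos(ph[j]); sph <- sin(ph[j])
      den <- sqrt(pmax(cc * cph^2 - 2 * cs * cph * sph + ss * sph^2, 0))
      num <- 0
      for (q in seq_len(nsig))
        num <- num + abs(xc_list[[q]] * cph - xs_list[[q]] * sph)
      val <- ifelse(den > 0, num / den, 0)
      bestv <- if (is.null(bestv)) val else pmax(bestv, val)
    }
    bestv
  }
  if (dict$has_gabor) {
    for (r in seq_along(dict$scales)) {
      sc <- dict$scales[[r]]
      g <- grid_scan(lapply(tabs, function(t) t$gabor[[r]]$xc),
                     lapply(tabs, function(t) t$gabor[[r]]$xs),
                     sc$cc, sc$ss, sc$cs)
      if (!is.null(sc$mask)) g[!sc$mask] <- -Inf
      top <- order(g, decreasing = TRUE)[seq_len(min(top_k, length(g)))]
      for (i in top[is.finite(g[top])]) {
        mi <- (i - 1L) %% sc$n_omega + 1L; ci <- (i - 1L) %/% sc$n_omega + 1L
        f <- .common_phi_objective(
          vapply(tabs, function(t) t$gabor[[r]]$xc[mi, ci], 0),
          vapply(tabs, function(t) t$gabor[[r]]$xs[mi, ci], 0),
          sc$cc[mi, ci], sc$ss[mi, ci], sc$cs[mi, ci])
        gj <- which.max(vapply(ph, f, 0))
        ref <- .golden_max(f, ph[gj] - pi / n_grid, ph[gj] + pi / n_grid)
        cands[[length(cands) + 1L]] <-
          list(score = ref$value, phi = ref$phi, family = "gabor", r = r,
               mi = mi, ci = ci, u = sc$u[ci], omega = sc$omega[mi],
               s = sc$s, ord = c(1, r, ci, mi))
      }
    }
  }
  if (!is.null(dict$harmonic)) {
    hm <- dict$harmonic
    g <- grid_scan(lapply(tabs, function(t) t$harmonic$xc),
                   lapply(tabs, function(t) t$harmonic$xs),
                   hm$cc, hm$ss, hm$cs)
    if (!is.null(hm$mask)) g[!hm$mask] <- -Inf
    top <- order(g, decreasing = TRUE)[seq_len(min(top_k, length(g)))]
    for (i in top[is.finite(g[top])]) {
      f <- .common_phi_objective(
        vapply(tabs, function(t) t$harmonic$xc[i], 0),
        vapply(tabs, function(t) t$harmonic$xs[i], 0),
        hm$cc[i], hm$ss[i], hm$cs[i])
      gj <- which.max(vapply(ph, f, 0))
      ref <- .golden_max(f, ph[gj] - pi / n_grid, ph[gj] + pi / n_grid)
      cands[[length(cands) + 1L]] <-
        list(score = ref$value, phi = ref$phi, family = "harmonic", r = NA,
             mi = i, ci = NA, u = NA_real_, omega = hm$omega[i], s = Inf,
             ord = c(2, 0, 0, i))
    }
  }
  if (dict$has_delta) {
    score <- 0
    for (x in rlist) score <- score + abs(x)
    if (!is.null(dict$delta_mask)) score[!dict$delta_mask] <- -Inf
    i <- which.max(score)
    if (is.finite(score[i]))
      cands[[length(cands) + 1L]] <-
        list(score = score[i], phi = 0, family = "delta", r = NA, mi = NA,
             ci = i, u = i - 1, omega = NA_real_, s = 0, ord = c(3, 0, i, 0))
  }
  if (dict$has_gaussian) {
    for (r in seq_along(dict$scales)) {
      sc <- dict$scales[[r]]
      score <- 0
      for (t in tabs) score <- score + abs(t$gaussian[[r]])
      if (!is.null(sc$gmask)) score[!sc$gmask] <- -Inf
      i <- which.max(score)
      if (is.finite(score[i]))
        cands[[length(cands) + 1L]] <-
          list(score = score[i], phi = 0, family = "gaussian", r = r,
               mi = NA, ci = i, u = sc$u[i], omega = 0, s = sc$s,
               ord = c(4, r, i, 0))
    }
  }
  if (!length(cands)) stop("empty dictionary: no selectable atom")
  # pick max refined score; ties broken by the stable enumeration order
  ords <- t(vapply(cands, function(c) c$ord, numeric(4)))
  scores <- vapply(cands, function(c) c$score, 0)
  o <- order(-scores, ords[, 1], ords[, 2], ords[, 3], ords[, 4])
  cands[[o[1]]]
}

# per-signal optimal phase + product of a selected class (free-phase
# weighting); exact, from the given vector
.fit_class_signal <- function(x, best, dict) {
  n <- length(x)
  if (best$family == "gabor") {
    ps <- phase_split(x, best$u, best$omega, best$s)
    return(.optimal_phase_scalars(ps$xc, ps$xs, ps$cc, ps$ss, ps$cs))
  }
  if (best$family == "harmonic") {
    t <- 0:(n - 1)
    hm <- dict$harmonic
    return(.optimal_phase_scalars(sum(x * cos(best$omega * t)),
                                  sum(x * sin(best$omega * t)),
                                  hm$cc[best$mi], hm$ss[best$mi],
                                  hm$cs[best$mi]))
  }
  wave <- .atom_waveform(best$family, best$u, best$omega, best$s, 0, n)
  list(phi = 0, product = sum(x * wave))
}

#' Multivariate matching pursuit decomposition
#'
#' Joint greedy decomposition of a channels x trials x time block.  In
#' every iteration one envelope class (u, omega, s) is selected for all
#' signals at once; how the selection criterion aggregates the signals,
#' and whether the phase is common or free, is set by the variant (see
#' \code{\link{mmp_variant}}).  Weights are always computed against the
#' unaveraged residua of the individual channels/trials, and every
#' channel/trial residual is updated with its own weighted atom.
#'
#' Variants across channels only (trials must be 1): \code{mmp1}
#' (common phase, maximal sum of absolute products), \code{mmp2}
#' (selection on the channel average; refuses average-reference data),
#' \code{mmp3} (free phase per channel, maximal sum of squared
#' products).  Compositions \code{mmpXY} apply rule Y across trials
#' (inner averaging step) and rule X across channels, per the catalog:
#' 11, 12, 21, 23, 32, 33.  For \code{mmp32} the free phase enters at
#' weighting (per channel and trial); selection on the trial averages
#' uses one phase per channel.
#'
#' @param x a \code{\link{trial_matrix}} (or vector/matrix/array
#'   coerced to one).
#' @param dictionary an \code{mp_dictionary}.
#' @param stop a \code{\link{stopping_rule}}.
#' @param variant one of \code{"mp"}, \code{"mmp1"}, \code{"mmp2"},
#'   \code{"mmp3"}, \code{"mmp11"}, \code{"mmp12"}, \code{"mmp21"},
#'   \code{"mmp23"}, \code{"mmp32"}, \code{"mmp33"}.
#' @param verbose log per-iteration residual energy to standard error.
#' @return An \code{mp_decomposition} with per-channel/per-trial weight
#'   and phase matrices.
#' @export
mmp_decompose <- function(x, dictionary, stop = stopping_rule(),
                          variant = "mmp1", verbose = FALSE) {
  variant <- mmp_variant(variant)
  if (!inherits(x, "trial_matrix")) x <- trial_matrix(x)
  stopifnot(inherits(dictionary, "mp_dictionary"))
  nc <- dim(x$data)[1]; nk <- dim(x$data)[2]; n <- dim(x$data)[3]
  if (n != dictionary$n)
    stop("mmp_decompose: epoch length does not match the dictionary")
  if (variant == "mp") {
    if (nc != 1L || nk != 1L)
      stop("variant 'mp' requires a single channel and trial")
    return(mp_decompose(as.numeric(x$data[1, 1, ]), dictionary, stop,
                        fs = x$fs, calibration = x$calibration,
                        verbose = verbose))
  }
  if (variant %in% c("mmp1", "mmp2", "mmp3") && nk != 1L)
    stop(variant, " operates across channels only; use the mmpXY form for multitrial data")
  if (variant %in% c("mmp2", "mmp21", "mmp23")) {
    avg <- .selection_signals(x$data, "mmp2")[[1]]
    ratio <- sum(avg^2) / max(mean(apply(x$data, c(1, 2),
                                         function(v) sum(v^2))),
                              .Machine$double.xmin)
    if (ratio < 1e-20)
      stop(variant, ": channel mean is numerically zero (average-reference montage?); selection on the average is undefined")
    if (ratio < 1e-10)
      warning(variant, ": channel mean carries almost no energy; the data look average-referenced and convergence will suffer")
  }
  mode <- switch(variant,
                 mmp1 = , mmp11 = , mmp12 = , mmp21 = "common",
                 mmp2 = "average",
                 mmp3 = , mmp23 = , mmp32 = , mmp33 = "free")
  res <- x$data
  e0 <- sum(res^2)
  cfg <- .decomp_config(dictionary, stop, x$fs, x$calibration, variant,
                        n_channels = nc, n_trials = nk)
  if (e0 == 0)
    return(.new_decomposition(.empty_params(), array(0, c(0, nc, nk)),
                              array(0, c(0, nc, nk)), e0, e0, cfg, res))
  params <- list()
  weights <- list(); phases <- list()
  res_energy <- e0
  m <- 0L
  repeat {
    sigs <- .selection_signals(res, variant)
    tabs <- lapply(sigs, .compute_tables, dict = dictionary)
    best <- if (mode %in% c("free", "average")) {
      b <- .select_free(tabs, sigs, dictionary)
      if (!is.finite(b$score)) stop("empty dictionary: no selectable atom")
      b
    } else .select_common(tabs, sigs, dictionary)
    has_phase <- best$family %in% c("gabor", "harmonic")
    # phases: one per selection signal (free) or a single common one
    if (mode == "common") {
      phi_common <- if (has_phase) best$phi else 0
    } else {
      sol <- lapply(sigs, .fit_class_signal, best = best, dict = dictionary)
      sig_phi <- vapply(sol, function(s) s$phi, 0)
    }
    wmat <- matrix(0, nc, nk); pmat <- matrix(0, nc, nk)
    for (k in seq_len(nk)) for (i in seq_len(nc)) {
      phi_ik <- if (mode == "common") phi_common
      else switch(variant,
                  mmp2 = sig_phi[1],
                  mmp3 = , mmp33 = sig_phi[(k - 1L) * nc + i],
                  mmp23 = sig_phi[k],
                  mmp32 = .fit_class_signal(res[i, k, ], best,
                                            dictionary)$phi)
      wave <- .atom_waveform(best$family, best$u, best$omega, best$s,
                             phi_ik, n)
      wmat[i, k] <- sum(res[i, k, ] * wave)
      pmat[i, k] <- phi_ik
      res[i, k, ] <- res[i, k, ] - wmat[i, k] * wave
    }
    m <- m + 1L
    params[[m]] <- list(iteration = m, family = best$family, u = best$u,
                        omega = best$omega, s = best$s)
    weights[[m]] <- wmat; phases[[m]] <- pmat
    res_energy[m + 1L] <- sum(res^2)
    if (verbose)
      message(sprintf("iter %3d (%s): %-8s residual %6.2f%%", m, variant,
                      best$family, 100 * res_energy[m + 1L] / e0))
    if (m >= stop$max_iterations ||
        100 * (1 - res_energy[m + 1L] / e0) >= stop$energy_percent) break
  }
  pdf <- do.call(rbind, lapply(params, function(p)
    data.frame(p, stringsAsFactors = FALSE)))
  warr <- array(0, c(m, nc, nk)); parr <- array(0, c(m, nc, nk))
  for (q in seq_len(m)) { warr[q, , ] <- weights[[q]]; parr[q, , ] <- phases[[q]] }
  .new_decomposition(pdf, warr, parr, res_energy, e0, cfg, res)
}

#' @rdname mmp_decompose
#' @param channels matrix (channels x time) or \code{trial_matrix} with
#'   a single trial.
#' @param ... passed to \code{mmp_decompose}.
#' @export
mmp1_decompose <- function(channels, dictionary, stop = stopping_rule(), ...)
  mmp_decompose(channels, dictionary, stop, variant = "mmp1", ...)

#' @rdname mmp_decompose
#' @export
mmp2_decompose <- function(channels, dictionary, stop = stopping_rule(), ...)
  mmp_decompose(channels, dictionary, stop, variant = "mmp2", ...)

#' @rdname mmp_decompose
#' @export
mmp3_decompose <- function(channels, dictionary, stop = stopping_rule(), ...)
  mmp_decompose(channels, dictionary, stop, variant = "mmp3", ...)

#' @rdname mmp_decompose
#' @param spec variant string for the channels-by-trials composition.
#' @param matrix a \code{\link{trial_matrix}}.
#' @export
mmpxy_decompose <- function(matrix, spec, dictionary,
                            stop = stopping_rule(), ...)
  mmp_decompose(matrix, dictionary, stop, variant = spec, ...)
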