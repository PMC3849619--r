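# Time-frequency energy maps, signal reconstruction, physical units,
# and parameter-based atom filtering with sleep-EEG presets.

#' Reconstruct a signal from selected atoms
#'
#' Sum of the weighted atom waveforms of the chosen book entries for
#' one channel/trial.  With the full entry set, reconstruction plus the
#' final residual reproduces the original epoch (telescoping of the
#' pursuit recursion).
#'
#' @param decomposition an \code{mp_decomposition}.
#' @param atoms integer indices of book entries (default: all).
#' @param channel,trial which channel/trial weights to use.
#' @return Numeric vector of length \code{n_samples}.
#' @export
reconstruct <- function(decomposition, atoms = NULL, channel = 1L,
                        trial = 1L) {
  stopifnot(inherits(decomposition, "mp_decomposition"))
  n <- decomposition$config$n_samples
  out <- numeric(n)
  m <- nrow(decomposition$params)
  if (is.null(atoms)) atoms <- seq_len(m)
  for (q in atoms) {
    p <- decomposition$params[q, ]
    w <- decomposition$weights[q, channel, trial]
    phi <- decomposition$phases[q, channel, trial]
    out <- out + w * .atom_waveform(p$family, p$u, p$omega, p$s, phi, n)
  }
  out
}

#' Physical parameters of the book atoms
#'
#' Converts book entries to the units used in EEG practice: peak
#' amplitude \code{|weight| * max|waveform|} (microvolts, for data
#' calibrated in microvolts), peak-to-peak amplitude (twice the peak
#' amplitude, per the encephalographic convention), frequency
#' \code{omega * fs / (2 pi)} in Hz, width \code{s / fs} and center
#' \code{u / fs} in seconds.
#'
#' @inheritParams reconstruct
#' @return Data frame with one row per book entry.
#' @export
atom_physical_params <- function(decomposition, channel = 1L, trial = 1L) {
  stopifnot(inherits(decomposition, "mp_decomposition"))
  fs <- decomposition$config$fs
  n <- decomposition$config$n_samples
  m <- nrow(decomposition$params)
  out <- decomposition$params[, c("iteration", "family")]
  amp <- wgt <- phs <- freq <- wid <- ctr <- numeric(m)
  for (q in seq_len(m)) {
    p <- decomposition$params[q, ]
    w <- decomposition$weights[q, channel, trial]
    phi <- decomposition$phases[q, channel, trial]
    wave <- .atom_waveform(p$family, p$u, p$omega, p$s, phi, n)
    amp[q] <- abs(w) * max(abs(wave))
    wgt[q] <- w; phs[q] <- phi
    freq[q] <- if (is.na(p$omega)) NA_real_ else p$omega * fs / (2 * pi)
    wid[q] <- if (is.infinite(p$s)) n / fs else p$s / fs
    ctr[q] <- if (is.na(p$u)) (n - 1) / 2 / fs else p$u / fs
  }
  out$amplitude <- amp
  out$peak_to_peak <- 2 * amp
  out$frequency_hz <- freq
  out$width_s <- wid
  out$center_s <- ctr
  out$weight <- wgt
  out$phase <- phs
  out
}

#' Atom filter on physical parameters
#'
#' All criteria combine with logical AND.  Amplitudes are peak-to-peak
#' (EEG convention: twice the mathematical amplitude of a Gabor).
#' Entries without a defined value for some quantity (e.g. frequency of
#' a Kronecker delta) pass only if that criterion is unbounded.
#'
#' @param min_p2p,max_p2p peak-to-peak amplitude bounds, microvolts.
#' @param min_freq_hz,max_freq_hz frequency bounds, Hz.
#' @param min_width_s,max_width_s width (scale) bounds, seconds.
#' @param t_min_s,t_max_s time-center window, seconds.
#' @return Object of class \code{"atom_filter"}.
#' @seealso \code{\link{filter_preset}} for the slow-wave and spindle
#'   presets.
#' @export
atom_filter <- function(min_p2p = 0, max_p2p = Inf,
                        min_freq_hz = 0, max_freq_hz = Inf,
                        min_width_s = 0, max_width_s = Inf,
                        t_min_s = 0, t_max_s = Inf) {
  f <- list(p2p = c(min_p2p, max_p2p),
            freq = c(min_freq_hz, max_freq_hz),
            width = c(min_width_s, max_width_s),
            t = c(t_min_s, t_max_s))
  for (nm in names(f))
    if (f[[nm]][1] > f[[nm]][2])
      stop("atom_filter: min exceeds max for ", nm)
  structure(f, class = "atom_filter")
}

#' Sleep-EEG filter presets
#'
#' \code{"swa"}: slow wave activity, peak-to-peak amplitude >= 50 uV,
#' width >= 0.5 s, frequency 0.5--4 Hz.  \code{"spindle"}: sleep
#' spindles, 11--15 Hz, width 0.5--2 s, peak-to-peak >= 15 uV.
#'
#' @param preset \code{"swa"} or \code{"spindle"}.
#' @return An \code{\link{atom_filter}}.
#' @export
filter_preset <- function(preset = c("swa", "spindle")) {
  switch(match.arg(preset),
         swa = atom_filter(min_p2p = 50, min_width_s = 0.5,
                           min_freq_hz = 0.5, max_freq_hz = 4),
         spindle = atom_filter(min_p2p = 15, min_freq_hz = 11,
                               max_freq_hz = 15, min_width_s = 0.5,
                               max_width_s = 2))
}

.crit_pass <- function(value, bounds) {
  ifelse(is.na(value),
         bounds[1] <= 0 & is.infinite(bounds[2]),
         value >= bounds[1] & value <= bounds[2])
}

#' Filter book atoms by physical criteria
#'
#' Keeps the entries satisfying all filter criteria (evaluated on the
#' given channel/trial), preserving iteration order.  Filtering is
#' idempotent and commutes with truncating the decomposition.
#'
#' @inheritParams reconstruct
#' @param filter an \code{\link{atom_filter}}.
#' @return An \code{mp_decomposition} containing the surviving entries
#'   (the residual-energy trace and provenance of the parent are kept).
#' @export
filter_atoms <- function(decomposition, filter, channel = 1L, trial = 1L) {
  stopifnot(inherits(decomposition, "mp_decomposition"),
            inherits(filter, "atom_filter"))
  pp <- atom_physical_params(decomposition, channel, trial)
  keep <- .crit_pass(pp$peak_to_peak, filter$p2p) &
    .crit_pass(pp$frequency_hz, filter$freq) &
    .crit_pass(pp$width_s, filter$width) &
    .crit_pass(pp$center_s, filter$t)
  out <- decomposition
  out$params <- decomposition$params[keep, , drop = FALSE]
  out$weights <- decomposition$weights[keep, , , drop = FALSE]
  out$phases <- decomposition$phases[keep, , , drop = FALSE]
  out$config$filter <- unclass(filter)
  out
}

#' Percentage of the epoch covered by book atoms
#'
#' Union (not sum) of the atom time supports, each taken as the
#' interval \code{[u - f*s/2, u + f*s/2]} with configurable width
#' multiplier \code{f} (one scale unit by default, matching the visual
#' width convention used for slow-wave marking), as a percentage of the
#' epoch length.  Harmonics cover the whole epoch; deltas have zero
#' width.
#'
#' @inheritParams reconstruct
#' @param width_factor multiplier on the scale for the covered
#'   interval.
#' @return Percentage in [0, 100].
#' @export
epoch_occupancy <- function(decomposition, width_factor = 1) {
  stopifnot(inherits(decomposition, "mp_decomposition"))
  n <- decomposition$config$n_samples
  m <- nrow(decomposition$params)
  if (m == 0) return(0)
  lo <- hi <- numeric(0)
  for (q in seq_len(m)) {
    p <- decomposition$params[q, ]
    if (is.infinite(p$s)) { lo <- c(lo, 0); hi <- c(hi, n - 1) }
    else if (p$s > 0) {
      lo <- c(lo, max(0, p$u - width_factor * p$s / 2))
      hi <- c(hi, min(n - 1, p$u + width_factor * p$s / 2))
    }
  }
  if (!length(lo)) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (q in seq_along(lo)[-1]) {
    if (lo[q] <= cur_hi) cur_hi <- max(cur_hi, hi[q])
    else { tot <- tot + (cur_hi - cur_lo); cur_lo <- lo[q]; cur_hi <- hi[q] }
  }
  tot <- tot + (cur_hi - cur_lo)
  100 * tot / (n - 1)
}

#' Time-frequency energy density map of a decomposition
#'
#' Sums, over the selected book entries, the squared weight times a
#' unit-integral time-frequency blob (no cross-terms): for a Gabor atom
#' the blob is the 2-d Gaussian
#' \code{exp(-2 pi ((t-u)/s)^2 - s^2 (w - w0)^2 / (2 pi))} of its
#' Wigner distribution (the negative-frequency mirror of the real
#' cosine is omitted); pure Gaussians are the same blob folded at 0 Hz,
#' deltas map to a time line (uniform over frequency), harmonics to a
#' frequency line (uniform over the epoch).  The integral of the map
#' over time and frequency approximates the summed squared weights.
#'
#' @inheritParams reconstruct
#' @param t_grid time axis in seconds (defaults to the epoch sampled at
#'   up to 256 points); must lie within the epoch.
#' @param f_grid frequency axis in Hz (defaults to 0..Nyquist at 129
#'   points); must lie within [0, Nyquist].
#' @return Object of class \code{"tf_map"}: list with \code{time},
#'   \code{frequency} and the nonnegative density matrix \code{energy}
#'   (frequency x time, microvolts squared per second per Hz).
#' @export
energy_map <- function(decomposition, t_grid = NULL, f_grid = NULL,
                       channel = 1L, trial = 1L) {
  stopifnot(inherits(decomposition, "mp_decomposition"))
  fs <- decomposition$config$fs
  n <- decomposition$config$n_samples
  if (is.null(t_grid))
    t_grid <- seq(0, (n - 1) / fs, length.out = min(n, 256L))
  if (is.null(f_grid))
    f_grid <- seq(0, fs / 2, length.out = 129L)
  if (any(t_grid < 0 | t_grid > (n - 1) / fs))
    stop("energy_map: time grid outside the epoch")
  if (any(f_grid < 0 | f_grid > fs / 2))
    stop("energy_map: frequency grid beyond the Nyquist frequency")
  E <- matrix(0, length(f_grid), length(t_grid))
  m <- nrow(decomposition$params)
  tsamp <- t_grid * fs                    # samples
  nu <- 2 * pi * f_grid / fs              # radians/sample
  for (q in seq_len(m)) {
    p <- decomposition$params[q, ]
    w2 <- decomposition$weights[q, channel, trial]^2
    if (w2 == 0) next
    if (p$family == "gabor" || p$family == "gaussian") {
      tf <- exp(-2 * pi * ((tsamp - p$u) / p$s)^2)
      w0 <- if (p$family == "gabor") p$omega else 0
      ff <- exp(-p$s^2 * (nu - w0)^2 / (2 * pi))
      fold <- if (p$family == "gaussian") 2 else 1
      E <- E + (2 * fold * w2) * (ff %o% tf)
    } else if (p$family == "delta") {
      sd_t <- 0.5 / fs
      tf <- stats::dnorm(t_grid, mean = p$u / fs, sd = sd_t)
      E <- E + w2 * (rep(1 / (fs / 2), length(nu)) %o% tf)
    } else if (p$family == "harmonic") {
      f0 <- p$omega * fs / (2 * pi)
      sd_f <- fs / (2 * sqrt(pi) * n)
      ff <- stats::dnorm(f_grid, mean = f0, sd = sd_f)
      E <- E + w2 * (ff %o% rep(fs / n, length(t_grid)))
    }
  }
  structure(list(time = t_grid, frequency = f_grid, energy = E),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("tf_map: %d frequencies x %d time points, total energy %.4g\n",
              length(x$frequency), length(x$time), .map_integral(x)))
  invisible(x)
}

# trapezoidal integral of the map over both axes
.map_integral <- function(map) {
  trap <- function(y, x) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  per_t <- apply(map$energy, 2, trap, x = map$frequency)
  trap(per_t, map$time)
}

#' Export a time-frequency map as delimited text
#'
#' Tab-separated matrix with the time axis in the header row and the
#' frequency axis in the first column.
#'
#' @param map a \code{\link{energy_map}} result.
#' @param path output file.
#' @export
write_tf_map <- function(map, path) {
  stopifnot(inherits(map, "tf_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("frequency_hz\\time_s",
                     sprintf("%.10g", map$time)), collapse = "\t"), con)
  for (r in seq_along(map$frequency))
    writeLines(paste(c(sprintf("%.10g", map$frequency[r]),
                       sprintf("%.10g", map$energy[r, ])),
                     collapse = "\t"), con)
  invisible(map)
}
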