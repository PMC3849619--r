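# Synthetic-signal generator: ground-truth atoms plus white Gaussian
# noise, with a sleep-EEG-like preset (one slow wave, two spindles).
# All test inputs of the package are synthesized here.

#' Specification of a synthetic epoch
#'
#' Ground-truth atoms are given in physical units: center \code{u_s}
#' and width \code{width_s} in seconds, frequency \code{f_hz} in Hz,
#' phase in radians, amplitude \code{p2p} as peak-to-peak microvolts
#' (the EEG convention; the mathematical amplitude is half of it).
#' Per-channel/per-trial amplitudes may be supplied as an array;
#' negative values flip the atom.
#'
#' @param atoms data frame with columns \code{family} (default
#'   "gabor"), \code{u_s}, \code{f_hz}, \code{width_s}, \code{phi},
#'   \code{p2p}.
#' @param n_samples,fs epoch length (samples) and sampling rate (Hz).
#' @param n_channels,n_trials dimensions of the generated block.
#' @param amplitudes optional array (atoms x channels x trials) of
#'   peak-to-peak amplitudes overriding \code{atoms$p2p}.
#' @param noise_sigma standard deviation of the added white Gaussian
#'   noise, microvolts.
#' @param seed RNG seed (generation is reproducible).
#' @return Object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(atoms, n_samples, fs, n_channels = 1L,
                           n_trials = 1L, amplitudes = NULL,
                           noise_sigma = 0, seed = 1L) {
  stopifnot(is.data.frame(atoms),
            all(c("u_s", "f_hz", "width_s", "phi", "p2p") %in% names(atoms)))
  if (is.null(atoms$family)) atoms$family <- "gabor"
  if (is.null(amplitudes))
    amplitudes <- array(rep(atoms$p2p, n_channels * n_trials),
                        c(nrow(atoms), n_channels, n_trials))
  stopifnot(all(dim(amplitudes) == c(nrow(atoms), n_channels, n_trials)),
            noise_sigma >= 0)
  structure(list(atoms = atoms, n_samples = as.integer(n_samples),
                 fs = fs, n_channels = as.integer(n_channels),
                 n_trials = as.integer(n_trials),
                 amplitudes = amplitudes, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sleep-EEG-like preset: one slow wave and two spindles
#'
#' One 1.5 Hz / 60 uV(peak-to-peak) / 1.2 s slow-wave atom centered
#' mid-epoch and two spindle atoms of 0.8 s and 30 uV peak-to-peak at
#' 12.5 and 13.5 Hz, in a 4 s epoch.  Distinct spindles in real sleep
#' EEG carry distinct instantaneous frequencies; identical carriers at
#' a separation of a whole number of periods would make the two bursts
#' mutually coherent, a degenerate scenario the preset does not
#' emulate.
#'
#' @param fs sampling rate (Hz).
#' @param n_samples epoch length.
#' @param noise_sigma white-noise standard deviation, microvolts.
#' @param seed RNG seed.
#' @return A \code{\link{synthetic_spec}}.
#' @export
sleep_preset_spec <- function(fs = 64, n_samples = 256, noise_sigma = 0,
                              seed = 1L) {
  atoms <- data.frame(
    family = "gabor",
    u_s = c(2.0, 1.0, 3.0),
    f_hz = c(1.5, 12.5, 13.5),
    width_s = c(1.2, 0.8, 0.8),
    phi = c(0.4, 1.1, 2.3),
    p2p = c(60, 30, 30),
    stringsAsFactors = FALSE)
  synthetic_spec(atoms, n_samples, fs, noise_sigma = noise_sigma,
                 seed = seed)
}

# ground-truth weight for a requested peak-to-peak amplitude
.truth_weight <- function(family, u, omega, s, phi, n, p2p) {
  wave <- .atom_waveform(family, u, omega, s, phi, n)
  (p2p / 2) / max(abs(wave))
}

#' Generate a synthetic epoch block from a specification
#'
#' Sums the specified unit-norm atoms weighted to reach their requested
#' peak-to-peak amplitudes, then adds white Gaussian noise.  The
#' ground-truth record (sample-domain parameters and weights actually
#' used) is returned beside the signal.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return List with \code{matrix} (a \code{\link{trial_matrix}}) and
#'   \code{truth} (data frame: family, u, omega, s, phi, weight per
#'   channel/trial as an attached array \code{weights}).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; fs <- spec$fs
  nc <- spec$n_channels; nk <- spec$n_trials
  na <- nrow(spec$atoms)
  arr <- array(0, c(nc, nk, n))
  truth <- data.frame(family = spec$atoms$family,
                      u = spec$atoms$u_s * fs,
                      omega = 2 * pi * spec$atoms$f_hz / fs,
                      s = spec$atoms$width_s * fs,
                      phi = spec$atoms$phi,
                      stringsAsFactors = FALSE)
  wts <- array(0, c(na, nc, nk))
  for (q in seq_len(na)) {
    tr <- truth[q, ]
    wave <- .atom_waveform(tr$family, tr$u, tr$omega, tr$s, tr$phi, n)
    wmax <- max(abs(wave))
    for (k in seq_len(nk)) for (i in seq_len(nc)) {
      w <- (spec$amplitudes[q, i, k] / 2) / wmax
      wts[q, i, k] <- w
      arr[i, k, ] <- arr[i, k, ] + w * wave
    }
  }
  if (spec$noise_sigma > 0)
    arr <- arr + .with_seed(spec$seed,
                            array(stats::rnorm(length(arr),
                                               sd = spec$noise_sigma),
                                  dim(arr)))
  attr(truth, "weights") <- wts
  list(matrix = trial_matrix(arr, fs = fs),
       truth = truth)
}

#' Noise level for a nominal signal-to-noise ratio
#'
#' Standard deviation of the white noise such that the expected noise
#' energy is \code{10^(-snr_db/10)} times the energy of the clean
#' (noise-free) realization of the specification.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param snr_db target SNR in decibels.
#' @return Noise standard deviation in microvolts.
#' @export
noise_sigma_for_snr <- function(spec, snr_db) {
  clean <- spec
  clean$noise_sigma <- 0
  x <- generate_synthetic(clean)$matrix$data
  sqrt(sum(x^2) / length(x) / 10^(snr_db / 10))
}
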