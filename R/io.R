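# File formats: raw float32 epochs with sidecar text headers,
# delimited-text epochs, and the structured text book format with full
# provenance.  Readers reject malformed input rather than guessing.

.hdr_path <- function(path) paste0(path, ".hdr")

.write_header <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("n_samples: %d", h$n_samples),
    sprintf("n_channels: %d", h$n_channels),
    sprintf("n_trials: %d", h$n_trials),
    sprintf("fs: %.17g", h$fs),
    sprintf("calibration: %.17g", h$calibration),
    sprintf("labels: %s", paste(h$labels, collapse = ",")),
    sprintf("montage: %s", h$montage),
    sprintf("encoding: %s", h$encoding)), con)
}

.read_header <- function(path) {
  if (!file.exists(path))
    stop("read_epoch: missing sidecar header ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^([a-z_]+):[ \t]*(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("read_epoch: malformed header line: ", lines[bad][1])
  h <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  need <- c("n_samples", "n_channels", "n_trials", "fs", "calibration",
            "encoding")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("read_epoch: header lacks field(s): ",
                         paste(miss, collapse = ", "))
  list(n_samples = as.integer(h$n_samples),
       n_channels = as.integer(h$n_channels),
       n_trials = as.integer(h$n_trials),
       fs = as.numeric(h$fs), calibration = as.numeric(h$calibration),
       labels = if (is.null(h$labels)) NULL
                else strsplit(h$labels, ",")[[1]],
       montage = h$montage %||% "unspecified",
       encoding = h$encoding)
}

#' Write an epoch block to disk
#'
#' Two encodings share the same sidecar text header
#' (\code{<path>.hdr}): \code{"float32le"}, raw little-endian float32,
#' multiplexed channel-fastest (channels within a sample, samples
#' within a trial, trials concatenated), and \code{"text"}, whitespace
#' separated with one column per channel and the trials stacked in
#' rows.  File values are raw (divided by the calibration);
#' \code{\link{read_epoch}} restores calibrated microvolts.
#'
#' @param matrix a \code{\link{trial_matrix}}.
#' @param path data file path.
#' @param encoding \code{"float32le"} or \code{"text"}.
#' @export
write_epoch <- function(matrix, path, encoding = c("float32le", "text")) {
  stopifnot(inherits(matrix, "trial_matrix"))
  encoding <- match.arg(encoding)
  d <- dim(matrix$data)
  h <- list(n_samples = d[3], n_channels = d[1], n_trials = d[2],
            fs = matrix$fs, calibration = matrix$calibration,
            labels = matrix$labels, montage = matrix$montage,
            encoding = encoding)
  raw_vals <- matrix$data / matrix$calibration
  # channel-fastest flattening: for each trial, channels x time
  flat <- unlist(lapply(seq_len(d[2]), function(k)
    as.vector(raw_vals[, k, , drop = FALSE][, 1, ])), use.names = FALSE)
  .write_header(h, .hdr_path(path))
  if (encoding == "float32le") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(flat, con, size = 4L, endian = "little")
  } else {
    m <- base::matrix(flat, nrow = d[1])       # channels x (time*trials)
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(t(signif(m, 9)), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(matrix)
}

#' Read an epoch block
#'
#' @param path data file path (sidecar header \code{<path>.hdr}, unless
#'   an explicit header list is supplied).
#' @param header optional header list overriding the sidecar (fields as
#'   written by \code{\link{write_epoch}}).
#' @return A calibrated \code{\link{trial_matrix}}.
#' @export
read_epoch <- function(path, header = NULL) {
  h <- if (is.null(header)) .read_header(.hdr_path(path)) else header
  nvals <- h$n_samples * h$n_channels * h$n_trials
  if (h$encoding == "float32le") {
    sz <- file.info(path)$size
    if (is.na(sz) || sz != 4 * nvals)
      stop(sprintf("read_epoch: size mismatch: expected %d samples (%d bytes), found %d bytes",
                   nvals, 4 * nvals, if (is.na(sz)) 0 else sz))
    con <- file(path, "rb")
    on.exit(close(con))
    flat <- readBin(con, "numeric", n = nvals, size = 4L,
                    endian = "little")
  } else if (h$encoding == "text") {
    m <- as.matrix(utils::read.table(path))
    if (length(m) != nvals || ncol(m) != h$n_channels)
      stop(sprintf("read_epoch: size mismatch: expected %d x %d values, found %d x %d",
                   h$n_samples * h$n_trials, h$n_channels, nrow(m), ncol(m)))
    flat <- as.vector(t(m))
  } else stop("read_epoch: unknown encoding ", h$encoding)
  if (!all(is.finite(flat))) stop("read_epoch: non-finite samples")
  arr <- array(0, c(h$n_channels, h$n_trials, h$n_samples))
  for (k in seq_len(h$n_trials)) {
    block <- flat[((k - 1) * h$n_channels * h$n_samples + 1):
                    (k * h$n_channels * h$n_samples)]
    arr[, k, ] <- base::matrix(block, nrow = h$n_channels)
  }
  trial_matrix(arr, fs = h$fs, calibration = h$calibration,
               labels = h$labels, montage = h$montage)
}

#' Write a decomposition ("book") as structured text
#'
#' Header lines (\code{# key: value}) carry the full provenance
#' (epsilon, dilation factor, dictionary type, seed, families, stopping
#' rule, sampling rate, calibration, variant, energies); the body is a
#' tab-separated table with one record per atom and channel/trial:
#' iteration, family, u (samples), f (Hz), omega (radians/sample,
#' authoritative), s (samples), channel, trial, weight, phase, all
#' numeric fields at 17 significant digits (lossless round trip).
#'
#' @param decomposition an \code{mp_decomposition}.
#' @param path output file.
#' @export
write_book <- function(decomposition, path) {
  stopifnot(inherits(decomposition, "mp_decomposition"))
  cfg <- decomposition$config
  con <- file(path, "w")
  on.exit(close(con))
  hl <- function(k, v) writeLines(sprintf("# %s: %s", k, v), con)
  hl("format", "gaborpursuit-book-1")
  hl("epsilon", sprintf("%.17g", cfg$epsilon))
  hl("a", sprintf("%.17g", cfg$a))
  hl("dict_type", cfg$dict_type)
  hl("percentage_chosen", sprintf("%.17g", cfg$percentage_chosen))
  hl("seed", sprintf("%d", cfg$seed))
  hl("include_families", paste(cfg$include_families, collapse = ","))
  hl("n_samples", sprintf("%d", cfg$n_samples))
  hl("n_channels", sprintf("%d", cfg$n_channels))
  hl("n_trials", sprintf("%d", cfg$n_trials))
  hl("max_iterations", sprintf("%d", cfg$max_iterations))
  hl("energy_percent", sprintf("%.17g", cfg$energy_percent))
  hl("fs", sprintf("%.17g", cfg$fs))
  hl("calibration", sprintf("%.17g", cfg$calibration))
  hl("variant", cfg$variant)
  hl("energy0", sprintf("%.17g", decomposition$energy0))
  hl("residual_energy",
     paste(sprintf("%.17g", decomposition$residual_energy), collapse = ","))
  writeLines(paste(c("iteration", "family", "u", "f_hz", "omega", "s",
                     "channel", "trial", "weight", "phase"),
                   collapse = "\t"), con)
  m <- nrow(decomposition$params)
  nc <- cfg$n_channels; nk <- cfg$n_trials
  for (q in seq_len(m)) {
    p <- decomposition$params[q, ]
    for (k in seq_len(nk)) for (i in seq_len(nc)) {
      writeLines(paste(c(
        sprintf("%d", p$iteration), p$family,
        sprintf("%.17g", p$u),
        sprintf("%.17g", if (is.na(p$omega)) NA else p$omega * cfg$fs / (2 * pi)),
        sprintf("%.17g", p$omega), sprintf("%.17g", p$s),
        sprintf("%d", i), sprintf("%d", k),
        sprintf("%.17g", decomposition$weights[q, i, k]),
        sprintf("%.17g", decomposition$phases[q, i, k])),
        collapse = "\t"), con)
    }
  }
  invisible(decomposition)
}

#' Read a book written by \code{\link{write_book}}
#'
#' Books without the provenance header are rejected.
#'
#' @param path book file.
#' @return An \code{mp_decomposition} (without residual waveforms).
#' @export
read_book <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(hdr_lines, regexec("^# ([a-z_0-9]+): ?(.*)$", hdr_lines))
  h <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  if (!identical(h$format, "gaborpursuit-book-1"))
    stop("read_book: missing or unknown provenance header")
  need <- c("epsilon", "a", "dict_type", "seed", "n_samples", "n_channels",
            "n_trials", "fs", "calibration", "variant", "energy0",
            "residual_energy", "max_iterations", "energy_percent")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("read_book: provenance header lacks field(s): ",
         paste(miss, collapse = ", "))
  body <- lines[!grepl("^# ", lines)]
  body <- body[nzchar(body)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  nc <- as.integer(h$n_channels); nk <- as.integer(h$n_trials)
  iter <- sort(unique(tab$iteration))
  m <- length(iter)
  first <- tab[!duplicated(tab$iteration), ]
  first <- first[order(first$iteration), ]
  params <- data.frame(iteration = first$iteration, family = first$family,
                       u = first$u, omega = first$omega, s = first$s,
                       stringsAsFactors = FALSE)
  weights <- array(0, c(m, nc, nk)); phases <- array(0, c(m, nc, nk))
  for (r in seq_len(nrow(tab))) {
    q <- match(tab$iteration[r], iter)
    weights[q, tab$channel[r], tab$trial[r]] <- tab$weight[r]
    phases[q, tab$channel[r], tab$trial[r]] <- tab$phase[r]
  }
  cfg <- list(epsilon = as.numeric(h$epsilon), a = as.numeric(h$a),
              dict_type = h$dict_type,
              percentage_chosen = as.numeric(h$percentage_chosen %||% 100),
              seed = as.integer(h$seed),
              include_families = strsplit(h$include_families %||% "", ",")[[1]],
              n_samples = as.integer(h$n_samples),
              max_iterations = as.integer(h$max_iterations),
              energy_percent = as.numeric(h$energy_percent),
              fs = as.numeric(h$fs),
              calibration = as.numeric(h$calibration),
              variant = h$variant, n_channels = nc, n_trials = nk)
  .new_decomposition(params, weights, phases,
                     as.numeric(strsplit(h$residual_energy, ",")[[1]]),
                     as.numeric(h$energy0), cfg, residuals = NULL)
}
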