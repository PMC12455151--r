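#' Epoched multichannel signal container
#'
#' An `epoch_array` holds trials x channels x samples data together with its
#' sampling rate, event-relative time axis and channel metadata. It is the
#' common currency passed between the synthetic generator, the time-frequency
#' stage, the permutation statistics and the beamformers.
#'
#' @param data numeric array, trials x channels x samples.
#' @param sfreq sampling frequency in Hz.
#' @param t0 time (s) of the first sample relative to the event (cue onset).
#' @param channels character vector of channel names; defaults to
#'   `ch01, ch02, ...`.
#' @param coords optional channels x 3 matrix of sensor positions.
#' @return an object of class `epoch_array` with elements `data`, `sfreq`,
#'   `times`, `channels`, `coords`.
#' @examples
#' ea <- epoch_array(array(rnorm(2 * 3 * 8), c(2, 3, 8)), sfreq = 8, t0 = -0.5)
#' dim(ea$data)
#' @export
epoch_array <- function(data, sfreq, t0 = 0, channels = NULL, coords = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x samples)")
  }
  if (!is.numeric(sfreq) || sfreq <= 0) stop("`sfreq` must be positive")
  n_ch <- dim(data)[2L]
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(n_ch))
  if (length(channels) != n_ch) stop("`channels` length does not match data")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n_ch || ncol(coords) != 3L) {
      stop("`coords` must be channels x 3")
    }
  }
  times <- t0 + (seq_len(dim(data)[3L]) - 1L) / sfreq
  structure(
    list(data = data, sfreq = sfreq, times = times,
         channels = channels, coords = coords),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_array> %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
    d[1], d[2], d[3], x$sfreq, x$times[1], x$times[length(x$times)]
  ))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

#' Time-frequency power container
#'
#' Holds power values (trials x channels x frequencies x times, or with the
#' trial dimension averaged out) plus the frequency axis and a per-frequency,
#' per-time validity mask marking samples contaminated by wavelet edge
#' effects.
#'
#' @param power numeric 4-d array trials x channels x freqs x times (use a
#'   leading dimension of 1 for trial-averaged maps).
#' @param freqs frequencies (Hz) of the third dimension.
#' @param times time axis (s) of the fourth dimension.
#' @param sfreq sampling frequency in Hz.
#' @param valid logical freqs x times matrix; FALSE marks edge-contaminated
#'   samples. Defaults to all TRUE.
#' @param channels optional channel names.
#' @return an object of class `tf_power`.
#' @export
tf_power <- function(power, freqs, times, sfreq, valid = NULL, channels = NULL) {
  if (length(dim(power)) != 4L) {
    stop("`power` must be 4-d (trials x channels x freqs x times)")
  }
  if (dim(power)[3L] != length(freqs)) stop("freqs length mismatch")
  if (dim(power)[4L] != length(times)) stop("times length mismatch")
  if (is.null(valid)) {
    valid <- matrix(TRUE, length(freqs), length(times))
  }
  structure(
    list(power = power, freqs = freqs, times = times, sfreq = sfreq,
         valid = valid, channels = channels),
    class = "tf_power"
  )
}

#' @export
print.tf_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tf_power> %d trials x %d channels x %d freqs x %d times (%g-%g Hz)\n",
    d[1], d[2], d[3], d[4], min(x$freqs), max(x$freqs)
  ))
  invisible(x)
}

#' Read / write a trial table as CSV
#'
#' The on-disk format is a plain CSV with header columns
#' `block, condition, validity, cue_loc, target_loc, target, response,
#' correct, rt_ms`.
#'
#' @param table a trial-table data.frame.
#' @param path file path.
#' @return `read_trial_table` returns the data.frame; `write_trial_table`
#'   returns `path` invisibly.
#' @export
write_trial_table <- function(table, path) {
  req <- c("block", "condition", "validity", "cue_loc", "target_loc",
           "target", "response", "correct", "rt_ms")
  missing <- setdiff(req, names(table))
  if (length(missing)) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  }
  utils::write.csv(table[req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$correct <- as.integer(tab$correct)
  tab
}

#' Persist an epoch array to disk
#'
#' Byte layout: the numeric data are written to `<path>.dat` as IEEE-754
#' little-endian float64 in R's native column-major order, i.e. the trial
#' index varies fastest, then channel, then sample. The sidecar
#' `<path>.json` records `dims` (trials, channels, samples), `sfreq`, `t0`,
#' `channels` and optional `coords`.
#'
#' @param x an `epoch_array`.
#' @param path base path without extension.
#' @return `read_epochs` returns the `epoch_array`; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_array"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(x$data), con, size = 8L, endian = "little")
  meta <- list(dims = dim(x$data), sfreq = x$sfreq, t0 = x$times[1],
               channels = x$channels)
  if (!is.null(x$coords)) meta$coords <- unname(x$coords)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(dims), size = 8L, endian = "little")
  coords <- if (!is.null(meta$coords)) matrix(as.numeric(meta$coords), ncol = 3) else NULL
  epoch_array(array(vals, dims), sfreq = meta$sfreq, t0 = meta$t0,
              channels = meta$channels, coords = coords)
}

# internal: deterministic per-stage seed fan-out from a master seed.
# stage index k maps to master*97 + k, folded into [0, 2^31) so set.seed()
# always receives a valid 32-bit integer.
stage_seed <- function(master, k) {
  as.integer((as.numeric(master) * 97 + k) %% 2147483647)
}
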