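#' Morlet wavelet specification
#'
#' A fixed-cycles complex Morlet family: at frequency f the Gaussian
#' envelope has temporal SD `sigma_t = n_cycles / (2 * pi * f)` and spectral
#' SD `sigma_f = f / n_cycles`. With the conventional 5 cycles, a spectral
#' bandwidth of 3 Hz corresponds to f = 15 Hz and a time resolution of
#' 53 ms.
#'
#' @param frequencies analysis frequencies in Hz (default 1-Hz steps,
#'   4-12 Hz, covering theta 4-7 and alpha 8-12).
#' @param n_cycles number of cycles (>= 1).
#' @param sfreq sampling frequency in Hz.
#' @return a `morlet_spec` list.
#' @export
morlet_spec <- function(frequencies = 4:12, n_cycles = 5, sfreq = 256) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (any(frequencies <= 0) || any(frequencies >= sfreq / 2)) {
    stop("frequencies must lie in (0, sfreq/2)")
  }
  structure(list(frequencies = frequencies, n_cycles = n_cycles, sfreq = sfreq),
            class = "morlet_spec")
}

#' Morlet temporal / spectral resolution
#'
#' @param f frequency in Hz.
#' @param n_cycles number of cycles.
#' @return `morlet_sigma_t` gives the envelope temporal SD in seconds;
#'   `morlet_sigma_f` the spectral SD in Hz.
#' @examples
#' morlet_sigma_t(15, 5) * 1000  # ~53 ms
#' @export
morlet_sigma_t <- function(f, n_cycles = 5) n_cycles / (2 * pi * f)

#' @rdname morlet_sigma_t
#' @export
morlet_sigma_f <- function(f, n_cycles = 5) f / n_cycles

#' Baseline-correction specification
#'
#' @param window baseline window in seconds, strictly pre-event.
#' @param mode only `absolute_subtract` is implemented: the mean baseline
#'   power (per trial, channel and frequency) is subtracted at every time
#'   point.
#' @return a `baseline_spec` list.
#' @export
baseline_spec <- function(window = c(-0.2, 0), mode = "absolute_subtract") {
  if (window[2] > 0 || window[1] >= window[2]) {
    stop("baseline window must precede the event (t <= 0)")
  }
  mode <- match.arg(mode, "absolute_subtract")
  structure(list(window = window, mode = mode), class = "baseline_spec")
}

#' Cut event-locked epochs from continuous data
#'
#' @param x channels x samples matrix of continuous data.
#' @param sfreq sampling frequency in Hz.
#' @param events event sample indices (1-based) marking t = 0.
#' @param window epoch window in seconds relative to each event.
#' @param channels,coords optional channel metadata.
#' @return an [epoch_array()]; events too close to the recording edge are
#'   dropped and listed in attribute `dropped_events`.
#' @export
epoch <- function(x, sfreq, events, window = c(-2, 2), channels = NULL,
                  coords = NULL) {
  x <- as.matrix(x)
  n_samp <- ncol(x)
  offs <- seq(round(window[1] * sfreq), round(window[2] * sfreq) - 1L)
  ok <- vapply(events, function(e) {
    e + offs[1] >= 1 && e + offs[length(offs)] <= n_samp
  }, logical(1))
  if (!any(ok)) stop("no event has enough surrounding data for the window")
  kept <- events[ok]
  out <- array(0, c(length(kept), nrow(x), length(offs)))
  for (i in seq_along(kept)) out[i, , ] <- x[, kept[i] + offs, drop = FALSE]
  ea <- epoch_array(out, sfreq = sfreq, t0 = offs[1] / sfreq,
                    channels = channels, coords = coords)
  attr(ea, "dropped_events") <- events[!ok]
  ea
}

#' Morlet wavelet time-frequency power
#'
#' Convolves every trial and channel with unit-energy complex Morlet
#' wavelets and returns squared magnitudes. Power is therefore in squared
#' input units, and the expected power of white noise is flat across
#' frequencies. Samples closer than `3 * sigma_t` to either epoch edge are
#' flagged invalid in the output's `valid` mask.
#'
#' @param epochs an [epoch_array()].
#' @param spec a [morlet_spec()] (its `sfreq` must match the epochs).
#' @return a [tf_power()] (trials x channels x freqs x times).
#' @export
morlet_power <- function(epochs, spec = morlet_spec(sfreq = epochs$sfreq)) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(spec, "morlet_spec"))
  if (abs(spec$sfreq - epochs$sfreq) > 1e-9) {
    stop("spec$sfreq does not match the epochs")
  }
  d <- dim(epochs$data)
  n_t <- d[3]
  sf <- spec$sfreq
  kernels <- lapply(spec$frequencies, function(f) morlet_kernel(f, spec$n_cycles, sf))
  max_half <- max(vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1)))
  if (2 * max_half + 1 > n_t) {
    stop(sprintf(
      "lowest frequency %.3g Hz needs a %d-sample kernel; epoch has only %d samples",
      min(spec$frequencies), 2 * max_half + 1, n_t))
  }
  n_fft <- stats::nextn(n_t + 2 * max_half, 2)
  # one forward FFT per trial x channel, reused across frequencies
  sig <- matrix(0, n_fft, d[1] * d[2])
  sig[seq_len(n_t), ] <- matrix(aperm(epochs$data, c(3, 1, 2)), n_t, d[1] * d[2])
  SIG <- stats::mvfft(sig)
  pow <- array(0, c(d[1], d[2], length(spec$frequencies), n_t))
  valid <- matrix(TRUE, length(spec$frequencies), n_t)
  for (fi in seq_along(kernels)) {
    k <- kernels[[fi]]
    half <- (length(k) - 1L) %/% 2L
    kpad <- complex(length.out = n_fft)
    kpad[seq_along(k)] <- k
    K <- stats::fft(kpad)
    conv <- stats::mvfft(SIG * K, inverse = TRUE) / n_fft
    # centre of the kernel aligns with the sample: take rows half+1 .. half+n_t
    seg <- conv[(half + 1):(half + n_t), , drop = FALSE]
    pow[, , fi, ] <- aperm(array(Mod(seg)^2, c(n_t, d[1], d[2])), c(2, 3, 1))
    edge <- ceiling(3 * morlet_sigma_t(spec$frequencies[fi], spec$n_cycles) * sf)
    if (edge >= 1) {
      valid[fi, seq_len(min(edge, n_t))] <- FALSE
      valid[fi, seq.int(max(1L, n_t - edge + 1L), n_t)] <- FALSE
    }
  }
  tf_power(pow, freqs = spec$frequencies, times = epochs$times, sfreq = sf,
           valid = valid, channels = epochs$channels)
}

# unit-energy complex Morlet kernel at frequency f
morlet_kernel <- function(f, n_cycles, sfreq) {
  sigma_t <- morlet_sigma_t(f, n_cycles)
  half <- ceiling(4 * sigma_t * sfreq)
  t <- (-half:half) / sfreq
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  k / sqrt(sum(Mod(k)^2))
}

#' Baseline-correct a time-frequency map
#'
#' Subtracts, for every trial, channel and frequency, the mean power over
#' the baseline window from all time points (absolute subtraction).
#'
#' @param tf a [tf_power()].
#' @param spec a [baseline_spec()].
#' @return the corrected [tf_power()].
#' @export
baseline_correct <- function(tf, spec = baseline_spec()) {
  stopifnot(inherits(tf, "tf_power"), inherits(spec, "baseline_spec"))
  in_win <- tf$times >= spec$window[1] & tf$times <= spec$window[2]
  if (!any(in_win)) stop("baseline window contains no samples")
  for (fi in seq_along(tf$freqs)) {
    use <- in_win & tf$valid[fi, ]
    if (!any(use)) {
      stop(sprintf("baseline window fully edge-contaminated at %.3g Hz",
                   tf$freqs[fi]))
    }
    base <- apply(tf$power[, , fi, use, drop = FALSE], c(1, 2), mean)
    tf$power[, , fi, ] <- tf$power[, , fi, , drop = FALSE] -
      array(base, c(dim(base), 1L, dim(tf$power)[4]))
  }
  tf
}

#' Average power over a frequency band and time window
#'
#' @param tf a [tf_power()].
#' @param band length-2 Hz range (inclusive); canonical choices are theta
#'   `c(4, 7)` and alpha `c(8, 12)`.
#' @param window length-2 time range in seconds (inclusive); only samples
#'   valid at every selected frequency are used.
#' @return trials x channels matrix of mean power.
#' @export
band_window_average <- function(tf, band = c(4, 7), window = c(0, 1)) {
  stopifnot(inherits(tf, "tf_power"))
  fsel <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  if (!length(fsel)) stop("no frequencies inside the requested band")
  tsel_raw <- tf$times >= window[1] & tf$times <= window[2]
  valid_all <- apply(tf$valid[fsel, , drop = FALSE], 2, all)
  tsel <- which(tsel_raw & valid_all)
  if (!length(tsel)) {
    stop("requested window has no samples valid at all band frequencies")
  }
  apply(tf$power[, , fsel, tsel, drop = FALSE], c(1, 2), mean)
}
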