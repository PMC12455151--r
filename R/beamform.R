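#' Trial-averaged cross-spectral density
#'
#' Windows each trial to `window` (default 0-600 ms after the event),
#' applies a Hann taper, Fourier-transforms every channel and averages the
#' cross-products over all frequency bins inside `band` and over trials.
#' The result is Hermitian and positive semi-definite by construction.
#'
#' @param epochs an [epoch_array()].
#' @param band length-2 Hz range.
#' @param window length-2 time range in seconds.
#' @param taper `"hann"` or `"none"`.
#' @return a `csd_matrix`: list with complex `C` (channels x channels),
#'   `band`, `freqs` (bins used), `window`, `n_trials` and
#'   `force_regularisation` (TRUE when trials < channels, which makes the
#'   sample CSD rank-deficient).
#' @export
estimate_csd <- function(epochs, band, window = c(0, 0.6),
                         taper = c("hann", "none")) {
  stopifnot(inherits(epochs, "epoch_array"))
  taper <- match.arg(taper)
  sel <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(sel)) stop("window lies outside the epochs")
  n_w <- length(sel)
  d <- dim(epochs$data)
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * (seq_len(n_w) - 1) / (n_w - 1))) else rep(1, n_w)
  freqs <- (seq_len(n_w) - 1) * epochs$sfreq / n_w
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(bins)) stop("no FFT bins inside the requested band")
  C <- matrix(0 + 0i, d[2], d[2])
  for (tr in seq_len(d[1])) {
    seg <- epochs$data[tr, , sel, drop = TRUE]
    if (d[2] == 1L) seg <- matrix(epochs$data[tr, , sel], 1, n_w)
    seg <- sweep(seg, 2, w, `*`)
    X <- t(stats::mvfft(t(seg)))  # channels x freq bins
    for (b in bins) C <- C + X[, b] %*% Conj(t(X[, b]))
  }
  C <- C / (d[1] * length(bins) * n_w)
  force_reg <- d[1] < d[2]
  if (force_reg) {
    warning("fewer trials than channels: CSD is rank-deficient, ",
            "regularisation will be forced in the beamformer")
  }
  structure(list(C = C, band = band, freqs = freqs[bins], window = window,
                 n_trials = d[1], force_regularisation = force_reg),
            class = "csd_matrix")
}

# unit-gain minimum-variance weights for one leadfield column
mv_weights <- function(Cinv, l) {
  num <- Cinv %*% l
  den <- Re(crossprod(l, num))[1, 1]
  if (den <= 0) stop("leadfield column lies in the null space of the matrix")
  num / den
}

#' DICS source power
#'
#' Frequency-domain beamforming: for each source with leadfield column l,
#' the unit-gain minimum-variance filter is
#' `w = C^-1 l / (l^T C^-1 l)` with `C = CSD + lambda * mean(diag(CSD)) * I`,
#' and the source power is `Re(w^H C_apply w)`. Passing `apply_to` projects
#' a common filter (built from, e.g., condition-concatenated data) onto a
#' per-condition CSD.
#'
#' @param csd a [estimate_csd()] result (or any `csd_matrix`).
#' @param leadfield sources x channels gain matrix.
#' @param lambda regularisation as a fraction of mean sensor power
#'   (default 0.05).
#' @param apply_to optional second `csd_matrix` to which the filters are
#'   applied; defaults to `csd` itself.
#' @return list with `power` (per source), `filters` (sources x channels
#'   complex matrix) and `lambda_abs` (absolute ridge added).
#' @export
dics_source_power <- function(csd, leadfield, lambda = 0.05, apply_to = NULL) {
  stopifnot(inherits(csd, "csd_matrix"))
  leadfield <- as.matrix(leadfield)
  C0 <- csd$C
  if (max(Mod(C0 - Conj(t(C0)))) > 1e-8 * max(1, max(Mod(C0)))) {
    stop("CSD must be Hermitian")
  }
  n_ch <- ncol(C0)
  if (ncol(leadfield) != n_ch) stop("leadfield channels do not match CSD")
  lam_abs <- lambda * mean(Re(diag(C0)))
  C <- C0 + diag(lam_abs, n_ch)
  if (lambda == 0 && (csd$force_regularisation || rcond_herm(C) < 1e-12)) {
    stop("CSD is singular; a positive lambda is required")
  }
  Cinv <- solve(C)
  Ca <- if (is.null(apply_to)) C0 else apply_to$C
  n_src <- nrow(leadfield)
  filters <- matrix(0 + 0i, n_src, n_ch)
  power <- numeric(n_src)
  for (s in seq_len(n_src)) {
    w <- mv_weights(Cinv, leadfield[s, ])
    filters[s, ] <- w
    power[s] <- Re(Conj(t(w)) %*% Ca %*% w)[1, 1]
  }
  list(power = power, filters = filters, lambda_abs = lam_abs)
}

rcond_herm <- function(C) {
  ev <- abs(eigen(C, only.values = TRUE)$values)
  min(ev) / max(ev)
}

#' LCMV spatial filters
#'
#' Time-domain analogue of [dics_source_power()]: unit-gain
#' minimum-variance filters from the real sensor covariance. A common
#' filter set can be computed once (e.g. from condition-concatenated data)
#' and reused across conditions.
#'
#' @param covariance channels x channels sensor covariance (PSD).
#' @param leadfield sources x channels gain matrix.
#' @param lambda ridge as a fraction of mean sensor power.
#' @return a `spatial_filter`: list with `weights` (sources x channels),
#'   `lambda_abs` and `constraint = "unit_gain"`. Each weight row w
#'   satisfies `w %*% l = 1` for its leadfield column l.
#' @export
lcmv_filters <- function(covariance, leadfield, lambda = 0.05) {
  covariance <- as.matrix(covariance)
  leadfield <- as.matrix(leadfield)
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance)))) {
    stop("covariance must be symmetric")
  }
  n_ch <- ncol(covariance)
  if (ncol(leadfield) != n_ch) stop("leadfield channels do not match covariance")
  lam_abs <- lambda * mean(diag(covariance))
  C <- covariance + diag(lam_abs, n_ch)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("covariance is rank-deficient; increase lambda")
  }
  Cinv <- solve(C)
  weights <- t(vapply(seq_len(nrow(leadfield)), function(s) {
    as.numeric(Re(mv_weights(Cinv, leadfield[s, ])))
  }, numeric(n_ch)))
  structure(list(weights = weights, lambda_abs = lam_abs,
                 constraint = "unit_gain"),
            class = "spatial_filter")
}

#' Top-percent source mask
#'
#' Selects the `ceiling(percent/100 * N)` highest-power sources; values
#' tied with the cut-off are all included, so the mask can exceed the
#' nominal count under ties.
#'
#' @param source_power numeric vector of source power values.
#' @param percent percentage of sources to keep.
#' @return logical mask over sources.
#' @examples
#' sum(top_percent_mask(runif(100), 5))  # 5 (absent ties)
#' @export
top_percent_mask <- function(source_power, percent = 5) {
  if (!length(source_power)) stop("empty power map")
  k <- ceiling(percent / 100 * length(source_power))
  k <- max(1L, min(k, length(source_power)))
  cutoff <- sort(source_power, decreasing = TRUE)[k]
  source_power >= cutoff
}

#' Reconstruct ROI source time courses
#'
#' Applies spatial filters to sensor epochs and returns one time course per
#' ROI. By default the ROI signal is the filter output at the ROI's
#' peak-power source (highest output variance across all trials);
#' `method = "pc1"` instead returns the first principal component of the
#' ROI's source outputs.
#'
#' @param epochs an [epoch_array()].
#' @param filters a [lcmv_filters()] result whose weights span the same
#'   channels.
#' @param roi list of integer vectors of source indices (one per ROI).
#' @param method `"peak"` or `"pc1"`.
#' @return trials x ROIs x samples array; the chosen peak source per ROI is
#'   attached as attribute `peak_sources` (NA under `"pc1"`).
#' @export
extract_roi_timecourses <- function(epochs, filters, roi,
                                    method = c("peak", "pc1")) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(filters, "spatial_filter"))
  method <- match.arg(method)
  if (!length(roi)) stop("empty ROI list")
  if (any(!vapply(roi, length, integer(1)))) stop("empty ROI")
  d <- dim(epochs$data)
  if (ncol(filters$weights) != d[2]) stop("filters and epochs disagree on channels")
  n_src <- nrow(filters$weights)
  src <- array(0, c(d[1], n_src, d[3]))
  for (tr in seq_len(d[1])) {
    sl <- matrix(epochs$data[tr, , ], d[2], d[3])
    src[tr, , ] <- filters$weights %*% sl
  }
  out <- array(0, c(d[1], length(roi), d[3]))
  peaks <- rep(NA_integer_, length(roi))
  for (r in seq_along(roi)) {
    ids <- roi[[r]]
    if (method == "peak") {
      v <- vapply(ids, function(s) stats::var(as.vector(src[, s, ])), numeric(1))
      peaks[r] <- ids[which.max(v)]
      out[, r, ] <- src[, peaks[r], ]
    } else {
      flat <- matrix(aperm(src[, ids, , drop = FALSE], c(1, 3, 2)),
                     d[1] * d[3], length(ids))
      pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)$x[, 1]
      out[, r, ] <- array(pc, c(d[1], d[3]))
    }
  }
  attr(out, "peak_sources") <- peaks
  out
}
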