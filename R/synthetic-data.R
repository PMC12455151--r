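#' Experimental design specification
#'
#' Describes a blocked spatial-cueing session: three uncertainty conditions
#' run as one block each, a fixed proportion of valid trials (cue and target
#' at the same location), four possible stimulus locations, and the epoching
#' parameters used for the simulated EEG.
#'
#' @param conditions condition labels, one block per condition.
#' @param trials_per_block trials in each block.
#' @param p_valid proportion of valid trials (0 < p_valid < 1, or exactly 1
#'   for degenerate all-valid designs used in testing).
#' @param n_locations number of peripheral stimulus locations.
#' @param sfreq sampling frequency (Hz) for simulated signals.
#' @param epoch_window epoch limits (s) relative to cue onset; must contain
#'   the analysis window \[-0.2, 1.0\] s.
#' @param seed default seed used by generators when none is passed.
#' @return a `design_spec` list.
#' @export
design_spec <- function(conditions = c("high_uc", "low_uc", "low_uc_difficult"),
                        trials_per_block = 256L,
                        p_valid = 0.25,
                        n_locations = 4L,
                        sfreq = 256,
                        epoch_window = c(-2, 2),
                        seed = 1L) {
  if (p_valid <= 0 || p_valid > 1) stop("p_valid must be in (0, 1]")
  if (trials_per_block < 1) stop("trials_per_block must be positive")
  if (epoch_window[1] > -0.2 || epoch_window[2] < 1.0) {
    stop("epoch_window must contain [-0.2, 1.0] s")
  }
  structure(
    list(conditions = conditions, trials_per_block = as.integer(trials_per_block),
         p_valid = p_valid, n_locations = as.integer(n_locations),
         sfreq = sfreq, epoch_window = epoch_window, seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Behavioural generator parameters
#'
#' One row per condition x validity cell with the hit rate (probability of a
#' correct response to the signal letter), false-alarm rate (probability of a
#' signal response to the noise letter) and lognormal RT parameters
#' (`rt_mu`, `rt_sigma` on the log-ms scale).
#'
#' The defaults are chosen so that the implied d' (`qnorm(hit) - qnorm(fa)`
#' with an unbiased criterion, i.e. `hit = pnorm(d'/2)`) and the median RTs
#' sit at the magnitudes typical of masked spatial-cueing studies: d'
#' around 1-3, mean RTs around 370-490 ms, valid trials better than invalid,
#' high-uncertainty blocks slightly more sensitive on valid trials.
#'
#' @param table optional replacement data.frame with columns `condition`,
#'   `validity`, `hit_rate`, `fa_rate`, `rt_mu`, `rt_sigma`.
#' @return a data.frame of class `behavior_params`.
#' @export
behavior_params <- function(table = NULL) {
  if (is.null(table)) {
    dp <- c(high_uc.valid = 2.7, high_uc.invalid = 2.1,
            low_uc.valid = 2.2, low_uc.invalid = 1.8,
            low_uc_difficult.valid = 1.7, low_uc_difficult.invalid = 1.1)
    rt <- c(376, 414, 393, 434, 429, 489)
    cv <- do.call(rbind, strsplit(names(dp), ".", fixed = TRUE))
    sigma <- 0.35
    table <- data.frame(
      condition = cv[, 1], validity = cv[, 2],
      hit_rate = stats::pnorm(dp / 2),
      fa_rate = stats::pnorm(-dp / 2),
      rt_mu = log(rt) - sigma^2 / 2,
      rt_sigma = sigma,
      row.names = NULL
    )
  }
  req <- c("condition", "validity", "hit_rate", "fa_rate", "rt_mu", "rt_sigma")
  if (!all(req %in% names(table))) {
    stop("behavior_params table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(table$hit_rate <= 0 | table$hit_rate >= 1 |
          table$fa_rate <= 0 | table$fa_rate >= 1)) {
    stop("hit/fa rates must lie strictly in (0, 1)")
  }
  class(table) <- c("behavior_params", "data.frame")
  table
}

#' Simulate a blocked spatial-cueing trial table
#'
#' Generates one block per condition with an exact proportion of valid trials
#' (cue location equal to target location). The target letter ('E' or 'H')
#' is drawn uniformly; following the signal-detection convention 'E' is the
#' signal, so correct 'E' trials are hits and incorrect 'H' trials are false
#' alarms. Responses are Bernoulli draws from the cell's hit / false-alarm
#' rate and RTs are lognormal in ms.
#'
#' @param design a [design_spec()].
#' @param behavior a [behavior_params()] table covering every
#'   condition x validity cell of the design.
#' @param seed integer seed; defaults to `design$seed`.
#' @return data.frame with columns `block, condition, validity, cue_loc,
#'   target_loc, target, response, correct, rt_ms`.
#' @examples
#' tab <- generate_trial_table(design_spec(), behavior_params(), seed = 1)
#' nrow(tab)                    # 768
#' mean(tab$validity == "valid") # 0.25
#' @export
generate_trial_table <- function(design, behavior = behavior_params(),
                                 seed = design$seed) {
  stopifnot(inherits(design, "design_spec"))
  behavior <- behavior_params(behavior)
  needed <- expand.grid(condition = design$conditions,
                        validity = c("valid", "invalid"),
                        stringsAsFactors = FALSE)
  key <- paste(behavior$condition, behavior$validity)
  miss <- setdiff(paste(needed$condition, needed$validity), key)
  if (design$p_valid < 1 && length(miss)) {
    stop("behavior parameters missing for cells: ", paste(miss, collapse = "; "))
  }
  if (design$p_valid == 1) {
    miss_valid <- setdiff(paste(design$conditions, "valid"), key)
    if (length(miss_valid)) {
      stop("behavior parameters missing for cells: ",
           paste(miss_valid, collapse = "; "))
    }
  }
  set.seed(seed)
  n_valid <- round(design$trials_per_block * design$p_valid)
  blocks <- lapply(seq_along(design$conditions), function(b) {
    cond <- design$conditions[b]
    n <- design$trials_per_block
    validity <- rep("invalid", n)
    validity[sample.int(n, n_valid)] <- "valid"
    cue <- sample.int(design$n_locations, n, replace = TRUE)
    target <- ifelse(
      validity == "valid", cue,
      vapply(cue, function(cl) {
        sample(setdiff(seq_len(design$n_locations), cl), 1L)
      }, integer(1))
    )
    letter <- sample(c("E", "H"), n, replace = TRUE)
    idx <- match(paste(cond, validity), key)
    p_signal_resp <- ifelse(letter == "E",
                            behavior$hit_rate[idx], behavior$fa_rate[idx])
    response <- ifelse(stats::runif(n) < p_signal_resp, "E", "H")
    rt <- stats::rlnorm(n, behavior$rt_mu[idx], behavior$rt_sigma[idx])
    data.frame(block = b, condition = cond, validity = validity,
               cue_loc = cue, target_loc = target, target = letter,
               response = response,
               correct = as.integer(response == letter),
               rt_ms = rt)
  })
  do.call(rbind, blocks)
}

#' Coupled (non)linear MVAR system specification
#'
#' Defines the ground-truth source dynamics: an order-`p` linear MVAR part
#' given by coefficient matrices `A[[k]]` (entry `[j, i]` is the influence of
#' region i at lag k on region j), an optional list of nonlinear interaction
#' terms, and per-region innovation noise. The linear part must be
#' stationary (companion-matrix spectral radius < 1).
#'
#' Nonlinear terms are rows of a data.frame `(target, source, lag, gain, fun)`
#' with `fun` one of:
#' \describe{
#'   \item{`square`}{adds `gain * x_source[n - lag]^2` to the target update;}
#'   \item{`tanh_product`}{adds `gain * tanh(x_source[n - lag]) *
#'     x_target[n - 1]`, a cross-signal interaction.}
#' }
#'
#' @param M number of regions (sources).
#' @param A list of p coefficient matrices, each M x M.
#' @param nonlinear_terms data.frame as above, or NULL.
#' @param noise_sd innovation standard deviation, scalar or length M.
#' @param band optional length-2 Hz band; when set, simulated sources are
#'   band-limited with [bandpass_fir()] after simulation.
#' @return a `coupling_spec` list.
#' @export
coupling_spec <- function(M, A, nonlinear_terms = NULL, noise_sd = 1,
                          band = NULL) {
  if (!is.list(A) || !length(A)) stop("`A` must be a non-empty list of matrices")
  A <- lapply(A, function(a) {
    a <- as.matrix(a)
    if (!all(dim(a) == c(M, M))) stop("each A[[k]] must be M x M")
    a
  })
  p <- length(A)
  rho <- companion_spectral_radius(A)
  if (rho >= 1) {
    stop(sprintf("linear part is non-stationary: companion spectral radius %.3f >= 1", rho))
  }
  if (!is.null(nonlinear_terms)) {
    req <- c("target", "source", "lag", "gain", "fun")
    if (!all(req %in% names(nonlinear_terms))) {
      stop("nonlinear_terms needs columns: ", paste(req, collapse = ", "))
    }
    if (!all(nonlinear_terms$fun %in% c("square", "tanh_product"))) {
      stop("nonlinear fun must be 'square' or 'tanh_product'")
    }
    if (any(nonlinear_terms$lag < 1 | nonlinear_terms$lag > p)) {
      stop("nonlinear term lags must be in 1..p")
    }
  }
  noise_sd <- rep_len(noise_sd, M)
  structure(
    list(M = as.integer(M), p = p, A = A, nonlinear_terms = nonlinear_terms,
         noise_sd = noise_sd, band = band, spectral_radius = rho),
    class = "coupling_spec"
  )
}

companion_spectral_radius <- function(A) {
  M <- nrow(A[[1]]); p <- length(A)
  comp <- matrix(0, M * p, M * p)
  for (k in seq_len(p)) comp[seq_len(M), (k - 1) * M + seq_len(M)] <- A[[k]]
  if (p > 1) {
    comp[(M + 1):(M * p), seq_len(M * (p - 1))] <- diag(M * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate trials from a coupled MVAR system
#'
#' Each trial is simulated independently with its own burn-in, which is
#' discarded so the retained samples are (approximately) draws from the
#' stationary process. Innovations are Gaussian.
#'
#' @param spec a [coupling_spec()].
#' @param n_trials number of independent trials.
#' @param n_samples retained samples per trial (must exceed `10 * p`).
#' @param seed integer seed.
#' @param burn_in samples discarded at the start of every trial.
#' @param init optional M x p matrix of initial values (most recent state in
#'   column p); used together with `burn_in = 0` to study deterministic
#'   transients.
#' @return numeric array, trials x M x n_samples.
#' @export
simulate_sources <- function(spec, n_trials, n_samples, seed = 1,
                             burn_in = 200L, init = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (n_samples <= 10 * spec$p) stop("n_samples must exceed 10 * p")
  M <- spec$M; p <- spec$p
  set.seed(seed)
  total <- burn_in + n_samples + p
  out <- array(0, c(n_trials, M, n_samples))
  nl <- spec$nonlinear_terms
  for (tr in seq_len(n_trials)) {
    x <- matrix(0, M, total)
    if (!is.null(init)) x[, seq_len(p)] <- init
    eps <- matrix(stats::rnorm(M * total, sd = spec$noise_sd), M, total)
    for (n in (p + 1):total) {
      xn <- eps[, n]
      for (k in seq_len(p)) xn <- xn + spec$A[[k]] %*% x[, n - k]
      if (!is.null(nl)) {
        for (r in seq_len(nrow(nl))) {
          src <- x[nl$source[r], n - nl$lag[r]]
          xn[nl$target[r]] <- xn[nl$target[r]] + switch(
            nl$fun[r],
            square = nl$gain[r] * src^2,
            tanh_product = nl$gain[r] * tanh(src) * x[nl$target[r], n - 1]
          )
        }
      }
      x[, n] <- xn
    }
    out[tr, , ] <- x[, (burn_in + p + 1):total, drop = FALSE]
  }
  if (!is.null(spec$band)) {
    sf <- attr(spec$band, "sfreq")
    if (is.null(sf)) sf <- 256
    for (tr in seq_len(n_trials)) {
      for (m in seq_len(M)) {
        out[tr, m, ] <- bandpass_fir(out[tr, m, ], band = spec$band, sfreq = sf)
      }
    }
  }
  out
}

#' Synthetic sensor (forward) model
#'
#' A stand-in for a realistic EEG head model (synthetic; no volume
#' conduction physics): sensors sit on a unit sphere and each source's gain
#' at a sensor falls off with squared distance. The leadfield must have full
#' row rank and no all-zero sensor column.
#'
#' @param leadfield sources x channels gain matrix.
#' @param channel_coords channels x 3 positions on the unit sphere.
#' @param sensor_noise_sd additive Gaussian sensor noise SD.
#' @return a `sensor_model` list.
#' @export
sensor_model <- function(leadfield, channel_coords, sensor_noise_sd = 0.1) {
  leadfield <- as.matrix(leadfield)
  channel_coords <- as.matrix(channel_coords)
  if (ncol(leadfield) != nrow(channel_coords)) {
    stop("leadfield columns must match number of channels")
  }
  if (qr(leadfield)$rank < nrow(leadfield)) {
    stop("leadfield must have full row rank")
  }
  if (any(colSums(abs(leadfield)) == 0)) stop("leadfield has an all-zero channel")
  structure(
    list(leadfield = leadfield, channel_coords = channel_coords,
         sensor_noise_sd = sensor_noise_sd),
    class = "sensor_model"
  )
}

#' Build a spherical-geometry synthetic sensor model
#'
#' Places `n_channels` sensors quasi-uniformly on the unit sphere (Fibonacci
#' lattice) and `n_sources` sources on an interior spherical shell, with
#' gains `1 / (d^2 + 0.1)` for sensor-source distance d.
#'
#' @param n_channels number of sensors.
#' @param n_sources number of sources.
#' @param source_radius radius of the source shell (< 1).
#' @param sensor_noise_sd additive sensor noise SD.
#' @return a [sensor_model()]; source positions are attached as attribute
#'   `source_coords`.
#' @export
make_spherical_sensor_model <- function(n_channels = 30L, n_sources = 16L,
                                        source_radius = 0.6,
                                        sensor_noise_sd = 0.1) {
  sensors <- fibonacci_sphere(n_channels, 1)
  sources <- fibonacci_sphere(n_sources, source_radius)
  d2 <- outer(seq_len(n_sources), seq_len(n_channels), Vectorize(function(s, c) {
    sum((sources[s, ] - sensors[c, ])^2)
  }))
  lf <- 1 / (d2 + 0.1)
  m <- sensor_model(lf, sensors, sensor_noise_sd)
  attr(m, "source_coords") <- sources
  m
}

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Project source signals to sensors
#'
#' Sensor data are `t(leadfield) %*% sources` plus independent Gaussian
#' sensor noise.
#'
#' @param sources trials x M x samples array (from [simulate_sources()]).
#' @param model a [sensor_model()] whose leadfield has M rows.
#' @param sfreq sampling frequency of the output epochs (Hz).
#' @param t0 time of the first sample relative to the event (s).
#' @param seed integer seed for the sensor noise.
#' @return an [epoch_array()] (trials x channels x samples).
#' @export
project_to_sensors <- function(sources, model, sfreq = 256, t0 = 0, seed = 1) {
  stopifnot(inherits(model, "sensor_model"))
  d <- dim(sources)
  if (length(d) != 3L) stop("sources must be trials x M x samples")
  if (d[2] != nrow(model$leadfield)) {
    stop(sprintf("leadfield expects %d sources, got %d",
                 nrow(model$leadfield), d[2]))
  }
  n_ch <- ncol(model$leadfield)
  set.seed(seed)
  out <- array(0, c(d[1], n_ch, d[3]))
  for (tr in seq_len(d[1])) {
    sens <- crossprod(model$leadfield, sources[tr, , , drop = TRUE])
    if (d[2] == 1L) sens <- crossprod(model$leadfield, matrix(sources[tr, , ], 1, d[3]))
    if (model$sensor_noise_sd > 0) {
      sens <- sens + stats::rnorm(length(sens), sd = model$sensor_noise_sd)
    }
    out[tr, , ] <- sens
  }
  epoch_array(out, sfreq = sfreq, t0 = t0, coords = model$channel_coords)
}

#' Generate sensor epochs with condition-dependent oscillatory bursts
#'
#' Emulates the kind of data the cluster-based permutation stage consumes:
#' every epoch is a 1/f-like noise floor on all channels, plus theta and
#' alpha sinusoidal bursts (Hann-windowed) confined to 0-1000 ms after cue
#' onset. Burst amplitudes on `effect_channels` are taken from the per
#' condition x validity `effects` table; other channels receive the
#' `base_amp` amplitudes, so spatially localised condition effects have a
#' known ground truth.
#'
#' @param design a [design_spec()].
#' @param effects data.frame with columns `condition`, `validity`,
#'   `theta_amp`, `alpha_amp`.
#' @param model a [sensor_model()] providing channel count and coordinates.
#' @param n_trials trials per condition x validity cell.
#' @param effect_channels integer indices of channels carrying the condition
#'   effect (default: first third of the montage).
#' @param base_amp named vector `c(theta=, alpha=)` used off the effect
#'   channels.
#' @param burst_freqs named vector `c(theta=, alpha=)`; theta must lie in
#'   4-7 Hz and alpha in 8-12 Hz.
#' @param noise_sd SD of the 1/f noise floor.
#' @param seed integer seed.
#' @return named list of [epoch_array()]s, one per `condition|validity` cell.
#' @export
generate_band_power_epochs <- function(design, effects, model,
                                       n_trials = 40L,
                                       effect_channels = NULL,
                                       base_amp = c(theta = 1, alpha = 1),
                                       burst_freqs = c(theta = 5.5, alpha = 10),
                                       noise_sd = 1, seed = 1) {
  stopifnot(inherits(design, "design_spec"), inherits(model, "sensor_model"))
  if (burst_freqs["theta"] < 4 || burst_freqs["theta"] > 7) {
    stop("theta burst frequency must lie in 4-7 Hz")
  }
  if (burst_freqs["alpha"] < 8 || burst_freqs["alpha"] > 12) {
    stop("alpha burst frequency must lie in 8-12 Hz")
  }
  req <- c("condition", "validity", "theta_amp", "alpha_amp")
  if (!all(req %in% names(effects))) {
    stop("effects needs columns: ", paste(req, collapse = ", "))
  }
  n_ch <- nrow(model$channel_coords)
  if (is.null(effect_channels)) effect_channels <- seq_len(max(1L, n_ch %/% 3L))
  set.seed(seed)
  sf <- design$sfreq
  times <- seq(design$epoch_window[1], design$epoch_window[2] - 1 / sf, by = 1 / sf)
  n_t <- length(times)
  burst_idx <- which(times >= 0 & times < 1)
  env <- numeric(n_t)
  env[burst_idx] <- 0.5 * (1 - cos(2 * pi * seq_along(burst_idx) / length(burst_idx)))
  out <- list()
  for (r in seq_len(nrow(effects))) {
    dat <- array(0, c(n_trials, n_ch, n_t))
    amp_theta <- rep(base_amp[["theta"]], n_ch)
    amp_alpha <- rep(base_amp[["alpha"]], n_ch)
    amp_theta[effect_channels] <- effects$theta_amp[r]
    amp_alpha[effect_channels] <- effects$alpha_amp[r]
    for (tr in seq_len(n_trials)) {
      ph_t <- stats::runif(1, 0, 2 * pi)
      ph_a <- stats::runif(1, 0, 2 * pi)
      burst_t <- env * sin(2 * pi * burst_freqs[["theta"]] * times + ph_t)
      burst_a <- env * sin(2 * pi * burst_freqs[["alpha"]] * times + ph_a)
      noise <- one_over_f_noise(n_ch, n_t, noise_sd)
      dat[tr, , ] <- noise +
        outer(amp_theta, burst_t) + outer(amp_alpha, burst_a)
    }
    key <- paste(effects$condition[r], effects$validity[r], sep = "|")
    out[[key]] <- epoch_array(dat, sfreq = sf, t0 = design$epoch_window[1],
                              coords = model$channel_coords)
  }
  out
}

# 1/f-amplitude noise via spectral shaping of white noise
one_over_f_noise <- function(n_ch, n_t, sd) {
  freqs <- c(1, seq_len(n_t - 1))
  shape <- 1 / sqrt(pmin(freqs, n_t - freqs + 1))
  x <- matrix(stats::rnorm(n_ch * n_t), n_ch, n_t)
  shaped <- t(apply(x, 1, function(row) {
    Re(stats::fft(stats::fft(row) * shape, inverse = TRUE)) / n_t
  }))
  shaped <- shaped / stats::sd(shaped) * sd
  shaped
}
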