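#' Condition-effect presets for the synthetic oscillatory generator
#'
#' `"null"`: identical burst amplitudes everywhere (no condition effect).
#' `"paper_like"`: theta bursts on invalid trials twice as strong under low
#' as under high uncertainty (so the high-vs-low invalid theta contrast is
#' negative on the effect channels), and alpha bursts stronger on valid
#' than invalid trials under high uncertainty.
#'
#' @param preset preset name.
#' @return effects data.frame for [generate_band_power_epochs()].
#' @export
preset_effects <- function(preset = c("paper_like", "null")) {
  preset <- match.arg(preset)
  grid <- expand.grid(condition = c("high_uc", "low_uc", "low_uc_difficult"),
                      validity = c("valid", "invalid"),
                      stringsAsFactors = FALSE)
  grid$theta_amp <- 1
  grid$alpha_amp <- 1
  if (preset == "paper_like") {
    grid$theta_amp[grid$condition == "low_uc" & grid$validity == "invalid"] <- 2
    grid$alpha_amp[grid$condition == "high_uc" & grid$validity == "valid"] <- 2
  }
  grid
}

config_defaults <- function() {
  list(
    seed = 1L,
    n_subjects = 12L,
    design = list(),
    effects_preset = "paper_like",
    cbpt = list(n_perm = 500L, alpha_sample = 0.05, alpha_cluster = 0.05,
                n_trials = 8L, n_channels = 21L, band = c(4, 7)),
    beamform = list(n_channels = 24L, n_sources = 12L, lambda = 0.05,
                    n_trials = 30L),
    connectivity = list(p = 5L, hidden_units = 10L, cv_folds = 3L,
                        max_epochs = 60L, n_surrogates = 20L,
                        n_trials = 30L, trial_samples = 256L)
  )
}

#' Load a pipeline run configuration
#'
#' Configurations are JSON objects (a standard key-value text format; see
#' the vignette) with the top-level keys `seed`, `n_subjects`, `design`,
#' `effects_preset`, `cbpt`, `beamform` and `connectivity`. Unknown keys —
#' at the top level or within a section — are rejected by name; missing
#' keys fall back to documented defaults, and every applied default is
#' listed in a warning.
#'
#' @param path path to a JSON config file.
#' @return a `run_config` list with all defaults filled in;
#'   `attr(, "defaulted")` names every key that came from the defaults.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  defs <- config_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaulted <- character(0)
  cfg <- defs
  for (key in names(defs)) {
    if (is.null(user[[key]])) {
      defaulted <- c(defaulted, key)
    } else if (key == "design") {
      allowed <- c("conditions", "trials_per_block", "p_valid", "n_locations",
                   "sfreq", "epoch_window", "seed")
      sub_unknown <- setdiff(names(user[[key]]), allowed)
      if (length(sub_unknown)) {
        stop("unknown config key(s) in `design`: ",
             paste(sub_unknown, collapse = ", "))
      }
      cfg$design <- as.list(user$design)
    } else if (is.list(defs[[key]]) && length(names(defs[[key]]))) {
      sub_unknown <- setdiff(names(user[[key]]), names(defs[[key]]))
      if (length(sub_unknown)) {
        stop("unknown config key(s) in `", key, "`: ",
             paste(sub_unknown, collapse = ", "))
      }
      cfg[[key]] <- utils::modifyList(defs[[key]], as.list(user[[key]]))
      defaulted <- c(defaulted,
                     paste0(key, ".", setdiff(names(defs[[key]]), names(user[[key]]))))
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  if (length(defaulted)) {
    warning("config defaults applied for: ", paste(defaulted, collapse = ", "))
  }
  attr(cfg, "defaulted") <- defaulted
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: behavioural simulation and analysis (screening,
#' per-cell summaries, repeated-measures ANOVAs, the planned high-vs-low
#' valid d' contrast), oscillatory-epoch simulation with Morlet power,
#' baseline correction and a cluster-based permutation contrast
#' (high-vs-low uncertainty, invalid trials, theta band), beamforming
#' (DICS source power with top-5% masking, LCMV ROI time courses) and
#' nCREANN effective connectivity with surrogate thresholds. All stage
#' seeds are fanned out deterministically from the master seed, every
#' intermediate artifact is written under `outdir`, and a line-delimited
#' JSON log records per-stage seeds. Re-running the same config reproduces
#' the outputs bit-identically.
#'
#' @param config a [load_config()] result (or the path to a config file).
#' @param outdir output directory (created if absent).
#' @return the summary list (invisibly written to `summary.json`).
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "log.jsonl")
  if (file.exists(logfile)) unlink(logfile)
  log_stage <- function(stage, seed, info = list()) {
    rec <- c(list(stage = stage, seed = seed,
                  package_version = as.character(utils::packageVersion("uncflow"))),
             info)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logfile, append = TRUE, sep = "")
  }
  master <- as.integer(config$seed)
  design <- do.call(design_spec, config$design)
  summary <- list(seed = master)

  ## stage 1: behaviour -----------------------------------------------------
  seed_beh <- stage_seed(master, 1)
  log_stage("behavior", seed_beh)
  tables <- lapply(seq_len(config$n_subjects), function(s) {
    generate_trial_table(design, behavior_params(), seed = stage_seed(seed_beh, s))
  })
  names(tables) <- sprintf("S%02d", seq_len(config$n_subjects))
  scr <- screen_participants(tables)
  summaries <- lapply(scr$retained, function(s) {
    cbind(subject = s, subject_summary(tables[[s]]))
  })
  long <- do.call(rbind, summaries)
  utils::write.csv(long, file.path(outdir, "behavior_summaries.csv"),
                   row.names = FALSE)
  anova_d <- rm_anova(long, "d_prime")
  anova_rt <- rm_anova(long, "mean_rt")
  utils::write.csv(rbind(cbind(dv = "d_prime", anova_d),
                         cbind(dv = "mean_rt", anova_rt)),
                   file.path(outdir, "behavior_anova.csv"), row.names = FALSE)
  contrast <- paired_contrasts(long, "d_prime",
                               list(condition = "high_uc", validity = "valid"),
                               list(condition = "low_uc", validity = "valid"))
  jsonlite::write_json(contrast, file.path(outdir, "behavior_contrast.json"),
                       auto_unbox = TRUE, digits = NA)
  cells <- stats::aggregate(cbind(d_prime, mean_rt, accuracy) ~ condition + validity,
                            long, mean)
  summary$behavior <- list(n_retained = length(scr$retained), cells = cells,
                           anova_d_prime = anova_d, contrast = contrast)

  ## stage 2: time-frequency + CBPT -----------------------------------------
  seed_tf <- stage_seed(master, 2)
  log_stage("timefreq_cbpt", seed_tf)
  cb <- config$cbpt
  model <- make_spherical_sensor_model(cb$n_channels, 8)
  effects <- preset_effects(config$effects_preset)
  cells_tf <- effects[effects$validity == "invalid" &
                        effects$condition %in% c("high_uc", "low_uc"), ]
  n_eff <- max(2L, cb$n_channels %/% 3L)
  band_power <- lapply(seq_len(config$n_subjects), function(s) {
    ep <- generate_band_power_epochs(design, cells_tf, model,
                                     n_trials = cb$n_trials,
                                     effect_channels = seq_len(n_eff),
                                     seed = stage_seed(seed_tf, s))
    vapply(ep, function(e) {
      tf <- morlet_power(e, morlet_spec(4:12, sfreq = e$sfreq))
      tf <- baseline_correct(tf)
      colMeans(band_window_average(tf, band = cb$band, window = c(0, 1)))
    }, numeric(cb$n_channels))
  })
  A <- t(vapply(band_power, function(m) m[, "high_uc|invalid"], numeric(cb$n_channels)))
  B <- t(vapply(band_power, function(m) m[, "low_uc|invalid"], numeric(cb$n_channels)))
  graph <- build_neighbors(model$channel_coords)
  clus <- cluster_test(A, B, graph, alpha_sample = cb$alpha_sample,
                       alpha_cluster = cb$alpha_cluster, n_perm = cb$n_perm,
                       seed = stage_seed(seed_tf, 9999))
  topo <- data.frame(channel = seq_len(cb$n_channels), t = clus$t,
                     cluster_id = clus$membership)
  utils::write.csv(topo, file.path(outdir, "cbpt_topography.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(clusters = clus$clusters,
                            n_permutations = clus$n_permutations,
                            p_bonferroni = bonferroni(clus$clusters$p, m = 3)),
                       file.path(outdir, "cbpt_result.json"),
                       auto_unbox = TRUE, digits = NA)
  summary$cbpt <- list(n_clusters = nrow(clus$clusters),
                       clusters = clus$clusters)

  ## stage 3: beamforming ----------------------------------------------------
  seed_bf <- stage_seed(master, 3)
  log_stage("beamform", seed_bf)
  bf <- config$beamform
  bmodel <- make_spherical_sensor_model(bf$n_channels, bf$n_sources,
                                        sensor_noise_sd = 0.05)
  theta_sys <- theta_var_system(2)
  src <- simulate_sources(theta_sys, n_trials = bf$n_trials, n_samples = 256,
                          seed = stage_seed(seed_bf, 1))
  active <- c(2L, bf$n_sources - 1L)
  full_src <- array(0, c(bf$n_trials, bf$n_sources, 256))
  full_src[, active, ] <- src
  ep <- project_to_sensors(full_src, bmodel, sfreq = design$sfreq, t0 = 0,
                           seed = stage_seed(seed_bf, 2))
  csd <- estimate_csd(ep, band = c(4, 7), window = c(0, 0.6))
  dics <- dics_source_power(csd, bmodel$leadfield, lambda = bf$lambda)
  mask <- top_percent_mask(dics$power, 25)
  grid <- attr(bmodel, "source_coords")
  utils::write.csv(
    data.frame(source_id = seq_len(bf$n_sources), x = grid[, 1], y = grid[, 2],
               z = grid[, 3], power = dics$power, mask = mask),
    file.path(outdir, "dics_power.csv"), row.names = FALSE)
  cov <- sensor_covariance(ep)
  filt <- lcmv_filters(cov, bmodel$leadfield, lambda = bf$lambda)
  roi <- extract_roi_timecourses(ep, filt, roi = as.list(active))
  summary$beamform <- list(peak_source = which.max(dics$power),
                           active_sources = active,
                           n_masked = sum(mask))

  ## stage 4: effective connectivity -----------------------------------------
  seed_cn <- stage_seed(master, 4)
  log_stage("connectivity", seed_cn)
  cn <- config$connectivity
  spec <- nmvar_spec(p = cn$p, hidden_units = cn$hidden_units,
                     cv_folds = cn$cv_folds, max_epochs = cn$max_epochs)
  roi_sig <- aperm(roi, c(1, 2, 3))
  res <- estimate_connectivity(roi_sig, spec, seed = seed_cn,
                               n_surrogates = cn$n_surrogates)
  utils::write.csv(as.data.frame(res$lC), file.path(outdir, "connectivity_lC.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$NC), file.path(outdir, "connectivity_NC.csv"),
                   row.names = FALSE)
  if (!is.null(res$null_lC)) {
    utils::write.csv(
      data.frame(surrogate = rep(seq_len(cn$n_surrogates), times = res$M^2),
                 from = rep(rep(seq_len(res$M), each = cn$n_surrogates), res$M),
                 to = rep(seq_len(res$M), each = cn$n_surrogates * res$M),
                 lC = as.vector(res$null_lC), NC = as.vector(res$null_NC)),
      file.path(outdir, "connectivity_null.csv"), row.names = FALSE)
  }
  summary$connectivity <- list(
    lC = res$lC, NC = res$NC,
    mask_lC = res$mask_lC, mask_NC = res$mask_NC,
    mean_train_r2 = mean(attr(res, "net")$folds$r2_train),
    mean_test_r2 = mean(attr(res, "net")$folds$r2_test))

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(summary)
}

# a stationary 2-region VAR with a theta-band resonance at ~5.5 Hz (256 Hz
# sampling) and a lag-1 directed coupling 1 -> 2
theta_var_system <- function(M = 2, f0 = 5.5, r = 0.95, coupling = 0.3,
                             sfreq = 256, noise_sd = 1) {
  w <- 2 * pi * f0 / sfreq
  a1 <- 2 * r * cos(w); a2 <- -r^2
  A1 <- diag(a1, M); A2 <- diag(a2, M)
  A1[2, 1] <- coupling
  coupling_spec(M, list(A1, A2), noise_sd = noise_sd)
}

#' Sensor covariance from epochs
#'
#' Channel covariance pooled over trials and samples (time-domain analogue
#' of the CSD, used by the LCMV beamformer).
#'
#' @param epochs an [epoch_array()].
#' @param window optional time window in seconds.
#' @return channels x channels covariance matrix.
#' @export
sensor_covariance <- function(epochs, window = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  sel <- if (is.null(window)) seq_along(epochs$times) else {
    which(epochs$times >= window[1] & epochs$times <= window[2])
  }
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data[, , sel, drop = FALSE], c(2, 1, 3)),
                 d[2], d[1] * length(sel))
  stats::cov(t(flat))
}
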