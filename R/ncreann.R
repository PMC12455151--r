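#' Zero-phase Hamming-windowed sinc bandpass filter
#'
#' Designs a linear-phase FIR bandpass as the difference of two
#' Hamming-windowed sinc lowpass kernels and applies it forward and
#' backward (zero net phase, squared magnitude response) with reflection
#' padding, preserving the signal length.
#'
#' The default tap count follows the Hamming transition-width rule
#' `n_taps ~ 3.3 / (transition / sfreq)` with a 2 Hz transition band; when
#' the signal is too short for that kernel, the order is reduced to fit
#' (largest odd number at most a third of the signal length).
#'
#' @param x numeric signal.
#' @param band length-2 passband in Hz (default theta, 4-7 Hz).
#' @param sfreq sampling frequency in Hz.
#' @param n_taps odd FIR length; `NULL` for the automatic choice.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_fir <- function(x, band = c(4, 7), sfreq = 256, n_taps = NULL) {
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= sfreq / 2) {
    stop("band edges must satisfy 0 < lo < hi < sfreq/2")
  }
  n <- length(x)
  if (is.null(n_taps)) n_taps <- round(3.3 / (2 / sfreq))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  if (n_taps > n %/% 3) {
    n_taps <- max(5L, (n %/% 3) - ((n %/% 3 + 1) %% 2))
  }
  h <- fir_bandpass_kernel(n_taps, band, sfreq)
  y <- conv_centered(x, h)
  rev(conv_centered(rev(y), h))
}

fir_bandpass_kernel <- function(n_taps, band, sfreq) {
  m <- (n_taps - 1) / 2
  t <- -m:m
  sinc <- function(fc) {
    out <- 2 * fc / sfreq * rep(1, length(t))
    nz <- t != 0
    out[nz] <- sin(2 * pi * fc / sfreq * t[nz]) / (pi * t[nz])
    out
  }
  w <- 0.54 + 0.46 * cos(pi * t / m)  # Hamming
  h <- (sinc(band[2]) - sinc(band[1])) * w
  # normalise to unit gain at the band centre
  f0 <- mean(band)
  g <- sum(h * cos(2 * pi * f0 / sfreq * t))
  h / g
}

# centred convolution with reflection padding; output length == input length
conv_centered <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad <- min(m, n - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  full <- stats::convolve(xp, rev(h), type = "open")
  full[(pad + m + 1):(pad + m + n)]
}

#' Linear VAR model-order selection
#'
#' Fits linear vector-autoregressions of order 1..`p_max` by least squares
#' and scores them with the multivariate Akaike (AIC) and Schwarz (SBC)
#' information criteria, `N * log det(Sigma_p) + penalty * p * M^2` with
#' penalty 2 (AIC) or log N (SBC). Returns the AIC minimiser; the SBC
#' choice and the full table are reported alongside.
#'
#' @param signals M x L matrix, trials x M x samples array, or list of
#'   M x samples trial matrices.
#' @param p_max maximum order considered.
#' @return list with `order` (AIC minimiser), `order_sbc` and `table`
#'   (data.frame p, aic, sbc, logdet).
#' @export
select_model_order <- function(signals, p_max = 10) {
  trials <- as_trial_list(signals)
  M <- nrow(trials[[1]])
  total <- sum(vapply(trials, ncol, integer(1)))
  if (total <= p_max * M * 10) stop("insufficient samples for p_max")
  rows <- lapply(seq_len(p_max), function(p) {
    xy <- build_lagged(trials, p)
    N <- nrow(xy$Y)
    X1 <- cbind(1, xy$X)
    B <- qr.solve(X1, xy$Y)
    resid <- xy$Y - X1 %*% B
    Sigma <- crossprod(resid) / N
    ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
    data.frame(p = p, aic = N * ld + 2 * p * M^2,
               sbc = N * ld + log(N) * p * M^2, logdet = ld)
  })
  tab <- do.call(rbind, rows)
  list(order = tab$p[which.min(tab$aic)],
       order_sbc = tab$p[which.min(tab$sbc)],
       table = tab)
}

#' Nonlinear MVAR network specification
#'
#' Hyperparameters of the one-hidden-layer tanh network that implements the
#' nonlinear MVAR map from `M * p` past samples to the current sample of
#' all M regions: model order `p` (default 10), 10 hidden units, incremental
#' back-propagation with momentum and an adaptive learning rate (x1.05
#' after an epoch that lowers the training MSE, x0.7 otherwise), uniform
#' initialisation in \[-0.5, 0.5\], permuted cross-validation with an
#' 80/10/10 train/validation/test split, and patience-based early stopping
#' on the validation MSE.
#'
#' @param p model order.
#' @param hidden_units hidden-layer width.
#' @param momentum momentum coefficient alpha.
#' @param learning_rate initial learning rate eta.
#' @param init_range uniform initialisation range.
#' @param cv_folds number of permuted CV folds.
#' @param split train/validation/test proportions (must sum to 1).
#' @param patience early-stopping patience in epochs.
#' @param max_epochs hard epoch cap.
#' @return an `nmvar_spec` list.
#' @export
nmvar_spec <- function(p = 10, hidden_units = 10, momentum = 0.9,
                       learning_rate = 0.01, init_range = c(-0.5, 0.5),
                       cv_folds = 10, split = c(0.8, 0.1, 0.1),
                       patience = 10, max_epochs = 200) {
  if (p < 1 || hidden_units < 1) stop("p and hidden_units must be >= 1")
  if (abs(sum(split) - 1) > 1e-9) stop("split must sum to 1")
  structure(list(p = as.integer(p), hidden_units = as.integer(hidden_units),
                 momentum = momentum, learning_rate = learning_rate,
                 init_range = init_range, cv_folds = as.integer(cv_folds),
                 split = split, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs)),
            class = "nmvar_spec")
}

as_trial_list <- function(signals) {
  if (is.list(signals) && !is.data.frame(signals)) {
    lapply(signals, as.matrix)
  } else if (is.matrix(signals)) {
    list(signals)
  } else if (length(dim(signals)) == 3L) {
    lapply(seq_len(dim(signals)[1]), function(tr) {
      matrix(signals[tr, , ], dim(signals)[2], dim(signals)[3])
    })
  } else {
    stop("signals must be a matrix, 3-d array, or list of trial matrices")
  }
}

# lagged design matrix; input column (k-1)*M + i holds x_i[n - k].
# trial boundaries are respected: no sample's past crosses a trial edge.
build_lagged <- function(trials, p) {
  Xs <- list(); Ys <- list()
  M <- nrow(trials[[1]])
  for (tt in seq_along(trials)) {
    x <- trials[[tt]]
    T <- ncol(x)
    if (T <= p) next
    idx <- (p + 1):T
    X <- matrix(0, length(idx), M * p)
    for (k in seq_len(p)) {
      X[, (k - 1) * M + seq_len(M)] <- t(x[, idx - k, drop = FALSE])
    }
    Xs[[length(Xs) + 1]] <- X
    Ys[[length(Ys) + 1]] <- t(x[, idx, drop = FALSE])
  }
  if (!length(Xs)) stop("all trials shorter than the model order")
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

pooled_r2 <- function(Y, Yhat) {
  mu <- colMeans(Y)
  sst <- sum(sweep(Y, 2, mu)^2)
  if (sst == 0) return(NA_real_)
  1 - sum((Y - Yhat)^2) / sst
}

predict_net <- function(W_in, b_hidden, W_out, b_out, X) {
  H <- tanh(X %*% t(W_in) + matrix(b_hidden, nrow(X), length(b_hidden), byrow = TRUE))
  H %*% t(W_out) + matrix(b_out, nrow(X), length(b_out), byrow = TRUE)
}

#' Train the nonlinear MVAR network
#'
#' Concatenates the (standardized) trial signals into a lagged regression
#' problem — `M * p` past samples predicting the current sample of all M
#' regions, never crossing trial boundaries — and trains the one-hidden-
#' layer network by incremental back-propagation under the permuted
#' cross-validation protocol of the [nmvar_spec()]. Each fold draws its own
#' random permutation of the samples, splits it train/validation/test,
#' trains with early stopping on the validation MSE and records training
#' and test R-squared / MSE. The returned network is the fold with the best
#' validation MSE.
#'
#' @param signals M x L matrix, trials x M x samples array, or list of
#'   M x samples matrices (single-trial source signals to concatenate).
#' @param spec an [nmvar_spec()].
#' @param seed integer seed (fold seeds are derived from it).
#' @return a `trained_net`: weights (`W_in`, `b_hidden`, `W_out`, `b_out`),
#'   `folds` metrics data.frame, `scaling`, the standardized lagged inputs
#'   `X` (reused by [decompose_connectivity()]), `M` and `spec`.
#' @export
train_nmvar_net <- function(signals, spec = nmvar_spec(), seed = 1) {
  stopifnot(inherits(spec, "nmvar_spec"))
  trials <- as_trial_list(signals)
  if (any(!vapply(trials, function(x) all(is.finite(x)), logical(1)))) {
    stop("signals contain non-finite values")
  }
  M <- nrow(trials[[1]])
  allx <- do.call(cbind, trials)
  mu <- rowMeans(allx)
  sdv <- apply(allx, 1, stats::sd)
  if (any(sdv == 0)) stop("a region has zero variance; cannot standardize")
  trials <- lapply(trials, function(x) (x - mu) / sdv)
  xy <- build_lagged(trials, spec$p)
  N <- nrow(xy$X)
  if (N <= 10 * M * spec$p) {
    stop("signal too short: need more than 10 * M * p usable samples")
  }
  folds <- vector("list", spec$cv_folds)
  nets <- vector("list", spec$cv_folds)
  n_tr <- floor(spec$split[1] * N)
  n_val <- floor(spec$split[2] * N)
  for (f in seq_len(spec$cv_folds)) {
    fseed <- stage_seed(seed, f)
    set.seed(fseed)
    perm <- sample.int(N)
    id_tr <- perm[seq_len(n_tr)]
    id_val <- perm[n_tr + seq_len(n_val)]
    id_te <- perm[(n_tr + n_val + 1):N]
    fit <- train_ebp_cpp(xy$X, xy$Y, id_tr - 1L, id_val - 1L,
                         spec$hidden_units, spec$learning_rate, spec$momentum,
                         spec$max_epochs, spec$patience,
                         spec$init_range[1], spec$init_range[2], fseed)
    if (isTRUE(fit$diverged)) {
      stop("training diverged (non-finite loss) in fold ", f,
           "; training MSE history: ",
           paste(signif(fit$mse_train_history, 3), collapse = ", "))
    }
    pr_tr <- predict_net(fit$W_in, fit$b_hidden, fit$W_out, fit$b_out,
                         xy$X[id_tr, , drop = FALSE])
    pr_te <- predict_net(fit$W_in, fit$b_hidden, fit$W_out, fit$b_out,
                         xy$X[id_te, , drop = FALSE])
    folds[[f]] <- data.frame(
      fold = f,
      r2_train = pooled_r2(xy$Y[id_tr, , drop = FALSE], pr_tr),
      mse_train = mean((xy$Y[id_tr, , drop = FALSE] - pr_tr)^2),
      r2_test = pooled_r2(xy$Y[id_te, , drop = FALSE], pr_te),
      mse_test = mean((xy$Y[id_te, , drop = FALSE] - pr_te)^2),
      best_val_mse = fit$best_val_mse,
      n_epochs = fit$n_epochs
    )
    nets[[f]] <- fit
  }
  folds <- do.call(rbind, folds)
  best <- which.min(folds$best_val_mse)
  net <- nets[[best]]
  structure(
    list(W_in = net$W_in, b_hidden = as.numeric(net$b_hidden),
         W_out = net$W_out, b_out = as.numeric(net$b_out),
         folds = folds, best_fold = best,
         scaling = list(mean = mu, sd = sdv),
         X = xy$X, M = M, spec = spec, seed = seed),
    class = "trained_net"
  )
}

#' @export
print.trained_net <- function(x, ...) {
  cat(sprintf("<trained_net> M = %d, p = %d, hidden = %d\n",
              x$M, x$spec$p, x$spec$hidden_units))
  cat(sprintf("mean train R2 = %.4f, mean test R2 = %.4f (over %d folds)\n",
              mean(x$folds$r2_train), mean(x$folds$r2_test), nrow(x$folds)))
  invisible(x)
}

#' Split a trained network into linear and nonlinear connectivity
#'
#' The fitted map f is decomposed as `f = f(0) + f_Lin + f_NonLin`. The
#' linear part is the first-order Taylor term at the origin, with Jacobian
#' `J = W_out diag(g'(b_hidden)) W_in`; the linear connectivity
#' `lC[i, j]` (i -> j) is the mean over lags of `|J[j, (i, k)]|`. The
#' nonlinear connectivity `NC[i, j]` is the data-averaged sensitivity of
#' `f_NonLin`: the mean over training samples and lags of
#' `|d f_j / d u_(i,k) (x) - J[j, (i,k)]|`.
#'
#' Both matrices are nonnegative; the diagonal (self-influence) is reported
#' but conventionally excluded from group statistics.
#'
#' @param net a [train_nmvar_net()] result.
#' @param inputs standardized lagged input matrix at which to average the
#'   nonlinear sensitivity (default: the net's own training inputs).
#' @return a `connectivity_result` with `lC` and `NC` (M x M, `[i, j]`
#'   meaning i -> j).
#' @export
decompose_connectivity <- function(net, inputs = NULL) {
  stopifnot(inherits(net, "trained_net"))
  if (is.null(inputs)) inputs <- net$X
  M <- net$M; p <- net$spec$p
  gp0 <- 1 - tanh(net$b_hidden)^2
  J <- net$W_out %*% (net$W_in * gp0)   # M x (M*p)
  lag_cols <- function(i) (seq_len(p) - 1) * M + i
  lC <- matrix(0, M, M); NC <- matrix(0, M, M)
  A <- inputs %*% t(net$W_in) +
    matrix(net$b_hidden, nrow(inputs), length(net$b_hidden), byrow = TRUE)
  G <- 1 - tanh(A)^2                    # N x H
  for (j in seq_len(M)) {
    Dj <- (G * matrix(net$W_out[j, ], nrow(G), ncol(G), byrow = TRUE)) %*% net$W_in
    dev <- abs(sweep(Dj, 2, J[j, ]))
    for (i in seq_len(M)) {
      lC[i, j] <- mean(abs(J[j, lag_cols(i)]))
      NC[i, j] <- mean(dev[, lag_cols(i)])
    }
  }
  structure(list(lC = lC, NC = NC, M = M), class = "connectivity_result")
}

#' Time-shifted surrogate significance threshold
#'
#' Builds the null distribution of the connectivity estimator: each
#' surrogate circularly shifts every region's concatenated time series by
#' an independent random offset (at least `min_shift` of the length),
#' destroying cross-regional causal structure while leaving each series'
#' own dynamics (circular autocorrelation, spectrum) untouched; the full
#' estimator — identical architecture and hyperparameters — is re-run on
#' each surrogate. The per-connection significance threshold is the 90th
#' percentile of its null, and observed connections below it are masked
#' out.
#'
#' @param signals as in [train_nmvar_net()].
#' @param spec an [nmvar_spec()].
#' @param n_surrogates number of surrogate datasets (warning below 20).
#' @param seed integer seed.
#' @param observed optional precomputed `connectivity_result` for the
#'   original data (it is computed here when `NULL`).
#' @param level quantile of the null used as threshold.
#' @return a `connectivity_result` augmented with `null_lC`, `null_NC`
#'   (n_surrogates x M x M), `thr_lC`, `thr_NC`, `mask_lC`, `mask_NC` and
#'   `n_surrogates`.
#' @export
surrogate_null <- function(signals, spec = nmvar_spec(), n_surrogates = 100,
                           seed = 1, observed = NULL, level = 0.9) {
  if (n_surrogates < 20) {
    warning("n_surrogates < 20: the 90% threshold is unstable")
  }
  trials <- as_trial_list(signals)
  lens <- vapply(trials, ncol, integer(1))
  concat <- do.call(cbind, trials)
  M <- nrow(concat); L <- ncol(concat)
  if (is.null(observed)) {
    net <- train_nmvar_net(trials, spec, seed = seed)
    observed <- decompose_connectivity(net)
  }
  null_lC <- array(0, c(n_surrogates, M, M))
  null_NC <- array(0, c(n_surrogates, M, M))
  lo <- max(1L, floor(0.1 * L))
  for (s in seq_len(n_surrogates)) {
    sseed <- stage_seed(seed, 1000 + s)
    set.seed(sseed)
    shifts <- sample(lo:(L - lo), M, replace = TRUE)
    surr <- concat
    for (m in seq_len(M)) surr[m, ] <- circshift(concat[m, ], shifts[m])
    surr_trials <- split_columns(surr, lens)
    net_s <- train_nmvar_net(surr_trials, spec, seed = sseed)
    d <- decompose_connectivity(net_s)
    null_lC[s, , ] <- d$lC
    null_NC[s, , ] <- d$NC
  }
  thr_lC <- apply(null_lC, c(2, 3), stats::quantile, probs = level, names = FALSE)
  thr_NC <- apply(null_NC, c(2, 3), stats::quantile, probs = level, names = FALSE)
  observed$null_lC <- null_lC
  observed$null_NC <- null_NC
  observed$thr_lC <- thr_lC
  observed$thr_NC <- thr_NC
  observed$mask_lC <- observed$lC > thr_lC
  observed$mask_NC <- observed$NC > thr_NC
  observed$n_surrogates <- n_surrogates
  observed
}

# circular shift by k samples (x[k+1] becomes the first sample)
circshift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(k + 1):n], x[1:k])
}

split_columns <- function(x, lens) {
  out <- vector("list", length(lens))
  at <- 0L
  for (i in seq_along(lens)) {
    out[[i]] <- x[, at + seq_len(lens[i]), drop = FALSE]
    at <- at + lens[i]
  }
  out
}

#' Fit, decompose and significance-test effective connectivity
#'
#' Convenience wrapper: trains the network, decomposes it into linear and
#' nonlinear connectivity, and (optionally) attaches time-shifted surrogate
#' thresholds and masks.
#'
#' @inheritParams surrogate_null
#' @return a `connectivity_result` (with the trained net as attribute
#'   `net`).
#' @export
estimate_connectivity <- function(signals, spec = nmvar_spec(), seed = 1,
                                  n_surrogates = 100) {
  net <- train_nmvar_net(signals, spec, seed = seed)
  res <- decompose_connectivity(net)
  if (n_surrogates > 0) {
    res <- surrogate_null(signals, spec, n_surrogates = n_surrogates,
                          seed = seed, observed = res)
  }
  attr(res, "net") <- net
  res
}

wilcoxon_signed <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (!n) {
    return(list(V = NA_real_, p = 1, n = 0,
                note = "all differences zero; Wilcoxon undefined, p set to 1"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = n <= 25, correct = TRUE)
  )
  list(V = unname(wt$statistic), p = wt$p.value, n = n, note = NULL)
}

#' Group comparison of connectivity between two conditions
#'
#' For every directed off-diagonal connection, subjects whose connection
#' survived the surrogate mask in both conditions are retained (so the
#' degrees of freedom can differ by connection); a two-sided paired t test
#' compares the linear connectivity and a Wilcoxon signed-rank test (exact
#' for n <= 25, normal approximation with continuity correction above) the
#' nonlinear connectivity. All-zero difference vectors yield p = 1 with a
#' note.
#'
#' @param resA,resB per-subject lists of `connectivity_result`s (from
#'   [surrogate_null()] / [estimate_connectivity()]) for the two
#'   conditions.
#' @param use_mask apply the surrogate masks for subject selection
#'   (requires masked results).
#' @return data.frame with one row per connection: from, to, n_linear, t,
#'   df, p_linear, mean_diff, sd_diff, n_nonlinear, V, p_nonlinear, note.
#' @export
group_compare <- function(resA, resB, use_mask = TRUE) {
  if (length(resA) != length(resB)) stop("conditions must share subjects")
  M <- resA[[1]]$M
  rows <- list()
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      keep_l <- keep_n <- rep(TRUE, length(resA))
      if (use_mask) {
        keep_l <- vapply(seq_along(resA), function(s) {
          isTRUE(resA[[s]]$mask_lC[i, j]) && isTRUE(resB[[s]]$mask_lC[i, j])
        }, logical(1))
        keep_n <- vapply(seq_along(resA), function(s) {
          isTRUE(resA[[s]]$mask_NC[i, j]) && isTRUE(resB[[s]]$mask_NC[i, j])
        }, logical(1))
      }
      la <- vapply(resA, function(r) r$lC[i, j], numeric(1))[keep_l]
      lb <- vapply(resB, function(r) r$lC[i, j], numeric(1))[keep_l]
      na_ <- vapply(resA, function(r) r$NC[i, j], numeric(1))[keep_n]
      nb_ <- vapply(resB, function(r) r$NC[i, j], numeric(1))[keep_n]
      note <- NULL
      if (sum(keep_l) >= 2) {
        d <- la - lb
        sd_d <- stats::sd(d)
        if (sd_d == 0) {
          t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
          p_t <- if (mean(d) == 0) 1 else 0
        } else {
          t <- mean(d) / (sd_d / sqrt(length(d)))
          p_t <- 2 * stats::pt(-abs(t), length(d) - 1)
        }
        md <- mean(d); sdd <- sd_d; df <- length(d) - 1
      } else {
        t <- NA_real_; p_t <- NA_real_; md <- NA_real_; sdd <- NA_real_
        df <- NA_integer_
      }
      if (sum(keep_n) >= 2) {
        wt <- wilcoxon_signed(na_ - nb_)
        note <- wt$note
      } else {
        wt <- list(V = NA_real_, p = NA_real_)
      }
      rows[[length(rows) + 1]] <- data.frame(
        from = i, to = j, n_linear = sum(keep_l), t = t, df = df,
        p_linear = p_t, mean_diff = md, sd_diff = sdd,
        n_nonlinear = sum(keep_n), V = wt$V, p_nonlinear = wt$p,
        note = if (is.null(note)) "" else note
      )
    }
  }
  do.call(rbind, rows)
}
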