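test_that("the FIR bandpass matches its frequency-response oracle", {
  sf <- 256
  tt <- seq(0, 20 - 1 / sf, 1 / sf)
  mid <- 1500:3500
  gain_at <- function(f) {
    x <- sin(2 * pi * f * tt)
    sd(bandpass_fir(x, c(4, 7), sf)[mid]) / sd(x[mid])
  }
  expect_lt(abs(gain_at(5.5) - 1), 0.05)
  expect_lt(20 * log10(gain_at(20)), -20)
  expect_equal(bandpass_fir(rep(0, 1000), c(4, 7), sf), rep(0, 1000))
  expect_error(bandpass_fir(rnorm(100), c(7, 4), sf), "band edges")
})

test_that("model-order selection matches the closed-form criteria", {
  set.seed(21)
  # VAR(3) with clear dynamics: the consistent SBC criterion recovers the
  # order in >= 90% of seeds; AIC overselects with its known ~25% chance,
  # so it is held to a correspondingly weaker bound
  A <- list(matrix(c(0.4, 0.2, 0, 0.3), 2, 2), matrix(0, 2, 2),
            matrix(c(-0.3, 0, 0.15, -0.35), 2, 2))
  cs <- coupling_spec(2, A, noise_sd = 1)
  sel <- lapply(1:10, function(s) {
    x <- simulate_sources(cs, 1, 2000, seed = 100 + s)
    select_model_order(matrix(x[1, , ], 2), p_max = 10)
  })
  expect_gte(mean(vapply(sel, function(r) r$order_sbc %in% c(3, 4), logical(1))),
             0.9)
  expect_gte(mean(vapply(sel, function(r) r$order %in% c(3, 4), logical(1))),
             0.6)
  # white noise: the reported order is the AIC minimiser of the table
  wn <- matrix(rnorm(2 * 3000), 2)
  res <- select_model_order(wn, p_max = 6)
  expect_equal(res$order, res$table$p[which.min(res$table$aic)])
  # recompute AIC from scratch for p = 1 as an independent check
  Y <- t(wn[, 2:3000]); X1 <- cbind(1, t(wn[, 1:2999]))
  r <- Y - X1 %*% qr.solve(X1, Y)
  aic1 <- 2999 * determinant(crossprod(r) / 2999, TRUE)$modulus[1] + 2 * 4
  expect_equal(res$table$aic[1], aic1, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(select_model_order(wn, p_max = 1)$order, 1)
})

test_that("the network learns low-noise linear dynamics and nothing from noise", {
  cs <- make_theta_system(2, r = 0.9, lin_coupling = 0.3, noise_sd = 1)
  x <- simulate_sources(cs, 1, 4000, seed = 22)
  sig <- matrix(x[1, , ], 2)
  spec <- nmvar_spec(p = 2, cv_folds = 2, max_epochs = 60)
  net <- train_nmvar_net(sig, spec, seed = 23)
  expect_gt(mean(net$folds$r2_train), 0.95)
  # test error within the training-error range (well-specified model)
  expect_lt(abs(mean(net$folds$r2_test) - mean(net$folds$r2_train)), 0.02)
  # reproducibility: identical data + seed -> identical weights
  net2 <- train_nmvar_net(sig, spec, seed = 23)
  expect_identical(net$W_in, net2$W_in)
  expect_identical(net$W_out, net2$W_out)
  # white noise: nothing to predict
  wn <- matrix(rnorm(2 * 4000), 2)
  netw <- train_nmvar_net(wn, nmvar_spec(p = 2, cv_folds = 2, max_epochs = 30),
                          seed = 24)
  expect_lt(abs(mean(netw$folds$r2_train)), 0.1)
  expect_error(train_nmvar_net(matrix(c(NA, rnorm(199)), 2), spec), "finite")
})

test_that("the decomposition matches a finite-difference oracle", {
  # random small network, checked against numerical derivatives
  set.seed(25)
  M <- 2; p <- 3; H <- 4
  net <- structure(list(
    W_in = matrix(rnorm(H * M * p, sd = 0.4), H, M * p),
    b_hidden = rnorm(H, sd = 0.2),
    W_out = matrix(rnorm(M * H, sd = 0.6), M, H),
    b_out = rnorm(M), M = M,
    spec = nmvar_spec(p = p, hidden_units = H),
    X = matrix(rnorm(40 * M * p), 40, M * p)), class = "trained_net")
  f <- function(u) as.numeric(net$W_out %*% tanh(net$W_in %*% u + net$b_hidden) + net$b_out)
  eps <- 1e-6
  num_jac <- function(u) {
    vapply(seq_len(M * p), function(i) {
      e <- numeric(M * p); e[i] <- eps
      (f(u + e) - f(u - e)) / (2 * eps)
    }, numeric(M))
  }
  J0 <- num_jac(numeric(M * p))
  res <- decompose_connectivity(net)
  lag_cols <- function(i) (seq_len(p) - 1) * M + i
  for (i in 1:M) for (j in 1:M) {
    expect_equal(res$lC[i, j], mean(abs(J0[j, lag_cols(i)])), tolerance = 1e-6)
  }
  # NC: average |sample Jacobian - origin Jacobian| over the stored inputs
  devs <- array(0, c(nrow(net$X), M, M * p))
  for (n in seq_len(nrow(net$X))) {
    devs[n, , ] <- abs(num_jac(net$X[n, ]) - J0)
  }
  for (i in 1:M) for (j in 1:M) {
    expect_equal(res$NC[i, j], mean(devs[, j, lag_cols(i)]), tolerance = 1e-5)
  }
})

test_that("a near-linear network has NC ~ 0 and lC matching the VAR weights", {
  # manufactured net in the tanh linear regime: f(x) ~ (Wout Win) x
  M <- 2; p <- 1; H <- 6
  set.seed(26)
  W1 <- matrix(rnorm(H * M), H, M)
  target <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)  # desired Jacobian
  W2 <- target %*% solve(crossprod(W1), t(W1))  # left pseudo-inverse
  eps <- 1e-3
  net <- structure(list(
    W_in = eps * W1, b_hidden = numeric(H), W_out = W2 / eps,
    b_out = numeric(M), M = M, spec = nmvar_spec(p = 1, hidden_units = H),
    X = matrix(rnorm(200 * M, sd = 0.1), 200, M)), class = "trained_net")
  res <- decompose_connectivity(net)
  # lC[i, j] is i -> j, i.e. |J[j, i]| = |t(target)[i, j]|
  expect_equal(res$lC, t(abs(target)), tolerance = 0.05)
  expect_lt(max(res$NC), 0.01)
})

test_that("the decomposition is equivariant under region permutation", {
  set.seed(27)
  M <- 3; p <- 2; H <- 5
  net <- structure(list(
    W_in = matrix(rnorm(H * M * p), H, M * p), b_hidden = rnorm(H),
    W_out = matrix(rnorm(M * H), M, H), b_out = rnorm(M), M = M,
    spec = nmvar_spec(p = p, hidden_units = H),
    X = matrix(rnorm(50 * M * p), 50, M * p)), class = "trained_net")
  res <- decompose_connectivity(net)
  perm <- c(2, 3, 1)
  cols <- as.vector(vapply(seq_len(p), function(k) (k - 1) * M + perm,
                           numeric(M)))
  net_p <- net
  net_p$W_in <- net$W_in[, cols]
  net_p$W_out <- net$W_out[perm, ]
  net_p$b_out <- net$b_out[perm]
  net_p$X <- net$X[, cols]
  res_p <- decompose_connectivity(net_p)
  expect_equal(res_p$lC, res$lC[perm, perm], tolerance = 1e-12)
  expect_equal(res_p$NC, res$NC[perm, perm], tolerance = 1e-12)
})

test_that("connectivity is invariant to rescaling an input channel", {
  cs <- make_theta_system(2, r = 0.7, lin_coupling = 0.3)
  x <- simulate_sources(cs, 1, 3000, seed = 28)
  sig <- matrix(x[1, , ], 2)
  spec <- nmvar_spec(p = 2, cv_folds = 2, max_epochs = 40)
  r1 <- decompose_connectivity(train_nmvar_net(sig, spec, seed = 29))
  sig2 <- sig; sig2[1, ] <- 10 * sig[1, ]
  r2 <- decompose_connectivity(train_nmvar_net(sig2, spec, seed = 29))
  expect_equal(r1$lC, r2$lC, tolerance = 1e-10)
  expect_equal(r1$NC, r2$NC, tolerance = 1e-10)
})

test_that("square coupling raises directed NC above the reverse direction", {
  w <- 2 * pi * 5.5 / 256; r <- 0.5
  A1 <- diag(2 * r * cos(w), 2); A2 <- diag(-r^2, 2)
  nl <- data.frame(target = 2, source = 1, lag = 1, gain = 0.3, fun = "square")
  cs <- coupling_spec(2, list(A1, A2), nonlinear_terms = nl, noise_sd = 1)
  x <- simulate_sources(cs, 1, 5000, seed = 30)
  sig <- matrix(x[1, , ], 2)
  spec <- nmvar_spec(p = 2, cv_folds = 2, max_epochs = 120)
  res <- decompose_connectivity(train_nmvar_net(sig, spec, seed = 31))
  expect_gt(res$NC[1, 2], res$NC[2, 1])
})

test_that("circular shifting preserves the autocorrelation function", {
  set.seed(32)
  x <- as.numeric(arima.sim(list(ar = 0.8), 3000))
  y <- uncflow:::circshift(x, 700)
  a1 <- acf(x, lag.max = 10, plot = FALSE)$acf
  a2 <- acf(y, lag.max = 10, plot = FALSE)$acf
  expect_lt(max(abs(a1 - a2)), 0.05)
  expect_identical(sort(x), sort(y))
})

test_that("a strongly coupled pair exceeds its surrogate threshold", {
  hits <- vapply(1:5, function(s) {
    cs <- make_theta_system(2, r = 0.5, lin_coupling = 0.4)
    x <- simulate_sources(cs, 1, 3000, seed = 400 + s)
    sig <- matrix(x[1, , ], 2)
    spec <- nmvar_spec(p = 2, cv_folds = 2, max_epochs = 100)
    res <- estimate_connectivity(sig, spec, seed = 500 + s, n_surrogates = 30)
    res$mask_lC[1, 2]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Wilcoxon matches an exhaustive enumeration oracle", {
  d <- c(1, 2, -1.5, 3, 2.5)
  res <- uncflow:::wilcoxon_signed(d)
  # brute force: V = sum of ranks of |d| with positive sign
  r <- rank(abs(d))
  expect_equal(res$V, sum(r[d > 0]))  # 13
  # exact two-sided p from all 2^5 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  Vnull <- signs %*% r
  p_exact <- min(1, 2 * min(mean(Vnull >= res$V), mean(Vnull <= res$V)))
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("group comparison applies masks, t and Wilcoxon as specified", {
  mk_res <- function(lC, NC, mask = TRUE) {
    structure(list(lC = lC, NC = NC, M = 2,
                   mask_lC = matrix(mask, 2, 2), mask_NC = matrix(mask, 2, 2)),
              class = "connectivity_result")
  }
  # identical conditions: t = 0, Wilcoxon p = 1 with note
  resA <- lapply(1:6, function(s) mk_res(matrix(s / 10, 2, 2), matrix(s / 20, 2, 2)))
  out <- group_compare(resA, resA, use_mask = FALSE)
  expect_true(all(out$t == 0))
  expect_true(all(out$p_nonlinear == 1))
  expect_match(out$note[1], "zero")
  # t oracle at mean .006, sd .012, n 35 (the reduced-df situation)
  set.seed(33)
  raw <- rnorm(35); dd <- (raw - mean(raw)) / sd(raw) * 0.012 + 0.006
  A <- lapply(seq_len(35), function(s) mk_res(matrix(0.03 + dd[s], 2, 2),
                                              matrix(0.02 + dd[s], 2, 2)))
  B <- lapply(seq_len(35), function(s) mk_res(matrix(0.03, 2, 2),
                                              matrix(0.02, 2, 2)))
  out2 <- group_compare(A, B)
  expect_equal(out2$t[1], 0.006 / (0.012 / sqrt(35)), tolerance = 1e-10)
  expect_equal(out2$df[1], 34)
  expect_lt(out2$p_linear[1], 0.01)
  # masked-out subjects shrink n per connection
  C <- A; C[[1]]$mask_lC[] <- FALSE
  out3 <- group_compare(C, B)
  expect_equal(out3$n_linear[1], 34)
})
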