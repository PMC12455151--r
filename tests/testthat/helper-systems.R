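# shared ground-truth systems and small fixtures, built in code

# stationary AR(2) resonance at f0 Hz on the diagonal, optional linear
# 1 -> 2 coupling and square 2 -> 3 coupling
make_theta_system <- function(M = 2, r = 0.7, f0 = 5.5, sfreq = 256,
                              lin_coupling = 0, square_gain = 0,
                              noise_sd = 1) {
  w <- 2 * pi * f0 / sfreq
  A1 <- diag(2 * r * cos(w), M)
  A2 <- diag(-r^2, M)
  nl <- NULL
  if (lin_coupling != 0) A1[2, 1] <- lin_coupling
  if (square_gain != 0) {
    stopifnot(M >= 3)
    nl <- data.frame(target = 3, source = 2, lag = 1, gain = square_gain,
                     fun = "square")
  }
  coupling_spec(M, list(A1, A2), nonlinear_terms = nl, noise_sd = noise_sd)
}

# subjects x channels paired-difference matrix with exact per-channel t
# values: every channel shares a zero-mean unit-sd pattern, so
# t_j = mu_j * sqrt(n)
exact_t_differences <- function(tvals, n = 10) {
  pattern <- as.numeric(scale(seq_len(n)))
  mu <- tvals / sqrt(n)
  outer(pattern, rep(1, length(tvals))) +
    matrix(mu, n, length(tvals), byrow = TRUE)
}

# chain adjacency graph over k channels at unit spacing
chain_graph <- function(k) {
  build_neighbors(cbind(seq_len(k), 0, 0), threshold = 1)
}
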