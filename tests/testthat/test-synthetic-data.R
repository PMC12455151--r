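test_that("default design reproduces the session structure", {
  tab <- generate_trial_table(design_spec(), behavior_params(), seed = 1)
  expect_equal(nrow(tab), 768)
  expect_equal(unname(table(tab$condition)), rep(256L, 3), ignore_attr = TRUE)
  expect_equal(mean(tab$validity == "valid"), 0.25)
  # valid <=> cue and target collocated
  expect_true(all((tab$validity == "valid") == (tab$cue_loc == tab$target_loc)))
})

test_that("trial generation is deterministic and validates its config", {
  t1 <- generate_trial_table(design_spec(), seed = 42)
  t2 <- generate_trial_table(design_spec(), seed = 42)
  expect_identical(t1, t2)
  d1 <- generate_trial_table(design_spec(p_valid = 1), seed = 3)
  expect_true(all(d1$cue_loc == d1$target_loc))
  bad <- behavior_params()
  bad <- bad[bad$condition != "low_uc" | bad$validity != "invalid", ]
  expect_error(generate_trial_table(design_spec(), bad), "low_uc invalid")
})

test_that("hit = fa = 0.5 yields empirical d' near zero at 1e4 trials", {
  des <- design_spec(conditions = "c1", trials_per_block = 10000L)
  beh <- behavior_params(data.frame(
    condition = "c1", validity = c("valid", "invalid"),
    hit_rate = 0.5, fa_rate = 0.5, rt_mu = log(400), rt_sigma = 0.3))
  tab <- generate_trial_table(des, beh, seed = 11)
  dp <- compute_dprime(sum(tab$target == "E" & tab$correct == 1),
                       sum(tab$target == "E" & tab$correct == 0),
                       sum(tab$target == "H" & tab$correct == 0),
                       sum(tab$target == "H" & tab$correct == 1))
  expect_lt(abs(dp), 0.1)
})

test_that("per-cell accuracy converges to the configured mixture", {
  # accuracy in a cell is a 50/50 mixture of hit_rate and 1 - fa_rate
  des <- design_spec(conditions = "c1", trials_per_block = 8000L)
  beh <- behavior_params(data.frame(
    condition = "c1", validity = c("valid", "invalid"),
    hit_rate = c(0.9, 0.7), fa_rate = c(0.2, 0.4),
    rt_mu = log(400), rt_sigma = 0.3))
  tab <- generate_trial_table(des, beh, seed = 12)
  for (v in c("valid", "invalid")) {
    cell <- tab[tab$validity == v, ]
    p_exp <- 0.5 * beh$hit_rate[beh$validity == v] +
      0.5 * (1 - beh$fa_rate[beh$validity == v])
    ci <- stats::binom.test(sum(cell$correct), nrow(cell))$conf.int
    expect_true(p_exp >= ci[1] && p_exp <= ci[2])
  }
})

test_that("MVAR simulation matches a least-squares refit oracle", {
  cs <- coupling_spec(2, list(matrix(c(0.5, 0.4, 0, 0.5), 2, 2)), noise_sd = 1)
  x <- simulate_sources(cs, 1, 10000, seed = 2)
  xm <- matrix(x[1, , ], 2)
  B <- t(qr.solve(t(xm[, -10000]), t(xm[, -1])))
  expect_lt(max(abs(B - matrix(c(0.5, 0.4, 0, 0.5), 2, 2))), 0.05)
})

test_that("zero coupling gives white noise; zero noise decays to zero", {
  cs0 <- coupling_spec(2, list(matrix(0, 2, 2)), noise_sd = 1)
  x <- simulate_sources(cs0, 1, 10000, seed = 4)
  x1 <- x[1, 1, ]; x2 <- x[1, 2, ]
  expect_lt(abs(cor(x1[-1], x2[-10000])), 0.05)
  expect_lt(abs(cor(x2[-1], x1[-10000])), 0.05)
  csd <- make_theta_system(2, r = 0.7, noise_sd = 0)
  xd <- simulate_sources(csd, 1, 500, seed = 5, burn_in = 0,
                         init = matrix(5, 2, 2))
  expect_lt(max(abs(xd[1, , 450:500])), 1e-3)
  expect_gt(max(abs(xd[1, , 1:10])), 0.1)
})

test_that("unstable linear systems are rejected", {
  expect_error(coupling_spec(2, list(diag(1.05, 2))), "non-stationary")
})

test_that("sensor projection obeys the leadfield algebra", {
  src <- array(rnorm(2 * 3 * 50), c(2, 3, 50))
  ident <- sensor_model(diag(3), matrix(rnorm(9), 3, 3), sensor_noise_sd = 0)
  ep <- project_to_sensors(src, ident, seed = 1)
  expect_equal(ep$data, src)
  # single active source, zero noise: channels are scalar multiples
  lf <- matrix(runif(3 * 4, 0.5, 2), 3, 4)
  m <- sensor_model(lf, matrix(rnorm(12), 4, 3), sensor_noise_sd = 0)
  src1 <- array(0, c(1, 3, 100)); src1[1, 2, ] <- rnorm(100)
  ep1 <- project_to_sensors(src1, m, seed = 1)
  for (ch in 2:4) {
    expect_equal(abs(cor(ep1$data[1, 1, ], ep1$data[1, ch, ])), 1)
  }
  # doubling a leadfield row doubles that source's contribution (variance x4)
  src2 <- array(0, c(1, 3, 2000)); src2[1, 1, ] <- rnorm(2000)
  lf2 <- lf; lf2[1, ] <- 2 * lf[1, ]
  m2 <- sensor_model(lf2, m$channel_coords, sensor_noise_sd = 0)
  v1 <- apply(project_to_sensors(src2, m, seed = 1)$data[1, , ], 1, var)
  v2 <- apply(project_to_sensors(src2, m2, seed = 1)$data[1, , ], 1, var)
  expect_equal(v2 / v1, rep(4, 4), tolerance = 1e-10)
  expect_error(project_to_sensors(array(0, c(1, 5, 10)), m), "got 5")
})

test_that("oscillatory epochs respect amplitudes and validate bands", {
  des <- design_spec(epoch_window = c(-1, 1.5))
  model <- make_spherical_sensor_model(12, 4)
  eff0 <- data.frame(condition = "high_uc", validity = "invalid",
                     theta_amp = 0, alpha_amp = 0)
  ep <- generate_band_power_epochs(des, eff0, model, n_trials = 12,
                                   base_amp = c(theta = 0, alpha = 0),
                                   seed = 7)[[1]]
  tf <- morlet_power(ep, morlet_spec(4:7, sfreq = des$sfreq))
  post <- band_window_average(tf, c(4, 7), c(0, 0.9))
  pre <- band_window_average(tf, c(4, 7), c(-0.4, 0))
  expect_lt(abs(mean(post) - mean(pre)) / mean(pre), 0.25)
  expect_error(
    generate_band_power_epochs(des, eff0, model, burst_freqs = c(theta = 9, alpha = 10)),
    "theta")
})
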