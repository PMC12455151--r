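test_that("participant screening applies a strict 55% accuracy cut", {
  mk <- function(acc, n = 100) {
    data.frame(condition = "c", validity = "invalid", target = "E",
               correct = rep(c(1L, 0L), c(round(acc * n), n - round(acc * n))),
               rt_ms = 400)
  }
  res <- screen_participants(list(a = mk(0.54), b = mk(0.56), c = mk(1)))
  expect_identical(res$retained, c("b", "c"))
  expect_identical(res$excluded, "a")
  expect_error(screen_participants(list(ok = mk(0.9), empty = mk(0.9)[0, ])),
               "empty")
})

test_that("RT filtering keeps correct trials inside [100, 2000] ms inclusive", {
  tab <- data.frame(correct = 1L, rt_ms = c(50, 150, 800, 2500))
  expect_equal(filter_rts(tab)$rt_ms, c(150, 800))
  # bounds are strict "faster/slower than", so the limits themselves survive
  tab2 <- data.frame(correct = 1L, rt_ms = c(100, 2000, 99.99, 2000.01))
  expect_equal(filter_rts(tab2)$rt_ms, c(100, 2000))
  tab3 <- data.frame(correct = 0L, rt_ms = c(500, 600))
  expect_warning(out <- filter_rts(tab3), "no trials")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "removed_fraction"), 1)
})

test_that("d' follows the inverse-normal definition with extreme-rate correction", {
  expect_equal(compute_dprime(50, 50, 50, 50), 0)
  expect_equal(compute_dprime(90, 10, 10, 90),
               qnorm(0.9) - qnorm(0.1), tolerance = 1e-12)
  # 100/0 at N = 100: rate corrected to 1 - 1/(2*100) = 0.995
  expect_equal(compute_dprime(100, 0, 10, 90),
               qnorm(0.995) - qnorm(0.1), tolerance = 1e-12)
  expect_equal(compute_dprime(0, 50, 5, 45),
               qnorm(1 / 100) - qnorm(0.1), tolerance = 1e-12)
  expect_error(compute_dprime(0, 0, 5, 5), "signal")
})

test_that("d' is unchanged when the signal/noise letters are reassigned", {
  # under the correctness-based convention, reversing which letter counts
  # as signal maps hits <-> correct rejections and misses <-> false alarms,
  # and z(1-x) = -z(x) leaves d' invariant — the assignment is arbitrary
  for (counts in list(c(80, 20, 30, 70), c(55, 45, 10, 90), c(99, 1, 50, 50))) {
    d1 <- compute_dprime(counts[1], counts[2], counts[3], counts[4])
    d2 <- compute_dprime(counts[4], counts[3], counts[2], counts[1])
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("subject summaries carry one row per cell with valid fields", {
  tab <- generate_trial_table(design_spec(), seed = 2)
  s <- subject_summary(tab)
  expect_equal(nrow(s), 6)
  expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
  expect_true(all(s$n_trials_used <= 256))
})

test_that("rm_anova matches the aov error-strata oracle to 1e-10", {
  set.seed(31)
  dat <- expand.grid(subject = factor(1:4), condition = c("a", "b", "c"),
                     validity = c("v", "i"))
  dat$y <- rnorm(24) + 0.8 * (dat$condition == "b") + 0.3 * (dat$validity == "v")
  mine <- rm_anova(dat, "y")
  fit <- summary(stats::aov(
    y ~ condition * validity + Error(subject / (condition * validity)), dat))
  f_or <- c(fit[["Error: subject:condition"]][[1]]["condition", "F value"],
            fit[["Error: subject:validity"]][[1]]["validity", "F value"],
            fit[["Error: subject:condition:validity"]][[1]][
              "condition:validity", "F value"])
  expect_equal(mine$F, f_or, tolerance = 1e-10)
  expect_true(all(mine$pes >= 0 & mine$pes <= 1))
  expect_equal(mine$df_num, c(2, 1, 2))
  expect_equal(mine$df_den, c(6, 3, 6))
})

test_that("rm_anova handles degenerate structure as specified", {
  dat <- expand.grid(subject = 1:5, condition = c("a", "b", "c"),
                     validity = c("v", "i"))
  dat$y <- 1  # identical everywhere
  res <- rm_anova(dat, "y")
  expect_equal(res$F, rep(0, 3))
  # constant within subject, differing between subjects: still no effect
  dat$y <- as.numeric(dat$subject)
  res2 <- rm_anova(dat, "y")
  expect_equal(res2$F, rep(0, 3))
  # per-subject constants do not change F
  set.seed(5)
  dat$y <- rnorm(nrow(dat))
  base <- rm_anova(dat, "y")
  dat$y2 <- dat$y + 100 * as.numeric(dat$subject)
  shifted <- rm_anova(dat, "y2")
  expect_equal(base$F, shifted$F, tolerance = 1e-8)
  expect_error(rm_anova(dat[-1, ], "y"), "missing cells|one observation")
})

test_that("paired contrasts match the closed-form t oracle", {
  dat <- expand.grid(subject = 1:3, condition = c("a", "b"), validity = "v")
  dat$y <- c(1, 2, 3, 1, 2, 3)
  same <- paired_contrasts(dat, "y", list(condition = "a"),
                           list(condition = "b"))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # differences engineered to mean .006, sd .012, n 35
  set.seed(8)
  raw <- rnorm(35)
  d <- (raw - mean(raw)) / sd(raw) * 0.012 + 0.006
  dat2 <- data.frame(subject = rep(1:35, 2),
                     condition = rep(c("a", "b"), each = 35),
                     y = c(d, rep(0, 35)))
  res <- paired_contrasts(dat2, "y", list(condition = "a"),
                          list(condition = "b"))
  expect_equal(res$t, 0.006 / (0.012 / sqrt(35)), tolerance = 1e-10)
  expect_equal(res$df, 34)
  # swapping the cells flips the sign exactly
  rev <- paired_contrasts(dat2, "y", list(condition = "b"),
                          list(condition = "a"))
  expect_equal(rev$t, -res$t, tolerance = 1e-12)
})

test_that("paired contrast type-I rate is calibrated under the null", {
  # vectorised null simulation: 1e4 paired designs of n = 12
  set.seed(77)
  n <- 12; nsim <- 10000
  D <- matrix(rnorm(n * nsim), n, nsim)
  t <- colMeans(D) / (apply(D, 2, sd) / sqrt(n))
  # oracle identical to paired_contrasts' formula; spot-check agreement
  d1 <- data.frame(subject = 1:n, condition = "a", y = D[, 1])
  d2 <- data.frame(subject = 1:n, condition = "b", y = 0)
  pc <- paired_contrasts(rbind(d1, d2), "y", list(condition = "a"),
                         list(condition = "b"))
  expect_equal(pc$t, t[1], tolerance = 1e-10)
  rej <- mean(2 * pt(-abs(t), n - 1) < 0.05)
  expect_lte(rej, 0.055)
})

test_that("a-priori paired-t sample size matches the standard computation", {
  expect_identical(paired_t_sample_size(1.01, 0.8, 0.05), 10L)
  # larger effects need fewer subjects
  expect_lt(paired_t_sample_size(1.5), paired_t_sample_size(0.8))
})
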