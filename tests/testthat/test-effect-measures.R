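test_that("binary log effects and variances match hand-computed values", {
  e <- effect_binary(10, 100, 5, 100, "logRR", correction = "none")
  expect_equal(e$y, log(2), tolerance = 1e-12)
  expect_equal(e$v, 1 / 10 - 1 / 100 + 1 / 5 - 1 / 100, tolerance = 1e-12)

  expect_equal(effect_binary(7, 50, 7, 50, "logOR")$y, 0, tolerance = 1e-12)

  e <- effect_binary(0, 10, 5, 10, "logOR")  # add_half default
  expect_equal(e$y, log((0.5 * 5.5) / (10.5 * 5.5)), tolerance = 1e-12)
  expect_equal(e$v, 1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5, tolerance = 1e-12)

  # corrected logRR uses the inflated arm totals
  e <- effect_binary(0, 10, 5, 10, "logRR")
  expect_equal(e$y, log((0.5 / 11) / (5.5 / 11)), tolerance = 1e-12)
})

test_that("uninformative 2x2 tables are flagged non-estimable, not dropped silently", {
  e <- effect_binary(0, 20, 0, 25, "logOR")
  expect_false(is_estimable(e))
  expect_match(e$reason, "zero events")
  expect_false(is_estimable(effect_binary(20, 20, 25, 25, "logRR")))
  expect_false(is_estimable(
    effect_binary(0, 10, 5, 10, "logOR", correction = "none")))
})

test_that("continuous effects match hand-computed values", {
  e <- effect_continuous(1, 1, 20, 0, 1, 20, "MD")
  expect_equal(e$y, 1, tolerance = 1e-12)
  expect_equal(e$v, 0.1, tolerance = 1e-12)

  expect_equal(effect_continuous(5, 2, 30, 5, 2, 30, "MD")$y, 0)

  # Hedges g with the small-sample factor applied to estimate and variance
  J <- 1 - 3 / 151
  g <- effect_continuous(1, 1, 20, 0, 1, 20, "SMD")
  expect_equal(g$y, J * 1, tolerance = 1e-10)
  expect_equal(g$v, J^2 * (1 / 20 + 1 / 20 + 1 / 80), tolerance = 1e-10)
  expect_equal(g$y, 0.9801, tolerance = 1e-4)
  expect_equal(g$v, 0.1080, tolerance = 1e-3)

  d <- effect_continuous(1, 1, 20, 0, 1, 20, "SMD", smd_variant = "cohen_d")
  expect_equal(d$y, 1, tolerance = 1e-10)
})

test_that("before-after designs require the pre/post correlation", {
  expect_error(
    effect_continuous(1, 1, 20, 0, 1, 20, "MD", design = "prepost"),
    "prepost_correlation")
  e <- effect_continuous(1, 2, 20, 0, 2, 20, "MD", design = "prepost",
                         prepost_correlation = 0.5)
  sd_change <- sqrt(4 + 4 - 2 * 0.5 * 2 * 2)
  expect_equal(e$v, sd_change^2 / 20, tolerance = 1e-12)
})

test_that("reported estimate/CI inversion recovers the analysis-scale effect", {
  e <- effect_from_reported(2.0, 1.0, 4.0, "logOR")
  expect_equal(e$y, log(2), tolerance = 1e-12)
  expect_equal(sqrt(e$v), log(4) / (2 * qnorm(0.975)), tolerance = 1e-10)
  expect_equal(sqrt(e$v), 0.3537, tolerance = 1e-3)

  e <- effect_from_reported(0, -1.959964, 1.959964, "MD")
  expect_equal(e$y, 0)
  expect_equal(sqrt(e$v), 1, tolerance = 1e-6)

  e <- effect_from_reported(1.0, 0.5, 2.0, "logRR")
  expect_equal(e$y, 0, tolerance = 1e-12)
  expect_equal(sqrt(e$v), 0.3537, tolerance = 1e-3)

  expect_error(effect_from_reported(5, 1, 4, "logOR"), "inconsistent report")
  expect_error(effect_from_reported(-1, -2, 1, "logRR"), "inconsistent report")
})

test_that("swapping arm labels negates the effect and keeps the variance", {
  set.seed(11)
  for (i in 1:20) {
    e1 <- sample(1:30, 1); n1 <- e1 + sample(10:100, 1)
    e2 <- sample(1:30, 1); n2 <- e2 + sample(10:100, 1)
    for (m in c("logOR", "logRR")) {
      a <- effect_binary(e1, n1, e2, n2, m)
      b <- effect_binary(e2, n2, e1, n1, m)
      expect_equal(a$y, -b$y, tolerance = 1e-12)
      if (m == "logOR") expect_equal(a$v, b$v, tolerance = 1e-12)
    }
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, .5, 2); s2 <- runif(1, .5, 2)
    a <- effect_continuous(m1, s1, 25, m2, s2, 30, "SMD")
    b <- effect_continuous(m2, s2, 30, m1, s1, 25, "SMD")
    expect_equal(a$y, -b$y, tolerance = 1e-12)
    expect_equal(a$v, b$v, tolerance = 1e-12)
  }
})

test_that("reported-CI inversion is the right inverse of CI construction", {
  set.seed(7)
  z <- qnorm(0.975)
  for (i in 1:50) {
    y <- rnorm(1); v <- runif(1, 0.001, 1)
    for (m in c("MD", "logRR")) {
      if (m == "MD")
        est <- c(y, y - z * sqrt(v), y + z * sqrt(v))
      else
        est <- exp(c(y, y - z * sqrt(v), y + z * sqrt(v)))
      back <- effect_from_reported(est[1], est[2], est[3], m)
      expect_equal(back$y, y, tolerance = 1e-10)
      expect_equal(back$v, v, tolerance = 1e-10)
    }
  }
})

test_that("Hedges g approaches Cohen d as samples grow", {
  g <- effect_continuous(0.5, 1, 200, 0, 1, 200, "SMD")
  d <- effect_continuous(0.5, 1, 200, 0, 1, 200, "SMD", smd_variant = "cohen_d")
  expect_lt(abs(g$y - d$y), 0.01)
})

test_that("log-RR variance formula matches the Monte-Carlo sampling variance", {
  set.seed(42)
  n <- 100; p1 <- 0.3; p2 <- 0.2
  e1 <- rbinom(1e4, n, p1); e2 <- rbinom(1e4, n, p2)
  ok <- e1 > 0 & e2 > 0
  y <- log((e1[ok] / n) / (e2[ok] / n))
  v_formula <- 1 / (n * p1) - 1 / n + 1 / (n * p2) - 1 / n
  expect_lt(abs(var(y) - v_formula) / v_formula, 0.10)
})

test_that("effects agree with metafor escalc where conventions coincide", {
  skip_if_not_installed("metafor")
  for (m in list(c("logOR", "OR"), c("logRR", "RR"))) {
    mine <- effect_binary(12, 80, 7, 90, m[1], correction = "none")
    ref <- metafor::escalc(measure = m[2], ai = 12, n1i = 80, ci = 7,
                           n2i = 90, to = "none")
    expect_equal(mine$y, as.numeric(ref$yi), tolerance = 1e-10)
    expect_equal(mine$v, as.numeric(ref$vi), tolerance = 1e-10)
  }
  mine <- effect_continuous(3.1, 1.2, 40, 2.5, 1.4, 45, "MD")
  ref <- metafor::escalc(measure = "MD", m1i = 3.1, sd1i = 1.2, n1i = 40,
                         m2i = 2.5, sd2i = 1.4, n2i = 45)
  expect_equal(mine$y, as.numeric(ref$yi), tolerance = 1e-10)
  expect_equal(mine$v, as.numeric(ref$vi), tolerance = 1e-10)
})

test_that("per-review effect tables route rows by available data", {
  studies <- data.frame(
    review_id = "r1", study_id = c("s1", "s2", "s3"),
    measure = "logOR",
    e1 = c(10, NA, 0), n1 = c(50, NA, 20),
    e2 = c(5, NA, 0), n2 = c(50, NA, 25),
    m1 = NA_real_, sd1 = NA_real_, m2 = NA_real_, sd2 = NA_real_,
    yi = c(NA, 1.8, NA), ci_low = c(NA, 1.1, NA), ci_high = c(NA, 3.0, NA),
    prepost_r = NA_real_)
  eff <- compute_study_effects(studies, "logOR")
  expect_equal(eff$source[1:2], c("from_summary_stats", "from_reported"))
  expect_false(eff$estimable[3])  # double-zero study
  expect_equal(sum(eff$estimable), 2)
})
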