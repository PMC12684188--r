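test_that("DerSimonian-Laird matches its closed form at k = 2", {
  out <- estimate_tau2(c(0.1, 0.5), c(0.04, 0.04), "DL")
  expect_equal(out$Q, 2, tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_equal(out$tau2, 0.04, tolerance = 1e-12)  # C = 25, (Q - df)/C

  # identical estimates: Q = 0, truncation at zero
  out <- estimate_tau2(c(0.3, 0.3), c(0.04, 0.09), "DL")
  expect_equal(out$Q, 0, tolerance = 1e-12)
  expect_equal(out$tau2, 0)

  expect_error(estimate_tau2(0.3, 0.04, "DL"), "insufficient studies")
})

test_that("REML matches an iteratively refined grid-search oracle", {
  cases <- list(
    list(yi = c(0.1, 0.5), vi = c(0.04, 0.04)),
    list(yi = c(-0.2, 0.1, 0.4, 0.9), vi = c(0.02, 0.05, 0.03, 0.08)),
    list(yi = c(0.3, 0.31, 0.29), vi = c(0.04, 0.05, 0.06)))  # near-zero tau2
  for (cs in cases) {
    oracle <- grid_reml(cs$yi, cs$vi)
    expect_equal(estimate_tau2(cs$yi, cs$vi, "REML")$tau2, oracle,
                 tolerance = 1e-6)
  }
  set.seed(5)
  for (i in 1:25) {
    inst <- random_instance()
    oracle <- grid_reml(inst$yi, inst$vi)
    expect_equal(estimate_tau2(inst$yi, inst$vi, "REML")$tau2, oracle,
                 tolerance = max(1e-6, 1e-6 * oracle))
  }
})

test_that("Paule-Mandel solves its estimating equation", {
  set.seed(9)
  for (i in 1:20) {
    inst <- random_instance()
    t2 <- estimate_tau2(inst$yi, inst$vi, "PM")$tau2
    w <- 1 / (inst$vi + t2)
    mu <- sum(w * inst$yi) / sum(w)
    gen_q <- sum(w * (inst$yi - mu)^2)
    if (t2 > 0) expect_equal(gen_q, length(inst$yi) - 1, tolerance = 1e-6)
    else expect_lte(gen_q, length(inst$yi) - 1 + 1e-8)
  }
})

test_that("tau2 estimators agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(21)
  for (i in 1:10) {
    inst <- random_instance()
    for (m in c("DL", "REML", "PM")) {
      ref <- suppressWarnings(
        metafor::rma(yi = inst$yi, vi = inst$vi, method = m))
      # metafor iterates to its own (looser) convergence threshold
      expect_lt(abs(estimate_tau2(inst$yi, inst$vi, m)$tau2 - ref$tau2),
                1e-4)
    }
  }
})

test_that("inverse-variance pooling matches hand calculations", {
  # equal weights reduce to the arithmetic mean
  r <- pool_inverse_variance(c(1, 2, 3), c(1, 1, 1), meta_config("fixed"))
  expect_equal(r$y_pooled, 2, tolerance = 1e-12)

  # a single study is returned unchanged, CI included
  r <- pool_inverse_variance(0.4, 0.01, meta_config("fixed"))
  expect_equal(r$y_pooled, 0.4)
  expect_equal(r$ci_low, 0.4 - qnorm(0.975) * 0.1, tolerance = 1e-12)

  # random effects with DL at k = 2: tau2 = 0.04, equal weights 12.5
  r <- pool_inverse_variance(c(0.1, 0.5), c(0.04, 0.04),
                             meta_config("random", tau2_estimator = "DL"))
  expect_equal(r$tau2, 0.04, tolerance = 1e-12)
  expect_equal(r$y_pooled, 0.3, tolerance = 1e-12)
  expect_equal(r$se_pooled, 0.2, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * (1 - pnorm(1.5)), tolerance = 1e-12)
  expect_equal(r$p_value, 0.1336, tolerance = 1e-3)

  expect_error(pool_inverse_variance(numeric(0), numeric(0)), "no estimable")
})

test_that("single-study random-effects requests fall back to fixed with a note", {
  r <- pool_inverse_variance(0.4, 0.01, meta_config("random"))
  expect_equal(r$config$model, "fixed")
  expect_match(r$notes, "single study", all = FALSE)
})

test_that("fixed-effect pooling matches the brute-force weighted mean on random instances", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_instance()
    r <- pool_inverse_variance(inst$yi, inst$vi, meta_config("fixed"))
    oracle <- brute_force_fixed(inst$yi, inst$vi)
    expect_equal(r$y_pooled, oracle$y, tolerance = 1e-12)
    expect_equal(r$se_pooled, oracle$se, tolerance = 1e-12)
    expect_equal(sum(r$weights), 1, tolerance = 1e-9)
    expect_gte(r$y_pooled, min(inst$yi))
    expect_lte(r$y_pooled, max(inst$yi))
    expect_equal(dl_closed_form(inst$yi, inst$vi),
                 estimate_tau2(inst$yi, inst$vi, "DL")$tau2,
                 tolerance = 1e-12)
  }
})

test_that("random-effects intervals are at least as wide as fixed-effect ones", {
  set.seed(31)
  for (i in 1:50) {
    inst <- random_instance()
    fe <- pool_inverse_variance(inst$yi, inst$vi, meta_config("fixed"))
    re <- pool_inverse_variance(inst$yi, inst$vi,
                                meta_config("random", tau2_estimator = "DL"))
    expect_gte(re$ci_high - re$ci_low + 1e-12, fe$ci_high - fe$ci_low)
  }
})

test_that("Hartung-Knapp interval uses the t distribution and the weighted residual variance", {
  skip_if_not_installed("metafor")
  set.seed(77)
  inst <- random_instance(6)
  r <- pool_inverse_variance(inst$yi, inst$vi,
                             meta_config("random", tau2_estimator = "DL",
                                         ci_method = "hartung_knapp"))
  ref <- suppressWarnings(metafor::rma(yi = inst$yi, vi = inst$vi,
                                       method = "DL", test = "knha"))
  expect_equal(r$y_pooled, as.numeric(ref$b), tolerance = 1e-8)
  expect_equal(r$ci_low, ref$ci.lb, tolerance = 1e-6)
  expect_equal(r$ci_high, ref$ci.ub, tolerance = 1e-6)
  expect_equal(r$p_value, ref$pval, tolerance = 1e-6)
})

test_that("Mantel-Haenszel pooling matches the crude OR for one stratum and is replication-invariant", {
  one <- data.frame(e1 = 10, n1 = 100, e2 = 5, n2 = 100)
  r <- pool_mantel_haenszel(one, "logOR")
  expect_equal(exp(r$y_pooled), (10 * 95) / (90 * 5), tolerance = 1e-12)

  two <- rbind(one, one)
  r2 <- pool_mantel_haenszel(two, "logOR")
  expect_equal(r2$y_pooled, r$y_pooled, tolerance = 1e-12)

  # a double-zero stratum contributes nothing
  with_zero <- rbind(one, data.frame(e1 = 0, n1 = 40, e2 = 0, n2 = 45))
  rz <- pool_mantel_haenszel(with_zero, "logOR")
  expect_equal(rz$y_pooled, r$y_pooled, tolerance = 1e-12)
  expect_match(rz$notes, "non-estimable", all = FALSE)

  expect_error(
    pool_mantel_haenszel(data.frame(e1 = 0, n1 = 10, e2 = 0, n2 = 10), "logOR"),
    "all strata non-estimable")
})

test_that("Mantel-Haenszel agrees with metafor rma.mh, both measures", {
  skip_if_not_installed("metafor")
  tab <- data.frame(e1 = c(12, 5, 30), n1 = c(80, 40, 200),
                    e2 = c(7, 9, 21), n2 = c(90, 44, 190))
  for (m in list(c("logOR", "OR"), c("logRR", "RR"))) {
    r <- pool_mantel_haenszel(tab, m[1])
    ref <- metafor::rma.mh(measure = m[2], ai = tab$e1, n1i = tab$n1,
                           ci = tab$e2, n2i = tab$n2, correct = FALSE)
    expect_equal(r$y_pooled, as.numeric(ref$b), tolerance = 1e-10)
    expect_equal(r$se_pooled, ref$se, tolerance = 1e-10)
  }
})

test_that("Mantel-Haenszel approaches fixed-effect IV for large balanced strata", {
  tab <- data.frame(e1 = c(3000, 2800), n1 = c(10000, 10000),
                    e2 = c(2000, 2100), n2 = c(10000, 10000))
  mh <- pool_mantel_haenszel(tab, "logOR")
  eff <- compute_study_effects(
    data.frame(review_id = "x", study_id = c("a", "b"), measure = "logOR",
               tab, m1 = NA_real_, sd1 = NA_real_, m2 = NA_real_,
               sd2 = NA_real_, yi = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, prepost_r = NA_real_), "logOR")
  iv <- pool_inverse_variance(eff$yi, eff$vi, meta_config("fixed"), "logOR")
  expect_lt(abs(mh$y_pooled - iv$y_pooled) / abs(iv$y_pooled), 0.01)
})

test_that("heterogeneity summaries follow their definitions", {
  h <- heterogeneity_stats(2, 1)
  expect_equal(h$i2, 50)
  expect_equal(h$h2, 2)
  expect_equal(heterogeneity_stats(0.5, 1)$i2, 0)  # Q <= df truncates
  expect_true(is.na(heterogeneity_stats(0, 0)$i2))
})

test_that("DL recovers the true heterogeneity on average", {
  set.seed(2024)
  k <- 10; tau2 <- 0.04; vi <- rep(0.02, k)
  est <- replicate(500, {
    yi <- 0.3 + rnorm(k, 0, sqrt(tau2)) + rnorm(k, 0, sqrt(vi))
    estimate_tau2(yi, vi, "DL")$tau2
  })
  expect_lt(abs(mean(est) - tau2) / tau2, 0.20)
})
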