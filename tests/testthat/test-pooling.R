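# Heterogeneity and pooled-effect estimation.

test_that("cochran_q matches the two-study closed form and null cases", {
  h <- cochran_q(c(0, 0.5), se = c(0.1, 0.1))
  expect_equal(h$q, 0.5^2 / (0.1^2 + 0.1^2), tolerance = 1e-12)  # 12.5
  expect_equal(h$df, 1L)

  h0 <- cochran_q(c(0.3, 0.3), se = c(0.2, 0.2))
  expect_equal(h0$q, 0)
  expect_equal(h0$i2, 0)
  expect_equal(h0$tau2, 0)

  expect_error(cochran_q(0.5, se = 0.1), "fewer than 2")

  # general k: oracle recomputation from the definition
  set.seed(51)
  for (i in 1:10) {
    e <- random_estimates(sample(3:12, 1))
    h <- cochran_q(e)
    w <- 1 / e$se^2
    th <- sum(w * e$log_or) / sum(w)
    q <- sum(w * (e$log_or - th)^2)
    expect_equal(h$q, q, tolerance = 1e-12)
    expect_equal(h$tau2, max(0, (q - (nrow(e) - 1)) /
                               (sum(w) - sum(w^2) / sum(w))),
                 tolerance = 1e-12)
    expect_gte(h$i2, 0)
    expect_lt(h$i2, 100)
  }
})

test_that("Mantel-Haenszel pooling matches its definition and identities", {
  t1 <- collapse_counts(c(20, 30, 50), c(10, 40, 50), "dominant", study_id = "s1")
  t2 <- collapse_counts(c(15, 25, 60), c(12, 30, 58), "dominant", study_id = "s2")
  t3 <- collapse_counts(c(40, 10, 50), c(25, 25, 50), "dominant", study_id = "s3")

  # k = 1: pooled OR is the study's cross-product OR
  f1 <- pool_fixed_mh(list(t1))
  expect_equal(f1$or, odds_ratio(t1)$or, tolerance = 1e-12)

  # replication invariance of the point estimate
  f2 <- pool_fixed_mh(list(t1, t1))
  expect_equal(f2$or, odds_ratio(t1)$or, tolerance = 1e-12)

  # definition oracle on several tables
  f3 <- pool_fixed_mh(list(t1, t2, t3))
  expect_equal(f3$or, mh_oracle(list(t1, t2, t3)), tolerance = 1e-12)
  expect_equal(f3$method, "MH-fixed")

  # pooled estimate lies within the per-study OR range
  ors <- vapply(list(t1, t2, t3), function(t) odds_ratio(t)$or, numeric(1))
  expect_gte(f3$or, min(ors))
  expect_lte(f3$or, max(ors))

  # weights are positive and normalize to 1
  w <- weights(f3)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("DerSimonian-Laird with tau2 = 0 equals inverse-variance fixed effects", {
  set.seed(52)
  e <- random_estimates(8)
  fit <- pool_random_dl(e, het = 0)
  w <- 1 / e$se^2
  expect_equal(fit$log_or, sum(w * e$log_or) / sum(w), tolerance = 1e-14)
  expect_equal(fit$se, 1 / sqrt(sum(w)), tolerance = 1e-14)

  # DL pooled log OR is a convex combination of study log ORs
  h <- cochran_q(e)
  fr <- pool_random_dl(e, h)
  expect_gte(fr$log_or, min(e$log_or))
  expect_lte(fr$log_or, max(e$log_or))
})

test_that("the Q-test gate selects MH fixed above the threshold, DL below", {
  fit_add <- pool_or(mdm2, "additive")
  expect_equal(fit_add$method, "DL-random")     # Q-test p = 0.001 < 0.1
  expect_lt(fit_add$het$p, 0.1)

  cauc <- mdm2[mdm2$ethnicity == "Caucasian", ]
  fit_c <- pool_or(cauc, "dominant")
  expect_equal(fit_c$method, "MH-fixed")        # Q-test p = 0.218 > 0.1
  expect_gt(fit_c$het$p, 0.1)
  expect_equal(fit_c$or, 0.952, tolerance = 1e-3)

  # forcing overrides the gate
  expect_equal(pool_or(cauc, "dominant", method = "random")$method, "DL-random")
  expect_equal(pool_or(mdm2, "additive", method = "fixed")$method, "MH-fixed")

  # k = 1 pools trivially as fixed with no heterogeneity block
  one <- pool_or(mdm2[mdm2$study_id == "Chua", , drop = FALSE], "dominant")
  expect_equal(one$method, "MH-fixed")
  expect_null(one$het)
  expect_equal(one$or,
               odds_ratio(collapse_counts(c(29, 65, 29), c(51, 83, 25),
                                          "dominant"))$or,
               tolerance = 1e-12)
})

test_that("pooled estimates agree with metafor as an independent implementation", {
  skip_if_not_installed("metafor")
  e <- study_estimates(mdm2, "additive")
  ref <- metafor::rma(yi = e$log_or, vi = e$se^2, method = "DL")
  fit <- pool_or(mdm2, "additive")
  expect_equal(fit$log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(fit$se, ref$se, tolerance = 1e-10)
  expect_equal(fit$het$q, ref$QE, tolerance = 1e-10)
  expect_equal(fit$het$tau2, ref$tau2, tolerance = 1e-10)

  cauc <- mdm2[mdm2$ethnicity == "Caucasian", ]
  refmh <- metafor::rma.mh(ai = cauc$case_gg + cauc$case_gt, bi = cauc$case_tt,
                           ci = cauc$ctrl_gg + cauc$ctrl_gt, di = cauc$ctrl_tt,
                           correct = FALSE)
  fitmh <- pool_or(cauc, "dominant")
  expect_equal(fitmh$log_or, as.numeric(refmh$beta), tolerance = 1e-10)
  expect_equal(fitmh$se, refmh$se, tolerance = 1e-10)
})

test_that("scale equivariance: inflating all cells keeps estimates, shrinks CIs", {
  ds <- as.data.frame(mdm2)
  big <- ds
  cnt <- c("case_gg", "case_gt", "case_tt", "ctrl_gg", "ctrl_gt", "ctrl_tt")
  big[cnt] <- lapply(big[cnt], `*`, 5L)
  for (m in c("dominant", "recessive")) {
    f <- pool_or(ds, m, method = "fixed")
    g <- pool_or(big, m, method = "fixed")
    expect_equal(g$or, f$or, tolerance = 1e-10)
    expect_lt(g$ci_high - g$ci_low, f$ci_high - f$ci_low)
  }
})

test_that("z_test identities", {
  expect_equal(z_test(0, 1), list(z = 0, p = 1))
  zq <- qnorm(0.975)
  expect_equal(z_test(zq * 0.3, 0.3)$p, 0.05, tolerance = 1e-10)
  zt <- z_test(0.565, 0.134)
  expect_equal(zt$z, 0.565 / 0.134, tolerance = 1e-12)
  expect_equal(zt$p, 2 * pnorm(-0.565 / 0.134), tolerance = 1e-15)
  expect_lt(zt$p, 1e-4)
  expect_error(z_test(1, 0), "positive")
})
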