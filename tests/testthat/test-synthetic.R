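# Seeded synthetic-study generator and recovery harness.

test_that("genotype tilting matches hand renormalization", {
  # null: case and control probabilities identical
  pr0 <- genotype_probs(0.3, 1, "dominant")
  expect_equal(pr0$case, pr0$control, tolerance = 1e-15)
  expect_equal(sum(pr0$control), 1, tolerance = 1e-15)
  expect_equal(pr0$control, c(0.09, 0.42, 0.49), tolerance = 1e-12)

  # recessive, p = 0.5, OR 2: (0.25*2, 0.5, 0.25)/1.25 = (0.4, 0.4, 0.2)
  pr <- genotype_probs(0.5, 2, "recessive")
  expect_equal(pr$case, c(0.4, 0.4, 0.2), tolerance = 1e-12)

  # the model-matched collapsed 2x2 has population OR exactly psi
  set.seed(71)
  for (m in c("dominant", "additive", "recessive")) for (i in 1:5) {
    p <- runif(1, 0.1, 0.9); psi <- exp(rnorm(1, 0, 0.7))
    pr <- genotype_probs(p, psi, m)
    ca <- pr$case; co <- pr$control
    or <- switch(m,
      additive  = (ca[1] * co[3]) / (ca[3] * co[1]),
      dominant  = ((ca[1] + ca[2]) * co[3]) / (ca[3] * (co[1] + co[2])),
      recessive = (ca[1] * (co[2] + co[3])) / ((ca[2] + ca[3]) * co[1]))
    expect_equal(or, psi, tolerance = 1e-12)
  }
})

test_that("simulation is deterministic per (config, seed, index)", {
  cfg <- sim_config(k = 4, n_cases = 300, n_controls = 400, p_g = 0.35,
                    true_or = 1.4, gen_model = "dominant", tau = 0.2,
                    seed = 99)
  s1 <- simulate_study(cfg, 2)
  s2 <- simulate_study(cfg, 2)
  expect_identical(s1$record, s2$record)
  expect_equal(s1$truth$log_or, s2$truth$log_or)

  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(plain(d1$data), plain(d2$data))
  # the dataset rows are the per-index records (stream splitting)
  expect_identical(plain(d1$data[2, ]), plain(s1$record))

  cfg_b <- cfg; cfg_b$seed <- 100L
  d3 <- simulate_dataset(cfg_b)
  cnt <- c("case_gg", "case_gt", "case_tt", "ctrl_gg", "ctrl_gt", "ctrl_tt")
  expect_false(identical(d1$data[, cnt], d3$data[, cnt]))

  # results do not depend on ambient RNG state
  set.seed(1); d4 <- simulate_dataset(cfg)
  set.seed(777); d5 <- simulate_dataset(cfg)
  expect_identical(plain(d4$data), plain(d5$data))
})

test_that("simulated datasets have the requested shape and pass I/O", {
  cfg <- sim_config(k = 11, n_cases = c(717, 1026, 341, 582, 133, 371, 1106,
                                        1787, 633, 123, 377),
                    n_controls = 800, p_g = 0.4, true_or = 1, seed = 5,
                    strata = list(smoking = c(ever = 0.6, never = 0.4)))
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$data), 11L)
  tot <- study_totals(sim$data)
  expect_equal(tot$cases, cfg$n_cases)
  expect_equal(tot$controls, rep(800L, 11))
  expect_true(all(sim$data$smoking %in% c("ever", "never")))
  expect_length(sim$truth$log_or, 11L)
  expect_equal(sim$truth$log_or, rep(0, 11))       # psi = 1, tau = 0

  # generator output round-trips through the study_data reader
  f <- withr::local_tempfile(fileext = ".csv")
  write_studies(sim$data, f)
  expect_equal(plain(read_studies(f)), plain(sim$data))

  expect_error(sim_config(k = 0, n_cases = 10, n_controls = 10, p_g = 0.5),
               "positive")
  expect_error(sim_config(k = 2, n_cases = 10, n_controls = 10, p_g = 1.2),
               "p_g")
  expect_error(sim_config(k = 2, n_cases = 10, n_controls = 10, p_g = 0.5,
                          tau = -1), "tau")
})

test_that("control arms are generated under HWE", {
  cfg <- sim_config(k = 60, n_cases = 100, n_controls = 500, p_g = 0.3,
                    true_or = 2, gen_model = "recessive", seed = 31)
  sim <- simulate_dataset(cfg)
  h <- hwe_table(sim$data, alpha = 0.05)
  # rejection rate compatible with the nominal 5% level (binomial 99.9% bound)
  expect_lte(sum(!h$hwe_pass), qbinom(0.999, 60, 0.05))
  expect_equal(mean(h$g_freq), 0.3, tolerance = 0.02)
})

test_that("evaluate_recovery scores bias, coverage and heterogeneity", {
  cfg <- sim_config(k = 8, n_cases = 800, n_controls = 800, p_g = 0.4,
                    true_or = 1.5, gen_model = "dominant", tau = 0, seed = 13)
  r <- evaluate_recovery(cfg, reps = 30)
  expect_s3_class(r, "gm_recovery")
  expect_equal(r$reps, 30)
  expect_lt(abs(r$mean_or - 1.5), 0.1)
  expect_lt(abs(r$bias), 0.05)
  expect_gt(r$coverage, 0.8)
  # deterministic given the config seed
  r2 <- evaluate_recovery(cfg, reps = 30)
  expect_equal(r$mean_or, r2$mean_or, tolerance = 1e-15)

  # heterogeneity injection raises observed I2 on average
  cfg_t <- cfg; cfg_t$tau <- 0.5
  r_t <- evaluate_recovery(cfg_t, reps = 30)
  expect_gt(r_t$mean_i2, r$mean_i2)
  expect_gt(r_t$q_reject_rate, r$q_reject_rate)
})

test_that("simulate() on a fitted pool mimics the fitted analysis", {
  fit <- pool_or(mdm2, "dominant")
  sims <- simulate(fit, nsim = 2, seed = 17)
  expect_length(sims, 2L)
  expect_equal(study_totals(sims[[1]])$cases, study_totals(mdm2)$cases)
  refit <- pool_or(sims[[1]], "dominant")
  expect_equal(refit$k, 11L)
  # pooled OR of a replicate stays in the neighbourhood of the fitted OR
  expect_lt(abs(refit$log_or - fit$log_or), 0.5)
})
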