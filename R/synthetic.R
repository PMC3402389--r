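# Seeded generator of case-control genotype-count studies with known truth,
# plus an estimator-recovery evaluation harness.

#' Simulation configuration
#'
#' Describes a collection of synthetic case-control SNP studies: control
#' genotypes follow Hardy-Weinberg proportions at variant-allele frequency
#' `p_g`; case genotype probabilities are the control probabilities tilted
#' by a study-level odds ratio under the chosen inheritance model; the
#' study-level log odds ratio is drawn from
#' `Normal(log(true_or), tau^2)` (log-normal between-study heterogeneity,
#' the DerSimonian-Laird generative assumption); genotype counts are
#' multinomial with fixed arm sizes (case-control design).
#'
#' @param k Number of studies (>= 1).
#' @param n_cases,n_controls Arm sizes, scalar or length-`k`.
#' @param p_g Control variant-allele frequency, in (0, 1).
#' @param true_or True odds ratio psi (> 0) under `gen_model`.
#' @param gen_model Inheritance model whose collapsed 2x2 has population
#'   odds ratio exactly `true_or`.
#' @param tau Between-study standard deviation of the log odds ratio (>= 0).
#' @param strata Optional named list: column name -> named vector of level
#'   probabilities, sampled independently per study.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(k = 5, n_cases = 500, n_controls = 500, p_g = 0.4,
#'                   true_or = 1.5, gen_model = "dominant", seed = 7)
#' @export
sim_config <- function(k, n_cases, n_controls, p_g, true_or = 1,
                       gen_model = c("dominant", "additive", "recessive"),
                       tau = 0, strata = NULL, seed = 1) {
  gen_model <- match.arg(gen_model)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  rec_len <- function(x, nm) {
    x <- as.integer(x)
    if (length(x) == 1L) x <- rep(x, k)
    if (length(x) != k || any(is.na(x)) || any(x < 1L))
      stop(nm, " must be a positive scalar or length-k vector")
    x
  }
  n_cases <- rec_len(n_cases, "n_cases")
  n_controls <- rec_len(n_controls, "n_controls")
  if (!is.finite(p_g) || p_g <= 0 || p_g >= 1) stop("p_g must be in (0, 1)")
  if (!is.finite(true_or) || true_or <= 0) stop("true_or must be positive")
  if (!is.finite(tau) || tau < 0) stop("tau must be non-negative")
  if (!is.null(strata)) {
    if (is.null(names(strata)) || any(names(strata) == ""))
      stop("strata must be a named list")
    for (nm in names(strata)) {
      pr <- strata[[nm]]
      if (is.null(names(pr)) || any(pr < 0) || sum(pr) <= 0)
        stop("stratum '", nm, "' needs named non-negative level probabilities")
    }
  }
  structure(list(k = k, n_cases = n_cases, n_controls = n_controls,
                 p_g = p_g, true_or = true_or, gen_model = gen_model,
                 tau = tau, strata = strata, seed = as.integer(seed)),
            class = "sim_config")
}

#' Genotype probabilities under HWE with odds-ratio tilting
#'
#' Control probabilities are the Hardy-Weinberg proportions
#' `(p^2, 2p(1-p), (1-p)^2)` for `(GG, GT, TT)`. Case probabilities multiply
#' the probability of each genotype counted as "exposed" under the
#' inheritance model by `or` and renormalize, so the model-matched collapsed
#' 2x2 table has population odds ratio exactly `or`.
#'
#' @param p_g Variant-allele frequency in (0, 1).
#' @param or Odds ratio (> 0).
#' @param gen_model `"dominant"`, `"additive"` or `"recessive"`. Dominant
#'   tilts GG and GT; additive and recessive tilt GG only.
#' @return List with numeric length-3 vectors `control` and `case`.
#' @examples
#' genotype_probs(0.5, 2, "recessive")$case   # (0.4, 0.4, 0.2)
#' @export
genotype_probs <- function(p_g, or = 1,
                           gen_model = c("dominant", "additive", "recessive")) {
  gen_model <- match.arg(gen_model)
  stopifnot(p_g > 0, p_g < 1, or > 0)
  ctrl <- c(p_g^2, 2 * p_g * (1 - p_g), (1 - p_g)^2)
  exposed <- switch(gen_model,
                    dominant = c(1, 1, 0),
                    additive = c(1, 0, 0),
                    recessive = c(1, 0, 0))
  case <- ctrl * or^exposed
  list(control = ctrl, case = case / sum(case))
}

# deterministic per-study substream: every study draws from its own seed so
# results depend only on (config, seed, index), never on process RNG state
study_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483647)
}

#' Simulate one case-control genotype study
#'
#' @param cfg A [sim_config()] object.
#' @param index Study index in `1:cfg$k`; determines the RNG substream, so
#'   repeated calls with the same `(cfg, index)` reproduce the same record.
#' @return A list with `record` (one-row study data.frame in the
#'   [read_studies()] schema, plus any strata columns) and `truth` (list
#'   with the realized `log_or`, `psi`, and the case/control genotype
#'   probabilities).
#' @export
simulate_study <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  index <- as.integer(index)
  if (index < 1L || index > cfg$k) stop("index must be in 1..k")
  set.seed(study_seed(cfg$seed, index))
  psi <- exp(stats::rnorm(1, log(cfg$true_or), cfg$tau))
  pr <- genotype_probs(cfg$p_g, psi, cfg$gen_model)
  co <- as.integer(stats::rmultinom(1, cfg$n_controls[index], pr$control))
  ca <- as.integer(stats::rmultinom(1, cfg$n_cases[index], pr$case))
  rec <- data.frame(study_id = sprintf("sim%03d", index),
                    first_author = "Synthetic", year = 2000L + index,
                    ethnicity = "Simulated", control_source = "PB",
                    method = "simulated",
                    case_gg = ca[1], case_gt = ca[2], case_tt = ca[3],
                    ctrl_gg = co[1], ctrl_gt = co[2], ctrl_tt = co[3],
                    stringsAsFactors = FALSE)
  if (!is.null(cfg$strata))
    for (nm in names(cfg$strata)) {
      pr_s <- cfg$strata[[nm]]
      rec[[nm]] <- sample(names(pr_s), 1, prob = pr_s)
    }
  list(record = rec,
       truth = list(log_or = log(psi), psi = psi,
                    p_case = pr$case, p_control = pr$control))
}

#' Simulate a dataset of case-control genotype studies
#'
#' Generates `cfg$k` independent studies, each from its own seeded
#' substream. Deterministic in `(cfg, cfg$seed)`.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `"gm_sim"` with `data` (a `"genemeta_studies"`
#'   data.frame) and `truth` (the config plus per-study realized log odds
#'   ratios and genotype probabilities).
#' @examples
#' sim <- simulate_dataset(sim_config(k = 3, n_cases = 200, n_controls = 200,
#'                                    p_g = 0.3, true_or = 2, seed = 11))
#' sim$data
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  studies <- lapply(seq_len(cfg$k), function(i) simulate_study(cfg, i))
  data <- do.call(rbind, lapply(studies, `[[`, "record"))
  rownames(data) <- NULL
  structure(list(
    data = structure(data, provenance = "simulate_dataset",
                     class = c("genemeta_studies", "data.frame")),
    truth = list(config = cfg,
                 log_or = vapply(studies, function(s) s$truth$log_or,
                                 numeric(1)),
                 per_study = lapply(studies, `[[`, "truth"))),
    class = "gm_sim")
}

#' Estimator-recovery evaluation by Monte Carlo
#'
#' Repeatedly simulates datasets from `cfg` and pools each with
#' [pool_or()], scoring recovery of the true odds ratio: bias of the pooled
#' log odds ratio, RMSE, coverage of the confidence interval, and the
#' Q-test rejection rate at the selection gate.
#'
#' @param cfg A [sim_config()] object (replicate r uses seed
#'   `cfg$seed + r`).
#' @param reps Number of Monte-Carlo replicates (>= 1).
#' @param model Inheritance model used for analysis (default: the
#'   generating model).
#' @param het_threshold Q-test gate passed to [pool_or()] (default 0.1).
#' @return A list of class `"gm_recovery"`: `reps`, `true_or`, `mean_or`
#'   (mean pooled OR), `bias` (mean pooled log OR minus true log OR),
#'   `rmse` (log scale), `coverage` (fraction of CIs containing `true_or`),
#'   `q_reject_rate` (fraction of Q-tests with `p <= het_threshold`), and
#'   `mean_i2`.
#' @examples
#' cfg <- sim_config(k = 10, n_cases = 500, n_controls = 500, p_g = 0.4,
#'                   true_or = 1.5, gen_model = "dominant", seed = 3)
#' evaluate_recovery(cfg, reps = 20)
#' @export
evaluate_recovery <- function(cfg, reps, model = cfg$gen_model,
                              het_threshold = 0.1) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 1)
  res <- vapply(seq_len(reps), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- study_seed(cfg$seed, 7907 * r)  # distinct substream per rep
    sim <- simulate_dataset(cfg_r)
    fit <- pool_or(sim$data, model = model, het_threshold = het_threshold)
    c(log_or = fit$log_or,
      cover = as.numeric(fit$ci_low <= cfg$true_or &
                           cfg$true_or <= fit$ci_high),
      q_rej = if (is.null(fit$het)) NA_real_
              else as.numeric(fit$het$p <= het_threshold),
      i2 = if (is.null(fit$het)) NA_real_ else fit$het$i2)
  }, numeric(4))
  log_psi <- log(cfg$true_or)
  structure(list(reps = reps, true_or = cfg$true_or,
                 mean_or = mean(exp(res["log_or", ])),
                 bias = mean(res["log_or", ]) - log_psi,
                 rmse = sqrt(mean((res["log_or", ] - log_psi)^2)),
                 coverage = mean(res["cover", ]),
                 q_reject_rate = mean(res["q_rej", ], na.rm = TRUE),
                 mean_i2 = mean(res["i2", ], na.rm = TRUE)),
            class = "gm_recovery")
}

#' @export
print.gm_recovery <- function(x, ...) {
  cat(sprintf(paste0("Recovery over %d replicates (true OR = %g):\n",
                     "  mean pooled OR = %.3f, bias(log) = %+.4f, RMSE(log) = %.4f\n",
                     "  CI coverage = %.3f, Q-test rejection rate = %.3f, mean I2 = %.1f%%\n"),
              x$reps, x$true_or, x$mean_or, x$bias, x$rmse,
              x$coverage, x$q_reject_rate, x$mean_i2))
  invisible(x)
}
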