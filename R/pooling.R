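# Heterogeneity (Cochran Q, I-squared, DerSimonian-Laird tau-squared) and
# pooled odds ratios by Mantel-Haenszel fixed effects or DerSimonian-Laird
# random effects, with automatic selection on the Q-test p-value.

#' Cochran Q heterogeneity test with I-squared and tau-squared
#'
#' Inverse-variance weighted heterogeneity of per-study log odds ratios:
#' `Q = sum w_i (theta_i - theta_hat)^2` with `w_i = 1/se_i^2`, referred to a
#' chi-square distribution on `k - 1` degrees of freedom;
#' `I2 = max(0, (Q - df)/Q) * 100`; and the DerSimonian-Laird moment
#' estimator `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` of the
#' between-study variance.
#'
#' @param estimates A data.frame with columns `log_or` and `se` (as from
#'   [study_estimates()]), or a numeric vector of log odds ratios.
#' @param se Standard errors, when `estimates` is a numeric vector.
#' @return A list of class `"gm_het"`: `k`, `q`, `df`, `p`, `i2` (percent),
#'   `tau2`.
#' @examples
#' cochran_q(study_estimates(mdm2_studies(), "additive"))
#' @export
cochran_q <- function(estimates, se = NULL) {
  if (is.data.frame(estimates)) {
    theta <- estimates$log_or
    se <- estimates$se
  } else theta <- as.numeric(estimates)
  k <- length(theta)
  if (k < 2L) stop("heterogeneity undefined for fewer than 2 studies")
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be finite and positive")
  w <- 1 / se^2
  theta_hat <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - theta_hat)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  structure(list(k = k, q = q, df = df,
                 p = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = i2, tau2 = tau2),
            class = "gm_het")
}

#' @export
print.gm_het <- function(x, ...) {
  cat("Cochran Q = ", format(round(x$q, 3), nsmall = 3), " on ", x$df,
      " df, p = ", format.pval(x$p, digits = 3),
      "; I2 = ", round(x$i2, 1), "%; tau2 = ",
      format(round(x$tau2, 4), nsmall = 4), "\n", sep = "")
  invisible(x)
}

#' Z-test for a pooled log odds ratio
#'
#' @param log_or Pooled log odds ratio.
#' @param se Its standard error (must be positive).
#' @return List with `z = log_or/se` and the two-sided standard-normal
#'   p-value.
#' @export
z_test <- function(log_or, se) {
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  z <- log_or / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# shared construction of the fitted-pool object
new_gm_pool <- function(method, model, estimates, log_or, se, conf_level,
                        weights, het = NULL, het_threshold = NA_real_,
                        cc = NA_real_, call = NULL) {
  zt <- z_test(log_or, se)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  per_study <- estimates
  per_study$weight <- weights
  per_study$weight_pct <- 100 * weights / sum(weights)
  structure(list(model = model, method = method,
                 k = nrow(per_study),
                 log_or = log_or, se = se, or = exp(log_or),
                 ci_low = exp(log_or - zq * se),
                 ci_high = exp(log_or + zq * se),
                 z = zt$z, p = zt$p,
                 het = het, conf_level = conf_level,
                 het_threshold = het_threshold, cc = cc,
                 study = per_study, call = call),
            class = "gm_pool")
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Pooled odds ratio `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` across 2x2
#' tables, with the Robins-Breslow-Greenland variance estimator for its log
#' and a normal-theory confidence interval. With a single table the pooled
#' odds ratio equals that table's cross-product ratio.
#'
#' @param tables A list of `"gm_2x2"` tables (see [collapse_counts()]).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"gm_pool"`; see [pool_or()].
#' @examples
#' ds <- mdm2_studies()
#' tabs <- lapply(seq_len(nrow(ds)), function(i)
#'   collapse_counts(as.numeric(ds[i, 7:9]), as.numeric(ds[i, 10:12]),
#'                   "dominant", study_id = ds$study_id[i]))
#' pool_fixed_mh(tabs)
#' @export
pool_fixed_mh <- function(tables, conf_level = 0.95) {
  if (inherits(tables, "gm_2x2")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  cc <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  n <- a + b + cc + d
  R_i <- a * d / n; S_i <- b * cc / n
  R <- sum(R_i); S <- sum(S_i)
  if (R == 0 || S == 0) stop("Mantel-Haenszel pooled odds ratio undefined: zero cross-product sum")
  log_or <- log(R / S)
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P_i <- (a + d) / n; Q_i <- (b + cc) / n
  v <- sum(P_i * R_i) / (2 * R^2) +
    sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
    sum(Q_i * S_i) / (2 * S^2)
  est <- do.call(rbind, lapply(tables, function(t) {
    e <- odds_ratio(t, conf_level)
    data.frame(study_id = if (is.null(e$study_id)) NA_character_ else e$study_id,
               log_or = e$log_or, se = e$se, or = e$or,
               ci_low = e$ci_low, ci_high = e$ci_high,
               cc_applied = e$cc_applied, stringsAsFactors = FALSE)
  }))
  new_gm_pool("MH-fixed", tables[[1]]$model, est, log_or, sqrt(v),
              conf_level, weights = S_i)
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Inverse-variance pooling with the between-study variance `tau2` added to
#' each study's sampling variance: weights `w*_i = 1/(se_i^2 + tau2)`. With
#' `tau2 = 0` this reduces exactly to the inverse-variance fixed-effect
#' pool.
#'
#' @param estimates Per-study estimates (data.frame with `log_or`, `se`;
#'   see [study_estimates()]).
#' @param het A `"gm_het"` object computed on the same estimates (its
#'   `tau2` is used), or a single number taken as `tau2` directly.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"gm_pool"`; see [pool_or()].
#' @export
pool_random_dl <- function(estimates, het, conf_level = 0.95) {
  tau2 <- if (inherits(het, "gm_het")) het$tau2 else as.numeric(het)
  stopifnot(nrow(estimates) >= 1L, tau2 >= 0)
  w <- 1 / (estimates$se^2 + tau2)
  log_or <- sum(w * estimates$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  new_gm_pool("DL-random", attr(estimates, "model"), estimates, log_or, se,
              conf_level, weights = w,
              het = if (inherits(het, "gm_het")) het else NULL)
}

#' Pool per-study odds ratios with automatic model selection
#'
#' The central fitting function: collapses every study of a genotype-count
#' dataset under one inheritance model, computes Woolf log odds ratios,
#' quantifies heterogeneity ([cochran_q()]), and pools. With
#' `method = "auto"` the fixed-effect Mantel-Haenszel pool is used when the
#' Q-test gives `p > het_threshold` (lack of heterogeneity), and the
#' DerSimonian-Laird random-effects pool otherwise — ties at the threshold
#' go to random effects. A single-study "pool" is the study's own estimate,
#' labelled MH-fixed, with no heterogeneity block.
#'
#' @param data A study data.frame (see [read_studies()]).
#' @param model Inheritance model: `"additive"` (GG vs TT homozygote
#'   contrast), `"dominant"` ((GG+GT) vs TT) or `"recessive"`
#'   (GG vs (GT+TT)).
#' @param method `"auto"` (Q-test gate, the default), or force `"fixed"`
#'   (Mantel-Haenszel) or `"random"` (DerSimonian-Laird).
#' @param het_threshold Q-test p-value above which the fixed-effect model is
#'   selected (default 0.1).
#' @param cc Continuity correction for zero cells (default 0.5).
#' @param conf_level Confidence level for all intervals (default 0.95).
#' @return An object of class `"gm_pool"` with components `model`, `method`
#'   (`"MH-fixed"` or `"DL-random"`), `k`, `or`, `ci_low`, `ci_high`,
#'   `log_or`, `se`, `z`, `p`, `het` (a `"gm_het"` or `NULL` when `k = 1`)
#'   and `study` (per-study estimates with normalized weights). Supports
#'   `print`, `summary`, `coef`, `confint`, `plot` (forest/funnel),
#'   `residuals`, `weights` and `simulate` methods.
#' @examples
#' fit <- pool_or(mdm2_studies(), model = "additive")
#' fit                    # pooled OR 1.14 (0.95-1.37), DL random effects
#' summary(fit)
#' @export
pool_or <- function(data, model = c("additive", "dominant", "recessive"),
                    method = c("auto", "fixed", "random"),
                    het_threshold = 0.1, cc = 0.5, conf_level = 0.95) {
  model <- match.arg(model)
  method <- match.arg(method)
  stopifnot(het_threshold > 0, het_threshold < 1,
            conf_level > 0, conf_level < 1)
  cl <- match.call()
  tabs <- study_tables(data, model, cc)
  est <- do.call(rbind, lapply(tabs, function(t) {
    e <- odds_ratio(t, conf_level)
    data.frame(study_id = e$study_id, log_or = e$log_or, se = e$se,
               or = e$or, ci_low = e$ci_low, ci_high = e$ci_high,
               cc_applied = e$cc_applied, stringsAsFactors = FALSE)
  }))
  attr(est, "model") <- model

  if (nrow(est) == 1L) {
    fit <- pool_fixed_mh(tabs, conf_level)
  } else {
    het <- cochran_q(est)
    use_fixed <- switch(method,
                        auto = het$p > het_threshold,
                        fixed = TRUE,
                        random = FALSE)
    fit <- if (use_fixed) pool_fixed_mh(tabs, conf_level)
           else pool_random_dl(est, het, conf_level)
    fit$het <- het
  }
  fit$model <- model
  fit$het_threshold <- het_threshold
  fit$cc <- cc
  fit$call <- cl
  fit$data <- data
  fit
}
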