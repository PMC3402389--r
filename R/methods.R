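# S3 methods for fitted pooled-odds-ratio objects.

model_label <- function(model) switch(model,
  additive = "GG vs TT (homozygote contrast)",
  dominant = "(GG+GT) vs TT (dominant)",
  recessive = "GG vs (GT+TT) (recessive)",
  model)

#' @export
print.gm_pool <- function(x, digits = 2, ...) {
  cat("Pooled odds ratio — ", model_label(x$model), "\n", sep = "")
  cat("Method: ", if (x$method == "MH-fixed") "Mantel-Haenszel fixed effects"
      else "DerSimonian-Laird random effects",
      " (k = ", x$k, if (x$k == 1L) " study)" else " studies)", "\n", sep = "")
  cat(sprintf("OR = %.*f (%g%% CI %.*f-%.*f), Z = %.2f, p = %s\n",
              digits, x$or, 100 * x$conf_level, digits, x$ci_low,
              digits, x$ci_high, x$z, format.pval(x$p, digits = 3)))
  if (!is.null(x$het))
    cat(sprintf("Heterogeneity: Q = %.3f (df = %d, p = %s), I2 = %.1f%%, tau2 = %.4f\n",
                x$het$q, x$het$df, format.pval(x$het$p, digits = 3),
                x$het$i2, x$het$tau2))
  invisible(x)
}

#' @export
summary.gm_pool <- function(object, ...) {
  structure(list(fit = object), class = "summary.gm_pool")
}

#' @export
print.summary.gm_pool <- function(x, digits = 2, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  cat("\nPer-study estimates:\n")
  st <- fit$study
  out <- data.frame(study = st$study_id,
                    OR = round(st$or, digits),
                    CI = sprintf("(%.*f-%.*f)", digits, st$ci_low,
                                 digits, st$ci_high),
                    `weight%` = round(st$weight_pct, 1),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gm_pool <- function(object, ...) {
  stats::setNames(object$log_or, "log_or")
}

#' @export
confint.gm_pool <- function(object, parm = "or", level = NULL, ...) {
  level <- if (is.null(level)) object$conf_level else level
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- object$log_or - zq * object$se
  hi <- object$log_or + zq * object$se
  if (identical(parm, "log_or")) c(lower = lo, upper = hi)
  else c(lower = exp(lo), upper = exp(hi))
}

#' Residuals of a pooled odds-ratio fit
#'
#' Deviations of per-study log odds ratios from the pooled log odds ratio.
#' Standardized residuals divide by `sqrt(se_i^2 + tau2)` (with `tau2 = 0`
#' for fixed-effect fits), so under homogeneity they are approximately
#' standard normal.
#'
#' @param object A `"gm_pool"` fit.
#' @param type `"raw"` or `"standardized"`.
#' @param ... Unused.
#' @return Named numeric vector, one element per study.
#' @export
residuals.gm_pool <- function(object, type = c("raw", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$study$log_or - object$log_or
  if (type == "standardized") {
    tau2 <- if (!is.null(object$het) && object$method == "DL-random")
      object$het$tau2 else 0
    r <- r / sqrt(object$study$se^2 + tau2)
  }
  stats::setNames(r, object$study$study_id)
}

#' @export
weights.gm_pool <- function(object, normalized = TRUE, ...) {
  w <- if (normalized) object$study$weight / sum(object$study$weight)
       else object$study$weight
  stats::setNames(w, object$study$study_id)
}

#' Forest or funnel plot of a pooled fit
#'
#' @param x A `"gm_pool"` fit.
#' @param type `"forest"` (per-study ORs with the pooled diamond) or
#'   `"funnel"` (SE of log OR against log OR, inverted y axis).
#' @param ... Passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.gm_pool <- function(x, type = c("forest", "funnel"), ...) {
  type <- match.arg(type)
  st <- x$study
  if (type == "forest") {
    k <- nrow(st)
    ylim <- c(0, k + 2)
    xlim <- range(log(c(st$ci_low, st$ci_high, x$ci_low, x$ci_high)))
    graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                   xlab = "log odds ratio", ylab = "",
                   main = paste("Forest plot:", model_label(x$model)), ...)
    graphics::abline(v = 0, lty = 3)
    for (i in seq_len(k)) {
      y <- k + 1 - i
      graphics::segments(log(st$ci_low[i]), y, log(st$ci_high[i]), y)
      graphics::points(st$log_or[i], y, pch = 15,
                       cex = 0.5 + 1.5 * st$weight_pct[i] / max(st$weight_pct))
    }
    graphics::segments(log(x$ci_low), 0, log(x$ci_high), 0, lwd = 2)
    graphics::points(x$log_or, 0, pch = 18, cex = 2)
    graphics::axis(2, at = c(k + 1 - seq_len(k), 0),
                   labels = c(st$study_id, "Pooled"), las = 1, cex.axis = 0.7)
  } else {
    graphics::plot(st$log_or, st$se, ylim = rev(range(c(0, st$se))),
                   xlab = "log odds ratio", ylab = "standard error of log OR",
                   main = paste("Funnel plot:", model_label(x$model)), ...)
    graphics::abline(v = x$log_or, lty = 2)
  }
  invisible(x)
}

#' Simulate datasets from a fitted pool (parametric bootstrap)
#'
#' Generates synthetic study collections mimicking the fitted analysis: each
#' study keeps its observed arm sizes and its control-arm variant-allele
#' frequency, control genotypes are drawn under Hardy-Weinberg equilibrium,
#' and case genotypes are tilted by the pooled odds ratio under the fitted
#' inheritance model, with between-study spread `sqrt(tau2)` for
#' random-effects fits.
#'
#' @param object A `"gm_pool"` fit (must have been produced by [pool_or()],
#'   which retains the input data).
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` study data.frames.
#' @export
simulate.gm_pool <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$data))
    stop("fit carries no source data; refit with pool_or()")
  if (!is.null(seed)) set.seed(seed)
  ds <- object$data
  ids <- object$study$study_id
  ds <- ds[ds$study_id %in% ids, , drop = FALSE]
  tau <- if (!is.null(object$het) && object$method == "DL-random")
    sqrt(object$het$tau2) else 0
  lapply(seq_len(nsim), function(s) {
    rows <- lapply(seq_len(nrow(ds)), function(i) {
      n_ca <- sum(ds[i, c("case_gg", "case_gt", "case_tt")])
      n_co <- sum(ds[i, c("ctrl_gg", "ctrl_gt", "ctrl_tt")])
      p_g <- (2 * ds$ctrl_gg[i] + ds$ctrl_gt[i]) / (2 * n_co)
      p_g <- min(max(p_g, 1e-6), 1 - 1e-6)
      psi <- exp(stats::rnorm(1, object$log_or, tau))
      pr <- genotype_probs(p_g, psi, object$model)
      rec <- ds[i, , drop = FALSE]
      rec[, c("ctrl_gg", "ctrl_gt", "ctrl_tt")] <-
        as.integer(stats::rmultinom(1, n_co, pr$control))
      rec[, c("case_gg", "case_gt", "case_tt")] <-
        as.integer(stats::rmultinom(1, n_ca, pr$case))
      rec
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
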