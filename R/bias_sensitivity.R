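# Publication-bias diagnostics (funnel coordinates, Egger regression) and
# one-way leave-one-out sensitivity analysis.

as_estimates <- function(x) {
  if (inherits(x, "gm_pool")) return(x$study)
  if (is.data.frame(x) && all(c("log_or", "se") %in% names(x))) return(x)
  stop("expected a 'gm_pool' fit or a data.frame with columns log_or and se")
}

#' Funnel-plot coordinates
#'
#' One point per study: the log odds ratio on x and its standard error on y.
#' Coordinates are exported untransformed; inverting the y axis is a
#' plotting concern (see [plot.gm_pool()]).
#'
#' @param estimates A `"gm_pool"` fit or a per-study estimates data.frame.
#' @return A data.frame with columns `study_id`, `log_or`, `se`, input
#'   order preserved.
#' @export
funnel_data <- function(estimates) {
  est <- as_estimates(estimates)
  data.frame(study_id = if ("study_id" %in% names(est)) est$study_id
             else as.character(seq_len(nrow(est))),
             log_or = est$log_or, se = est$se, stringsAsFactors = FALSE)
}

#' Egger's linear regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standard normal deviate
#' `log_or_i / se_i` on the precision `1 / se_i`. A pooled-effect slope and
#' a zero intercept are the no-bias expectation; the test statistic is
#' `t = intercept / se(intercept)` on `k - 2` degrees of freedom.
#'
#' @param estimates A `"gm_pool"` fit or a per-study estimates data.frame
#'   with at least 3 studies.
#' @return A list of class `"gm_egger"`: `intercept`, `se_intercept`, `t`,
#'   `df`, `p` (two-sided), `slope`, `k`.
#' @examples
#' egger_test(pool_or(mdm2_studies(), "recessive"))   # t = -0.72
#' @export
egger_test <- function(estimates) {
  est <- as_estimates(estimates)
  k <- nrow(est)
  if (k < 3L) stop("Egger test undefined for fewer than 3 studies")
  snd <- est$log_or / est$se
  prec <- 1 / est$se
  fit <- stats::lm(snd ~ prec)
  cf <- summary(fit)$coefficients
  structure(list(intercept = cf[1, 1], se_intercept = cf[1, 2],
                 t = cf[1, 3], df = k - 2L,
                 p = 2 * stats::pt(-abs(cf[1, 3]), k - 2L),
                 slope = cf[2, 1], k = k),
            class = "gm_egger")
}

#' @export
print.gm_egger <- function(x, ...) {
  cat(sprintf("Egger regression: intercept = %.3f (SE %.3f), t = %.2f on %d df, p = %s\n",
              x$intercept, x$se_intercept, x$t, x$df,
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' One-way leave-one-out sensitivity analysis
#'
#' Re-pools the dataset omitting each study in turn, re-running the full
#' fit — including Q-test based model selection — on every subset. Used to
#' check that no single study drives the pooled conclusion.
#'
#' @inheritParams pool_or
#' @return An object of class `"gm_loo"`: a list of `"gm_pool"` fits named
#'   by the omitted `study_id`. `as.data.frame()` gives a summary table.
#' @examples
#' loo <- leave_one_out(mdm2_studies(), "additive")
#' as.data.frame(loo)
#' @export
leave_one_out <- function(data, model = c("additive", "dominant", "recessive"),
                          method = c("auto", "fixed", "random"),
                          het_threshold = 0.1, cc = 0.5, conf_level = 0.95) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (nrow(data) < 2L) stop("leave-one-out needs at least 2 studies")
  fits <- lapply(seq_len(nrow(data)), function(i)
    pool_or(data[-i, , drop = FALSE], model = model, method = method,
            het_threshold = het_threshold, cc = cc, conf_level = conf_level))
  names(fits) <- data$study_id
  structure(fits, class = "gm_loo")
}

#' @export
as.data.frame.gm_loo <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(id) {
    f <- x[[id]]
    data.frame(omitted = id, k = f$k, method = f$method,
               or = f$or, ci_low = f$ci_low, ci_high = f$ci_high,
               p = f$p, significant = f$ci_low > 1 | f$ci_high < 1,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.gm_loo <- function(x, digits = 2, ...) {
  cat("Leave-one-out sensitivity analysis (", length(x), " omissions)\n", sep = "")
  df <- as.data.frame(x)
  df$or <- round(df$or, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
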