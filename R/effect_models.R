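# Inheritance-model collapse of genotype triples to 2x2 exposure tables,
# per-study odds ratios with Woolf intervals, and Hardy-Weinberg QC.

.gm_models <- c("additive", "dominant", "recessive")

check_counts <- function(x, what) {
  if (length(x) != 3L || any(is.na(x)) || any(x < 0))
    stop(what, " must be three non-negative counts (gg, gt, tt)")
  if (sum(x) <= 0) stop(what, " arm has zero total")
  as.numeric(x)
}

#' Collapse genotype triples into a 2x2 exposure table
#'
#' Collapses case and control genotype counts `(gg, gt, tt)` into a 2x2 table
#' under an inheritance model for the variant (G) allele:
#' \describe{
#'   \item{additive}{homozygote contrast GG vs TT — heterozygotes are
#'     excluded (this is the homozygote odds ratio, not a per-allele trend
#'     test);}
#'   \item{dominant}{G-carriers (GG+GT) vs TT;}
#'   \item{recessive}{GG vs T-carriers (GT+TT).}
#' }
#' If any resulting cell is zero, the Haldane-Anscombe continuity correction
#' `cc` is added to all four cells and `cc_applied` is set.
#'
#' @param cases,controls Numeric length-3 vectors of genotype counts
#'   `(gg, gt, tt)` for the case and control arm.
#' @param model One of `"additive"`, `"dominant"`, `"recessive"`.
#' @param cc Continuity-correction constant added to every cell when at
#'   least one raw cell is zero (default 0.5).
#' @param study_id Optional label carried through to estimates.
#' @return An object of class `"gm_2x2"`: list with cells `a` (exposed
#'   cases), `b` (unexposed cases), `c` (exposed controls), `d` (unexposed
#'   controls), plus `cc_applied`, `model` and `study_id`.
#' @examples
#' # homozygote contrast for a study with cases (2, 20, 111), controls (5, 47, 203)
#' collapse_counts(c(2, 20, 111), c(5, 47, 203), model = "additive")
#' @export
collapse_counts <- function(cases, controls,
                            model = c("additive", "dominant", "recessive"),
                            cc = 0.5, study_id = NULL) {
  model <- match.arg(model)
  ca <- check_counts(cases, "cases")
  co <- check_counts(controls, "controls")
  cells <- switch(model,
    additive  = c(a = ca[1], b = ca[3], c = co[1], d = co[3]),
    dominant  = c(a = ca[1] + ca[2], b = ca[3], c = co[1] + co[2], d = co[3]),
    recessive = c(a = ca[1], b = ca[2] + ca[3], c = co[1], d = co[2] + co[3]))
  if (cells["a"] + cells["b"] == 0 || cells["c"] + cells["d"] == 0)
    stop("degenerate table under the ", model, " model",
         if (!is.null(study_id)) paste0(" (study ", study_id, ")"),
         ": an arm collapses to zero")
  cc_applied <- any(cells == 0)
  if (cc_applied) cells <- cells + cc
  structure(list(a = unname(cells["a"]), b = unname(cells["b"]),
                 c = unname(cells["c"]), d = unname(cells["d"]),
                 cc_applied = cc_applied, model = model,
                 study_id = study_id),
            class = "gm_2x2")
}

#' Exchange the case and control rows of a 2x2 table
#'
#' Swapping arms inverts the odds ratio; applying it twice is the identity.
#'
#' @param t A `"gm_2x2"` table.
#' @return The table with `a` and `c`, `b` and `d` exchanged.
#' @export
swap_arms <- function(t) {
  stopifnot(inherits(t, "gm_2x2"))
  out <- t
  out$a <- t$c; out$c <- t$a
  out$b <- t$d; out$d <- t$b
  out
}

#' @export
print.gm_2x2 <- function(x, ...) {
  cat("2x2 exposure table (", x$model, " model",
      if (!is.null(x$study_id)) paste0(", ", x$study_id), ")\n", sep = "")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("exposed", "unexposed")))
  print(m)
  if (x$cc_applied) cat("continuity correction applied\n")
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio of a 2x2 table with the Woolf (log) standard
#' error `sqrt(1/a + 1/b + 1/c + 1/d)` and a log-symmetric normal-theory
#' confidence interval.
#'
#' @param t A `"gm_2x2"` table (all cells positive, guaranteed after
#'   [collapse_counts()] with continuity correction).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `"gm_estimate"`: `study_id`, `log_or`, `se`,
#'   `or`, `ci_low`, `ci_high`, `conf_level`, `cc_applied`.
#' @examples
#' t <- collapse_counts(c(2, 20, 111), c(5, 47, 203), "additive")
#' round(odds_ratio(t)$or, 2)   # 0.73
#' @export
odds_ratio <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "gm_2x2") || all(c("a", "b", "c", "d") %in% names(t)))
  if (any(unlist(t[c("a", "b", "c", "d")]) <= 0))
    stop("all four cells must be positive; collapse with a continuity correction first")
  log_or <- log(t$a * t$d / (t$b * t$c))
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(study_id = t$study_id,
                 log_or = log_or, se = se, or = exp(log_or),
                 ci_low = exp(log_or - z * se),
                 ci_high = exp(log_or + z * se),
                 conf_level = conf_level,
                 cc_applied = isTRUE(t$cc_applied)),
            class = "gm_estimate")
}

#' @export
print.gm_estimate <- function(x, digits = 2, ...) {
  cat(if (!is.null(x$study_id)) paste0(x$study_id, ": "),
      "OR = ", round(x$or, digits),
      " (", format(100 * x$conf_level), "% CI ",
      round(x$ci_low, digits), "-", round(x$ci_high, digits), ")\n", sep = "")
  invisible(x)
}

#' Per-study effect estimates for a dataset
#'
#' Collapses every study record under one inheritance model and computes its
#' Woolf log odds ratio. Studies whose table degenerates under the model are
#' excluded with a warning.
#'
#' @inheritParams pool_or
#' @return A data.frame with one row per usable study: `study_id`, `log_or`,
#'   `se`, `or`, `ci_low`, `ci_high`, `cc_applied`.
#' @examples
#' head(study_estimates(mdm2_studies(), "additive"))
#' @export
study_estimates <- function(data, model = c("additive", "dominant", "recessive"),
                            cc = 0.5, conf_level = 0.95) {
  model <- match.arg(model)
  tabs <- study_tables(data, model, cc)
  est <- lapply(tabs, odds_ratio, conf_level = conf_level)
  do.call(rbind, lapply(est, function(e)
    data.frame(study_id = e$study_id, log_or = e$log_or, se = e$se,
               or = e$or, ci_low = e$ci_low, ci_high = e$ci_high,
               cc_applied = e$cc_applied, stringsAsFactors = FALSE)))
}

# list of gm_2x2 per study; degenerate studies dropped with a warning
study_tables <- function(data, model, cc = 0.5) {
  out <- list()
  for (i in seq_len(nrow(data))) {
    tab <- tryCatch(
      collapse_counts(as.numeric(data[i, c("case_gg", "case_gt", "case_tt")]),
                      as.numeric(data[i, c("ctrl_gg", "ctrl_gt", "ctrl_tt")]),
                      model = model, cc = cc, study_id = data$study_id[i]),
      error = function(e) {
        warning("study ", data$study_id[i], " excluded under the ", model,
                " model: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(tab)) out[[length(out) + 1L]] <- tab
  }
  if (length(out) == 0L) stop("no usable study under the ", model, " model")
  out
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness-of-fit chi-square of observed genotype counts against the
#' Hardy-Weinberg proportions `(p^2, 2p(1-p), (1-p)^2)` at the estimated
#' variant-allele frequency `p = (2 gg + gt) / (2 n)`, with 1 degree of
#' freedom and no continuity correction. Conventionally applied to control
#' arms as a genotyping-quality check.
#'
#' @param counts Numeric length-3 vector `(gg, gt, tt)`.
#' @return A list of class `"gm_hwe"`: `chi2`, `df` (1), `p`, `g_freq`,
#'   `monomorphic`. Monomorphic samples (allele frequency 0 or 1) get
#'   `chi2 = 0` and are flagged.
#' @examples
#' hwe_chisq(c(51, 83, 25))$chi2   # 0.841
#' @export
hwe_chisq <- function(counts) {
  counts <- check_counts(counts, "genotype")
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) {
    return(structure(list(chi2 = 0, df = 1L, p = 1, g_freq = p,
                          monomorphic = TRUE), class = "gm_hwe"))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, 1L, lower.tail = FALSE),
                 g_freq = p, monomorphic = FALSE),
            class = "gm_hwe")
}

#' @export
print.gm_hwe <- function(x, ...) {
  cat("HWE chi-square = ", format(round(x$chi2, 3), nsmall = 3),
      ", df = 1, p = ", format.pval(x$p, digits = 3),
      " (variant-allele frequency ", round(x$g_freq, 3), ")",
      if (x$monomorphic) " [monomorphic]", "\n", sep = "")
  invisible(x)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test conditional on the observed allele counts: the probabilities
#' of all heterozygote counts compatible with the allele counts are
#' enumerated, and the p-value is the sum of those no more probable than the
#' observed configuration.
#'
#' @param counts Numeric length-3 vector `(gg, gt, tt)`.
#' @return The exact p-value, in `(0, 1]`.
#' @examples
#' hwe_exact(c(25, 50, 25))   # modal configuration, p = 1
#' @export
hwe_exact <- function(counts) {
  counts <- check_counts(counts, "genotype")
  n <- sum(counts)
  n_g <- 2 * counts[1] + counts[2]   # variant alleles
  n_t <- 2 * n - n_g
  if (n_g == 0 || n_t == 0) return(1)
  hets <- seq(n_g %% 2, min(n_g, n_t), by = 2)
  # log P(het = h | n, n_g) up to a constant: 2^h / ((n_g-h)/2)! h! ((n_t-h)/2)!
  logp <- hets * log(2) - lgamma((n_g - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((n_t - hets) / 2 + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(counts[2], hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg QC table for the control arms of a dataset
#'
#' @param ds A study data.frame.
#' @param alpha Flagging level for the chi-square p-value (default 0.05).
#' @return A data.frame with one row per study: `study_id`, `g_freq`,
#'   `chi2`, `p`, `exact_p`, `hwe_pass`.
#' @export
hwe_table <- function(ds, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    counts <- as.numeric(ds[i, c("ctrl_gg", "ctrl_gt", "ctrl_tt")])
    h <- hwe_chisq(counts)
    data.frame(study_id = ds$study_id[i], g_freq = h$g_freq, chi2 = h$chi2,
               p = h$p, exact_p = hwe_exact(counts),
               hwe_pass = h$p > alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
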