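# End-to-end orchestration: per-study estimates, HWE QC, overall and
# subgroup pooling for the requested inheritance models, sensitivity and
# bias analyses, and report rendering.

#' Subgroup (stratified) pooled analysis
#'
#' Partitions the dataset by the levels of a categorical column and pools
#' each level separately. Levels containing a single study yield that
#' study's estimate labelled MH-fixed, with no heterogeneity block.
#'
#' @inheritParams pool_or
#' @param column Name of the stratification column (any column of the
#'   dataset, e.g. `"ethnicity"` or `"control_source"`).
#' @return A named list of `"gm_pool"` fits, one per level (level order =
#'   order of first appearance).
#' @examples
#' sg <- subgroup_analysis(mdm2_studies(), "ethnicity", model = "dominant")
#' sg$Caucasian
#' @export
subgroup_analysis <- function(data, column,
                              model = c("additive", "dominant", "recessive"),
                              method = c("auto", "fixed", "random"),
                              het_threshold = 0.1, cc = 0.5,
                              conf_level = 0.95) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (!column %in% names(data))
    stop("unknown column '", column, "'; available: ",
         paste(names(data), collapse = ", "))
  levels <- unique(as.character(data[[column]]))
  fits <- lapply(levels, function(lv)
    pool_or(data[data[[column]] == lv, , drop = FALSE], model = model,
            method = method, het_threshold = het_threshold, cc = cc,
            conf_level = conf_level))
  stats::setNames(fits, levels)
}

#' Run the full meta-analysis pipeline
#'
#' Validates the dataset, computes per-study estimates and Hardy-Weinberg QC
#' for the control arms, pools overall effects for each requested
#' inheritance model with Q-test based model selection, runs subgroup,
#' leave-one-out sensitivity and publication-bias (funnel + Egger) analyses,
#' and returns everything as one report object. Studies violating HWE at
#' `hwe_alpha` are flagged, never dropped.
#'
#' Subgroup model selection: with `subgroup_selection = "overall"` (the
#' default) every stratum of a genetic model is pooled with the method the
#' Q-test selected on the *overall* data for that model, keeping the
#' estimator consistent across the rows of one results table; `"stratum"`
#' re-applies the `p > het_threshold` gate within each stratum.
#'
#' @inheritParams pool_or
#' @param models Character vector of inheritance models to analyse.
#' @param subgroups Character vector of stratification columns (default
#'   `c("ethnicity", "control_source")`); use `character(0)` to skip.
#' @param hwe_alpha Flagging level for control-arm HWE (default 0.05).
#' @param subgroup_selection `"overall"` or `"stratum"` (see Details).
#' @return An object of class `"gm_report"`: list with elements `per_study`,
#'   `hwe`, `overall`, `subgroups`, `sensitivity`, `bias`, `config`,
#'   `provenance`, `validation`.
#' @examples
#' rep <- run_pipeline(mdm2_studies())
#' rep
#' @export
run_pipeline <- function(data,
                         models = c("additive", "dominant", "recessive"),
                         subgroups = c("ethnicity", "control_source"),
                         het_threshold = 0.1, conf_level = 0.95, cc = 0.5,
                         hwe_alpha = 0.05,
                         subgroup_selection = c("overall", "stratum")) {
  subgroup_selection <- match.arg(subgroup_selection)
  models <- match.arg(models, .gm_models, several.ok = TRUE)
  findings <- validate_dataset(data)
  if (any(findings$severity == "error"))
    stop("dataset fails validation:\n",
         paste(findings$finding[findings$severity == "error"], collapse = "\n"))
  missing_sg <- setdiff(subgroups, names(data))
  if (length(missing_sg) > 0L)
    stop("unknown subgroup column(s): ", paste(missing_sg, collapse = ", "),
         "; available: ", paste(names(data), collapse = ", "))

  hwe <- hwe_table(data, alpha = hwe_alpha)

  per_study <- list(); overall <- list(); sensitivity <- list(); bias <- list()
  subgrp <- list()
  for (m in models) {
    per_study[[m]] <- study_estimates(data, m, cc = cc, conf_level = conf_level)
    fit <- pool_or(data, model = m, het_threshold = het_threshold,
                   cc = cc, conf_level = conf_level)
    overall[[m]] <- fit
    sensitivity[[m]] <- leave_one_out(data, m, het_threshold = het_threshold,
                                      cc = cc, conf_level = conf_level)
    bias[[m]] <- list(egger = if (fit$k >= 3L) egger_test(fit) else NULL,
                      funnel = funnel_data(fit))
    sg_method <- if (subgroup_selection == "overall")
      switch(fit$method, `MH-fixed` = "fixed", `DL-random` = "random")
    else "auto"
    for (colnm in subgroups)
      subgrp[[colnm]][[m]] <- subgroup_analysis(
        data, colnm, model = m, method = sg_method,
        het_threshold = het_threshold, cc = cc, conf_level = conf_level)
  }

  structure(list(per_study = per_study, hwe = hwe, overall = overall,
                 subgroups = subgrp, sensitivity = sensitivity, bias = bias,
                 validation = findings,
                 config = list(models = models, subgroups = subgroups,
                               het_threshold = het_threshold,
                               conf_level = conf_level, cc = cc,
                               hwe_alpha = hwe_alpha,
                               subgroup_selection = subgroup_selection),
                 provenance = attr(data, "provenance")),
            class = "gm_report")
}

# one summary row for a gm_pool fit
pool_row <- function(fit, label = NA_character_) {
  tot <- study_totals(fit$data)
  data.frame(group = label, model = fit$model, k = fit$k,
             cases = sum(tot$cases), controls = sum(tot$controls),
             method = fit$method, or = fit$or,
             ci_low = fit$ci_low, ci_high = fit$ci_high,
             z = fit$z, p = fit$p,
             q = if (is.null(fit$het)) NA_real_ else fit$het$q,
             p_q = if (is.null(fit$het)) NA_real_ else fit$het$p,
             i2 = if (is.null(fit$het)) NA_real_ else fit$het$i2,
             tau2 = if (is.null(fit$het)) NA_real_ else fit$het$tau2,
             stringsAsFactors = FALSE)
}

report_tables <- function(r) {
  overall <- do.call(rbind, lapply(r$overall, pool_row, label = "Total"))
  rownames(overall) <- NULL
  sg_rows <- list()
  for (colnm in names(r$subgroups))
    for (m in names(r$subgroups[[colnm]]))
      for (lv in names(r$subgroups[[colnm]][[m]])) {
        row <- pool_row(r$subgroups[[colnm]][[m]][[lv]], label = lv)
        row <- cbind(data.frame(column = colnm, stringsAsFactors = FALSE), row)
        sg_rows[[length(sg_rows) + 1L]] <- row
      }
  subgroups <- if (length(sg_rows)) do.call(rbind, sg_rows) else NULL
  sens <- do.call(rbind, lapply(names(r$sensitivity), function(m) {
    df <- as.data.frame(r$sensitivity[[m]])
    cbind(data.frame(model = m, stringsAsFactors = FALSE), df)
  }))
  funnel <- lapply(r$bias, `[[`, "funnel")
  list(overall = overall, subgroups = subgroups, hwe = r$hwe,
       sensitivity = sens, funnel = funnel)
}

fmt_or_ci <- function(or, lo, hi) sprintf("%.2f (%.2f-%.2f)", or, lo, hi)

#' Render a pipeline report
#'
#' Serializes a `"gm_report"`. The `tsv` and `json` forms are loss-free at
#' full precision; the `text` form rounds odds ratios and CIs to 2 decimals
#' and heterogeneity statistics to 3, mirroring conventional results tables.
#'
#' @param r A `"gm_report"` from [run_pipeline()].
#' @param format `"text"`, `"json"` or `"tsv"`.
#' @param out Optional output directory; when given, files are written
#'   (`overall.tsv`, `subgroups.tsv`, `hwe.tsv`, `sensitivity.tsv`,
#'   `funnel_<model>.tsv` for `"tsv"`; `report.json`; `report.txt`).
#' @return For `"text"` a character vector of lines; for `"json"` a JSON
#'   string; for `"tsv"` a named list of data.frames. Invisible when `out`
#'   is given.
#' @export
render_report <- function(r, format = c("text", "json", "tsv"), out = NULL) {
  format <- match.arg(format)
  tabs <- report_tables(r)
  result <- switch(format,
    tsv = tabs,
    json = {
      plain <- list(
        config = r$config, provenance = r$provenance,
        per_study = r$per_study, hwe = tabs$hwe,
        overall = tabs$overall, subgroups = tabs$subgroups,
        sensitivity = tabs$sensitivity, funnel = tabs$funnel,
        egger = lapply(r$bias, function(b) if (is.null(b$egger)) NULL
                       else unclass(b$egger)))
      as.character(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                                    null = "null", na = "null", pretty = TRUE))
    },
    text = {
      lines <- c("Meta-analysis report", "====================", "")
      ov <- tabs$overall
      lines <- c(lines, "Overall pooled results:")
      for (i in seq_len(nrow(ov)))
        lines <- c(lines, sprintf(
          "  %-9s %-9s k=%-2d OR %s  p=%.3f  P(Q)=%.3f  I2=%.1f%%",
          ov$model[i], ov$method[i], ov$k[i],
          fmt_or_ci(ov$or[i], ov$ci_low[i], ov$ci_high[i]),
          ov$p[i], ov$p_q[i], ov$i2[i]))
      if (!is.null(tabs$subgroups)) {
        lines <- c(lines, "", "Subgroups:")
        sg <- tabs$subgroups
        for (i in seq_len(nrow(sg)))
          lines <- c(lines, sprintf(
            "  %-15s %-10s %-9s k=%-2d OR %s  p=%.3f  P(Q)=%s",
            sg$column[i], sg$group[i], sg$model[i], sg$k[i],
            fmt_or_ci(sg$or[i], sg$ci_low[i], sg$ci_high[i]), sg$p[i],
            ifelse(is.na(sg$p_q[i]), "-", sprintf("%.3f", sg$p_q[i]))))
      }
      lines <- c(lines, "", "Control-arm HWE:")
      for (i in seq_len(nrow(tabs$hwe)))
        lines <- c(lines, sprintf("  %-16s chi2=%.3f p=%.3f %s",
                                  tabs$hwe$study_id[i], tabs$hwe$chi2[i],
                                  tabs$hwe$p[i],
                                  ifelse(tabs$hwe$hwe_pass[i], "", "FLAG")))
      eg <- r$bias
      lines <- c(lines, "", "Egger funnel-asymmetry tests:")
      for (m in names(eg)) if (!is.null(eg[[m]]$egger))
        lines <- c(lines, sprintf("  %-9s t=%.2f (df=%d) p=%.3f", m,
                                  eg[[m]]$egger$t, eg[[m]]$egger$df,
                                  eg[[m]]$egger$p))
      lines
    })
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) utils::write.table(
      df, file.path(out, f), sep = "\t", row.names = FALSE, quote = FALSE)
    if (format == "tsv") {
      wr(tabs$overall, "overall.tsv")
      if (!is.null(tabs$subgroups)) wr(tabs$subgroups, "subgroups.tsv")
      wr(tabs$hwe, "hwe.tsv")
      wr(tabs$sensitivity, "sensitivity.tsv")
      for (m in names(tabs$funnel)) wr(tabs$funnel[[m]],
                                       paste0("funnel_", m, ".tsv"))
    } else if (format == "json") {
      writeLines(result, file.path(out, "report.json"))
    } else writeLines(result, file.path(out, "report.txt"))
    return(invisible(result))
  }
  result
}

#' @export
print.gm_report <- function(x, ...) {
  writeLines(render_report(x, "text"))
  invisible(x)
}
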