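# Data model, file I/O and validation for per-study genotype count records.
#
# A study dataset is a plain data.frame with one row per case-control study
# and a fixed header vocabulary; any column beyond the required schema is
# carried along as a stratification variable.

.count_cols <- c("case_gg", "case_gt", "case_tt", "ctrl_gg", "ctrl_gt", "ctrl_tt")
.required_cols <- c("study_id", "first_author", "year", "ethnicity",
                    "control_source", "method", .count_cols)
.known_ethnicity <- c("Asian", "Caucasian", "African")
.known_control_source <- c("HB", "PB")

#' Read per-study genotype count records
#'
#' Reads a delimited table (CSV by default, TSV accepted) of case-control
#' genotype counts, one row per study. The required columns are
#' `study_id, first_author, year, ethnicity, control_source, method,
#' case_gg, case_gt, case_tt, ctrl_gg, ctrl_gt, ctrl_tt`; additional columns
#' are kept and treated as stratification variables. Case and control totals
#' are always derived from the genotype triples, never from a totals column.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter. `NULL` (default) chooses `"\t"` for files
#'   ending in `.tsv`/`.txt` and `","` otherwise.
#' @return A `data.frame` of class `"genemeta_studies"` with one row per
#'   study, counts as integers, and the source path in
#'   `attr(, "provenance")`.
#' @examples
#' ds <- mdm2_studies()
#' nrow(ds)                       # 11 case-control studies
#' sum(study_totals(ds)$cases)    # 7196
#' @seealso [write_studies()], [validate_dataset()], [mdm2_studies()]
#' @export
read_studies <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) stop("no records in ", path)

  for (cl in .count_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0L)
      stop("column '", cl, "': non-integer or negative count in data row(s) ",
           paste(bad, collapse = ", "))
    raw[[cl]] <- as.integer(v)
  }
  raw$year <- suppressWarnings(as.integer(raw$year))
  dup <- unique(raw$study_id[duplicated(raw$study_id)])
  if (length(dup) > 0L)
    stop("duplicate study_id: ", paste(dup, collapse = ", "))

  structure(raw,
            provenance = path,
            class = c("genemeta_studies", "data.frame"))
}

#' Write per-study genotype count records
#'
#' Inverse of [read_studies()]: writes the dataset so that reading it back
#' reproduces every count and metadata field.
#'
#' @param ds A study data.frame (as returned by [read_studies()]).
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_studies <- function(ds, path, delim = ",") {
  utils::write.table(as.data.frame(ds), path, sep = delim, row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}

#' The 11-study MDM2 T309G lung-cancer dataset
#'
#' Genotype counts (GG/GT/TT in cases and controls) for the eleven published
#' case-control studies of the MDM2 promoter T309G polymorphism (rs2279744)
#' and lung cancer risk, with study metadata (ethnicity, hospital- vs
#' population-based controls, genotyping method). One study typed two ethnic
#' groups and appears as two records. Totals: 7196 cases, 8456 controls.
#'
#' @return A `"genemeta_studies"` data.frame with 11 rows.
#' @examples
#' fit <- pool_or(mdm2_studies(), model = "dominant")
#' fit
#' @export
mdm2_studies <- function() {
  read_studies(system.file("extdata", "mdm2_t309g_lung.csv",
                           package = "genemeta", mustWork = TRUE))
}

#' Per-study case and control totals
#'
#' Arm totals derived from the genotype triples (the authoritative source;
#' totals columns in publications occasionally disagree with their own
#' genotype tables).
#'
#' @param ds A study data.frame.
#' @return A data.frame with columns `study_id`, `cases`, `controls`.
#' @export
study_totals <- function(ds) {
  data.frame(study_id = ds$study_id,
             cases = ds$case_gg + ds$case_gt + ds$case_tt,
             controls = ds$ctrl_gg + ds$ctrl_gt + ds$ctrl_tt,
             stringsAsFactors = FALSE)
}

#' Validate a study dataset
#'
#' Non-throwing structural checks: empty arms, duplicate study ids, labels
#' outside the declared ethnicity / control-source vocabularies, missing
#' metadata. Unknown labels are findings, not errors — such studies form
#' their own subgroup rather than being dropped.
#'
#' @param ds A study data.frame.
#' @return A data.frame of findings with columns `study_id`, `severity`
#'   (`"error"` or `"warning"`) and `finding`; zero rows when clean.
#' @examples
#' validate_dataset(mdm2_studies())   # clean: zero findings
#' @export
validate_dataset <- function(ds) {
  findings <- list()
  add <- function(id, severity, msg)
    findings[[length(findings) + 1L]] <<- data.frame(
      study_id = id, severity = severity, finding = msg,
      stringsAsFactors = FALSE)

  dup <- unique(ds$study_id[duplicated(ds$study_id)])
  for (id in dup) add(id, "error", "duplicate study_id")

  tot <- study_totals(ds)
  for (i in seq_len(nrow(ds))) {
    id <- ds$study_id[i]
    if (tot$cases[i] == 0L) add(id, "error", "empty case arm")
    if (tot$controls[i] == 0L) add(id, "error", "empty control arm")
    if (!ds$ethnicity[i] %in% .known_ethnicity)
      add(id, "warning", paste0("ethnicity label outside declared vocabulary: '",
                                ds$ethnicity[i], "'"))
    if (!ds$control_source[i] %in% .known_control_source)
      add(id, "warning", paste0("control_source outside declared vocabulary: '",
                                ds$control_source[i], "'"))
    if (is.na(ds$year[i])) add(id, "warning", "missing year")
  }
  if (length(findings) == 0L)
    return(data.frame(study_id = character(), severity = character(),
                      finding = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Extra stratification columns of a dataset
#'
#' @param ds A study data.frame.
#' @return Character vector of column names beyond the required schema.
#' @export
strata_columns <- function(ds) setdiff(names(ds), .required_cols)
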