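#' Cohort and SISH tabular input/output
#'
#' A cohort is a tibble with one row per tumor; per-nucleus SISH signal
#' counts live in a companion tibble with one row per nucleus. Both are
#' plain delimiter-separated files (TSV or CSV, chosen by extension) with a
#' header row. Empty fields are missing markers: they are preserved as `NA`
#' and never coerced to a default at I/O time (imputation happens only in
#' marker calling, where it leaves a flag).
#'
#' Canonical cohort columns: `case_id, age, sex, location, size_cm,
#' differentiation, lauren, lvi, lnm, pt_stage, overall_stage, egfr_ihc,
#' her2_ihc, met_ihc, mlh1, msh2, msh6, pms2, p53_class, p53_pct, eber,
#' rfs_months, rfs_event, os_months, os_event`. Only `case_id` is required;
#' any other column may be absent (it is filled with `NA`) or renamed via
#' `col_map`.
#'
#' Canonical SISH columns: `case_id, gene, core_id, gene_signals,
#' small_clusters, large_clusters, chr_signals`.
#'
#' @param path File to read or write.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(case_id = "PatientID", her2_ihc = "HER2score")`.
#' @return `read_cohort()` and `read_sish()` return validated tibbles in
#'   canonical column order; the writers return `path` invisibly.
#' @name cohort_io
NULL

cohort_columns <- function() {
  c("case_id", "age", "sex", "location", "size_cm", "differentiation",
    "lauren", "lvi", "lnm", "pt_stage", "overall_stage",
    "egfr_ihc", "her2_ihc", "met_ihc",
    "mlh1", "msh2", "msh6", "pms2", "p53_class", "p53_pct", "eber",
    "rfs_months", "rfs_event", "os_months", "os_event")
}

sish_columns <- function() {
  c("case_id", "gene", "core_id", "gene_signals", "small_clusters",
    "large_clusters", "chr_signals")
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Input file does not exist: %s", path),
          class = "ragc_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, na = c("", "NA"),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
}

apply_col_map <- function(df, col_map, path) {
  if (is.null(col_map)) return(df)
  missing_src <- setdiff(unname(col_map), names(df))
  if (length(missing_src) > 0) {
    abort(sprintf("Column(s) named in `col_map` not found in %s: %s",
                  path, paste(missing_src, collapse = ", ")),
          class = "ragc_schema_error")
  }
  names(df)[match(unname(col_map), names(df))] <- names(col_map)
  df
}

as_num <- function(x, field, case_id) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(sprintf("Non-numeric value for `%s` (case %s): %s", field,
                  paste(case_id[bad], collapse = ", "),
                  paste(x[bad], collapse = ", ")),
          class = "ragc_validation_error")
  }
  out
}

as_score <- function(x, field, case_id) {
  out <- as_num(x, field, case_id)
  bad <- !is.na(out) & !(out %in% 0:3)
  if (any(bad)) {
    abort(sprintf(
      "IHC score out of range for `%s` (case %s): %s. Scores are 0-3.",
      field, paste(case_id[bad], collapse = ", "),
      paste(out[bad], collapse = ", ")
    ), class = "ragc_validation_error")
  }
  as.integer(out)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path, col_map = NULL) {
  df <- read_delim_auto(path)
  df <- apply_col_map(df, col_map, path)
  if (!"case_id" %in% names(df)) {
    abort(sprintf("Required column `case_id` is missing from %s.", path),
          class = "ragc_schema_error")
  }
  for (col in setdiff(cohort_columns(), names(df))) {
    df[[col]] <- NA_character_
  }
  df <- df[cohort_columns()]
  validate_cohort(df)
}

#' Validate a cohort tibble
#'
#' Coerces columns to canonical types and checks every enumeration and
#' range. Validation is total: every row either passes or the function
#' aborts with a `ragc_validation_error` naming the case and field; nothing
#' is silently dropped. `rfs_months > os_months` is reported as a warning
#' (registry data can violate it) and later flagged by [derive_status()].
#'
#' @param df A data frame with at least a `case_id` column.
#' @return The validated cohort tibble.
#' @export
validate_cohort <- function(df) {
  df <- as_tibble(df)
  if (anyNA(df$case_id)) {
    abort("`case_id` must be non-missing for every row.",
          class = "ragc_validation_error")
  }
  if (anyDuplicated(df$case_id)) {
    abort(sprintf("Duplicated case_id: %s",
                  paste(unique(df$case_id[duplicated(df$case_id)]),
                        collapse = ", ")),
          class = "ragc_validation_error")
  }
  id <- df$case_id

  df$age <- as_num(as.character(df$age), "age", id)
  df$size_cm <- as_num(as.character(df$size_cm), "size_cm", id)
  for (fld in c("age", "size_cm")) {
    bad <- !is.na(df[[fld]]) & df[[fld]] <= 0
    if (any(bad)) {
      abort(sprintf("`%s` must be positive (case %s).", fld,
                    paste(id[bad], collapse = ", ")),
            class = "ragc_validation_error")
    }
  }

  check_enum(df$sex, c("male", "female"), "sex", id)
  check_enum(df$location, c("lower_third", "upper_mid_third"), "location", id)
  check_enum(df$differentiation, c("differentiated", "undifferentiated"),
             "differentiation", id)
  check_enum(df$lauren, lauren_levels(), "lauren", id)
  check_enum(df$lvi, c("present", "absent"), "lvi", id)
  check_enum(df$lnm, c("present", "absent"), "lnm", id)
  check_enum(df$pt_stage, c("T2", "T3", "T4"), "pt_stage", id)
  check_enum(df$overall_stage, c("II", "III", "IV"), "overall_stage", id)

  for (fld in c("egfr_ihc", "her2_ihc", "met_ihc")) {
    df[[fld]] <- as_score(as.character(df[[fld]]), fld, id)
  }
  for (fld in c("mlh1", "msh2", "msh6", "pms2")) {
    check_enum(df[[fld]], c("intact", "lost"), fld, id)
  }
  check_enum(df$p53_class, c("complete_loss", "strong_nuclear", "other"),
             "p53_class", id)
  df$p53_pct <- as_num(as.character(df$p53_pct), "p53_pct", id)
  bad <- !is.na(df$p53_pct) & (df$p53_pct < 0 | df$p53_pct > 100)
  if (any(bad)) {
    abort(sprintf("`p53_pct` must lie in [0, 100] (case %s).",
                  paste(id[bad], collapse = ", ")),
          class = "ragc_validation_error")
  }
  check_enum(df$eber, c("positive", "negative"), "eber", id)

  df$rfs_months <- as_num(as.character(df$rfs_months), "rfs_months", id)
  df$os_months <- as_num(as.character(df$os_months), "os_months", id)
  check_enum(df$rfs_event, c("event", "censored"), "rfs_event", id)
  check_enum(df$os_event, c("death", "censored"), "os_event", id)
  for (fld in c("rfs_months", "os_months")) {
    bad <- !is.na(df[[fld]]) & df[[fld]] < 0
    if (any(bad)) {
      abort(sprintf("`%s` must be non-negative (case %s).", fld,
                    paste(id[bad], collapse = ", ")),
            class = "ragc_validation_error")
    }
  }
  inconsistent <- !is.na(df$rfs_months) & !is.na(df$os_months) &
    df$rfs_months > df$os_months
  if (any(inconsistent)) {
    warn(sprintf(
      "rfs_months > os_months for case %s; kept and flagged downstream.",
      paste(id[inconsistent], collapse = ", ")
    ))
  }
  df
}

#' @rdname cohort_io
#' @export
read_sish <- function(path, col_map = NULL) {
  df <- read_delim_auto(path)
  df <- apply_col_map(df, col_map, path)
  missing_cols <- setdiff(sish_columns(), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Required SISH column(s) missing from %s: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "ragc_schema_error")
  }
  validate_sish(df[sish_columns()])
}

#' Validate a per-nucleus SISH tibble
#'
#' @param df Data frame with the canonical SISH columns.
#' @return The validated tibble (counts as integers).
#' @export
validate_sish <- function(df) {
  df <- as_tibble(df)
  id <- df$case_id
  check_enum(df$gene, rtk_genes(), "gene", id)
  for (fld in c("core_id", "gene_signals", "small_clusters",
                "large_clusters", "chr_signals")) {
    df[[fld]] <- as_num(as.character(df[[fld]]), fld, id)
    bad <- is.na(df[[fld]]) | df[[fld]] < 0 | df[[fld]] != round(df[[fld]])
    if (any(bad)) {
      abort(sprintf("`%s` must be a non-negative integer (case %s).", fld,
                    paste(id[bad], collapse = ", ")),
            class = "ragc_validation_error")
    }
    df[[fld]] <- as.integer(df[[fld]])
  }
  bad_core <- !(df$core_id %in% c(1L, 2L))
  if (any(bad_core)) {
    abort(sprintf("`core_id` must be 1 or 2 (case %s).",
                  paste(id[bad_core], collapse = ", ")),
          class = "ragc_validation_error")
  }
  df
}

write_delim_auto <- function(df, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @param cohort A cohort tibble (for `write_cohort()`).
#' @export
write_cohort <- function(cohort, path) {
  write_delim_auto(cohort[intersect(cohort_columns(), names(cohort))], path)
}

#' @rdname cohort_io
#' @param sish A per-nucleus SISH tibble (for `write_sish()`).
#' @export
write_sish <- function(sish, path) {
  write_delim_auto(sish[sish_columns()], path)
}

derived_column_types <- function() {
  list(
    character = c("case_id", "lauren", "mmr", "p53", "eber_effective",
                  "egfr_amp", "her2_amp", "met_amp",
                  "subgroup_putative", "subgroup_histologic",
                  "recommendation", "target_gene", "rationale_path", "flags"),
    integer = c("egfr_ihc", "her2_ihc", "met_ihc"),
    logical = c("egfr_pos", "her2_pos", "met_pos", "rtk_ihc_positive",
                "ra_gc", "sish_required"),
    double = c("egfr_ratio", "her2_ratio", "met_ratio")
  )
}

#' Write and re-read derived per-case status
#'
#' `write_derived()` serializes the annotated per-case table produced by
#' [derive_status()] / [annotate_cohort()]; `read_derived()` restores it with
#' identical column types, so `read_derived(write_derived(x))` reproduces
#' every derived field exactly. Data-quality flags are a single
#' semicolon-joined string per case (empty when there are none).
#'
#' @param derived Annotated status tibble.
#' @param path Output file (TSV or CSV by extension).
#' @param cohort Optional cohort tibble; when supplied, `case_id`s must match
#'   the derived table pairwise or a pairing error is raised.
#' @return `write_derived()` returns `path` invisibly; `read_derived()`
#'   returns the tibble.
#' @export
write_derived <- function(derived, path, cohort = NULL) {
  if (!is.null(cohort)) {
    if (nrow(cohort) != nrow(derived) ||
        !identical(cohort$case_id, derived$case_id)) {
      abort("`cohort` and `derived` case_ids do not match pairwise.",
            class = "ragc_pairing_error")
    }
  }
  write_delim_auto(derived, path)
}

#' @rdname write_derived
#' @export
read_derived <- function(path) {
  df <- read_delim_auto(path)
  types <- derived_column_types()
  for (col in intersect(names(df), types$integer)) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in intersect(names(df), types$logical)) {
    df[[col]] <- as.logical(df[[col]])
  }
  for (col in intersect(names(df), types$double)) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in intersect(names(df), c("flags", "rationale_path"))) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}
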