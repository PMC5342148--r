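#' @importFrom rlang abort warn .data :=
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols n count across row_number if_else case_when
#'   all_of any_of pull relocate distinct
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats pchisq pt rnorm rpois runif rexp rbinom setNames
NULL

# Controlled vocabularies used across the package ---------------------------

rtk_genes <- function() c("EGFR", "HER2", "MET")

lauren_levels <- function() c("intestinal", "mixed", "diffuse")

subgroup_levels <- function(system = c("putative", "histologic")) {
  system <- match.arg(system)
  if (system == "putative") {
    c("EBV_positive", "MMR_deficient", "pGS", "pCIN")
  } else {
    c("EBV_positive", "MMR_deficient", "D_pGS", "I_pCIN")
  }
}

amp_call_levels <- function() {
  c("amplified", "not_amplified", "insufficient", "not_tested")
}

#' Round half away from zero
#'
#' Percentages in pathology tables are conventionally rounded half-up
#' (`34.25` to one decimal is `34.3`), whereas [base::round()] rounds half to
#' even. This helper reproduces the tabular convention; full precision is
#' retained everywhere internally and rounding is applied only when a value
#' is compared with, or displayed next to, a printed table.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(34.25, 87.45), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Validate that `x` takes values in `levels` (NA allowed); abort naming the
# offending cases otherwise.
check_enum <- function(x, levels, field, case_id = NULL) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    who <- if (!is.null(case_id)) {
      paste0(" (case ", paste(unique(case_id[bad]), collapse = ", "), ")")
    } else {
      ""
    }
    abort(sprintf(
      "Invalid value for `%s`%s: %s. Allowed: %s.",
      field, who,
      paste(unique(x[bad]), collapse = ", "),
      paste(levels, collapse = ", ")
    ), class = "ragc_validation_error")
  }
  invisible(x)
}

# Join per-case flag fragments into the semicolon-separated convention used
# in derived-status tables ("" when no flags).
join_flags <- function(...) {
  frags <- list(...)
  out <- do.call(paste, c(frags, sep = ";"))
  out <- gsub(";{2,}", ";", out)
  out <- gsub("^;|;$", "", out)
  out
}
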