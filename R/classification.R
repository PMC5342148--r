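#' Putative-molecular subgroup
#'
#' Four mutually exclusive surrogate subgroups applied in strict precedence
#' order EBV, then MMR, then p53: EBER-positive cases are `EBV_positive`;
#' remaining MMR-deficient cases are `MMR_deficient`; remaining p53
#' wild-pattern cases are `pGS` (putative genome-stable); the rest (p53
#' mutant-pattern) are `pCIN` (putative chromosomal instability).
#'
#' @param eber_effective `"positive"`/`"negative"` (vectorized).
#' @param mmr `"deficient"`/`"proficient"`.
#' @param p53 `"wild_pattern"`/`"mutant_pattern"`.
#' @return Character vector of subgroup labels.
#' @export
classify_putative <- function(eber_effective, mmr, p53) {
  check_enum(eber_effective, c("positive", "negative"), "eber_effective")
  check_enum(mmr, c("deficient", "proficient"), "mmr")
  check_enum(p53, c("wild_pattern", "mutant_pattern"), "p53")
  dplyr::case_when(
    eber_effective == "positive" ~ "EBV_positive",
    mmr == "deficient" ~ "MMR_deficient",
    p53 == "wild_pattern" ~ "pGS",
    TRUE ~ "pCIN"
  )
}

#' Histologic-molecular subgroup
#'
#' Refines the putative classification with the Lauren histotype: EBV and
#' MMR branches are unchanged; p53 mutant-pattern cases are `I_pCIN`
#' regardless of Lauren type; p53 wild-pattern cases are `D_pGS` when
#' diffuse and `I_pCIN` when intestinal or mixed. Consequently `I_pCIN`
#' always contains `pCIN`, and `D_pGS` is always contained in `pGS`.
#'
#' @inheritParams classify_putative
#' @param lauren `"intestinal"`, `"mixed"` or `"diffuse"`.
#' @return Character vector of subgroup labels.
#' @export
classify_histologic <- function(eber_effective, mmr, p53, lauren) {
  check_enum(eber_effective, c("positive", "negative"), "eber_effective")
  check_enum(mmr, c("deficient", "proficient"), "mmr")
  check_enum(p53, c("wild_pattern", "mutant_pattern"), "p53")
  check_enum(lauren, lauren_levels(), "lauren")
  dplyr::case_when(
    eber_effective == "positive" ~ "EBV_positive",
    mmr == "deficient" ~ "MMR_deficient",
    p53 == "mutant_pattern" ~ "I_pCIN",
    lauren == "diffuse" ~ "D_pGS",
    TRUE ~ "I_pCIN"
  )
}

#' Add both subgroup labels to a derived-status table
#'
#' @param derived Output of [derive_status()].
#' @return `derived` with `subgroup_putative` and `subgroup_histologic`
#'   columns appended.
#' @export
classify_subgroups <- function(derived) {
  if (anyNA(derived$lauren)) {
    abort(sprintf(
      "Lauren type is required for histologic-molecular classification; missing for case %s.",
      paste(derived$case_id[is.na(derived$lauren)], collapse = ", ")
    ), class = "ragc_validation_error")
  }
  derived |>
    mutate(
      subgroup_putative = classify_putative(
        .data$eber_effective, .data$mmr, .data$p53),
      subgroup_histologic = classify_histologic(
        .data$eber_effective, .data$mmr, .data$p53, .data$lauren)
    )
}

triage_one <- function(subgroup_histologic, egfr_ihc, her2_ihc, met_ihc,
                       egfr_amp, her2_amp, met_amp, policy) {
  path <- character()
  score <- c(EGFR = egfr_ihc, HER2 = her2_ihc, MET = met_ihc)
  amp <- c(EGFR = egfr_amp, HER2 = her2_amp, MET = met_amp)
  score[is.na(score)] <- 0L

  outcome <- function(recommendation, target_gene, sish_required, flag = "") {
    tibble(recommendation = recommendation, target_gene = target_gene,
           sish_required = sish_required,
           rationale_path = paste(path, collapse = ">"),
           triage_flag = flag)
  }

  path <- c(path, "ebv_mmr_screen")
  if (subgroup_histologic %in% c("EBV_positive", "MMR_deficient")) {
    path <- c(path, "immunotherapy_candidate")
    return(outcome("immunotherapy_candidate", "none", FALSE))
  }
  if (policy$route_dpgs_to_ngs && subgroup_histologic == "D_pGS") {
    path <- c(path, "d_pgs_direct_to_ngs")
    return(outcome("target_sequencing_ngs", "none", FALSE))
  }

  path <- c(path, "rtk_ihc_panel")
  if (score[["HER2"]] == 3L) {
    # HER2 3+ is a sufficient indicator on its own; SISH is optional and
    # only informative for response prediction.
    path <- c(path, "her2_3plus")
    return(outcome("her2_targeted_therapy", "HER2", FALSE))
  }

  pending <- character()
  needs_sish <- any(score[c("EGFR", "MET")] == 3L) || any(score == 2L)
  for (g in c("EGFR", "MET")) {
    if (score[[g]] == 3L) {
      path <- c(path, paste0(tolower(g), "_3plus_sish"))
      if (amp[[g]] == "amplified") {
        return(outcome("rtk_targeted_therapy", g, TRUE))
      }
      if (amp[[g]] %in% c("not_tested", "insufficient")) {
        pending <- c(pending, g)
      }
    }
  }
  two_plus <- names(score)[score == 2L]
  if (length(two_plus) > 0) {
    path <- c(path, "rtk_2plus_sish")
    for (g in two_plus) {
      if (amp[[g]] == "amplified") {
        return(outcome("rtk_targeted_therapy", g, TRUE))
      }
      if (amp[[g]] %in% c("not_tested", "insufficient")) {
        pending <- c(pending, g)
      }
    }
  }

  if (length(pending) > 0 && !policy$defer_pending_to_ngs) {
    path <- c(path, "sish_pending")
    return(outcome("sish_pending", "none", TRUE,
                   flag = paste0("sish_pending_",
                                 paste(tolower(pending), collapse = "_"))))
  }
  path <- c(path, "target_sequencing_ngs")
  outcome("target_sequencing_ngs", "none", needs_sish,
          flag = if (length(pending) > 0) "sish_pending_deferred" else "")
}

#' Triage cases for targeted-therapy work-up
#'
#' Applies the screening decision tree to a classified cohort. EBV-positive
#' and MMR-deficient cases are immunotherapy candidates. Remaining cases are
#' screened by the RTK IHC panel: HER2 3+ is a sufficient indicator for
#' HER2-targeted therapy (SISH confirmation optional); EGFR or MET 3+
#' requires SISH and leads to RTK-targeted therapy only when the gene is
#' amplified; any 2+ score requires SISH, with amplification of that gene
#' leading to RTK-targeted therapy. Cases with no overexpression, or whose
#' tested genes are all not amplified, are routed to target sequencing
#' (NGS). When a required SISH result is unavailable the case is reported as
#' `sish_pending` unless the policy defers such cases to NGS. When several
#' 2+ genes are amplified, the first in the fixed gene order EGFR, HER2, MET
#' is reported as the target. Each case records the ordered decision nodes
#' it traversed in `rationale_path` (`>`-joined).
#'
#' @param classified Output of [classify_subgroups()].
#' @param policy A [calling_policy()].
#' @return `classified` with `recommendation`, `target_gene`,
#'   `sish_required` and `rationale_path` columns appended; triage flags are
#'   merged into `flags`.
#' @export
triage <- function(classified, policy = calling_policy()) {
  needed <- c("subgroup_histologic", "egfr_ihc", "her2_ihc", "met_ihc",
              "egfr_amp", "her2_amp", "met_amp")
  missing_cols <- setdiff(needed, names(classified))
  if (length(missing_cols) > 0) {
    abort(sprintf("`classified` lacks column(s): %s. Run derive_status() and classify_subgroups() first.",
                  paste(missing_cols, collapse = ", ")))
  }
  res <- purrr::pmap(
    classified[needed],
    function(subgroup_histologic, egfr_ihc, her2_ihc, met_ihc,
             egfr_amp, her2_amp, met_amp) {
      triage_one(subgroup_histologic, egfr_ihc, her2_ihc, met_ihc,
                 egfr_amp, her2_amp, met_amp, policy)
    }
  ) |> bind_rows()
  out <- bind_cols(classified, res)
  if (!"flags" %in% names(out)) out$flags <- ""
  out$flags <- join_flags(out$flags, out$triage_flag)
  out$triage_flag <- NULL
  out
}

#' Full per-case annotation
#'
#' Convenience composition of [derive_status()], [classify_subgroups()] and
#' [triage()]: from raw cohort readings (plus optional SISH counts) to the
#' complete derived-status table.
#'
#' @inheritParams derive_status
#' @return Fully annotated per-case tibble.
#' @export
annotate_cohort <- function(cohort, sish = NULL, policy = calling_policy()) {
  derive_status(cohort, sish, policy) |>
    classify_subgroups() |>
    triage(policy = policy)
}

#' Subgroup composition table
#'
#' @param classified Output of [classify_subgroups()] or [annotate_cohort()].
#' @param system `"putative"` or `"histologic"`.
#' @return Tibble with one row per subgroup (in canonical order):
#'   `subgroup`, `n`, `pct` (full precision), and `n_flagged` (cases whose
#'   classification used an imputed EBER or MMR value).
#' @export
subgroup_table <- function(classified, system = c("putative", "histologic")) {
  system <- match.arg(system)
  if (nrow(classified) == 0) {
    abort("Cannot tabulate an empty cohort.")
  }
  col <- paste0("subgroup_", system)
  levels <- subgroup_levels(system)
  flagged <- grepl("eber_not_evaluated|mmr_not_evaluated",
                   classified$flags %||% "")
  tibble(subgroup = factor(classified[[col]], levels = levels),
         flagged = flagged) |>
    group_by(.data$subgroup, .drop = FALSE) |>
    summarise(n = n(), n_flagged = sum(.data$flagged), .groups = "drop") |>
    mutate(subgroup = as.character(.data$subgroup),
           pct = 100 * .data$n / sum(.data$n)) |>
    select("subgroup", "n", "pct", "n_flagged")
}
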