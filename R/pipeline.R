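#' Run the full screening pipeline
#'
#' Orchestrates read, marker calling, classification, triage, subgroup
#' tabulation, screening accuracy and (when follow-up is present) survival
#' comparison, from either in-memory tibbles or file paths.
#'
#' @param cohort Cohort tibble or path to a cohort TSV/CSV.
#' @param sish Optional SISH tibble or path.
#' @param policy A [calling_policy()].
#' @param out_dir Optional directory; when given, the annotated per-case
#'   table, subgroup summaries and a run log (policy settings, counts,
#'   package version) are written there as TSV/text.
#' @param verbose Emit stage messages (default `TRUE`).
#' @return List of class `ragc_pipeline`: `annotated` (per-case table),
#'   `subgroups` (putative and histologic composition tables),
#'   `triage_summary`, `accuracy` (screening accuracy of pCIN and I-pCIN
#'   for RTK amplification, when any case is amplified), `association`
#'   (subgroup-vs-amplification tests), and `survival` (log-rank across
#'   subgroups per endpoint, when follow-up exists).
#' @export
run_pipeline <- function(cohort, sish = NULL, policy = calling_policy(),
                         out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(cohort)) {
    say("Reading cohort from %s", cohort)
    cohort <- read_cohort(cohort)
  } else {
    cohort <- suppressWarnings(validate_cohort(cohort))
  }
  if (is.character(sish)) {
    say("Reading SISH counts from %s", sish)
    sish <- read_sish(sish)
  }
  say("Calling markers and triaging %d cases", nrow(cohort))
  annotated <- annotate_cohort(cohort, sish, policy)
  n_flagged <- sum(annotated$flags != "")
  if (n_flagged > 0) {
    say("%d case(s) carry data-quality flags (imputed or missing readings)",
        n_flagged)
  }

  subgroups <- list(
    putative = subgroup_table(annotated, "putative"),
    histologic = subgroup_table(annotated, "histologic")
  )
  triage_summary <- annotated |>
    count(.data$recommendation, name = "n") |>
    mutate(pct = 100 * .data$n / sum(.data$n))

  accuracy <- NULL
  association <- NULL
  if (any(annotated$ra_gc)) {
    acc_for <- function(system, screen_label) {
      col <- paste0("subgroup_", system)
      screening_accuracy(
        tp = sum(annotated[[col]] == screen_label & annotated$ra_gc),
        fp = sum(annotated[[col]] == screen_label & !annotated$ra_gc),
        fn = sum(annotated[[col]] != screen_label & annotated$ra_gc),
        tn = sum(annotated[[col]] != screen_label & !annotated$ra_gc)
      ) |>
        mutate(system = system, screen_subgroup = screen_label, .before = 1)
    }
    accuracy <- bind_rows(acc_for("putative", "pCIN"),
                          acc_for("histologic", "I_pCIN"))
    assoc_for <- function(system) {
      ct <- crosstab(annotated, paste0("subgroup_", system), "ra_gc",
                     row_levels = subgroup_levels(system))
      m <- ct$counts[rowSums(ct$counts) > 0, , drop = FALSE]
      if (nrow(m) < 2 || any(colSums(m) == 0)) {
        return(tibble(system = system, method = NA_character_,
                      statistic = NA_real_, df = NA_integer_,
                      p_value = NA_real_))
      }
      test_association(m) |> mutate(system = system, .before = 1)
    }
    association <- bind_rows(assoc_for("putative"), assoc_for("histologic"))
  }

  surv <- NULL
  has_fu <- "rfs_months" %in% names(cohort) && any(!is.na(cohort$rfs_months))
  if (has_fu) {
    say("Comparing survival across subgroups")
    fu <- cohort[c("case_id", "rfs_months", "rfs_event",
                   "os_months", "os_event")]
    with_fu <- left_join(annotated, fu, by = "case_id")
    cmp <- function(time_col, event_col, group_col) {
      ok <- !is.na(with_fu[[time_col]]) & !is.na(with_fu[[event_col]])
      if (length(unique(with_fu[[group_col]][ok])) < 2) return(NULL)
      compare_survival(with_fu, time_col, event_col, group_col)
    }
    surv <- list(
      rfs = list(
        putative = cmp("rfs_months", "rfs_event", "subgroup_putative"),
        histologic = cmp("rfs_months", "rfs_event", "subgroup_histologic")
      ),
      os = list(
        putative = cmp("os_months", "os_event", "subgroup_putative"),
        histologic = cmp("os_months", "os_event", "subgroup_histologic")
      )
    )
  }

  result <- structure(
    list(annotated = annotated, subgroups = subgroups,
         triage_summary = triage_summary, accuracy = accuracy,
         association = association, survival = surv, policy = policy),
    class = "ragc_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_derived(annotated, file.path(out_dir, "annotated_cases.tsv"))
    readr::write_tsv(subgroups$putative,
                     file.path(out_dir, "subgroups_putative.tsv"))
    readr::write_tsv(subgroups$histologic,
                     file.path(out_dir, "subgroups_histologic.tsv"))
    readr::write_tsv(triage_summary, file.path(out_dir, "triage_summary.tsv"))
    if (!is.null(accuracy)) {
      readr::write_tsv(accuracy, file.path(out_dir, "screening_accuracy.tsv"))
    }
    log_lines <- c(
      sprintf("ragcscreen %s", as.character(utils::packageVersion("ragcscreen"))),
      sprintf("cases: %d, flagged: %d", nrow(annotated), n_flagged),
      sprintf("ratio_threshold: %s", policy$ratio_threshold),
      sprintf("min_cells: %s (%s)", policy$min_cells,
              if (policy$min_cells_per_core) "per core" else "pooled"),
      sprintf("pool_cores: %s", policy$pool_cores),
      sprintf("mmr_single_loss: %s", policy$mmr_single_loss),
      sprintf("defer_pending_to_ngs: %s", policy$defer_pending_to_ngs)
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    say("Outputs written to %s", out_dir)
  }
  result
}

#' @export
print.ragc_pipeline <- function(x, ...) {
  cat(sprintf("<ragc_pipeline> %d cases, %d RA-GC (%.1f%%)\n",
              nrow(x$annotated), sum(x$annotated$ra_gc),
              100 * mean(x$annotated$ra_gc)))
  cat("\nHistologic-molecular subgroups:\n")
  print(x$subgroups$histologic)
  if (!is.null(x$accuracy)) {
    cat("\nScreening accuracy for RTK amplification:\n")
    print(x$accuracy)
  }
  cat("\nTriage:\n")
  print(x$triage_summary)
  invisible(x)
}

#' Subgroup composition bar chart
#'
#' @param classified Output of [classify_subgroups()] or [annotate_cohort()].
#' @param system `"putative"` or `"histologic"`.
#' @return A ggplot object.
#' @export
plot_subgroups <- function(classified, system = c("histologic", "putative")) {
  system <- match.arg(system)
  tab <- subgroup_table(classified, system)
  tab$subgroup <- factor(tab$subgroup, levels = subgroup_levels(system))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$subgroup, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Share of cohort (%)",
                  title = paste0(system, "-molecular classification")) +
    ggplot2::theme_minimal()
}

paper_reference_values <- function() {
  tibble::tribble(
    ~quantity,                  ~printed, ~source,
    "ipcin_sensitivity_pct",    87.5,     "classification cross-tab",
    "ipcin_specificity_pct",    34.3,     "classification cross-tab",
    "pcin_sensitivity_pct",     74.0,     "classification cross-tab",
    "pcin_specificity_pct",     45.1,     "classification cross-tab",
    "ipcin_share_pct",          68.0,     "classification cross-tab",
    "pcin_share_pct",           56.9,     "classification cross-tab",
    "ragc_prevalence_pct",      10.5,     "classification cross-tab",
    "egfr_ihc_positive_pct",    15.8,     "marker profile",
    "her2_amp_concordance_pct", 80.3,     "marker profile",
    "p53_mutant_pct",           62.6,     "marker profile",
    "eber_positive_pct",        6.3,      "marker profile",
    "mmr_deficient_n",          114,      "marker profile"
  )
}

compute_headline_quantities <- function(seed = 1, policy = calling_policy()) {
  cls <- expand_count_spec(spec_classification(), seed = seed)
  cls_ann <- annotate_cohort(cls$cohort, cls$sish, policy)
  sub_hist <- subgroup_table(cls_ann, "histologic")
  sub_put <- subgroup_table(cls_ann, "putative")
  acc <- function(col, label) {
    tp <- sum(cls_ann[[col]] == label & cls_ann$ra_gc)
    fn <- sum(cls_ann[[col]] != label & cls_ann$ra_gc)
    if (tp + fn == 0) {
      # degenerate run (e.g. a policy that calls nothing amplified): report
      # undefined accuracy rather than aborting the whole comparison
      return(tibble(sensitivity = NA_real_, specificity = NA_real_))
    }
    screening_accuracy(
      tp = tp, fn = fn,
      fp = sum(cls_ann[[col]] == label & !cls_ann$ra_gc),
      tn = sum(cls_ann[[col]] != label & !cls_ann$ra_gc)
    )
  }
  acc_i <- acc("subgroup_histologic", "I_pCIN")
  acc_p <- acc("subgroup_putative", "pCIN")

  prof <- fixture_marker_profile(seed = seed)
  prof_ann <- annotate_cohort(prof$cohort, prof$sish, policy)
  eber_eval <- !grepl("eber_not_evaluated", prof_ann$flags)
  mmr_eval <- !grepl("mmr_not_evaluated", prof_ann$flags)

  tibble::tribble(
    ~quantity, ~computed, ~n,
    "ipcin_sensitivity_pct", acc_i$sensitivity, nrow(cls_ann),
    "ipcin_specificity_pct", acc_i$specificity, nrow(cls_ann),
    "pcin_sensitivity_pct", acc_p$sensitivity, nrow(cls_ann),
    "pcin_specificity_pct", acc_p$specificity, nrow(cls_ann),
    "ipcin_share_pct",
    sub_hist$pct[sub_hist$subgroup == "I_pCIN"], nrow(cls_ann),
    "pcin_share_pct",
    sub_put$pct[sub_put$subgroup == "pCIN"], nrow(cls_ann),
    "ragc_prevalence_pct", 100 * mean(cls_ann$ra_gc), nrow(cls_ann),
    "egfr_ihc_positive_pct",
    100 * mean(prof_ann$egfr_pos), nrow(prof_ann),
    "her2_amp_concordance_pct",
    100 * mean(prof_ann$her2_amp[prof_ann$her2_pos] == "amplified"),
    sum(prof_ann$her2_pos),
    "p53_mutant_pct",
    100 * mean(prof_ann$p53 == "mutant_pattern"), nrow(prof_ann),
    "eber_positive_pct",
    100 * mean(prof_ann$eber_effective[eber_eval] == "positive"),
    sum(eber_eval),
    "mmr_deficient_n",
    as.numeric(sum(prof_ann$mmr == "deficient" & mmr_eval)), nrow(prof_ann)
  )
}

#' Recompute the published headline numbers from shipped fixtures
#'
#' Expands the shipped count specifications into per-case cohorts, runs the
#' full pipeline on them, and compares each recomputed quantity with the
#' corresponding published value at printed precision (percentages to one
#' decimal, counts exactly). The run is deterministic given `seed` and
#' idempotent.
#'
#' @param seed Seed for the fixtures' free fields (does not affect any
#'   compared quantity).
#' @param policy A [calling_policy()].
#' @return Tibble of class `ragc_reproduction`: `quantity`, `source`,
#'   `computed`, `printed`, `tolerance`, `pass`.
#' @export
reproduce_paper <- function(seed = 1, policy = calling_policy()) {
  computed <- compute_headline_quantities(seed = seed, policy = policy)
  out <- left_join(computed, paper_reference_values(), by = "quantity") |>
    mutate(
      tolerance = if_else(.data$quantity == "mmr_deficient_n", 0, 0.05),
      pass = !is.na(.data$computed) &
        abs(round_half_up(.data$computed, 1) - .data$printed) <=
        .data$tolerance + 1e-9
    ) |>
    select("quantity", "source", "computed", "printed", "n", "tolerance",
           "pass")
  class(out) <- c("ragc_reproduction", class(out))
  out
}

#' @export
print.ragc_reproduction <- function(x, ...) {
  cat(sprintf("<ragc_reproduction> %d/%d quantities reproduced\n\n",
              sum(x$pass), nrow(x)))
  df <- as.data.frame(x)
  df$computed <- round_half_up(df$computed, 2)
  print(df, row.names = FALSE)
  if (!all(x$pass)) {
    cat("\nMismatched quantities:",
        paste(x$quantity[!x$pass], collapse = ", "), "\n")
  }
  invisible(x)
}
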