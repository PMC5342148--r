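#' Score RTK immunohistochemistry on surgical-specimen criteria
#'
#' Maps a raw staining description to the 0/1+/2+/3+ band used for EGFR,
#' HER2 and MET: at least 10% of tumor cells must stain for any score above
#' 0; faint or partial-membranous staining is 1+; weak-to-moderate complete
#' or basolateral membranous staining is 2+; strong complete or basolateral
#' staining is 3+.
#'
#' @param intensity One of `"none"`, `"faint"`, `"weak_moderate"`,
#'   `"strong"` (vectorized).
#' @param percent_stained Percent of tumor cells stained, in `[0, 100]`.
#' @param pattern One of `"membranous_complete_or_basolateral"`,
#'   `"partial_membranous"`, `"none"`.
#' @return Integer score in `0:3`.
#' @examples
#' hofmann_score("strong", 60, "membranous_complete_or_basolateral")
#' hofmann_score("faint", 30, "partial_membranous")
#' @export
hofmann_score <- function(intensity, percent_stained, pattern) {
  check_enum(intensity, c("none", "faint", "weak_moderate", "strong"),
             "intensity")
  check_enum(pattern, c("membranous_complete_or_basolateral",
                        "partial_membranous", "none"), "pattern")
  if (any(!is.na(percent_stained) &
          (percent_stained < 0 | percent_stained > 100))) {
    abort("`percent_stained` must lie in [0, 100].",
          class = "ragc_validation_error")
  }
  out <- rep(NA_integer_, length(intensity))
  zero <- intensity == "none" | pattern == "none" | percent_stained < 10
  one <- !zero & (intensity == "faint" | pattern == "partial_membranous")
  two <- !zero & !one & intensity == "weak_moderate"
  three <- !zero & !one & intensity == "strong"
  out[zero] <- 0L
  out[one] <- 1L
  out[two] <- 2L
  out[three] <- 3L
  out
}

#' RTK IHC positivity
#'
#' A case is IHC-positive for a receptor when it scores 2+ or 3+. A missing
#' score propagates as `NA` (flagged downstream rather than silently
#' coerced).
#'
#' @param score Integer IHC score in `0:3`, `NA` allowed.
#' @return Logical vector.
#' @export
rtk_ihc_positive <- function(score) {
  bad <- !is.na(score) & !(score %in% 0:3)
  if (any(bad)) {
    abort("IHC scores must lie in 0:3.", class = "ragc_validation_error")
  }
  score >= 2L
}

#' Mismatch-repair status from the four-protein IHC panel
#'
#' MMR deficiency is complete loss of an MLH1/PMS2 or MSH2/MSH6 pair. Loss
#' of a single protein of a pair was never observed in the source cohort;
#' under the default policy it is called deficient with a `discordant_pair`
#' flag, while `single_loss = "strict_pair"` keeps the literal pair rule
#' (proficient unless both are lost, still flagged). A case with all four
#' stains missing is called proficient with an `mmr_not_evaluated` flag so
#' that every case can be classified.
#'
#' @param mlh1,msh2,msh6,pms2 Character vectors with values `"intact"`,
#'   `"lost"` or `NA`.
#' @param single_loss `"deficient"` (default) or `"strict_pair"`.
#' @return A tibble with columns `mmr` (`"deficient"`/`"proficient"`) and
#'   `mmr_flag`.
#' @examples
#' mmr_status("lost", "intact", "intact", "lost")
#' @export
mmr_status <- function(mlh1, msh2, msh6, pms2,
                       single_loss = c("deficient", "strict_pair")) {
  single_loss <- match.arg(single_loss)
  for (v in list(mlh1, msh2, msh6, pms2)) {
    check_enum(v, c("intact", "lost"), "mmr protein status")
  }
  lost <- function(x) !is.na(x) & x == "lost"
  pair1 <- lost(mlh1) & lost(pms2)
  pair2 <- lost(msh2) & lost(msh6)
  discordant <- xor(lost(mlh1), lost(pms2)) | xor(lost(msh2), lost(msh6))
  all_missing <- is.na(mlh1) & is.na(msh2) & is.na(msh6) & is.na(pms2)

  deficient <- pair1 | pair2
  if (single_loss == "deficient") {
    deficient <- deficient | discordant
  }
  flag <- character(length(deficient))
  flag[discordant] <- "discordant_pair"
  flag[all_missing] <- "mmr_not_evaluated"
  tibble(
    mmr = if_else(deficient & !all_missing, "deficient", "proficient"),
    mmr_flag = flag
  )
}

#' p53 staining pattern call
#'
#' The IHC surrogate for TP53 mutation: complete loss of nuclear expression,
#' or strong nuclear expression in more than 50% of tumor cells (strictly
#' greater), is mutant-pattern; everything else is wild-pattern.
#'
#' @param pattern_class `"complete_loss"`, `"strong_nuclear"` or `"other"`
#'   (vectorized, `NA` allowed and returned as `NA`).
#' @param percent_positive Percent of tumor cells with strong nuclear
#'   staining; required when `pattern_class == "strong_nuclear"`.
#' @return Character vector `"mutant_pattern"` / `"wild_pattern"`.
#' @examples
#' p53_pattern("strong_nuclear", 50)  # boundary: wild-pattern
#' @export
p53_pattern <- function(pattern_class, percent_positive = NA_real_) {
  check_enum(pattern_class, c("complete_loss", "strong_nuclear", "other"),
             "pattern_class")
  percent_positive <- rep_len(percent_positive, length(pattern_class))
  if (any(!is.na(percent_positive) &
          (percent_positive < 0 | percent_positive > 100))) {
    abort("`percent_positive` must lie in [0, 100].",
          class = "ragc_validation_error")
  }
  needs_pct <- !is.na(pattern_class) & pattern_class == "strong_nuclear" &
    is.na(percent_positive)
  if (any(needs_pct)) {
    abort("`percent_positive` is required when pattern_class = strong_nuclear.",
          class = "ragc_validation_error")
  }
  dplyr::case_when(
    is.na(pattern_class) ~ NA_character_,
    pattern_class == "complete_loss" ~ "mutant_pattern",
    pattern_class == "strong_nuclear" & percent_positive > 50 ~ "mutant_pattern",
    TRUE ~ "wild_pattern"
  )
}

#' EBER in situ hybridization call
#'
#' Only diffuse strong nuclear positivity in all tumor cells counts as
#' EBER-positive. A missing stain is imputed negative with an
#' `eber_not_evaluated` flag, which is how every case can carry a subgroup
#' label even when EBER was evaluated on fewer cases than the full cohort.
#'
#' @param reading Character vector. Accepts the raw reading vocabulary
#'   (`"diffuse_strong_nuclear_all_tumor_cells"`, `"other"`) or an already
#'   binarized one (`"positive"`, `"negative"`); `NA` is a missing stain.
#' @return A tibble with columns `eber_effective` and `eber_flag`.
#' @export
eber_call <- function(reading) {
  check_enum(reading,
             c("diffuse_strong_nuclear_all_tumor_cells", "other",
               "positive", "negative"),
             "eber reading")
  positive <- !is.na(reading) &
    reading %in% c("diffuse_strong_nuclear_all_tumor_cells", "positive")
  tibble(
    eber_effective = if_else(positive, "positive", "negative"),
    eber_flag = if_else(is.na(reading), "eber_not_evaluated", "")
  )
}

#' Effective gene signal count per nucleus
#'
#' Discrete SISH signals plus cluster equivalents: a small cluster counts as
#' 6 signals and a large cluster as 12.
#'
#' @param gene_signals,small_clusters,large_clusters Non-negative integer
#'   vectors.
#' @return Numeric vector of effective signals.
#' @examples
#' effective_gene_signals(2, 1, 1)  # 2 + 6 + 12 = 20
#' @export
effective_gene_signals <- function(gene_signals, small_clusters = 0L,
                                   large_clusters = 0L) {
  if (any(c(gene_signals, small_clusters, large_clusters) < 0, na.rm = TRUE)) {
    abort("Signal and cluster counts must be non-negative.",
          class = "ragc_validation_error")
  }
  gene_signals + 6 * small_clusters + 12 * large_clusters
}

empty_amp_result <- function(gene, call) {
  tibble(
    gene = gene %||% NA_character_,
    n_cells_evaluated = 0L,
    gene_signal_total = 0L,
    chr_signal_total = 0L,
    ratio = NA_real_,
    mean_copies_per_nucleus = NA_real_,
    call = call
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' SISH amplification call for one case and gene
#'
#' Pools evaluable nuclei (chromosome signals >= 1) across cores, computes
#' the gene-to-chromosome ratio as the ratio of pooled totals, and calls
#' amplification when the ratio strictly exceeds the policy threshold
#' (default 2.0). Fewer evaluable nuclei than `policy$min_cells` gives
#' `"insufficient"`; no nuclei at all gives `"not_tested"`. With
#' `pool_cores = FALSE` each core is called separately (requiring
#' `min_cells` per core) and the case is amplified when any core is; the
#' reported ratio is always the pooled one.
#'
#' @param cells Tibble of per-nucleus records with columns `gene_signals`,
#'   `small_clusters`, `large_clusters`, `chr_signals`, `core_id`. May be
#'   empty or `NULL`.
#' @param gene Gene label carried into the result (optional).
#' @param policy A [calling_policy()].
#' @return One-row tibble: `gene`, `n_cells_evaluated`, `gene_signal_total`,
#'   `chr_signal_total`, `ratio`, `mean_copies_per_nucleus`, `call`.
#' @examples
#' cells <- tibble::tibble(gene_signals = rep(5L, 60), small_clusters = 0L,
#'                         large_clusters = 0L, chr_signals = 2L,
#'                         core_id = rep(1:2, each = 30))
#' amplification_call(cells, gene = "EGFR")  # ratio 2.5, amplified
#' @export
amplification_call <- function(cells, gene = NULL,
                               policy = calling_policy()) {
  if (is.null(cells) || nrow(cells) == 0) {
    return(empty_amp_result(gene, "not_tested"))
  }
  eff <- effective_gene_signals(cells$gene_signals, cells$small_clusters,
                                cells$large_clusters)
  evaluable <- cells$chr_signals >= 1
  n <- sum(evaluable)
  if (n == 0) {
    return(empty_amp_result(gene, "insufficient"))
  }
  gene_total <- sum(eff[evaluable])
  chr_total <- sum(cells$chr_signals[evaluable])
  ratio <- gene_total / chr_total
  mean_copies <- gene_total / n

  core_n <- tapply(evaluable, cells$core_id, sum)
  enough <- if (policy$min_cells_per_core) {
    all(core_n >= policy$min_cells)
  } else {
    n >= policy$min_cells
  }

  if (policy$pool_cores) {
    call <- if (!enough) {
      "insufficient"
    } else if (ratio > policy$ratio_threshold) {
      "amplified"
    } else {
      "not_amplified"
    }
  } else {
    core_ratio <- tapply(eff * evaluable, cells$core_id, sum) /
      tapply(cells$chr_signals * evaluable, cells$core_id, sum)
    core_ok <- core_n >= policy$min_cells
    if (!any(core_ok)) {
      call <- "insufficient"
    } else if (any(core_ratio[core_ok] > policy$ratio_threshold)) {
      call <- "amplified"
    } else {
      call <- "not_amplified"
    }
  }
  tibble(
    gene = gene %||% NA_character_,
    n_cells_evaluated = as.integer(n),
    gene_signal_total = as.integer(gene_total),
    chr_signal_total = as.integer(chr_total),
    ratio = ratio,
    mean_copies_per_nucleus = mean_copies,
    call = call
  )
}

#' Amplification calls for every case/gene in a SISH table
#'
#' @param sish Validated per-nucleus SISH tibble (see [read_sish()]).
#' @param policy A [calling_policy()].
#' @return Tibble with one row per `case_id` x `gene` present in `sish`.
#' @export
amplification_table <- function(sish, policy = calling_policy()) {
  if (is.null(sish) || nrow(sish) == 0) {
    return(tibble(case_id = character(), gene = character(),
                  n_cells_evaluated = integer(), gene_signal_total = integer(),
                  chr_signal_total = integer(), ratio = double(),
                  mean_copies_per_nucleus = double(), call = character()))
  }
  sish <- validate_sish(sish)
  if (policy$pool_cores && !policy$min_cells_per_core) {
    # fast path used on large simulated cohorts
    sish |>
      mutate(
        eff = effective_gene_signals(.data$gene_signals, .data$small_clusters,
                                     .data$large_clusters),
        evaluable = .data$chr_signals >= 1
      ) |>
      group_by(.data$case_id, .data$gene) |>
      summarise(
        n_cells_evaluated = sum(.data$evaluable),
        gene_signal_total = as.integer(sum(.data$eff[.data$evaluable])),
        chr_signal_total = as.integer(sum(.data$chr_signals[.data$evaluable])),
        .groups = "drop"
      ) |>
      mutate(
        ratio = if_else(.data$n_cells_evaluated > 0,
                        .data$gene_signal_total / .data$chr_signal_total,
                        NA_real_),
        mean_copies_per_nucleus =
          if_else(.data$n_cells_evaluated > 0,
                  .data$gene_signal_total / .data$n_cells_evaluated,
                  NA_real_),
        call = case_when(
          .data$n_cells_evaluated < policy$min_cells ~ "insufficient",
          .data$ratio > policy$ratio_threshold ~ "amplified",
          TRUE ~ "not_amplified"
        )
      )
  } else {
    sish |>
      tidyr::nest(cells = -c("case_id", "gene")) |>
      mutate(res = purrr::map2(.data$cells, .data$gene,
                               amplification_call, policy = policy)) |>
      select("case_id", "res") |>
      tidyr::unnest("res")
  }
}

#' Derive per-case marker status
#'
#' Runs every marker call on a validated cohort: RTK IHC positivity (2+/3+),
#' MMR status, p53 pattern, effective EBER status, and per-gene SISH
#' amplification. SISH is interpreted only for genes scored 2+ or 3+ on IHC
#' (the assay is performed only on those cases); genes scored 0/1+ are
#' `not_tested` even if signal rows are present (flagged `sish_ignored`). A
#' case is an RTK-amplified gastric cancer (`ra_gc`) when any gene is called
#' amplified. All imputations and data-quality issues are accumulated in a
#' semicolon-joined `flags` column.
#'
#' @param cohort Cohort tibble (see [read_cohort()]; revalidated here).
#' @param sish Optional per-nucleus SISH tibble.
#' @param policy A [calling_policy()].
#' @return Tibble with one row per case: IHC scores and positivity, `mmr`,
#'   `p53`, `eber_effective`, per-gene `*_amp` calls and `*_ratio`s,
#'   `ra_gc`, carried `lauren`, and `flags`.
#' @export
derive_status <- function(cohort, sish = NULL, policy = calling_policy()) {
  cohort <- suppressWarnings(validate_cohort(cohort))
  amp <- amplification_table(sish, policy)

  eber <- eber_call(cohort$eber)
  mmr <- mmr_status(cohort$mlh1, cohort$msh2, cohort$msh6, cohort$pms2,
                    single_loss = policy$mmr_single_loss)
  p53_flag <- if_else(is.na(cohort$p53_class), "p53_not_evaluated", "")
  p53 <- p53_pattern(cohort$p53_class, cohort$p53_pct)
  p53[is.na(p53)] <- "wild_pattern"

  out <- tibble(
    case_id = cohort$case_id,
    lauren = cohort$lauren,
    egfr_ihc = cohort$egfr_ihc,
    her2_ihc = cohort$her2_ihc,
    met_ihc = cohort$met_ihc,
    egfr_pos = rtk_ihc_positive(cohort$egfr_ihc),
    her2_pos = rtk_ihc_positive(cohort$her2_ihc),
    met_pos = rtk_ihc_positive(cohort$met_ihc),
    mmr = mmr$mmr,
    p53 = p53,
    eber_effective = eber$eber_effective
  )
  out$rtk_ihc_positive <- (!is.na(out$egfr_pos) & out$egfr_pos) |
    (!is.na(out$her2_pos) & out$her2_pos) |
    (!is.na(out$met_pos) & out$met_pos)

  gene_flags <- rep("", nrow(out))
  for (g in rtk_genes()) {
    score_col <- paste0(tolower(g), "_ihc")
    amp_col <- paste0(tolower(g), "_amp")
    ratio_col <- paste0(tolower(g), "_ratio")
    gene_amp <- amp |> filter(.data$gene == g)
    idx <- match(out$case_id, gene_amp$case_id)
    has_sish <- !is.na(idx)
    tested <- !is.na(out[[score_col]]) & out[[score_col]] >= 2L

    call <- rep("not_tested", nrow(out))
    ratio <- rep(NA_real_, nrow(out))
    call[tested & has_sish] <- gene_amp$call[idx[tested & has_sish]]
    ratio[tested & has_sish] <- gene_amp$ratio[idx[tested & has_sish]]
    out[[amp_col]] <- call
    out[[ratio_col]] <- ratio

    gene_flags <- join_flags(
      gene_flags,
      if_else(is.na(out[[score_col]]),
              paste0(tolower(g), "_ihc_missing"), ""),
      if_else(tested & !has_sish, paste0("sish_missing_", tolower(g)), ""),
      if_else(!tested & has_sish, paste0("sish_ignored_", tolower(g)), "")
    )
  }

  out$ra_gc <- out$egfr_amp == "amplified" | out$her2_amp == "amplified" |
    out$met_amp == "amplified"

  followup_flag <- if_else(
    !is.na(cohort$rfs_months) & !is.na(cohort$os_months) &
      cohort$rfs_months > cohort$os_months,
    "followup_inconsistent", ""
  )
  out$flags <- join_flags(eber$eber_flag, mmr$mmr_flag, p53_flag,
                          gene_flags, followup_flag)
  out
}
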