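#' SISH signal-model parameters
#'
#' Parameters of the per-nucleus signal simulator. Chromosome signals per
#' nucleus are `1 + Poisson(chr_mean - 1)` (every evaluable nucleus carries
#' at least one centromere signal); gene signals are Poisson with mean
#' `true ratio x chromosome signals`, so the pooled gene-to-chromosome
#' ratio concentrates around the true ratio as cells accumulate. In
#' amplified nuclei part of the signal mass may condense into clusters
#' (small = 6 signals, large = 12), which changes the bookkeeping but not
#' the effective totals.
#'
#' @param n_cells Nuclei counted per case (split over two cores). Default
#'   70 (at least 60 are required for a call).
#' @param chr_mean Mean chromosome signals per nucleus. Default 2.
#' @param ratio_not_amplified True gene-to-chromosome ratio of
#'   non-amplified cases. Default 1.0.
#' @param ratio_amplified True ratio of amplified cases. Default 3.0.
#' @param p_small_cluster,p_large_cluster Per-nucleus probabilities that an
#'   amplified nucleus shows a small / large signal cluster. Defaults 0.15
#'   and 0.05.
#' @return List of class `ragc_sish_params`.
#' @export
sish_params <- function(n_cells = 70L, chr_mean = 2,
                        ratio_not_amplified = 1.0, ratio_amplified = 3.0,
                        p_small_cluster = 0.15, p_large_cluster = 0.05) {
  stopifnot(n_cells >= 1, chr_mean >= 1,
            ratio_not_amplified > 0, ratio_amplified > 0,
            p_small_cluster >= 0, p_small_cluster <= 1,
            p_large_cluster >= 0, p_large_cluster <= 1)
  structure(
    list(n_cells = as.integer(n_cells), chr_mean = chr_mean,
         ratio_not_amplified = ratio_not_amplified,
         ratio_amplified = ratio_amplified,
         p_small_cluster = p_small_cluster,
         p_large_cluster = p_large_cluster),
    class = "ragc_sish_params"
  )
}

#' Simulate per-nucleus SISH signal counts for one case and gene
#'
#' @param true_status `"amplified"` or `"not_amplified"`.
#' @param params A [sish_params()].
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so a caller can seed once for a whole cohort).
#' @param true_ratio Optional override of the status' true ratio.
#' @return Tibble of per-nucleus records (`core_id`, `gene_signals`,
#'   `small_clusters`, `large_clusters`, `chr_signals`).
#' @export
simulate_sish_cells <- function(true_status = c("not_amplified", "amplified"),
                                params = sish_params(), seed = NULL,
                                true_ratio = NULL) {
  true_status <- match.arg(true_status)
  gen <- function() {
    n <- params$n_cells
    ratio <- true_ratio %||% if (true_status == "amplified") {
      params$ratio_amplified
    } else {
      params$ratio_not_amplified
    }
    chr <- 1L + rpois(n, params$chr_mean - 1)
    total <- rpois(n, ratio * chr)
    large <- integer(n)
    small <- integer(n)
    if (true_status == "amplified") {
      large <- as.integer(runif(n) < params$p_large_cluster & total >= 12L)
      rem <- total - 12L * large
      small <- as.integer(runif(n) < params$p_small_cluster & rem >= 6L)
    }
    discrete <- total - 12L * large - 6L * small
    tibble(
      core_id = rep(c(1L, 2L), length.out = n),
      gene_signals = as.integer(discrete),
      small_clusters = small,
      large_clusters = large,
      chr_signals = chr
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Cohort-simulation parameters
#'
#' Defaults are calibrated to the source cohort's printed marginals:
#' histologic-molecular subgroup prevalences 6.1% EBV-positive, 11.5%
#' MMR-deficient, 14.4% D-pGS, 68.0% I-pCIN; IHC positivity 15.8%/6.1%/8.5%
#' for EGFR/HER2/MET with amplification-given-positive 31.2%/80.3%/30.6%;
#' p53 mutant-pattern among I-pCIN cases 565/675; MLH1/PMS2 (vs MSH2/MSH6)
#' co-loss among MMR-deficient cases 101/114. Ages are normal (mean 56.1,
#' SD 12.5) truncated to (18, 100). Follow-up uses per-subgroup exponential
#' recurrence and death hazards (EBV-positive and MMR-deficient cases have
#' the lower hazards, matching their favorable recurrence-free survival)
#' with uniform censoring over `censor_range` months.
#'
#' @param n_cases Number of cases.
#' @param subgroup_prevalences Named simplex over the four
#'   histologic-molecular subgroups.
#' @param ihc_positive Named per-gene IHC 2+/3+ probabilities.
#' @param p_score3_given_positive Named per-gene probability that a
#'   positive case is 3+ rather than 2+.
#' @param amp_given_positive Named per-gene amplification probabilities
#'   given IHC positivity.
#' @param p53_mutant_in_ipcin Probability that an I-pCIN case is p53
#'   mutant-pattern (the rest are p53-wild intestinal/mixed).
#' @param p_mlh1_pair MLH1/PMS2 share of MMR-deficient cases.
#' @param sish A [sish_params()].
#' @param hazard_rfs,hazard_os Named per-subgroup monthly exponential
#'   hazards for recurrence and death.
#' @param censor_range Uniform censoring window in months.
#' @param seed Integer seed; the only source of randomness.
#' @return List of class `ragc_sim_params`.
#' @export
simulation_params <- function(
    n_cases = 993L,
    subgroup_prevalences = c(EBV_positive = 0.061, MMR_deficient = 0.115,
                             D_pGS = 0.144, I_pCIN = 0.680),
    ihc_positive = c(EGFR = 0.158, HER2 = 0.061, MET = 0.085),
    p_score3_given_positive = c(EGFR = 38 / 157, HER2 = 32 / 61,
                                MET = 18 / 85),
    amp_given_positive = c(EGFR = 0.312, HER2 = 0.803, MET = 0.306),
    p53_mutant_in_ipcin = 565 / 675,
    p_mlh1_pair = 101 / 114,
    sish = sish_params(),
    hazard_rfs = c(EBV_positive = 0.010, MMR_deficient = 0.010,
                   D_pGS = 0.025, I_pCIN = 0.018),
    hazard_os = c(EBV_positive = 0.008, MMR_deficient = 0.008,
                  D_pGS = 0.020, I_pCIN = 0.015),
    censor_range = c(12, 120),
    seed = 1L) {
  if (abs(sum(subgroup_prevalences) - 1) > 1e-8 ||
      any(subgroup_prevalences < 0) ||
      !setequal(names(subgroup_prevalences), subgroup_levels("histologic"))) {
    abort("`subgroup_prevalences` must be a named simplex over the four histologic-molecular subgroups.",
          class = "ragc_validation_error")
  }
  probs <- c(ihc_positive, p_score3_given_positive, amp_given_positive,
             p53_mutant_in_ipcin, p_mlh1_pair)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1].",
          class = "ragc_validation_error")
  }
  if (any(c(hazard_rfs, hazard_os) <= 0)) {
    abort("Hazards must be positive.", class = "ragc_validation_error")
  }
  structure(
    list(n_cases = as.integer(n_cases),
         subgroup_prevalences = subgroup_prevalences,
         ihc_positive = ihc_positive,
         p_score3_given_positive = p_score3_given_positive,
         amp_given_positive = amp_given_positive,
         p53_mutant_in_ipcin = p53_mutant_in_ipcin,
         p_mlh1_pair = p_mlh1_pair,
         sish = sish,
         hazard_rfs = hazard_rfs, hazard_os = hazard_os,
         censor_range = censor_range,
         seed = as.integer(seed)),
    class = "ragc_sim_params"
  )
}

empty_sish <- function() {
  tibble(case_id = character(), gene = character(), core_id = integer(),
         gene_signals = integer(), small_clusters = integer(),
         large_clusters = integer(), chr_signals = integer())
}

#' Simulate a stochastic cohort
#'
#' Draws a cohort from [simulation_params()]: each case is assigned a
#' histologic-molecular subgroup, the marker readings that induce it (EBER,
#' MMR-protein panel, p53 pattern, Lauren type), per-gene IHC scores, and
#' - for IHC-positive genes - a latent amplification status realized as
#' simulated per-nucleus SISH counts. Follow-up comes from per-subgroup
#' exponential recurrence/death hazards with uniform censoring (so
#' recurrence-free survival never exceeds overall survival). All randomness
#' flows from `params$seed`; the same seed reproduces the cohort exactly.
#'
#' @param params A [simulation_params()].
#' @return List with `cohort`, `sish`, and `truth` (per-case generating
#'   subgroup and per-gene latent amplification status).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  if (!inherits(params, "ragc_sim_params")) {
    abort("`params` must come from simulation_params().")
  }
  n <- params$n_cases
  if (n == 0) {
    empty <- as_tibble(setNames(
      rep(list(character(0)), length(cohort_columns())), cohort_columns()
    ))
    return(list(cohort = validate_cohort(empty), sish = empty_sish(),
                truth = tibble(case_id = character())))
  }
  withr::with_seed(params$seed, {
    sg_levels <- subgroup_levels("histologic")
    subgroup <- sample(sg_levels, n, replace = TRUE,
                       prob = params$subgroup_prevalences[sg_levels])
    ch <- tibble(case_id = sprintf("sim_%05d", seq_len(n)))

    ch$eber <- if_else(subgroup == "EBV_positive", "positive", "negative")
    pair <- runif(n) < params$p_mlh1_pair
    deficient <- subgroup == "MMR_deficient"
    ch$mlh1 <- if_else(deficient & pair, "lost", "intact")
    ch$pms2 <- ch$mlh1
    ch$msh2 <- if_else(deficient & !pair, "lost", "intact")
    ch$msh6 <- ch$msh2

    p53_mutant <- dplyr::case_when(
      subgroup == "D_pGS" ~ FALSE,
      subgroup == "I_pCIN" ~ runif(n) < params$p53_mutant_in_ipcin,
      TRUE ~ runif(n) < 0.6
    )
    ch$p53_class <- if_else(p53_mutant, "complete_loss", "other")
    ch$p53_pct <- NA_real_

    ch$lauren <- dplyr::case_when(
      subgroup == "D_pGS" ~ "diffuse",
      subgroup == "I_pCIN" & !p53_mutant ~
        sample(c("intestinal", "mixed"), n, replace = TRUE,
               prob = c(0.85, 0.15)),
      subgroup == "I_pCIN" & p53_mutant ~
        sample(lauren_levels(), n, replace = TRUE, prob = c(0.55, 0.1, 0.35)),
      TRUE ~ sample(lauren_levels(), n, replace = TRUE, prob = c(0.4, 0.1, 0.5))
    )

    truth <- tibble(case_id = ch$case_id, subgroup = subgroup)
    for (g in rtk_genes()) {
      pos <- runif(n) < params$ihc_positive[[g]]
      score3 <- runif(n) < params$p_score3_given_positive[[g]]
      low1 <- runif(n) < 0.35
      ch[[paste0(tolower(g), "_ihc")]] <- dplyr::case_when(
        pos & score3 ~ 3L, pos ~ 2L, low1 ~ 1L, TRUE ~ 0L
      )
      truth[[paste0(tolower(g), "_positive")]] <- pos
      truth[[paste0(tolower(g), "_amplified")]] <-
        pos & runif(n) < params$amp_given_positive[[g]]
    }
    truth$ra_gc <- truth$egfr_amplified | truth$her2_amplified |
      truth$met_amplified

    ch$age <- round(pmin(pmax(rnorm(n, 56.1, 12.5), 18), 100), 1)
    ch <- complete_cohort_fields(ch)

    h_rfs <- params$hazard_rfs[subgroup]
    h_os <- params$hazard_os[subgroup]
    recur <- rexp(n, 1) / h_rfs
    death <- rexp(n, 1) / h_os
    censor <- runif(n, params$censor_range[1], params$censor_range[2])
    ch$rfs_months <- pmax(round(pmin(recur, death, censor), 2), 0.01)
    ch$rfs_event <- if_else(pmin(recur, death) <= censor, "event", "censored")
    ch$os_months <- pmax(round(pmin(death, censor), 2), ch$rfs_months)
    ch$os_event <- if_else(death <= censor, "death", "censored")

    todo <- purrr::map_dfr(rtk_genes(), function(g) {
      idx <- which(truth[[paste0(tolower(g), "_positive")]])
      if (length(idx) == 0) return(NULL)
      tibble(idx = idx, gene = g,
             amplified = truth[[paste0(tolower(g), "_amplified")]][idx])
    })
    sish <- if (nrow(todo) > 0) {
      purrr::pmap_dfr(todo, function(idx, gene, amplified) {
        cells <- simulate_sish_cells(
          if (amplified) "amplified" else "not_amplified",
          params = params$sish
        )
        bind_cols(tibble(case_id = ch$case_id[idx], gene = gene), cells)
      })
    } else {
      empty_sish()
    }

    for (col in setdiff(cohort_columns(), names(ch))) {
      ch[[col]] <- NA_character_
    }
    list(cohort = validate_cohort(ch[cohort_columns()]),
         sish = sish, truth = truth)
  })
}
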