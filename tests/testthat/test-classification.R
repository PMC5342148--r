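test_that("putative-molecular subgroups follow the EBV > MMR > p53 precedence", {
  expect_identical(classify_putative("positive", "deficient", "mutant_pattern"),
                   "EBV_positive")
  expect_identical(classify_putative("negative", "proficient", "wild_pattern"),
                   "pGS")
  expect_identical(classify_putative("negative", "proficient", "mutant_pattern"),
                   "pCIN")
  expect_identical(classify_putative("negative", "deficient", "wild_pattern"),
                   "MMR_deficient")
})

test_that("histologic-molecular subgroups split p53-wild cases by Lauren type", {
  expect_identical(
    classify_histologic("negative", "proficient", "wild_pattern", "diffuse"),
    "D_pGS")
  # p53 mutant-pattern is I-pCIN regardless of histotype
  expect_identical(
    classify_histologic("negative", "proficient", "mutant_pattern", "diffuse"),
    "I_pCIN")
  expect_identical(
    classify_histologic("negative", "proficient", "wild_pattern", "mixed"),
    "I_pCIN")
  expect_identical(
    classify_histologic("positive", "deficient", "wild_pattern", "diffuse"),
    "EBV_positive")
})

test_that("both systems partition every cohort and nest as expected across seeds", {
  for (seed in 1:25) {
    sim <- simulate_cohort(simulation_params(n_cases = 40, seed = seed))
    ann <- classify_subgroups(derive_status(sim$cohort, sim$sish))
    expect_false(anyNA(ann$subgroup_putative))
    expect_false(anyNA(ann$subgroup_histologic))
    expect_true(all(ann$subgroup_putative %in% subgroup_levels("putative")))
    expect_true(all(ann$subgroup_histologic %in% subgroup_levels("histologic")))
    expect_equal(sum(subgroup_table(ann, "putative")$n), nrow(ann))
    expect_equal(sum(subgroup_table(ann, "histologic")$n), nrow(ann))
    # EBV and MMR memberships identical between systems
    expect_identical(ann$subgroup_putative %in% c("EBV_positive", "MMR_deficient"),
                     ann$subgroup_histologic %in% c("EBV_positive", "MMR_deficient"))
    expect_identical(ann$subgroup_putative[ann$subgroup_putative %in%
                                             c("EBV_positive", "MMR_deficient")],
                     ann$subgroup_histologic[ann$subgroup_histologic %in%
                                               c("EBV_positive", "MMR_deficient")])
    # pCIN is contained in I-pCIN; D-pGS is contained in pGS
    expect_true(all(ann$subgroup_histologic[ann$subgroup_putative == "pCIN"] ==
                      "I_pCIN"))
    expect_true(all(ann$subgroup_putative[ann$subgroup_histologic == "D_pGS"] ==
                      "pGS"))
  }
})

test_that("subgroup tables reproduce the classification fixture composition", {
  ex <- expand_count_spec(spec_classification(), seed = 3)
  ann <- annotate_cohort(ex$cohort, ex$sish)
  hist <- subgroup_table(ann, "histologic")
  expect_identical(hist$n, c(61L, 114L, 143L, 675L))
  put <- subgroup_table(ann, "putative")
  expect_identical(put$n, c(61L, 114L, 253L, 565L))
  expect_equal(sum(hist$pct), 100)

  single <- subgroup_table(annotate_cohort(base_case("solo")), "putative")
  expect_identical(single$n[single$subgroup == "pGS"], 1L)
  expect_equal(single$pct[single$subgroup == "pGS"], 100)
})

make_status <- function(...) {
  annotate_cohort(base_case(...))
}

test_that("triage routes by subgroup first, then the RTK IHC panel", {
  ebv <- make_status("T1", eber = "positive")
  expect_identical(ebv$recommendation, "immunotherapy_candidate")
  expect_identical(ebv$target_gene, "none")
  expect_match(ebv$rationale_path, "^ebv_mmr_screen")

  mmr <- make_status("T2", mlh1 = "lost", pms2 = "lost")
  expect_identical(mmr$recommendation, "immunotherapy_candidate")

  # HER2 3+ is sufficient without SISH
  cohort <- base_case("T3", her2_ihc = 3L)
  her2 <- annotate_cohort(cohort)
  expect_identical(her2$recommendation, "her2_targeted_therapy")
  expect_identical(her2$target_gene, "HER2")
  expect_false(her2$sish_required)

  ngs <- make_status("T4", egfr_ihc = 1L, p53_class = "complete_loss")
  expect_identical(ngs$recommendation, "target_sequencing_ngs")
  expect_match(ngs$rationale_path, "rtk_ihc_panel>target_sequencing_ngs")
})

test_that("EGFR/MET 3+ require SISH confirmation before targeted-therapy routing", {
  cohort <- base_case("T5", egfr_ihc = 3L)
  amp <- annotate_cohort(
    cohort, uniform_cells(60, gene_signals = 6L, case_id = "T5", gene = "EGFR"))
  expect_identical(amp$recommendation, "rtk_targeted_therapy")
  expect_identical(amp$target_gene, "EGFR")
  expect_true(amp$sish_required)

  notamp <- annotate_cohort(
    cohort, uniform_cells(60, gene_signals = 2L, case_id = "T5", gene = "EGFR"))
  expect_identical(notamp$recommendation, "target_sequencing_ngs")

  # 2+ genes go through SISH too; an amplified 2+ HER2 is an RTK target
  cohort2 <- base_case("T6", her2_ihc = 2L)
  amp2 <- annotate_cohort(
    cohort2, uniform_cells(60, gene_signals = 6L, case_id = "T6", gene = "HER2"))
  expect_identical(amp2$recommendation, "rtk_targeted_therapy")
  expect_identical(amp2$target_gene, "HER2")
})

test_that("missing required SISH yields sish_pending unless the policy defers to NGS", {
  cohort <- base_case("T7", egfr_ihc = 2L)
  pending <- annotate_cohort(cohort)
  expect_identical(pending$recommendation, "sish_pending")
  expect_true(pending$sish_required)
  expect_match(pending$flags, "sish_pending_egfr")

  deferred <- annotate_cohort(
    cohort, policy = calling_policy(defer_pending_to_ngs = TRUE))
  expect_identical(deferred$recommendation, "target_sequencing_ngs")
  expect_match(deferred$flags, "sish_pending_deferred")
})

test_that("triage is deterministic and never targets an unamplified gene outside HER2 3+", {
  sim <- simulate_cohort(simulation_params(n_cases = 400, seed = 21))
  ann1 <- annotate_cohort(sim$cohort, sim$sish)
  ann2 <- annotate_cohort(sim$cohort, sim$sish)
  expect_identical(ann1, ann2)

  rtk <- ann1[ann1$recommendation == "rtk_targeted_therapy", ]
  for (i in seq_len(nrow(rtk))) {
    g <- tolower(rtk$target_gene[i])
    expect_identical(rtk[[paste0(g, "_amp")]][i], "amplified")
  }
  her2 <- ann1[ann1$recommendation == "her2_targeted_therapy", ]
  expect_true(all(her2$her2_ihc == 3L))
  expect_true(all(ann1$rationale_path != ""))
  # target gene is reported exactly for the two therapy recommendations
  expect_identical(
    ann1$target_gene != "none",
    ann1$recommendation %in% c("her2_targeted_therapy", "rtk_targeted_therapy"))
})

test_that("the optional D-pGS shortcut routes p53-wild diffuse cases straight to NGS", {
  cohort <- base_case("T8", lauren = "diffuse", her2_ihc = 3L)
  default <- annotate_cohort(cohort)
  expect_identical(default$recommendation, "her2_targeted_therapy")
  shortcut <- annotate_cohort(
    cohort, policy = calling_policy(route_dpgs_to_ngs = TRUE))
  expect_identical(shortcut$recommendation, "target_sequencing_ngs")
  expect_match(shortcut$rationale_path, "d_pgs_direct_to_ngs")
})
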