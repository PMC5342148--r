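test_that("surgical-specimen IHC scoring follows the intensity/pattern/10% bands", {
  expect_identical(
    hofmann_score("strong", 60, "membranous_complete_or_basolateral"), 3L)
  expect_identical(
    hofmann_score("strong", 9.9, "membranous_complete_or_basolateral"), 0L)
  expect_identical(hofmann_score("faint", 30, "partial_membranous"), 1L)
  expect_identical(
    hofmann_score("weak_moderate", 40, "membranous_complete_or_basolateral"), 2L)
  # partial-membranous staining caps the score at 1+ whatever the intensity
  expect_identical(hofmann_score("strong", 80, "partial_membranous"), 1L)
  expect_identical(hofmann_score("none", 90, "none"), 0L)
  expect_error(hofmann_score("vivid", 50, "none"),
               class = "ragc_validation_error")
})

test_that("IHC 2+ or 3+ is positive; missing scores propagate as NA", {
  expect_identical(rtk_ihc_positive(c(0L, 1L, 2L, 3L, NA)),
                   c(FALSE, FALSE, TRUE, TRUE, NA))
  expect_error(rtk_ihc_positive(5L), class = "ragc_validation_error")
})

test_that("MMR deficiency requires pair loss, with configurable single-loss handling", {
  expect_identical(mmr_status("lost", "intact", "intact", "lost")$mmr,
                   "deficient")
  expect_identical(mmr_status("intact", "lost", "lost", "intact")$mmr,
                   "deficient")
  expect_identical(mmr_status("intact", "intact", "intact", "intact")$mmr,
                   "proficient")
  # single loss of a pair: deficient-with-flag by default, proficient in
  # strict-pair mode (still flagged)
  single <- mmr_status("lost", "intact", "intact", "intact")
  expect_identical(single$mmr, "deficient")
  expect_identical(single$mmr_flag, "discordant_pair")
  strict <- mmr_status("lost", "intact", "intact", "intact",
                       single_loss = "strict_pair")
  expect_identical(strict$mmr, "proficient")
  expect_identical(strict$mmr_flag, "discordant_pair")
  # all-missing imputes proficient with a flag
  allna <- mmr_status(NA, NA, NA, NA)
  expect_identical(allna$mmr, "proficient")
  expect_identical(allna$mmr_flag, "mmr_not_evaluated")
})

test_that("p53 mutant-pattern is complete loss or strong nuclear staining in >50%", {
  expect_identical(p53_pattern("complete_loss"), "mutant_pattern")
  expect_identical(p53_pattern("strong_nuclear", 50.0), "wild_pattern")
  expect_identical(p53_pattern("strong_nuclear", 50.1), "mutant_pattern")
  expect_identical(p53_pattern("other"), "wild_pattern")
  expect_error(p53_pattern("strong_nuclear", NA),
               class = "ragc_validation_error")
})

test_that("EBER positivity requires diffuse strong nuclear staining; missing imputes negative", {
  expect_identical(
    eber_call("diffuse_strong_nuclear_all_tumor_cells")$eber_effective,
    "positive")
  expect_identical(eber_call("other")$eber_effective, "negative")
  na <- eber_call(NA_character_)
  expect_identical(na$eber_effective, "negative")
  expect_identical(na$eber_flag, "eber_not_evaluated")
})

test_that("cluster signals count as 6 (small) and 12 (large) per cluster", {
  expect_equal(effective_gene_signals(3, 0, 0), 3)
  expect_equal(effective_gene_signals(2, 1, 1), 20)
  expect_equal(effective_gene_signals(0, 0, 2), 24)
  expect_error(effective_gene_signals(-1, 0, 0),
               class = "ragc_validation_error")
})

test_that("amplification is a pooled ratio strictly above 2.0 over at least 60 nuclei", {
  disomy <- amplification_call(uniform_cells(60, gene_signals = 2L))
  expect_identical(disomy$call, "not_amplified")
  expect_equal(disomy$ratio, 1.0)

  amp <- amplification_call(uniform_cells(60, gene_signals = 5L), gene = "EGFR")
  expect_equal(amp$gene_signal_total, 300L)
  expect_equal(amp$chr_signal_total, 120L)
  expect_equal(amp$ratio, 2.5)
  expect_equal(amp$mean_copies_per_nucleus, 5)
  expect_identical(amp$call, "amplified")

  # threshold is strict: ratio exactly 2.0 is not amplified
  boundary <- amplification_call(uniform_cells(60, gene_signals = 4L))
  expect_equal(boundary$ratio, 2.0)
  expect_identical(boundary$call, "not_amplified")

  expect_identical(
    amplification_call(uniform_cells(30, gene_signals = 10L))$call,
    "insufficient")
  expect_identical(amplification_call(NULL)$call, "not_tested")
  expect_identical(amplification_call(uniform_cells(0))$call, "not_tested")
})

test_that("nuclei without chromosome signals are not evaluable", {
  cells <- uniform_cells(70, gene_signals = 5L)
  cells$chr_signals[1:20] <- 0L
  res <- amplification_call(cells)
  expect_equal(res$n_cells_evaluated, 50L)
  expect_identical(res$call, "insufficient")
})

test_that("adding gene signals never flips a call from amplified to not amplified", {
  withr::with_seed(42, {
    for (i in 1:20) {
      cells <- uniform_cells(60)
      cells$gene_signals <- rpois(60, sample(1:6, 1))
      cells$chr_signals <- 1L + rpois(60, 1)
      before <- amplification_call(cells)
      cells$gene_signals <- cells$gene_signals + rpois(60, 2)
      after <- amplification_call(cells)
      expect_gte(after$ratio, before$ratio)
      expect_false(before$call == "amplified" && after$call == "not_amplified")
    }
  })
})

test_that("core handling: pooling versus any-core-amplified", {
  cells <- dplyr::bind_rows(
    dplyr::mutate(uniform_cells(60, gene_signals = 6L), core_id = 1L),
    dplyr::mutate(uniform_cells(60, gene_signals = 2L), core_id = 2L)
  )
  pooled <- amplification_call(cells)  # (360+120)/(120+120) = 2.0
  expect_equal(pooled$ratio, 2.0)
  expect_identical(pooled$call, "not_amplified")

  per_core <- amplification_call(
    cells, policy = calling_policy(pool_cores = FALSE))
  expect_identical(per_core$call, "amplified")

  strict <- amplification_call(
    uniform_cells(70, gene_signals = 6L),  # 35 per core
    policy = calling_policy(min_cells_per_core = TRUE))
  expect_identical(strict$call, "insufficient")
})

test_that("derive_status composes the calls and applies the SISH-only-if-positive policy", {
  cohort <- dplyr::bind_rows(
    base_case("D1"),                      # all IHC 0, no SISH
    base_case("D2", her2_ihc = 3L),       # amplified HER2
    base_case("D3", egfr_ihc = 2L),       # EGFR ratio 1.4
    base_case("D4", met_ihc = 1L),        # SISH present but score too low
    base_case("D5", egfr_ihc = 2L)        # positive but no SISH rows
  )
  sish <- dplyr::bind_rows(
    uniform_cells(60, gene_signals = 6L, case_id = "D2", gene = "HER2"),
    uniform_cells(60, gene_signals = 7L, chr_signals = 5L,
                  case_id = "D3", gene = "EGFR"),
    uniform_cells(60, gene_signals = 2L, case_id = "D4", gene = "MET")
  )
  st <- derive_status(cohort, sish)

  expect_false(st$ra_gc[st$case_id == "D1"])
  expect_true(all(unlist(st[st$case_id == "D1",
                            c("egfr_amp", "her2_amp", "met_amp")]) ==
                    "not_tested"))
  expect_true(st$ra_gc[st$case_id == "D2"])
  expect_identical(st$her2_amp[st$case_id == "D2"], "amplified")
  expect_identical(st$egfr_amp[st$case_id == "D3"], "not_amplified")
  expect_equal(st$egfr_ratio[st$case_id == "D3"], 1.4)
  expect_false(st$ra_gc[st$case_id == "D3"])
  expect_identical(st$met_amp[st$case_id == "D4"], "not_tested")
  expect_match(st$flags[st$case_id == "D4"], "sish_ignored_met")
  expect_identical(st$egfr_amp[st$case_id == "D5"], "not_tested")
  expect_match(st$flags[st$case_id == "D5"], "sish_missing_egfr")
})

test_that("an amplified call always sits on an IHC score of at least 2", {
  sim <- simulate_cohort(simulation_params(n_cases = 300, seed = 11))
  st <- derive_status(sim$cohort, sim$sish)
  for (g in c("egfr", "her2", "met")) {
    amped <- st[[paste0(g, "_amp")]] == "amplified"
    expect_true(all(st[[paste0(g, "_ihc")]][amped] >= 2L))
  }
})
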