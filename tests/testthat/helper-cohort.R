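# One-row cohort builder with sensible defaults; override any field by name.
base_case <- function(case_id = "c1", ...) {
  row <- tibble::tibble(
    case_id = case_id, age = 60, sex = "male", location = "lower_third",
    size_cm = 5, differentiation = "differentiated", lauren = "intestinal",
    lvi = "absent", lnm = "present", pt_stage = "T3", overall_stage = "III",
    egfr_ihc = 0L, her2_ihc = 0L, met_ihc = 0L,
    mlh1 = "intact", msh2 = "intact", msh6 = "intact", pms2 = "intact",
    p53_class = "other", p53_pct = NA_real_, eber = "negative",
    rfs_months = 24, rfs_event = "censored",
    os_months = 30, os_event = "censored"
  )
  mods <- list(...)
  for (nm in names(mods)) row[[nm]] <- mods[[nm]]
  row
}

# Uniform per-nucleus signal block (two cores).
uniform_cells <- function(n = 60, gene_signals = 2L, chr_signals = 2L,
                          small = 0L, large = 0L,
                          case_id = NULL, gene = NULL) {
  out <- tibble::tibble(
    core_id = rep(c(1L, 2L), length.out = n),
    gene_signals = as.integer(gene_signals),
    small_clusters = as.integer(small),
    large_clusters = as.integer(large),
    chr_signals = as.integer(chr_signals)
  )
  if (!is.null(case_id)) {
    out <- dplyr::bind_cols(
      tibble::tibble(case_id = case_id, gene = gene), out
    )
  }
  out
}

# Independent two-sided Fisher p by full margin-fixed enumeration.
fisher_enumeration_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
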