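#' Collapse Lauren histotype to the two-level grouping used in cohort tables
#'
#' @param lauren Character vector of `"intestinal"`, `"mixed"`, `"diffuse"`.
#' @return `"intestinal_mixed"` or `"diffuse"`.
#' @export
collapse_lauren <- function(lauren) {
  check_enum(lauren, lauren_levels(), "lauren")
  if_else(lauren == "diffuse", "diffuse", "intestinal_mixed")
}

# Deterministic 60-nucleus signal blocks used by the count-spec expander:
# amplified cases carry 6 gene signals over 2 chromosome signals per nucleus
# (pooled ratio 3.0), non-amplified 2 over 2 (ratio 1.0).
fixed_sish_block <- function(case_id, gene, amplified, n_cells = 60L) {
  tibble(
    case_id = case_id,
    gene = gene,
    core_id = rep(c(1L, 2L), length.out = n_cells),
    gene_signals = if (amplified) 6L else 2L,
    small_clusters = 0L,
    large_clusters = 0L,
    chr_signals = 2L
  )
}

# Fill the free (unconstrained) cohort fields with seeded draws from
# realistic marginals; constrained fields are left untouched. Follow-up is
# drawn from exponential recurrence/death times with uniform censoring.
complete_cohort_fields <- function(df) {
  n <- nrow(df)
  if (n == 0) return(df)
  draw <- function(values, probs) {
    values[sample.int(length(values), n, replace = TRUE, prob = probs)]
  }
  if (!"age" %in% names(df) || all(is.na(df$age))) {
    df$age <- round(pmin(pmax(rnorm(n, 56.1, 12.5), 18), 100), 1)
  }
  defaults <- list(
    sex = function() draw(c("male", "female"), c(0.65, 0.35)),
    location = function() draw(c("lower_third", "upper_mid_third"),
                               c(0.56, 0.44)),
    size_cm = function() round(pmax(rexp(n, 1 / 5) + 1, 0.5), 1),
    differentiation = function() draw(c("differentiated", "undifferentiated"),
                                      c(0.28, 0.72)),
    lauren = function() draw(lauren_levels(), c(0.45, 0.07, 0.48)),
    lvi = function() draw(c("present", "absent"), c(0.29, 0.71)),
    lnm = function() draw(c("present", "absent"), c(0.72, 0.28)),
    pt_stage = function() draw(c("T2", "T3", "T4"), c(0.16, 0.36, 0.48)),
    overall_stage = function() draw(c("II", "III", "IV"), c(0.10, 0.31, 0.59))
  )
  for (col in names(defaults)) {
    if (!col %in% names(df) || all(is.na(df[[col]]))) {
      df[[col]] <- defaults[[col]]()
    }
  }
  if (!"rfs_months" %in% names(df) || all(is.na(df$rfs_months))) {
    recur <- rexp(n, 0.02)
    death <- rexp(n, 0.015)
    censor <- runif(n, 12, 120)
    df$rfs_months <- pmax(round(pmin(recur, death, censor), 2), 0.01)
    df$rfs_event <- if_else(pmin(recur, death) <= censor, "event", "censored")
    df$os_months <- pmax(round(pmin(death, censor), 2), df$rfs_months)
    df$os_event <- if_else(death <= censor, "death", "censored")
  }
  df
}

count_spec_variables <- function() {
  c("eber", "mmr", "p53", "lauren", "rtk_amplified", "rtk_ihc_positive",
    "sex", "location", "differentiation", "size_group", "lvi", "lnm",
    "pt_stage", "overall_stage")
}

#' Expand a joint count specification into per-case records
#'
#' A count spec is a tibble with an `n` column and any subset of the
#' variables `eber` (`positive`/`negative`/`missing`), `mmr`
#' (`deficient`/`proficient`/`missing`), `p53`
#' (`wild_pattern`/`mutant_pattern`), `lauren`, `rtk_amplified`,
#' `rtk_ihc_positive` (logical), plus clinicopathologic columns (`sex`,
#' `location`, `differentiation`, `size_group` `le5`/`gt5`, `lvi`, `lnm`,
#' `pt_stage`, `overall_stage`); `NA` in a cell leaves that variable
#' unconstrained for that row. Expansion is exact: each row emits exactly
#' `n` cases whose raw readings induce the stated categories when run
#' through the marker-calling pipeline (amplified cases get 60 HER2-SISH
#' nuclei at pooled ratio 3.0; IHC-positive non-amplified cases 60 EGFR
#' nuclei at ratio 1.0), so recomputing the cross-tab over the emitted
#' cohort reproduces the counts exactly. Unconstrained classification
#' fields default to the reference categories (EBER negative, MMR
#' proficient, p53 wild, Lauren diffuse); free clinicopathologic fields and
#' follow-up are drawn deterministically from `seed`.
#'
#' @param spec Count-spec tibble.
#' @param seed Integer seed driving all free-field draws.
#' @return A list with `cohort`, `sish` and `truth` tibbles (`truth` echoes
#'   the constrained categories per emitted case).
#' @examples
#' expand_count_spec(tibble::tibble(rtk_amplified = TRUE, n = 2))$cohort
#' @export
expand_count_spec <- function(spec, seed = 1) {
  spec <- as_tibble(spec)
  if (!"n" %in% names(spec)) abort("A count spec needs an `n` column.")
  if (any(is.na(spec$n)) || any(spec$n < 0) || any(spec$n != round(spec$n))) {
    abort("Counts `n` must be non-negative integers.",
          class = "ragc_validation_error")
  }
  unknown <- setdiff(names(spec), c(count_spec_variables(), "n", "provenance"))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown count-spec variable(s): %s. Supported: %s.",
                  paste(unknown, collapse = ", "),
                  paste(count_spec_variables(), collapse = ", ")))
  }
  total <- sum(spec$n)
  vars <- intersect(count_spec_variables(), names(spec))
  expanded <- spec[rep(seq_len(nrow(spec)), spec$n), vars, drop = FALSE]
  truth <- bind_cols(
    tibble(case_id = sprintf("case_%04d", seq_len(total))),
    expanded
  )

  withr::with_seed(seed, {
    ch <- tibble(case_id = truth$case_id)
    get_var <- function(v, default) {
      if (v %in% names(truth)) {
        out <- truth[[v]]
        out[is.na(out)] <- default
        out
      } else {
        rep(default, max(total, 0L))
      }
    }
    eber <- get_var("eber", "negative")
    check_enum(eber, c("positive", "negative", "missing"), "eber")
    ch$eber <- if_else(eber == "missing", NA_character_, eber)

    mmr <- get_var("mmr", "proficient")
    check_enum(mmr, c("deficient", "proficient", "missing"), "mmr")
    ch$mlh1 <- case_when(mmr == "deficient" ~ "lost",
                         mmr == "missing" ~ NA_character_,
                         TRUE ~ "intact")
    ch$pms2 <- ch$mlh1
    ch$msh2 <- if_else(mmr == "missing", NA_character_, "intact")
    ch$msh6 <- ch$msh2

    p53 <- get_var("p53", "wild_pattern")
    check_enum(p53, c("wild_pattern", "mutant_pattern"), "p53")
    ch$p53_class <- if_else(p53 == "mutant_pattern", "complete_loss", "other")
    ch$p53_pct <- NA_real_

    ch$lauren <- get_var("lauren", "diffuse")
    check_enum(ch$lauren, lauren_levels(), "lauren")

    amplified <- as.logical(get_var("rtk_amplified", FALSE))
    ihc_pos <- as.logical(get_var("rtk_ihc_positive", FALSE)) | amplified
    if ("rtk_ihc_positive" %in% names(truth)) {
      stated_neg <- !is.na(truth$rtk_ihc_positive) & !truth$rtk_ihc_positive
      if (any(stated_neg & amplified)) {
        abort("Inconsistent spec: rtk_amplified cases must be IHC-positive.",
              class = "ragc_validation_error")
      }
    }
    ch$her2_ihc <- if_else(amplified, 3L, 0L)
    ch$egfr_ihc <- if_else(ihc_pos & !amplified, 2L, 0L)
    ch$met_ihc <- 0L

    for (v in c("sex", "location", "differentiation", "lvi", "lnm",
                "pt_stage", "overall_stage")) {
      if (v %in% names(truth)) ch[[v]] <- truth[[v]]
    }
    if ("size_group" %in% names(truth)) {
      sg <- get_var("size_group", "le5")
      check_enum(sg, c("le5", "gt5"), "size_group")
      ch$size_cm <- if_else(sg == "gt5", 7.0, 3.5)
    }

    ch <- complete_cohort_fields(ch)

    sish_idx <- which(ihc_pos)
    sish <- purrr::map_dfr(sish_idx, function(i) {
      if (amplified[i]) {
        fixed_sish_block(ch$case_id[i], "HER2", TRUE)
      } else {
        fixed_sish_block(ch$case_id[i], "EGFR", FALSE)
      }
    })
    for (col in setdiff(cohort_columns(), names(ch))) {
      ch[[col]] <- NA_character_
    }
    list(
      cohort = validate_cohort(ch[cohort_columns()]),
      sish = if (nrow(sish) > 0) sish else
        tibble(case_id = character(), gene = character(), core_id = integer(),
               gene_signals = integer(), small_clusters = integer(),
               large_clusters = integer(), chr_signals = integer()),
      truth = truth
    )
  })
}

#' Read a count specification from a TSV/CSV file
#'
#' @param path File with an `n` column and count-spec variable columns.
#' @return Count-spec tibble suitable for [expand_count_spec()].
#' @export
read_count_spec <- function(path) {
  df <- read_delim_auto(path)
  if (!"n" %in% names(df)) {
    abort(sprintf("Count spec %s lacks an `n` column.", path),
          class = "ragc_schema_error")
  }
  df$n <- as_num(df$n, "n", seq_len(nrow(df)))
  if ("rtk_amplified" %in% names(df)) {
    df$rtk_amplified <- as.logical(df$rtk_amplified)
  }
  if ("rtk_ihc_positive" %in% names(df)) {
    df$rtk_ihc_positive <- as.logical(df$rtk_ihc_positive)
  }
  df
}

#' Shipped count specification: subgroup-by-amplification cross-tabs
#'
#' The joint count table underlying both classification systems' printed
#' subgroup-by-SISH columns. The putative and histologic cross-tabs are
#' marginals of one joint distribution (the p53-wild I-pCIN cases are the
#' intestinal/mixed part of pGS), so a single spec reproduces both: pGS
#' 253 with 18 amplified splits into D-pGS 143/4 plus intestinal p53-wild
#' 110/14, and pCIN 565/77 is the p53-mutant part of I-pCIN 675/91.
#'
#' @return Count-spec tibble (993 cases, 104 amplified).
#' @export
spec_classification <- function() {
  tibble::tribble(
    ~eber,      ~mmr,         ~p53,             ~lauren,      ~rtk_amplified, ~n,
    "positive", NA,           NA,               NA,           FALSE,          59,
    "positive", NA,           NA,               NA,           TRUE,            2,
    "negative", "deficient",  NA,               NA,           FALSE,         107,
    "negative", "deficient",  NA,               NA,           TRUE,            7,
    "negative", "proficient", "wild_pattern",   "diffuse",    FALSE,         139,
    "negative", "proficient", "wild_pattern",   "diffuse",    TRUE,            4,
    "negative", "proficient", "wild_pattern",   "intestinal", FALSE,          96,
    "negative", "proficient", "wild_pattern",   "intestinal", TRUE,           14,
    "negative", "proficient", "mutant_pattern", "intestinal", FALSE,         488,
    "negative", "proficient", "mutant_pattern", "intestinal", TRUE,           77
  )
}

#' Shipped count specification: amplification status by Lauren histotype
#'
#' The 2 x 2 cross-tab of RTK amplification against collapsed Lauren type
#' (90/14 amplified, 448/441 not) used for association examples.
#'
#' @return Count-spec tibble.
#' @export
spec_ragc_lauren <- function() {
  tibble::tribble(
    ~rtk_amplified, ~lauren,      ~n,
    TRUE,           "intestinal", 90,
    TRUE,           "diffuse",    14,
    FALSE,          "intestinal", 448,
    FALSE,          "diffuse",    441
  )
}

#' Marker-profile fixture cohort
#'
#' A 993-case cohort reproducing the per-marker marginal distributions of
#' the source cohort exactly: EGFR/HER2/MET IHC score distributions
#' (524/312/119/38, 846/86/29/32, 726/182/67/18), p53 wild/mutant 371/622,
#' EBER 61 positive / 910 negative / 22 not evaluated, MMR 101 MLH1+PMS2
#' co-loss, 13 MSH2+MSH6 co-loss, 876 intact, 3 not evaluated; and per-gene
#' SISH amplification among IHC-positive cases of 49/157 (EGFR), 49/61
#' (HER2) and 26/85 (MET). Variables are assigned by independent seeded
#' permutations, so only the marginals (not any joint distribution) are
#' meaningful; joint cross-tabs come from [spec_classification()] and
#' [spec_ragc_lauren()] instead.
#'
#' @param seed Integer seed for the permutations and free fields.
#' @return List with `cohort` and `sish` tibbles.
#' @export
fixture_marker_profile <- function(seed = 1) {
  n <- 993L
  withr::with_seed(seed, {
    scores <- list(
      egfr_ihc = rep(0:3, c(524L, 312L, 119L, 38L)),
      her2_ihc = rep(0:3, c(846L, 86L, 29L, 32L)),
      met_ihc = rep(0:3, c(726L, 182L, 67L, 18L))
    )
    ch <- tibble(case_id = sprintf("case_%04d", seq_len(n)))
    for (col in names(scores)) {
      ch[[col]] <- as.integer(sample(scores[[col]]))
    }
    ch$p53_class <- sample(rep(c("other", "complete_loss", "strong_nuclear"),
                               c(371L, 500L, 122L)))
    ch$p53_pct <- if_else(ch$p53_class == "strong_nuclear",
                          round(runif(n, 60, 95), 1), NA_real_)
    ch$eber <- sample(rep(c("positive", "negative", NA_character_),
                          c(61L, 910L, 22L)))
    mmr_kind <- sample(rep(c("mlh1_pms2", "msh2_msh6", "intact", "missing"),
                           c(101L, 13L, 876L, 3L)))
    ch$mlh1 <- case_when(mmr_kind == "mlh1_pms2" ~ "lost",
                         mmr_kind == "missing" ~ NA_character_,
                         TRUE ~ "intact")
    ch$pms2 <- ch$mlh1
    ch$msh2 <- case_when(mmr_kind == "msh2_msh6" ~ "lost",
                         mmr_kind == "missing" ~ NA_character_,
                         TRUE ~ "intact")
    ch$msh6 <- ch$msh2
    ch <- complete_cohort_fields(ch)

    amp_per_gene <- c(EGFR = 49L, HER2 = 49L, MET = 26L)
    sish <- purrr::map_dfr(rtk_genes(), function(g) {
      pos_idx <- which(ch[[paste0(tolower(g), "_ihc")]] >= 2L)
      amp_idx <- pos_idx[seq_len(amp_per_gene[[g]])]
      purrr::map_dfr(pos_idx, function(i) {
        fixed_sish_block(ch$case_id[i], g, i %in% amp_idx)
      })
    })
    for (col in setdiff(cohort_columns(), names(ch))) {
      ch[[col]] <- NA_character_
    }
    list(cohort = validate_cohort(ch[cohort_columns()]), sish = sish)
  })
}
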