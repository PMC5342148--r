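#' Marker-calling and triage policy
#'
#' Bundles the tunable thresholds and tie-break conventions of the pipeline.
#' The defaults reproduce the study conditions: SISH amplification is a
#' pooled gene-to-chromosome ratio strictly greater than 2.0 over at least 60
#' evaluable nuclei (two tissue-microarray cores pooled), single-protein
#' mismatch-repair loss counts as deficient but is flagged, and missing
#' EBER/MMR stains are imputed negative/proficient with flags so that every
#' case receives a subgroup label.
#'
#' @param ratio_threshold Gene-to-chromosome ratio above which (strictly) a
#'   gene is called amplified. Default 2.0.
#' @param min_cells Minimum number of evaluable nuclei for an amplification
#'   call. Default 60.
#' @param pool_cores If `TRUE` (default) signal counts from all cores are
#'   pooled before the ratio is computed. If `FALSE`, each core is called
#'   separately and the case is amplified when any core is.
#' @param min_cells_per_core If `TRUE`, `min_cells` applies to every core
#'   separately (strict reading of "at least 60 tumor cells per core");
#'   default `FALSE` applies it to the pooled total.
#' @param mmr_single_loss How to call loss of a single protein of an
#'   MLH1/PMS2 or MSH2/MSH6 pair: `"deficient"` (default; flagged
#'   `discordant_pair`) or `"strict_pair"` (deficient only on co-loss).
#' @param defer_pending_to_ngs If `TRUE`, triage routes cases whose required
#'   SISH result is unavailable to target sequencing; default `FALSE` reports
#'   `sish_pending` instead.
#' @param route_dpgs_to_ngs If `TRUE`, the triage tree sends D-pGS cases
#'   straight to target sequencing instead of through the RTK IHC panel.
#'   Default `FALSE` (all non-EBV, non-MMR-deficient cases are screened by
#'   IHC, which is what lets the tree capture the RTK-amplified cases found
#'   outside the I-pCIN subgroup).
#'
#' @return A list of class `ragc_policy`.
#' @examples
#' calling_policy(ratio_threshold = 2, min_cells = 60)
#' @export
calling_policy <- function(ratio_threshold = 2.0,
                           min_cells = 60L,
                           pool_cores = TRUE,
                           min_cells_per_core = FALSE,
                           mmr_single_loss = c("deficient", "strict_pair"),
                           defer_pending_to_ngs = FALSE,
                           route_dpgs_to_ngs = FALSE) {
  mmr_single_loss <- match.arg(mmr_single_loss)
  if (!is.numeric(ratio_threshold) || length(ratio_threshold) != 1 ||
      ratio_threshold <= 0) {
    abort("`ratio_threshold` must be a single positive number.")
  }
  if (!is.numeric(min_cells) || length(min_cells) != 1 || min_cells < 1) {
    abort("`min_cells` must be a single integer >= 1.")
  }
  structure(
    list(
      ratio_threshold = as.numeric(ratio_threshold),
      min_cells = as.integer(min_cells),
      pool_cores = isTRUE(pool_cores),
      min_cells_per_core = isTRUE(min_cells_per_core),
      mmr_single_loss = mmr_single_loss,
      defer_pending_to_ngs = isTRUE(defer_pending_to_ngs),
      route_dpgs_to_ngs = isTRUE(route_dpgs_to_ngs)
    ),
    class = "ragc_policy"
  )
}

#' @export
print.ragc_policy <- function(x, ...) {
  cat("<ragc_policy>\n")
  cat("  ratio threshold     :", x$ratio_threshold, "(strict >)\n")
  cat("  min evaluable nuclei:", x$min_cells,
      if (x$min_cells_per_core) "(per core)\n" else "(pooled)\n")
  cat("  core handling       :",
      if (x$pool_cores) "pool signals across cores\n" else "any core amplified\n")
  cat("  MMR single loss     :", x$mmr_single_loss, "\n")
  cat("  pending SISH        :",
      if (x$defer_pending_to_ngs) "defer to NGS\n" else "report sish_pending\n")
  invisible(x)
}
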