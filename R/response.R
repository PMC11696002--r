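#' Classify a gene's transcriptional response as early or late
#'
#' A gene is early-responding when any differential-expression evidence
#' exists at the 3 h direct-target experiment, the 8 h or 24 h
#' time-course timepoints, or the meta-analysis; late-responding when
#' evidence exists only at 72 h or 9 days; and unresponsive (`none`)
#' with no evidence at all. The rule keys on when differential
#' expression first appears; the direction of change is carried but not
#' used.
#'
#' @param gene_id Gene identifier.
#' @param records DE record data.frame (`gene_id`, `timepoint`,
#'   `direction`), possibly covering many genes.
#' @return `"early"`, `"late"` or `"none"`.
#' @export
classify_response <- function(gene_id, records) {
  records <- validate_de_records(records)
  tps <- records$timepoint[records$gene_id == gene_id]
  early_tps <- c("3h_direct", "8h", "24h", "meta")
  if (any(tps %in% early_tps)) "early"
  else if (length(tps) > 0L) "late"
  else "none"
}

#' Integrate STM-bound genes with transcriptional-response evidence
#'
#' Joins a ChIP-derived bound-gene set with DE records and classifies
#' every bound gene as early, late or unresponsive. Summary counts
#' partition the bound set exactly: `early + late + none = |bound|`.
#' `via_timecourse_meta` counts responsive bound genes with evidence in
#' any channel other than the 3 h direct-target experiment, and
#' `direct_only` the remainder that respond only there.
#'
#' @param chip_genes Character vector of bound gene ids (non-empty).
#' @param de_records DE record data.frame.
#' @return A list with `table` (gene_id, bound, response) and `summary`
#'   (named counts: bound, responsive, early, late, none,
#'   via_timecourse_meta, direct_only).
#' @export
integrate_bound_responsive <- function(chip_genes, de_records) {
  if (length(chip_genes) == 0L) stop("empty ChIP gene set")
  chip_genes <- unique(as.character(chip_genes))
  de_records <- validate_de_records(de_records)
  early_tps <- c("3h_direct", "8h", "24h", "meta")
  tp_by_gene <- split(de_records$timepoint, de_records$gene_id)
  response <- vapply(chip_genes, function(g) {
    tps <- tp_by_gene[[g]]
    if (is.null(tps)) "none"
    else if (any(tps %in% early_tps)) "early"
    else "late"
  }, character(1))
  non_direct <- setdiff(de_timepoints, "3h_direct")
  via_tc <- vapply(chip_genes, function(g) {
    any(tp_by_gene[[g]] %in% non_direct)
  }, logical(1))
  tab <- data.frame(gene_id = chip_genes, bound = TRUE, response = response,
                    stringsAsFactors = FALSE)
  counts <- c(
    bound = length(chip_genes),
    responsive = sum(response != "none"),
    early = sum(response == "early"),
    late = sum(response == "late"),
    none = sum(response == "none"),
    via_timecourse_meta = sum(via_tc),
    direct_only = sum(response != "none" & !via_tc)
  )
  stopifnot(counts["early"] + counts["late"] + counts["none"] ==
              counts["bound"])
  list(table = tab, summary = counts)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a target transcript relative to a reference gene,
#' treated versus control: `2^-ddCt` with
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Cycle-threshold values (finite; vectorised).
#' @return Fold change(s).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
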