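# Exposure summarization, free Cmax, safety margins and physiological
# flagging of on-/off-target activities.

#' Summarize heterogeneous exposure measurements
#'
#' Repeated Cmax or plasma-protein-binding measurements for one drug are
#' collapsed to their 3rd quartile (75th percentile, linear interpolation
#' between order statistics), the summary that best tracks curated
#' reference values for vendor-compiled exposure data.
#'
#' @param values numeric vector of measurements (may be empty).
#' @return the 3rd quartile, or `NA` for an empty vector.
#' @export
summarize_exposure <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) return(NA_real_)
  unname(stats::quantile(values, 0.75, type = 7))
}

#' Free Cmax from total Cmax and plasma protein binding
#'
#' The unbound maximal plasma concentration: the fraction unbound
#' `(100 - ppb_pct)/100` times the total Cmax, in micromolar.
#'
#' @param cmax_tot total Cmax in micromolar (> 0).
#' @param ppb_pct percent of drug bound to plasma protein, in \[0, 100\].
#' @return free Cmax in micromolar.
#' @export
compute_free_cmax <- function(cmax_tot, ppb_pct) {
  ok <- is.na(ppb_pct) | (ppb_pct >= 0 & ppb_pct <= 100)
  if (!all(ok)) stop("ppb_pct must lie in [0, 100]")
  if (any(!is.na(cmax_tot) & cmax_tot <= 0)) stop("cmax_tot must be positive")
  (100 - ppb_pct) / 100 * cmax_tot
}

#' Per-drug exposure summary
#'
#' Summarizes long-format exposure measurements to one total Cmax and one
#' PPB percent per drug (3rd quartile each), excluding protein-binding rows
#' labeled as albumin or glycoprotein binding, then derives the free Cmax.
#'
#' @param exposure data.frame from [read_exposure_table()].
#' @return data.frame with `drug_id`, `cmax_tot`, `ppb_pct`, `cmax_free`
#'   (`cmax_free` present only where both inputs are).
#' @export
compile_exposure <- function(exposure) {
  drop <- exposure$quantity == "ppb_pct" &
    !is.na(exposure$binding_label) &
    tolower(exposure$binding_label) %in% c("albumin", "glycoprotein")
  e <- exposure[!drop, ]
  ids <- sort(unique(exposure$drug_id))
  pick <- function(q) vapply(ids, function(d)
    summarize_exposure(e$value[e$drug_id == d & e$quantity == q]), 0)
  out <- data.frame(drug_id = ids, cmax_tot = pick("cmax_tot"),
                    ppb_pct = pick("ppb_pct"), stringsAsFactors = FALSE)
  out$cmax_free <- compute_free_cmax(out$cmax_tot, out$ppb_pct)
  rownames(out) <- NULL
  out
}

#' Safety margin of a qualified AC50 against an exposure
#'
#' `margin = ac50 / cmax`; the margin inherits the AC50's qualifier (a
#' censored AC50 gives a censored, i.e. lower-bound, margin).
#'
#' @param qualifier,ac50 qualified AC50 (micromolar).
#' @param cmax exposure in micromolar (`NA` gives an `NA` margin).
#' @return data.frame with `qualifier` and `margin`.
#' @export
compute_margin <- function(qualifier, ac50, cmax) {
  assert_qualified(qualifier, ac50)
  if (any(!is.na(cmax) & cmax <= 0)) stop("cmax must be positive")
  data.frame(qualifier = qualifier, margin = ac50 / cmax,
             stringsAsFactors = FALSE)
}

#' Classify activities as on-target, known or unpublished off-target
#'
#' An activity is on-target when the assay's target is among the drug's
#' mechanism-of-action (MOA) annotations, subject to mode matching: a
#' functional (agonist/antagonist) assay requires the same drug action
#' type; for binding or inhibition assays on GPCRs and nuclear receptors,
#' agonist drugs are excluded while antagonists are retained (binding and
#' functional antagonist readouts track each other on these panels).
#' Otherwise the activity is a known off-target when any external resource
#' reports a median AC50 below `known_cutoff` for the drug-target pair or
#' the pair carries an MOA annotation that failed mode matching; remaining
#' activities are unpublished off-target.
#'
#' @param rep_results representative activities.
#' @param assays assay metadata (with `protein_class`).
#' @param moa long MOA table from [parse_moa()].
#' @param external_summaries data.frame with `drug_id`, `target_gene`,
#'   `median_ac50` (from [summarize_external()]); may be `NULL`.
#' @param known_cutoff external-activity cutoff in micromolar.
#' @return `rep_results` with an `activity_class` column.
#' @export
classify_activities <- function(rep_results, assays, moa,
                                external_summaries = NULL,
                                known_cutoff = 10) {
  ai <- match(rep_results$assay_id, assays$assay_id)
  target <- assays$target_gene[ai]
  mode <- assays$mode[ai]
  pclass <- assays$protein_class[ai]
  moa_key <- paste(moa$drug_id, moa$target_gene)
  row_key <- paste(rep_results$drug_id, target)
  has_moa <- row_key %in% moa_key
  action <- stats::setNames(moa$action_type, moa_key)[row_key]
  on_target <- has_moa & ifelse(
    mode %in% c("agonist", "antagonist"),
    !is.na(action) & action == mode,
    ifelse(pclass %in% c("GPCR", "Nuclear receptor"),
           !is.na(action) & action != "agonist", TRUE))
  known_ext <- rep(FALSE, nrow(rep_results))
  if (!is.null(external_summaries) && nrow(external_summaries)) {
    ext <- external_summaries[!is.na(external_summaries$median_ac50) &
                              external_summaries$median_ac50 < known_cutoff, ]
    known_ext <- row_key %in% paste(ext$drug_id, ext$target_gene)
  }
  cls <- ifelse(on_target, "on_target",
                ifelse(known_ext | has_moa, "known_off_target",
                       "unpublished_off_target"))
  rep_results$activity_class <- cls
  rep_results
}

#' Margins table with physiological flags
#'
#' Joins representative activities to per-drug exposure, computes total and
#' free margins with qualifier propagation, and flags physiologically
#' relevant activities: a measured free margin at or below
#' `physiological_threshold`. Censored margins already above the threshold
#' can never be physiological; censored margins at or below it are
#' indeterminate (the true margin may lie either side) and are flagged
#' separately.
#'
#' @param rep_results representative activities, optionally already
#'   carrying `activity_class` (see [classify_activities()]).
#' @param exposure_summary per-drug exposure from [compile_exposure()].
#' @param physiological_threshold free-margin cutoff (default 10).
#' @return data.frame with margins, `physiological` and
#'   `indeterminate` flags.
#' @export
margin_table <- function(rep_results, exposure_summary,
                         physiological_threshold = 10) {
  di <- match(rep_results$drug_id, exposure_summary$drug_id)
  cm_tot <- exposure_summary$cmax_tot[di]
  cm_free <- exposure_summary$cmax_free[di]
  out <- rep_results
  out$total_margin <- out$ac50 / cm_tot
  out$free_margin <- out$ac50 / cm_free
  out$physiological <- !is.na(out$free_margin) & out$qualifier == "=" &
    out$free_margin <= physiological_threshold
  out$indeterminate <- !is.na(out$free_margin) & out$qualifier == ">" &
    out$free_margin <= physiological_threshold
  out
}
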