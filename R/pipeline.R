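# End-to-end orchestration: from an input bundle to non-redundant
# target-ADR associations, explanations and (for synthetic bundles) the
# planted-map recovery report.

#' Pipeline configuration
#'
#' All thresholds of the analysis with their standard defaults: the
#' physiological free-margin cutoff (10), the FAERS LRT multiplier (5),
#' training-set eligibility (10 positives / 50 negatives / 10 measured
#' values), truncation cutoff sets per measure, the systematic gate
#' (p <= 1e-06 and AUC >= 0.7), the literature gate (p <= 0.001 and
#' AUC >= 0.6), the sparse-model coefficient rule (-0.08), coverage and
#' cross-validation settings, and the explanation criteria (5 micromolar
#' ceiling, 10-fold rule).
#'
#' @param ... overrides of the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    physiological_threshold = 10, lrt_multiplier = 5,
    min_pos = 10, min_neg = 50, min_unqualified = 10,
    cutoffs = default_cutoffs(),
    p_gate = 1e-6, auc_gate = 0.7,
    lit_p = 0.001, lit_marginal = 0.05, lit_auc = 0.6,
    coef_threshold = -0.08, min_coverage = 0.7,
    n_trials = 50, holdout = 0.2,
    ac50_ceiling = 5, fold = 10, known_cutoff = 10,
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on an input bundle
#'
#' Stages, in dependency order: replicate summarization; concordance
#' grouping; representative selection; exposure and margins; external
#' cross-referencing and activity classification; ADR training sets;
#' systematic univariate scan with per-assay cutoff selection;
#' multivariate redundancy elimination; explanation flagging; and, when
#' the bundle carries a planted ground truth, recovery evaluation.
#'
#' @param bundle input bundle (list as from [generate_bundle()] or
#'   [read_bundle()]).
#' @param config a [pipeline_config()].
#' @param stages character vector of stage names to run (prefix of the
#'   full order); later stages error if an upstream stage is missing.
#' @return named list of stage artifacts plus a `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         stages = c("summarize", "group", "margins",
                                    "adrsets", "univariate", "multivariate",
                                    "explain")) {
  for (req in c("activities", "assays", "drugs", "exposure",
                "adr_annotations"))
    if (is.null(bundle[[req]])) stop("bundle is missing input table: ", req)
  if (is.null(bundle$hierarchy))
    bundle$hierarchy <- meddra_hierarchy(bundle$meddra_edges)
  out <- list(config = config)
  need <- function(stage, artifact) {
    if (is.null(out[[artifact]]))
      stop("stage '", stage, "' needs artifact '", artifact,
           "' from an earlier stage; enable it")
  }
  if ("summarize" %in% stages)
    out$summarized <- summarize_activities(bundle$activities)
  if ("group" %in% stages) {
    need("group", "summarized")
    out$concordance <- concordance_table(out$summarized, bundle$assays)
    out$assays <- build_assay_groups(bundle$assays, out$concordance,
                                     out$summarized)
    matches <- NULL
    if (!is.null(bundle$reference_structures))
      matches <- match_structures(
        data.frame(query_key = bundle$drugs$structure_key,
                   names = bundle$drugs$names, stringsAsFactors = FALSE),
        bundle$reference_structures)
    out$structure_matches <- matches
    out$representative <- representative_activities(
      out$summarized, bundle$drugs, out$assays, matches)
  }
  if ("margins" %in% stages) {
    need("margins", "representative")
    out$exposure <- compile_exposure(bundle$exposure)
    ext_sum <- NULL
    if (!is.null(bundle$external_activities))
      ext_sum <- summarize_external(bundle$external_activities)
    out$external_summaries <- ext_sum
    classed <- classify_activities(out$representative, out$assays,
                                   parse_moa(bundle$drugs), ext_sum,
                                   known_cutoff = config$known_cutoff)
    out$margins <- margin_table(classed, out$exposure,
                                config$physiological_threshold)
    out$promiscuity <- compute_promiscuity(out$representative)
  }
  if ("adrsets" %in% stages) {
    out$training <- build_training_sets(
      bundle$adr_annotations, bundle$hierarchy, bundle$drugs,
      min_pos = config$min_pos, min_neg = config$min_neg,
      lrt_multiplier = config$lrt_multiplier)
  }
  if ("univariate" %in% stages) {
    need("univariate", "representative"); need("univariate", "training")
    out$measures <- activity_measures(out$representative, out$exposure)
    out$scan <- systematic_scan(
      out$measures, out$training, cutoffs = config$cutoffs,
      min_pos = config$min_pos, min_neg = config$min_neg,
      min_unqualified = config$min_unqualified,
      p_gate = config$p_gate, auc_gate = config$auc_gate)
  }
  if ("multivariate" %in% stages) {
    need("multivariate", "scan")
    sig <- out$scan$significant
    trunc_values <- truncated_measure_values(out$measures,
                                             out$scan$cutoff_selection)
    out$nonredundant <- eliminate_redundant(
      sig[, c("term_code", "source", "assay_group_id", "measure")],
      trunc_values, out$training$labels,
      min_coverage = config$min_coverage,
      coef_threshold = config$coef_threshold,
      n_trials = config$n_trials, holdout = config$holdout,
      seed = config$seed)
  }
  if ("explain" %in% stages) {
    need("explain", "margins"); need("explain", "scan")
    lit_sig <- out$scan$all[out$scan$all$tested &
                            out$scan$all$kw_p <= config$lit_p &
                            out$scan$all$roc_auc >= config$lit_auc, ]
    out$explanations <- flag_explanations(
      out$margins, out$measures, out$training$labels, lit_sig,
      out$assays, parse_moa(bundle$drugs),
      ac50_ceiling = config$ac50_ceiling, fold = config$fold)
  }
  if (!is.null(bundle$ground_truth) && !is.null(out$nonredundant))
    out$recovery <- evaluate_recovery(out$nonredundant$pairs,
                                      bundle$ground_truth, out$assays,
                                      bundle$hierarchy)
  out$manifest <- pipeline_manifest(bundle, config, out)
  out
}

#' Truncate a long measure table at the selected per-assay cutoffs
#'
#' Applies each (assay group, measure) pair's selected cutoff to the long
#' measure table: censored values below the cutoff are dropped, everything
#' else is capped at it. The result supplies predictor values for the
#' multivariate stage.
#'
#' @param measures long table from [activity_measures()].
#' @param cutoff_selection data.frame with `assay_group_id`, `measure`,
#'   `cutoff` (from [systematic_scan()]).
#' @return data.frame with `drug_id`, `assay_group_id`, `measure`, `value`.
#' @export
truncated_measure_values <- function(measures, cutoff_selection) {
  key <- paste(measures$assay_group_id, measures$measure)
  cut <- stats::setNames(cutoff_selection$cutoff,
                         paste(cutoff_selection$assay_group_id,
                               cutoff_selection$measure))[key]
  keep <- !is.na(cut) & !(measures$qualifier == ">" & measures$value < cut)
  out <- measures[keep, c("drug_id", "assay_group_id", "measure")]
  out$value <- pmin(measures$value[keep], cut[keep])
  out
}

#' Recovery of the planted causal map
#'
#' Compares retained non-redundant PT-level (target, term) pairs against
#' the bundle's planted causal map. A predicted assay group counts as a
#' hit for a planted pair when it contains the causal assay's target.
#'
#' @param pairs `pairs` element of [eliminate_redundant()]'s result.
#' @param ground_truth planted causal map (with `target_gene`,
#'   `term_code`).
#' @param assays assay metadata with `group_id`.
#' @param hierarchy optional [meddra_hierarchy()]; when given, predictions
#'   are restricted to PT-level terms (the level the map is planted at)
#'   before comparing.
#' @return list with `precision`, `recall`, `n_predicted`, `n_planted`,
#'   `predicted` and `planted` pair tables.
#' @export
evaluate_recovery <- function(pairs, ground_truth, assays,
                              hierarchy = NULL) {
  ret <- pairs[pairs$status == "retained", ]
  gt <- unique(paste(ground_truth$target_gene, ground_truth$term_code))
  grp_target <- stats::setNames(assays$target_gene, assays$group_id)
  pred_tbl <- unique(data.frame(
    target_gene = unname(grp_target[ret$assay_group_id]),
    term_code = ret$term_code, stringsAsFactors = FALSE))
  if (!is.null(hierarchy) && nrow(pred_tbl))
    pred_tbl <- pred_tbl[meddra_level(hierarchy, pred_tbl$term_code) == "PT", ]
  pred <- unique(paste(pred_tbl$target_gene, pred_tbl$term_code))
  hits <- intersect(pred, gt)
  list(precision = if (length(pred)) length(hits) / length(pred) else NA,
       recall = length(hits) / length(gt),
       n_predicted = length(pred), n_planted = length(gt),
       predicted = pred_tbl,
       planted = unique(ground_truth[, c("target_gene", "term_code")]))
}

pipeline_manifest <- function(bundle, config, out) {
  counts <- vapply(out, function(a) {
    if (is.data.frame(a)) nrow(a) else NA_integer_
  }, 0L)
  list(seed = config$seed,
       config = unclass(config),
       input_rows = vapply(Filter(is.data.frame, bundle), nrow, 0L),
       artifact_rows = counts[!is.na(counts)])
}
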