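# Univariate assay-ADR association testing: truncation of censored
# activity measures, Kruskal-Wallis tests, ROC AUC, per-assay cutoff
# selection, and literature-association classification with hierarchy
# expansion.

#' Truncate qualified activity values at a cutoff
#'
#' Rank statistics need a common ceiling for censored measurements:
#' measured values above the cutoff are pulled down to it, censored values
#' at or above the cutoff are kept at the cutoff (their rank is correct),
#' and censored values below the cutoff are excluded -- their true value
#' could fall on either side.
#'
#' @param qualifier,value qualified activity values (AC50 or margin).
#' @param cutoff truncation value.
#' @return list with `value` (truncated values for kept entries), `keep`
#'   (logical mask into the input) and `n_excluded_censored`.
#' @export
truncate_activity <- function(qualifier, value, cutoff) {
  assert_qualified(qualifier, value)
  keep <- !(qualifier == ">" & value < cutoff)
  list(value = pmin(value[keep], cutoff), keep = keep,
       n_excluded_censored = sum(!keep))
}

#' Kruskal-Wallis p-value for a two-group comparison
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation (one degree of freedom for two groups). When every value
#' in both groups is identical the test carries no information and p is 1.
#'
#' @param pos,neg numeric activity values for ADR-positive and -negative
#'   drugs.
#' @return the p-value (unadjusted).
#' @export
kw_pvalue <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both groups must be non-empty")
  if (length(unique(c(pos, neg))) == 1L) return(1)
  stats::kruskal.test(list(pos, neg))$p.value
}

#' ROC AUC of an activity measure for an ADR
#'
#' The score is the negated log10 activity measure, so more potent (lower
#' AC50 or margin) means a higher score and AUC > 0.5 means potency
#' associates with the ADR. Computed in the Mann-Whitney form,
#' `P(score_pos > score_neg) + 0.5 P(tie)`, which is invariant to any
#' strictly monotone transform of the score.
#'
#' @inheritParams kw_pvalue
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both groups must be non-empty")
  score <- -log10(c(pos, neg))
  auc_from_scores(score, rep(c(1, 0), c(length(pos), length(neg))))
}

#' Test one assay x measure x cutoff x ADR-term association
#'
#' Truncates the qualified values, checks eligibility (at least `min_pos`
#' positive and `min_neg` negative drugs with usable values and at least
#' `min_unqualified` measured values overall), then computes the
#' Kruskal-Wallis p and ROC AUC on the same truncated values.
#'
#' @param pos_q,pos_v qualified values for ADR-positive drugs.
#' @param neg_q,neg_v qualified values for ADR-negative drugs.
#' @param cutoff truncation cutoff.
#' @param min_pos,min_neg,min_unqualified eligibility thresholds.
#' @return one-row data.frame with `kw_p`, `roc_auc`, `n_pos`, `n_neg`,
#'   `n_excluded_censored`, `tested`.
#' @export
test_association <- function(pos_q, pos_v, neg_q, neg_v, cutoff,
                             min_pos = 10, min_neg = 50,
                             min_unqualified = 10) {
  tp <- truncate_activity(pos_q, pos_v, cutoff)
  tn <- truncate_activity(neg_q, neg_v, cutoff)
  n_unq <- sum(pos_q[tp$keep] == "=") + sum(neg_q[tn$keep] == "=")
  eligible <- length(tp$value) >= min_pos && length(tn$value) >= min_neg &&
    n_unq >= min_unqualified
  if (!eligible)
    return(data.frame(kw_p = NA_real_, roc_auc = NA_real_,
                      n_pos = length(tp$value), n_neg = length(tn$value),
                      n_excluded_censored = tp$n_excluded_censored +
                        tn$n_excluded_censored,
                      tested = FALSE))
  data.frame(kw_p = kw_pvalue(tp$value, tn$value),
             roc_auc = roc_auc(tp$value, tn$value),
             n_pos = length(tp$value), n_neg = length(tn$value),
             n_excluded_censored = tp$n_excluded_censored +
               tn$n_excluded_censored,
             tested = TRUE)
}

#' Long activity-measure table for association testing
#'
#' Expands representative activities into one row per drug x assay group x
#' measure, attaching total and free margins where exposure is available.
#' Margins inherit the AC50 qualifier.
#'
#' @param rep_results representative activities.
#' @param exposure_summary per-drug exposure from [compile_exposure()].
#' @return data.frame with `drug_id`, `assay_group_id`, `measure`,
#'   `qualifier`, `value`.
#' @export
activity_measures <- function(rep_results, exposure_summary) {
  di <- match(rep_results$drug_id, exposure_summary$drug_id)
  base <- rep_results[, c("drug_id", "assay_group_id", "qualifier")]
  mk <- function(measure, value) {
    out <- cbind(base, measure = measure, value = value)
    out[!is.na(out$value), ]
  }
  out <- rbind(
    mk("ac50", rep_results$ac50),
    mk("total_margin", rep_results$ac50 / exposure_summary$cmax_tot[di]),
    mk("free_margin", rep_results$ac50 / exposure_summary$cmax_free[di]))
  rownames(out) <- NULL
  out
}

default_cutoffs <- function() {
  list(ac50 = c(10, 30), total_margin = c(2, 10), free_margin = c(10, 100))
}

#' Scan assay x measure x cutoff x term x source associations
#'
#' The exhaustive univariate scan: for every assay group and activity
#' measure, every configured truncation cutoff is evaluated against every
#' (term, source) training set.
#'
#' @param measures long table from [activity_measures()].
#' @param training output of [build_training_sets()].
#' @param cutoffs named list of cutoff vectors per measure.
#' @param min_pos,min_neg,min_unqualified eligibility thresholds.
#' @param terms optional restriction to a set of term codes.
#' @return data.frame with one row per evaluated combination.
#' @export
scan_associations <- function(measures, training,
                              cutoffs = default_cutoffs(),
                              min_pos = 10, min_neg = 50,
                              min_unqualified = 10, terms = NULL) {
  sets <- training$sets
  if (!is.null(terms)) sets <- sets[sets$term_code %in% terms, ]
  sets <- sets[sets$eligible, ]
  lab <- training$labels[training$labels$label %in% c("pos", "neg"), ]
  lab_split <- split(lab[, c("drug_id", "label")],
                     paste(lab$term_code, lab$source, sep = "\r"))
  res <- vector("list", 5000L); n_res <- 0L
  by_gm <- split(measures, paste(measures$assay_group_id, measures$measure,
                                 sep = "\r"))
  for (gm in names(by_gm)) {
    sub <- by_gm[[gm]]
    parts <- strsplit(gm, "\r", fixed = TRUE)[[1]]
    grp <- parts[1]; meas <- parts[2]
    q <- sub$qualifier; v <- sub$value
    names(q) <- names(v) <- sub$drug_id
    for (cutoff in cutoffs[[meas]]) {
      for (i in seq_len(nrow(sets))) {
        ls <- lab_split[[paste(sets$term_code[i], sets$source[i], sep = "\r")]]
        pos <- intersect(ls$drug_id[ls$label == "pos"], sub$drug_id)
        neg <- intersect(ls$drug_id[ls$label == "neg"], sub$drug_id)
        if (!length(pos) || !length(neg)) next
        r <- test_association(q[pos], v[pos], q[neg], v[neg], cutoff,
                              min_pos = min_pos, min_neg = min_neg,
                              min_unqualified = min_unqualified)
        n_res <- n_res + 1L
        res[[n_res]] <- cbind(
          data.frame(assay_group_id = grp, measure = meas, cutoff = cutoff,
                     term_code = sets$term_code[i], level = sets$level[i],
                     source = sets$source[i], stringsAsFactors = FALSE), r)
      }
    }
  }
  out <- do.call(rbind, res[seq_len(n_res)])
  if (is.null(out))
    out <- data.frame(assay_group_id = character(), measure = character(),
                      cutoff = numeric(), term_code = character(),
                      level = character(), source = character(),
                      kw_p = numeric(), roc_auc = numeric(),
                      n_pos = integer(), n_neg = integer(),
                      n_excluded_censored = integer(), tested = logical())
  rownames(out) <- NULL
  out
}

#' Select the truncation cutoff for one assay group x measure
#'
#' The cutoff yielding the larger number of associations passing the
#' systematic-scan gate is chosen; ties resolve to the higher cutoff.
#'
#' @param assoc scan results for one assay group and measure (both
#'   cutoffs).
#' @param p_gate,auc_gate systematic significance gates.
#' @return the selected cutoff value.
#' @export
select_assay_cutoff <- function(assoc, p_gate = 1e-6, auc_gate = 0.7) {
  cuts <- sort(unique(assoc$cutoff))
  hits <- vapply(cuts, function(cc) {
    s <- assoc[assoc$cutoff == cc & assoc$tested, ]
    sum(s$kw_p <= p_gate & s$roc_auc >= auc_gate, na.rm = TRUE)
  }, 0)
  cuts[max(which(hits == max(hits)))]
}

#' Systematic association scan with per-assay cutoff selection
#'
#' Runs the full scan at every configured cutoff, selects one cutoff per
#' (assay group, measure) via [select_assay_cutoff()], and reports the
#' associations at the selected cutoffs together with the significant
#' subset.
#'
#' @inheritParams scan_associations
#' @param p_gate,auc_gate systematic significance gates.
#' @return list with `associations` (selected-cutoff rows),
#'   `cutoff_selection`, `significant`, and `all` (every evaluated row).
#' @export
systematic_scan <- function(measures, training, cutoffs = default_cutoffs(),
                            min_pos = 10, min_neg = 50, min_unqualified = 10,
                            p_gate = 1e-6, auc_gate = 0.7, terms = NULL) {
  all_res <- scan_associations(measures, training, cutoffs = cutoffs,
                               min_pos = min_pos, min_neg = min_neg,
                               min_unqualified = min_unqualified,
                               terms = terms)
  key <- paste(all_res$assay_group_id, all_res$measure, sep = "\r")
  sel <- lapply(split(all_res, key), function(s)
    data.frame(assay_group_id = s$assay_group_id[1], measure = s$measure[1],
               cutoff = select_assay_cutoff(s, p_gate, auc_gate),
               stringsAsFactors = FALSE))
  sel <- do.call(rbind, c(sel, list(make.row.names = FALSE)))
  keep <- interaction(key, all_res$cutoff, drop = TRUE) %in%
    interaction(paste(sel$assay_group_id, sel$measure, sep = "\r"),
                sel$cutoff, drop = TRUE)
  associations <- all_res[keep, ]
  significant <- associations[associations$tested &
                              associations$kw_p <= p_gate &
                              associations$roc_auc >= auc_gate, ]
  rownames(associations) <- rownames(significant) <- NULL
  list(associations = associations, cutoff_selection = sel,
       significant = significant, all = all_res)
}

best_assoc_for_term <- function(assoc, term, groups, auc_gate) {
  s <- assoc[assoc$term_code == term & assoc$assay_group_id %in% groups &
             assoc$tested, ]
  n_tests <- nrow(s)
  s <- s[!is.na(s$roc_auc) & s$roc_auc >= auc_gate, ]
  if (!nrow(s)) return(list(best = NULL, n_tests = n_tests))
  list(best = s[which.min(s$kw_p), ], n_tests = n_tests)
}

#' Classify literature-reported target vs ADR associations
#'
#' For each literature pair the strongest test over the target's assay
#' groups, both annotation sources, all measures and both cutoffs is
#' classified as significant (p <= `p_sig` and AUC >= `auc_gate`),
#' marginal (`p_sig` < p <= `p_marginal`), not significant, or not tested.
#' When the focal term is not significant, sibling PTs sharing an HT are
#' examined in order of increasing p (distance 1), then PTs sharing an HG
#' (distance 2, flagged unconfirmed pending manual review), accumulating
#' the number of tests and stopping at the first term meeting the
#' significance criteria.
#'
#' @param lit data.frame with `target_gene` and `term_code` (PT codes).
#' @param assoc full scan results (all cutoffs retained -- the
#'   smallest-p-threshold mode).
#' @param assays assay metadata with `group_id`.
#' @param hierarchy a [meddra_hierarchy()].
#' @param p_sig,p_marginal,auc_gate classification gates.
#' @param max_distance hierarchy expansion depth (0, 1 or 2).
#' @return data.frame with one row per literature pair: `class`,
#'   `best_term`, `distance`, `kw_p`, `roc_auc`, `n_tests`, `confirmed`.
#' @export
classify_literature <- function(lit, assoc, assays, hierarchy,
                                p_sig = 0.001, p_marginal = 0.05,
                                auc_gate = 0.6, max_distance = 2) {
  out <- lapply(seq_len(nrow(lit)), function(i) {
    target <- lit$target_gene[i]; term <- lit$term_code[i]
    groups <- unique(assays$group_id[assays$target_gene == target])
    row <- data.frame(target_gene = target, term_code = term,
                      class = "not_tested", best_term = NA_character_,
                      distance = NA_integer_, kw_p = NA_real_,
                      roc_auc = NA_real_, n_tests = 0L, confirmed = NA,
                      stringsAsFactors = FALSE)
    b0 <- best_assoc_for_term(assoc, term, groups, auc_gate)
    row$n_tests <- b0$n_tests
    if (is.null(b0$best) && b0$n_tests > 0) {
      # tested, but no measure discriminates in the expected direction
      row$class <- "not_significant"
      row$best_term <- term; row$distance <- 0L; row$confirmed <- TRUE
    }
    if (!is.null(b0$best)) {
      row$best_term <- term; row$distance <- 0L
      row$kw_p <- b0$best$kw_p; row$roc_auc <- b0$best$roc_auc
      row$class <- if (b0$best$kw_p <= p_sig) "significant"
        else if (b0$best$kw_p <= p_marginal) "marginal"
        else "not_significant"
      row$confirmed <- TRUE
    }
    if (identical(row$class, "significant") || max_distance < 1) return(row)
    expand <- function(cands, dist, confirmed) {
      res <- lapply(cands, best_assoc_for_term, assoc = assoc,
                    groups = groups, auc_gate = auc_gate)
      ord <- order(vapply(res, function(r)
        if (is.null(r$best)) Inf else r$best$kw_p, 0))
      for (k in ord) {
        r <- res[[k]]
        row$n_tests <<- row$n_tests + r$n_tests
        if (!is.null(r$best) && r$best$kw_p <= p_sig) {
          row$class <<- "significant"; row$best_term <<- cands[k]
          row$distance <<- dist; row$kw_p <<- r$best$kw_p
          row$roc_auc <<- r$best$roc_auc; row$confirmed <<- confirmed
          return(TRUE)
        }
      }
      FALSE
    }
    sibs <- siblings_under_ht(hierarchy, term)
    if (length(sibs) && expand(sibs, 1L, TRUE)) return(row)
    if (max_distance >= 2) {
      hgs <- meddra_ancestors(hierarchy, term, "HG")
      cous <- setdiff(unique(unlist(lapply(hgs, pts_under, h = hierarchy))),
                      c(term, sibs))
      if (length(cous)) expand(cous, 2L, FALSE)
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
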