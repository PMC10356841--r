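# Flagging unpublished off-target activities as candidate mechanisms for
# known drug ADRs.

#' Flag unpublished activities that may explain known drug ADRs
#'
#' Evaluates every candidate (drug, assay group, ADR term) triple against
#' six criteria and flags the triples passing all of them:
#' \enumerate{
#'   \item the drug has a measured AC50 below `ac50_ceiling` micromolar at
#'     the target and the activity is unpublished (not reported in any
#'     external resource and not a mechanism-of-action annotation);
#'   \item the drug is positive for the term in at least one annotation
#'     source;
#'   \item the target-term association is significant (p <= `p_sig`,
#'     AUC >= `auc_gate`) on at least one activity measure;
#'   \item on the most significant such measure, the drug's value lies in
#'     the top three quartiles of potency (value <= 75th percentile)
#'     among drugs active in the assay and positive for the term;
#'   \item none of the drug's mechanism-of-action targets has a
#'     significant association with the same term (the ADR is not already
#'     explained on-target);
#'   \item every known off-target activity of the drug at a target
#'     significantly associated with the term is at least `fold` times
#'     weaker than the new activity.
#' }
#'
#' @param rep_results representative activities carrying
#'   `activity_class` (see [classify_activities()]).
#' @param measures long measure table from [activity_measures()].
#' @param labels training-set labels (long, from [build_training_sets()]).
#' @param sig_assoc significant associations with `assay_group_id`,
#'   `measure`, `cutoff`, `term_code`, `source`, `kw_p`, `roc_auc`
#'   (typically literature-gate rows, p <= 0.001 and AUC >= 0.6).
#' @param assays assay metadata with `group_id`.
#' @param moa long MOA table from [parse_moa()].
#' @param ac50_ceiling criterion-1 ceiling in micromolar.
#' @param fold criterion-6 potency ratio.
#' @param active_cutoff activity definition for the criterion-4 peer set.
#' @return data.frame of evaluated triples with the six criterion flags
#'   and `flagged`.
#' @export
flag_explanations <- function(rep_results, measures, labels, sig_assoc,
                              assays, moa, ac50_ceiling = 5, fold = 10,
                              active_cutoff = 10) {
  grp_target <- stats::setNames(assays$target_gene,
                                assays$group_id)[!duplicated(assays$group_id)]
  target_of <- function(g) unname(grp_target[g])
  rep_results$target_gene <- target_of(rep_results$assay_group_id)
  sig_assoc$target_gene <- target_of(sig_assoc$assay_group_id)
  pos_lab <- labels[labels$label == "pos", ]
  cand <- rep_results[rep_results$qualifier == "=" &
                      rep_results$ac50 < ac50_ceiling &
                      rep_results$activity_class == "unpublished_off_target", ]
  if (!nrow(cand) || !nrow(sig_assoc)) {
    return(data.frame(drug_id = character(), target_gene = character(),
                      assay_group_id = character(), ac50 = numeric(),
                      term_code = character(),
                      c1_unpublished_potent = logical(),
                      c2_drug_positive = logical(), c3_assoc_significant = logical(),
                      c4_top_quartiles = logical(), c5_not_on_target = logical(),
                      c6_known_weaker = logical(), flagged = logical()))
  }
  out <- list()
  for (i in seq_len(nrow(cand))) {
    drug <- cand$drug_id[i]; grp <- cand$assay_group_id[i]
    tgt <- cand$target_gene[i]
    terms <- unique(sig_assoc$term_code[sig_assoc$assay_group_id == grp])
    drug_pos_terms <- unique(pos_lab$term_code[pos_lab$drug_id == drug])
    for (term in terms) {
      sa <- sig_assoc[sig_assoc$assay_group_id == grp &
                      sig_assoc$term_code == term, ]
      c1 <- TRUE
      c2 <- term %in% drug_pos_terms
      c3 <- nrow(sa) > 0
      best <- sa[which.min(sa$kw_p), ]
      c4 <- FALSE
      if (c2 && c3) {
        pos_drugs <- unique(pos_lab$drug_id[pos_lab$term_code == term])
        mv <- measures[measures$assay_group_id == grp &
                       measures$measure == best$measure &
                       measures$qualifier == "=" &
                       measures$drug_id %in% pos_drugs, ]
        act <- mv[mv$value < active_cutoff, ]
        dv <- act$value[act$drug_id == drug]
        if (length(dv))
          c4 <- dv[1] <= stats::quantile(act$value, 0.75, type = 7)
      }
      moa_targets <- moa$target_gene[moa$drug_id == drug]
      c5 <- !any(sig_assoc$term_code == term &
                 sig_assoc$target_gene %in% moa_targets)
      known <- rep_results[rep_results$drug_id == drug &
                           rep_results$activity_class == "known_off_target" &
                           rep_results$qualifier == "=" &
                           rep_results$target_gene %in%
                             sig_assoc$target_gene[sig_assoc$term_code == term], ]
      c6 <- !nrow(known) || all(known$ac50 >= fold * cand$ac50[i])
      out[[length(out) + 1L]] <- data.frame(
        drug_id = drug, target_gene = tgt, assay_group_id = grp,
        ac50 = cand$ac50[i], term_code = term,
        c1_unpublished_potent = c1, c2_drug_positive = c2,
        c3_assoc_significant = c3, c4_top_quartiles = c4,
        c5_not_on_target = c5, c6_known_weaker = c6,
        flagged = c1 && c2 && c3 && c4 && c5 && c6,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- flag_explanations(cand[0, ], measures, labels,
                                             sig_assoc[0, ], assays, moa)
  rownames(res) <- NULL
  res
}
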