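# Construction of per-term ADR training sets: source-specific positives and
# hierarchy-aware negatives.

#' Apply the disproportionality threshold to pharmacovigilance annotations
#'
#' A drug is positive for a term when its likelihood-ratio-test (LRT)
#' score reaches `multiplier` times the drug-specific threshold. Rows
#' without a threshold are dropped (the drug cannot be assessed for that
#' term). Non-FAERS rows pass through unchanged.
#'
#' @param annotations data.frame from [read_adr_annotations()].
#' @param multiplier LRT multiplier (default 5; 2 is the lenient
#'   alternative).
#' @return `annotations` with `positive` filled for FAERS rows.
#' @export
apply_faers_threshold <- function(annotations, multiplier = 5) {
  f <- annotations$source == "FAERS" & !is.na(annotations$lrt)
  drop <- f & is.na(annotations$lrt_threshold)
  if (any(drop)) annotations <- annotations[!drop, ]
  f <- annotations$source == "FAERS" & !is.na(annotations$lrt)
  annotations$positive[f] <- annotations$lrt[f] >=
    multiplier * annotations$lrt_threshold[f]
  annotations
}

#' Roll preferred-term positives up the hierarchy
#'
#' A drug is positive for an HT or HG term iff it is positive for at least
#' one descendant PT.
#'
#' @param pt_positives data.frame with `drug_id`, `term_code` (PT-level
#'   positive annotations).
#' @param hierarchy a [meddra_hierarchy()].
#' @param levels levels to roll up to.
#' @return data.frame with `drug_id`, `term_code`, `level` covering PT
#'   plus the rolled-up levels.
#' @export
rollup_positives <- function(pt_positives, hierarchy,
                             levels = c("HT", "HG")) {
  out <- list(data.frame(drug_id = pt_positives$drug_id,
                         term_code = pt_positives$term_code,
                         level = "PT", stringsAsFactors = FALSE))
  for (lv in levels) {
    for (term in meddra_terms(hierarchy, lv)) {
      pts <- pts_under(hierarchy, term)
      pos <- unique(pt_positives$drug_id[pt_positives$term_code %in% pts])
      if (length(pos))
        out[[length(out) + 1L]] <- data.frame(drug_id = pos, term_code = term,
                                              level = lv,
                                              stringsAsFactors = FALSE)
    }
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Negative drug set for an ADR term
#'
#' Negatives avoid drugs causing a clinically similar reaction: for a PT,
#' drugs positive for the term or for a sister PT under any of its HTs are
#' excluded; for an HT, drugs positive for the (rolled-up) term or a
#' sister HT under any of its HGs; for an HG, any drug positive for a PT
#' beneath it. The remaining drugs are the negatives.
#'
#' @param term_code term whose negatives are wanted.
#' @param hierarchy a [meddra_hierarchy()].
#' @param pt_positives PT-level positive annotations (`drug_id`,
#'   `term_code`).
#' @param all_drugs character vector of the drug universe.
#' @return character vector of negative drug ids.
#' @export
define_negatives <- function(term_code, hierarchy, pt_positives, all_drugs) {
  lv <- meddra_level(hierarchy, term_code)
  pos_for <- function(terms) {
    pts <- unique(unlist(lapply(terms, pts_under, h = hierarchy)))
    unique(pt_positives$drug_id[pt_positives$term_code %in% pts])
  }
  excluded <- switch(lv,
    PT = pos_for(c(term_code, siblings_under_ht(hierarchy, term_code))),
    HT = pos_for(c(term_code, sisters_of(hierarchy, term_code))),
    HG = pos_for(term_code),
    stop("negatives are defined for PT, HT and HG terms only"))
  setdiff(all_drugs, excluded)
}

#' Build all per-term, per-source ADR training sets
#'
#' Derives PT-level positives per source (applying the LRT threshold to
#' FAERS rows), rolls them up to HT and HG, defines hierarchy-aware
#' negatives, and marks each set eligible when it has at least `min_pos`
#' positives and `min_neg` negatives (per-assay activity counts are
#' checked later at association time). Drug forms are treated as distinct
#' drugs: the universe is every row of `drugs`.
#'
#' @param annotations ADR annotations table.
#' @param hierarchy a [meddra_hierarchy()].
#' @param drugs drug metadata table (defines the drug universe).
#' @param min_pos,min_neg eligibility thresholds.
#' @param lrt_multiplier see [apply_faers_threshold()].
#' @return list with `sets` (term x source summary) and `labels` (long
#'   drug-level labels: `"pos"`, `"neg"` or `"excluded"`).
#' @export
build_training_sets <- function(annotations, hierarchy, drugs,
                                min_pos = 10, min_neg = 50,
                                lrt_multiplier = 5) {
  ann <- apply_faers_threshold(annotations, multiplier = lrt_multiplier)
  universe <- drugs$drug_id
  terms <- data.frame(
    term_code = c(meddra_terms(hierarchy, "PT"), meddra_terms(hierarchy, "HT"),
                  meddra_terms(hierarchy, "HG")),
    stringsAsFactors = FALSE)
  terms$level <- meddra_level(hierarchy, terms$term_code)
  sets <- list(); labels <- list()
  for (src in sort(unique(ann$source))) {
    pt_pos <- ann[ann$source == src & ann$positive %in% TRUE,
                  c("drug_id", "term_code")]
    roll <- rollup_positives(pt_pos, hierarchy)
    for (i in seq_len(nrow(terms))) {
      tc <- terms$term_code[i]
      pos <- unique(roll$drug_id[roll$term_code == tc])
      neg <- define_negatives(tc, hierarchy, pt_pos, universe)
      neg <- setdiff(neg, pos)
      excl <- setdiff(universe, c(pos, neg))
      sets[[length(sets) + 1L]] <- data.frame(
        term_code = tc, level = terms$level[i], source = src,
        n_pos = length(pos), n_neg = length(neg),
        eligible = length(pos) >= min_pos && length(neg) >= min_neg,
        stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- data.frame(
        term_code = tc, source = src,
        drug_id = c(pos, neg, excl),
        label = rep(c("pos", "neg", "excluded"),
                    c(length(pos), length(neg), length(excl))),
        stringsAsFactors = FALSE)
    }
  }
  list(sets = do.call(rbind, sets), labels = do.call(rbind, labels))
}
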