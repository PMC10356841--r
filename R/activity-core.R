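# Replicate summarization, assay-group construction, representative-result
# selection and promiscuity.

#' Summarize replicate activity rows per substance x assay
#'
#' Applies [summarize_ac50()] within each (drug, substance, assay) cell of a
#' replicate-level activity table.
#'
#' @param activities data.frame with `drug_id`, `substance_key`, `assay_id`,
#'   `qualifier`, `ac50` (one row per replicate run).
#' @return data.frame with one row per cell and columns `qualifier`, `ac50`,
#'   `n_summarized`, `n_total`.
#' @export
summarize_activities <- function(activities) {
  assert_qualified(activities$qualifier, activities$ac50)
  key <- paste(activities$drug_id, activities$substance_key,
               activities$assay_id, sep = "\r")
  f <- factor(key)
  k <- as.integer(f)
  nk <- nlevels(f)
  measured <- activities$qualifier == "="
  n_total <- tabulate(k, nk)
  n_meas <- tabulate(k[measured], nk)
  # geometric mean of measured values per cell (vectorized summarize_ac50)
  logsum <- as.numeric(rowsum(ifelse(measured, log(activities$ac50), 0),
                              factor(k, levels = seq_len(nk)))[, 1])
  o <- order(k, activities$ac50)
  last <- o[!duplicated(k[o], fromLast = TRUE)]
  vmax <- activities$ac50[last][order(k[last])]
  first <- match(seq_len(nk), k)
  has_meas <- n_meas > 0
  out <- data.frame(
    drug_id = activities$drug_id[first],
    substance_key = activities$substance_key[first],
    assay_id = activities$assay_id[first],
    qualifier = ifelse(has_meas, "=", ">"),
    ac50 = ifelse(has_meas, exp(logsum / pmax(n_meas, 1)), vmax),
    n_summarized = ifelse(has_meas, n_meas, n_total),
    n_total = n_total, stringsAsFactors = FALSE)
  out <- out[order(out$drug_id, out$substance_key, out$assay_id), ]
  rownames(out) <- NULL
  out
}

#' Concordance of two assays measuring the same target and mode
#'
#' Qualitative agreement uses actives defined as measured AC50 < 10
#' micromolar (censored results count as inactive): each assay's
#' sensitivity is the fraction of the other assay's shared actives it also
#' calls active. Quantitative agreement is the Pearson correlation of log
#' AC50 over shared compounds where both results are measured (`"="`).
#' A pair is evaluable with >= `min_overlap` shared compounds, and
#' concordant when both sensitivities reach `min_sens`, the correlation
#' reaches `min_r`, and at least `min_unqualified` measured pairs support
#' it.
#'
#' @param res_a,res_b data.frames with `drug_id`, `qualifier`, `ac50`
#'   (one summarized result per compound) for the two assays.
#' @param active_cutoff qualitative activity cutoff (micromolar).
#' @param min_overlap minimum shared compounds to evaluate the pair.
#' @param min_unqualified minimum measured/measured pairs for the correlation.
#' @param min_sens,min_r concordance thresholds.
#' @return one-row data.frame (`n_overlap`, `sens_a`, `sens_b`, `pearson_r`,
#'   `n_unqualified_pairs`, `evaluable`, `concordant`).
#' @export
assess_concordance <- function(res_a, res_b, active_cutoff = 10,
                               min_overlap = 10, min_unqualified = 10,
                               min_sens = 0.5, min_r = 0.7) {
  shared <- intersect(res_a$drug_id, res_b$drug_id)
  a <- res_a[match(shared, res_a$drug_id), ]
  b <- res_b[match(shared, res_b$drug_id), ]
  act_a <- a$qualifier == "=" & a$ac50 < active_cutoff
  act_b <- b$qualifier == "=" & b$ac50 < active_cutoff
  both <- sum(act_a & act_b)
  sens_a <- if (sum(act_a)) both / sum(act_a) else NA_real_
  sens_b <- if (sum(act_b)) both / sum(act_b) else NA_real_
  meas <- a$qualifier == "=" & b$qualifier == "="
  r <- if (sum(meas) >= 2 && stats::sd(log(a$ac50[meas])) > 0 &&
           stats::sd(log(b$ac50[meas])) > 0)
    stats::cor(log(a$ac50[meas]), log(b$ac50[meas])) else NA_real_
  evaluable <- length(shared) >= min_overlap
  concordant <- isTRUE(evaluable && !is.na(sens_a) && !is.na(sens_b) &&
                       !is.na(r) && sens_a >= min_sens && sens_b >= min_sens &&
                       r >= min_r && sum(meas) >= min_unqualified)
  data.frame(n_overlap = length(shared), sens_a = sens_a, sens_b = sens_b,
             pearson_r = r, n_unqualified_pairs = sum(meas),
             evaluable = evaluable, concordant = concordant)
}

#' Concordance results for every same-target, same-mode assay pair
#'
#' @param summarized substance-level summarized activities
#'   (from [summarize_activities()]).
#' @param assays assay metadata table.
#' @param ... passed to [assess_concordance()].
#' @return data.frame with one row per evaluated pair (`assay_a`, `assay_b`
#'   ordered lexicographically) plus the concordance fields.
#' @export
concordance_table <- function(summarized, assays, ...) {
  by_assay <- split(summarized, summarized$assay_id)
  out <- list()
  key <- paste(assays$target_gene, assays$mode)
  for (k in unique(key)) {
    ids <- sort(assays$assay_id[key == k])
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) for (j in seq(i + 1, length(ids))) {
      ra <- by_assay[[ids[i]]]; rb <- by_assay[[ids[j]]]
      if (is.null(ra) || is.null(rb)) next
      cc <- assess_concordance(ra, rb, ...)
      out[[length(out) + 1L]] <- cbind(
        data.frame(assay_a = ids[i], assay_b = ids[j],
                   stringsAsFactors = FALSE), cc)
    }
  }
  if (!length(out))
    return(data.frame(assay_a = character(), assay_b = character(),
                      n_overlap = integer(), sens_a = numeric(),
                      sens_b = numeric(), pearson_r = numeric(),
                      n_unqualified_pairs = integer(), evaluable = logical(),
                      concordant = logical()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Merge assays into concordance groups and pick the preferred assay
#'
#' Assays are nodes; concordant pairs are edges; the groups are the
#' connected components, so two assays may end up in one group through a
#' chain even if their direct pair was not evaluable. Within each group the
#' assay supplying the most summarized results is preferred; ties resolve
#' to the lexicographically smallest assay id.
#'
#' @param assays assay metadata table.
#' @param concordance output of [concordance_table()].
#' @param summarized summarized activities, used to count results per assay.
#' @return `assays` with `group_id` (named after the smallest member assay)
#'   and `is_preferred` columns replaced.
#' @export
build_assay_groups <- function(assays, concordance, summarized) {
  edges <- concordance[concordance$concordant, c("assay_a", "assay_b")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = assays$assay_id))
  comp <- igraph::components(g)$membership
  member <- split(names(comp), comp)
  group_of <- stats::setNames(
    rep(vapply(member, function(m) paste0("grp_", min(m)), ""), lengths(member)),
    unlist(member))
  assays$group_id <- unname(group_of[assays$assay_id])
  counts <- table(summarized$assay_id)
  n_res <- as.integer(counts[assays$assay_id])
  n_res[is.na(n_res)] <- 0L
  assays$is_preferred <- FALSE
  for (gid in unique(assays$group_id)) {
    i <- which(assays$group_id == gid)
    best <- i[order(-n_res[i], assays$assay_id[i])][1]
    assays$is_preferred[best] <- TRUE
  }
  assays
}

#' Select the representative activity record for one drug x assay group
#'
#' Precedence: (1) results measured on an active metabolite of the drug
#' beat results on the parent form; (2) better (lower) structure-match
#' quality level; (3) the group's preferred assay; (4) lexicographically
#' smallest substance key, then assay id, for determinism.
#'
#' @param candidates data.frame with at least `is_metabolite`,
#'   `match_level`, `assay_is_preferred`, `substance_key`, `assay_id`.
#' @return the selected row of `candidates`.
#' @export
select_representative <- function(candidates) {
  stopifnot(nrow(candidates) >= 1)
  o <- order(-candidates$is_metabolite, candidates$match_level,
             -candidates$assay_is_preferred, candidates$substance_key,
             candidates$assay_id)
  candidates[o[1], , drop = FALSE]
}

#' Representative activities per parent drug x assay group
#'
#' Collapses substance forms (parent, salts/lots, active metabolites) and
#' within-group assays to a single record per prescribed drug and assay
#' group, using [select_representative()].
#'
#' @param summarized summarized substance-level activities.
#' @param drugs drug metadata (with `parent_id`, `is_active_metabolite`).
#' @param assays assay metadata with `group_id`/`is_preferred` assigned.
#' @param matches optional structure-match table (`query_key`, `level`) from
#'   [match_structures()]; unmatched keys default to level 1.
#' @return data.frame keyed by (`drug_id`, `assay_group_id`) with the chosen
#'   qualified AC50 and `is_representative = TRUE`.
#' @export
representative_activities <- function(summarized, drugs, assays,
                                      matches = NULL) {
  parent <- stats::setNames(drugs$parent_id, drugs$drug_id)
  metab <- stats::setNames(drugs$is_active_metabolite, drugs$drug_id)
  s <- summarized
  s$parent_drug <- unname(parent[s$drug_id])
  s$parent_drug[is.na(s$parent_drug)] <- s$drug_id[is.na(s$parent_drug)]
  s$is_metabolite <- unname(metab[s$drug_id])
  s$is_metabolite[is.na(s$is_metabolite)] <- FALSE
  ai <- match(s$assay_id, assays$assay_id)
  s$assay_group_id <- assays$group_id[ai]
  s$assay_is_preferred <- assays$is_preferred[ai]
  key <- stats::setNames(drugs$structure_key, drugs$drug_id)
  s$match_level <- 1L
  if (!is.null(matches)) {
    lv <- stats::setNames(matches$level, matches$query_key)
    ml <- lv[unname(key[s$drug_id])]
    s$match_level <- ifelse(is.na(ml), 1L, as.integer(ml))
  }
  cells <- split(seq_len(nrow(s)), paste(s$parent_drug, s$assay_group_id,
                                         sep = "\r"))
  out <- do.call(rbind, lapply(cells, function(i) select_representative(s[i, ])))
  out <- data.frame(drug_id = out$parent_drug,
                    substance_key = out$substance_key,
                    assay_id = out$assay_id,
                    assay_group_id = out$assay_group_id,
                    qualifier = out$qualifier, ac50 = out$ac50,
                    n_summarized = out$n_summarized, n_total = out$n_total,
                    is_representative = TRUE, stringsAsFactors = FALSE)
  out <- out[order(out$drug_id, out$assay_group_id), ]
  rownames(out) <- NULL
  out
}

#' Drug promiscuity
#'
#' Fraction of tested assay groups in which the drug shows a measured AC50
#' below `cutoff` micromolar. Drugs with no tested group are omitted.
#'
#' @param rep_results representative activities
#'   (from [representative_activities()]).
#' @param cutoff activity cutoff in micromolar.
#' @return data.frame with `drug_id`, `n_active`, `n_tested`, `promiscuity`.
#' @export
compute_promiscuity <- function(rep_results, cutoff = 10) {
  act <- rep_results$qualifier == "=" & rep_results$ac50 < cutoff
  n_tested <- tapply(act, rep_results$drug_id, length)
  n_active <- tapply(act, rep_results$drug_id, sum)
  data.frame(drug_id = names(n_tested),
             n_active = as.integer(n_active),
             n_tested = as.integer(n_tested),
             promiscuity = as.numeric(n_active / n_tested),
             row.names = NULL, stringsAsFactors = FALSE)
}
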