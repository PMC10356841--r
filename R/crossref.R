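# Structure-key matching to external resources, external activity
# summarization, and modeling of panel-vs-literature activity differences.

#' Parse a three-block hashed structure key
#'
#' Keys are 27 characters in three hyphen-separated blocks of 14, 10 and 1
#' character(s): molecular graph, remaining layers, and protonation state.
#'
#' @param key character vector of keys.
#' @return data.frame with `graph`, `layers`, `protonation` and a `valid`
#'   flag (malformed keys yield `valid = FALSE`).
#' @export
parse_structure_key <- function(key) {
  parts <- strsplit(key, "-", fixed = TRUE)
  ok <- lengths(parts) == 3L &
    vapply(parts, function(p) length(p) == 3L && nchar(p[1]) == 14L &&
             nchar(p[2]) == 10L && nchar(p[3]) == 1L, TRUE)
  get <- function(i) vapply(parts, function(p)
    if (length(p) == 3L) p[i] else NA_character_, "")
  data.frame(graph = get(1), layers = get(2), protonation = get(3),
             valid = ok, stringsAsFactors = FALSE)
}

norm_names <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE),
         function(n) unique(tolower(trimws(n[nzchar(n)]))))
}

#' Match structure keys to a reference table at decreasing stringency
#'
#' Level 1: full 27-character key equality. Level 2: equality ignoring the
#' protonation block. Level 3: graph-block equality plus a shared
#' (case-insensitive) name or synonym. Level 4: name-only match, flagged
#' `needs_review`. Each query reports the best (lowest) achievable level;
#' ties among references at that level resolve to the smallest
#' `reference_id`. Malformed query keys are skipped with a warning (they can
#' still match at level 4 by name).
#'
#' @param query data.frame with `query_key` and `names` (pipe-separated
#'   synonyms).
#' @param reference data.frame with `reference_id`, `key`, `names`.
#' @return data.frame with `query_key`, `reference_id`, `level`,
#'   `needs_review` (unmatched queries are absent).
#' @export
match_structures <- function(query, reference) {
  qp <- parse_structure_key(query$query_key)
  rp <- parse_structure_key(reference$key)
  if (any(!qp$valid))
    warning("skipping malformed query key(s): ",
            paste(query$query_key[!qp$valid], collapse = ", "))
  qn <- norm_names(query$names)
  rn <- norm_names(reference$names)
  ref_by_name <- split(rep(seq_len(nrow(reference)), lengths(rn)), unlist(rn))
  out <- vector("list", nrow(query))
  for (i in seq_len(nrow(query))) {
    hit <- NULL
    name_refs <- sort(unique(unlist(ref_by_name[qn[[i]]], use.names = FALSE)))
    if (qp$valid[i]) {
      l1 <- which(reference$key == query$query_key[i])
      l2 <- which(rp$valid & rp$graph == qp$graph[i] & rp$layers == qp$layers[i])
      l3 <- intersect(which(rp$valid & rp$graph == qp$graph[i]), name_refs)
      if (length(l1)) hit <- c(l1[order(reference$reference_id[l1])][1], 1L)
      else if (length(l2)) hit <- c(l2[order(reference$reference_id[l2])][1], 2L)
      else if (length(l3)) hit <- c(l3[order(reference$reference_id[l3])][1], 3L)
    }
    if (is.null(hit) && length(name_refs))
      hit <- c(name_refs[order(reference$reference_id[name_refs])][1], 4L)
    if (!is.null(hit))
      out[[i]] <- data.frame(query_key = query$query_key[i],
                             reference_id = reference$reference_id[hit[1]],
                             level = hit[2], needs_review = hit[2] == 4L,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(query_key = character(), reference_id = character(),
                      level = integer(), needs_review = logical())
  rownames(out) <- NULL
  out
}

#' Summarize external activity records per drug x human gene
#'
#' External (literature-curated) records are pooled per drug and human
#' gene -- non-human genes are first mapped to their human ortholog -- and
#' summarized as the median, separately for AC50 records (micromolar) and
#' single-concentration percent-activity records.
#'
#' @param external data.frame with `drug_id`, `gene`, `value` and `type`
#'   (`"ac50"` or `"single_conc"`).
#' @param ortholog_map optional data.frame with `gene`, `human_gene`.
#' @return data.frame with `drug_id`, `target_gene`, `median_ac50`,
#'   `median_single_conc`, `n_ac50`, `n_single_conc`.
#' @export
summarize_external <- function(external, ortholog_map = NULL) {
  gene <- external$gene
  if (!is.null(ortholog_map)) {
    hm <- stats::setNames(ortholog_map$human_gene, ortholog_map$gene)
    mapped <- unname(hm[gene])
    gene <- ifelse(is.na(mapped), gene, mapped)
  }
  key <- paste(external$drug_id, gene, sep = "\r")
  cells <- split(seq_len(nrow(external)), key)
  rows <- lapply(cells, function(i) {
    v <- external$value[i]; ty <- external$type[i]
    data.frame(drug_id = external$drug_id[i[1]], target_gene = gene[i[1]],
               median_ac50 = if (any(ty == "ac50"))
                 stats::median(v[ty == "ac50"]) else NA_real_,
               median_single_conc = if (any(ty == "single_conc"))
                 stats::median(v[ty == "single_conc"]) else NA_real_,
               n_ac50 = sum(ty == "ac50"),
               n_single_conc = sum(ty == "single_conc"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a micromolar AC50 to pAC50
#'
#' `pAC50 = -log10(AC50 in molar)`, so 1 micromolar gives 6.
#'
#' @param ac50_um AC50 in micromolar.
#' @return pAC50.
#' @export
pac50 <- function(ac50_um) 6 - log10(ac50_um)

#' Assemble the panel-vs-external activity-difference dataset
#'
#' Matches panel results to individual external records for the same drug
#' and gene, keeping only pairs measured (`"="`) in both sources, converts
#' both to pAC50, and computes the absolute difference. Categorical
#' covariate levels can be merged (`merges`), and rows carrying a covariate
#' level supported by fewer than `min_support` pairs are dropped.
#'
#' @param panel panel results: `drug_id`, `target_gene`, `qualifier`, `ac50`
#'   plus covariate columns prefixed `cov_`.
#' @param ext external records: `drug_id`, `gene`, `qualifier`, `ac50` plus
#'   `cov_` columns; optional `same_species` (1/0).
#' @param min_support minimum pairs per covariate level.
#' @param merges named list: for covariate `cov_x`, a named character
#'   vector mapping old level -> merged level.
#' @return data.frame with `panel_pac50`, `ext_pac50`, `abs_delta`,
#'   `same_species` and the covariate columns.
#' @export
build_delta_dataset <- function(panel, ext, min_support = 500,
                                merges = list()) {
  panel <- panel[panel$qualifier == "=", ]
  ext <- ext[ext$qualifier == "=", ]
  m <- merge(panel, ext, by.x = c("drug_id", "target_gene"),
             by.y = c("drug_id", "gene"), suffixes = c("_panel", "_ext"))
  if (!nrow(m)) return(m)
  m$panel_pac50 <- pac50(m$ac50_panel)
  m$ext_pac50 <- pac50(m$ac50_ext)
  m$abs_delta <- abs(m$panel_pac50 - m$ext_pac50)
  if (!"same_species" %in% names(m)) m$same_species <- 1
  cov_cols <- grep("^cov_", names(m), value = TRUE)
  for (cc in intersect(names(merges), cov_cols)) {
    mp <- merges[[cc]]
    hit <- m[[cc]] %in% names(mp)
    m[[cc]][hit] <- unname(mp[m[[cc]][hit]])
  }
  keep <- rep(TRUE, nrow(m))
  for (cc in cov_cols) {
    supp <- table(m[[cc]])
    keep <- keep & m[[cc]] %in% names(supp)[supp >= min_support]
  }
  out <- m[keep, c("drug_id", "target_gene", "panel_pac50", "ext_pac50",
                   "abs_delta", "same_species", cov_cols)]
  rownames(out) <- NULL
  out
}

dummy_encode <- function(df, cols) {
  mats <- lapply(cols, function(cc) {
    lv <- sort(unique(df[[cc]]))
    m <- outer(df[[cc]], lv, `==`) * 1
    colnames(m) <- paste(cc, lv, sep = ".")
    m
  })
  do.call(cbind, mats)
}

#' Model panel-vs-external activity differences
#'
#' Fits an L1-penalized linear model of the absolute pAC50 difference on
#' the continuous pAC50s, the same-species indicator and dummy-encoded
#' categorical covariates, selects the 1-SE model by repeated holdout
#' cross-validation, and retains variables with `|coefficient| >=
#' coef_threshold` in that model. Constant columns are dropped with a
#' warning.
#'
#' @param deltas output of [build_delta_dataset()].
#' @param coef_threshold retention threshold on the absolute coefficient.
#' @param n_trials,holdout,seed cross-validation settings, see
#'   [fit_1se_lasso()].
#' @return list with the `sparse_fit` object and `retained`, a named vector
#'   of retained coefficients.
#' @export
model_activity_differences <- function(deltas, coef_threshold = 0.1,
                                       n_trials = 50, holdout = 0.2,
                                       seed = 1) {
  cov_cols <- grep("^cov_", names(deltas), value = TRUE)
  x <- cbind(panel_pac50 = deltas$panel_pac50, ext_pac50 = deltas$ext_pac50,
             same_species = deltas$same_species,
             if (length(cov_cols)) dummy_encode(deltas, cov_cols))
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  fit <- fit_1se_lasso(x, deltas$abs_delta, family = "gaussian",
                       n_trials = n_trials, holdout = holdout, seed = seed)
  cf <- fit$coefficients
  list(fit = fit, retained = cf[abs(cf) >= coef_threshold])
}
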