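# Shared fixture builders. Everything is generated in code; no data files.

toy_hierarchy <- function() {
  # 4 PTs / 2 HTs / 1 HG / 1 SOC, with PT04 also under HT1 (DAG case)
  meddra_hierarchy(data.frame(
    child_code = c("PT01", "PT02", "PT03", "PT04", "PT04",
                   "HT1", "HT2", "HG1"),
    parent_code = c("HT1", "HT1", "HT2", "HT2", "HT1",
                    "HG1", "HG1", "SOC1"),
    child_level = c("PT", "PT", "PT", "PT", "PT", "HT", "HT", "HG"),
    parent_level = c("HT", "HT", "HT", "HT", "HT", "HG", "HG", "SOC"),
    stringsAsFactors = FALSE))
}

# Random layered DAG for brute-force comparison of hierarchy queries.
random_hierarchy <- function(n_pt = 40, n_ht = 12, n_hg = 5, n_soc = 2,
                             multi_frac = 0.15) {
  pt <- sprintf("P%03d", seq_len(n_pt)); ht <- sprintf("H%03d", seq_len(n_ht))
  hg <- sprintf("G%02d", seq_len(n_hg)); soc <- sprintf("S%d", seq_len(n_soc))
  e <- rbind(
    data.frame(child_code = pt, parent_code = sample(ht, n_pt, TRUE),
               child_level = "PT", parent_level = "HT"),
    data.frame(child_code = ht, parent_code = sample(hg, n_ht, TRUE),
               child_level = "HT", parent_level = "HG"),
    data.frame(child_code = hg, parent_code = sample(soc, n_hg, TRUE),
               child_level = "HG", parent_level = "SOC"))
  extra <- pt[runif(n_pt) < multi_frac]
  if (length(extra))
    e <- rbind(e, data.frame(child_code = extra,
                             parent_code = sample(ht, length(extra), TRUE),
                             child_level = "PT", parent_level = "HT"))
  e <- unique(e)
  meddra_hierarchy(e)
}

# Brute-force ancestor scan on the raw edge list, for oracle comparisons.
brute_ancestors <- function(edges, code, level) {
  found <- character(); frontier <- code
  repeat {
    up <- unique(edges$parent_code[edges$child_code %in% frontier])
    up <- setdiff(up, found)
    if (!length(up)) break
    found <- c(found, up); frontier <- up
  }
  lv <- unique(rbind(data.frame(code = edges$child_code, l = edges$child_level),
                     data.frame(code = edges$parent_code, l = edges$parent_level)))
  sort(found[found %in% lv$code[lv$l == level]])
}

brute_descendants <- function(edges, code, level) {
  found <- character(); frontier <- code
  repeat {
    dn <- unique(edges$child_code[edges$parent_code %in% frontier])
    dn <- setdiff(dn, found)
    if (!length(dn)) break
    found <- c(found, dn); frontier <- dn
  }
  lv <- unique(rbind(data.frame(code = edges$child_code, l = edges$child_level),
                     data.frame(code = edges$parent_code, l = edges$parent_level)))
  sort(found[found %in% lv$code[lv$l == level]])
}

small_sim_config <- function(n_causal = 3, ...) {
  sim_config(n_drugs = 200, n_assays = 16, duplicate_assay_targets = 2,
             n_pt = 20, n_ht = 8, n_hg = 4, n_soc = 2, n_causal = n_causal,
             ...)
}

# Exact Kruskal-Wallis p by enumerating every same-sized 2-group split.
kw_exact_p <- function(pos, neg) {
  v <- c(pos, neg); n <- length(v); n1 <- length(pos)
  r <- rank(v)
  stat <- function(idx) {
    R1 <- sum(r[idx])
    H <- 12 / (n * (n + 1)) * (R1^2 / n1 + (sum(r) - R1)^2 / (n - n1)) -
      3 * (n + 1)
    ties <- table(v)
    H / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  H_obs <- stat(seq_len(n1))
  cs <- utils::combn(n, n1)
  Hs <- apply(cs, 2, stat)
  mean(Hs >= H_obs - 1e-9)
}

# O(n^2) pairwise ROC AUC oracle on the potency scale.
auc_brute <- function(pos, neg) {
  sp <- -log10(pos); sn <- -log10(neg)
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
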