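#!/usr/bin/env Rscript
# Prior-likelihood model: which literature-style target-ADR associations
# can this dataset validate at all? Features summarize each assay's
# truncated AC50 distribution (low percentiles, potent-result counts),
# the training-set size, and the ADR's system-organ-class membership;
# labels are AC50-only significance (p <= 0.001, AUC >= 0.6). A 1-SE
# lasso logistic model assigns each association a likely-significant /
# likely-non-significant class at probability 0.5.

library(targetadr)

bundle <- read_bundle("results/bundle")
assoc <- utils::read.delim("results/associations.tsv")
groups <- utils::read.delim("results/assay_groups.tsv")
rep_act <- read_activity_table("results/representative_activities.tsv")
rep_act$assay_group_id <- groups$group_id[match(rep_act$assay_id,
                                                groups$assay_id)]
sets <- utils::read.delim("results/training_sets.tsv")

# association universe: every (assay group, PT term) tested on AC50;
# the planted map is the "literature" subset of interest
ac <- assoc[assoc$measure == "ac50" & assoc$tested & assoc$level == "PT" &
              assoc$source == "SIDER", ]
feats <- list(); labs <- logical()
for (i in seq_len(nrow(ac))) {
  grp <- ac$assay_group_id[i]
  cut <- ac$cutoff[i]
  sub <- rep_act[rep_act$assay_group_id == grp &
                   !(rep_act$qualifier == ">" & rep_act$ac50 < cut), ]
  v <- pmin(sub$ac50, cut)
  st <- sets[sets$term_code == ac$term_code[i] & sets$source == "SIDER", ]
  feats[[i]] <- featurize_literature_assoc(v, ac$term_code[i],
                                           bundle$hierarchy,
                                           n_pos = st$n_pos[1],
                                           n_neg = st$n_neg[1])
  labs[i] <- ac$kw_p[i] <= 0.001 & ac$roc_auc[i] >= 0.6
}
x <- do.call(rbind, feats)
pm <- fit_prior_model(x, labs, seed = 1)

out <- data.frame(ac[, c("assay_group_id", "term_code")],
                  significant = labs, probability = pm$probability,
                  class = pm$class)
write_tsv(out, "results/prior_model_classes.tsv")

cat(sprintf("%d (assay, PT) associations featurized; %d significant on AC50 gates\n",
            nrow(out), sum(labs)))
agree <- mean((pm$class == "likely_significant") == labs)
cat(sprintf("prior-model class agreement with observed significance: %.2f\n",
            agree))
if (!is.null(pm$fit)) {
  nz <- pm$fit$coefficients[pm$fit$coefficients != 0]
  cat("non-zero prior-model coefficients:\n")
  print(round(nz, 3))
}
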