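#!/usr/bin/env Rscript
# De-confound the univariately significant associations: for every ADR
# term with several candidate (assay group, measure) predictors, fit a
# 1-SE lasso logistic model of the ADR labels on log10 activity values
# and keep only the non-redundant predictors (coefficient < -0.08);
# then score recovery of the planted causal map.

library(targetadr)

bundle <- read_bundle("results/bundle")
sig <- utils::read.delim("results/significant_associations.tsv",
                         colClasses = "character")
assoc <- utils::read.delim("results/associations.tsv")
cutoff_sel <- utils::read.delim("results/cutoff_selection.tsv")
rep_act <- read_activity_table("results/representative_activities.tsv")
groups <- utils::read.delim("results/assay_groups.tsv")
rep_act$assay_group_id <- groups$group_id[match(rep_act$assay_id,
                                                groups$assay_id)]
exposure <- utils::read.delim("results/exposure_summary.tsv")
labels <- utils::read.delim("results/training_labels.tsv",
                            colClasses = "character")

measures <- activity_measures(rep_act, exposure)
trunc <- truncated_measure_values(measures, cutoff_sel)
nr <- eliminate_redundant(sig[, c("term_code", "source", "assay_group_id",
                                  "measure")],
                          trunc, labels, seed = 1)
write_tsv(nr$pairs, "results/nonredundant_pairs.tsv")

st <- table(nr$pairs$status)
cat(sprintf("%d candidate pairs -> %d retained, %d eliminated as redundant\n",
            nrow(nr$pairs), st["retained"],
            ifelse(is.na(st["eliminated"]), 0, st["eliminated"])))

assays_g <- merge(bundle$assays, groups)
rec <- evaluate_recovery(nr$pairs, bundle$ground_truth, assays_g,
                         bundle$hierarchy)
cat(sprintf("planted-map recovery: precision %.2f, recall %.2f (%d predicted PT pairs, %d planted)\n",
            rec$precision, rec$recall, rec$n_predicted, rec$n_planted))
write_tsv(rec$predicted, "results/recovered_pairs.tsv")
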