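#!/usr/bin/env Rscript
# Flag unpublished off-target activities that may explain known drug
# ADRs: a measured AC50 below 5 uM at a target absent from the external
# resources, for a drug positive for an ADR term whose target association
# is significant, with the drug's potency in the top three quartiles of
# active ADR-positive drugs, no on-target explanation, and any known
# off-target explanation at least 10-fold weaker.

library(targetadr)

bundle <- read_bundle("results/bundle")
margins <- utils::read.delim("results/margins.tsv",
                             colClasses = "character")
for (cc in c("ac50", "total_margin", "free_margin"))
  margins[[cc]] <- as.numeric(margins[[cc]])
groups <- utils::read.delim("results/assay_groups.tsv")
labels <- utils::read.delim("results/training_labels.tsv",
                            colClasses = "character")
assoc <- utils::read.delim("results/associations_all_cutoffs.tsv")
exposure <- utils::read.delim("results/exposure_summary.tsv")

assays_g <- merge(bundle$assays, groups)
rep_like <- margins[, c("drug_id", "assay_group_id", "qualifier", "ac50",
                        "activity_class")]
measures <- activity_measures(
  cbind(rep_like[, c("drug_id", "assay_group_id", "qualifier", "ac50")]),
  exposure)
lit_sig <- assoc[assoc$tested & assoc$kw_p <= 0.001 & assoc$roc_auc >= 0.6, ]

ex <- flag_explanations(rep_like, measures, labels, lit_sig, assays_g,
                        parse_moa(bundle$drugs))
write_tsv(ex, "results/explanations.tsv")

flagged <- ex[ex$flagged, ]
cat(sprintf("%d candidate (drug, target, ADR) triples evaluated; %d flagged\n",
            nrow(ex), nrow(flagged)))
if (nrow(flagged)) {
  tab <- sort(table(flagged$target_gene), decreasing = TRUE)
  cat("flagged triples by target:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  print(utils::head(flagged[, c("drug_id", "target_gene", "ac50",
                                "term_code")], 10))
}
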