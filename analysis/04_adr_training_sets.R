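#!/usr/bin/env Rscript
# Build per-term, per-source ADR training sets: PT-level positives
# (FAERS positivity at LRT >= 5x the drug-specific threshold), rollup to
# HT and HG, and hierarchy-aware negatives that exclude drugs positive
# for sibling terms.

library(targetadr)

bundle <- read_bundle("results/bundle")
training <- build_training_sets(bundle$adr_annotations, bundle$hierarchy,
                                bundle$drugs)

write_tsv(training$sets, "results/training_sets.tsv")
write_tsv(training$labels, "results/training_labels.tsv")

cat(sprintf("%d (term, source) training sets; %d eligible (>=10 pos, >=50 neg)\n",
            nrow(training$sets), sum(training$sets$eligible)))
by_lvl <- tapply(training$sets$eligible, training$sets$level, sum)
cat("eligible by level:",
    paste(names(by_lvl), by_lvl, sep = "=", collapse = ", "), "\n")
excl <- training$labels$label == "excluded"
cat(sprintf("sibling exclusion removed %.1f drugs per PT set on average\n",
            mean(tapply(excl, paste(training$labels$term_code,
                                    training$labels$source), sum))))
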