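#!/usr/bin/env Rscript
# Summarize replicate qualified AC50s per substance x assay, merge
# concordant protocols into assay groups, and pick one representative
# result per prescribed drug x assay group (active-metabolite results
# representing the parent drug).

library(targetadr)

bundle <- read_bundle("results/bundle")

summarized <- summarize_activities(bundle$activities)
conc <- concordance_table(summarized, bundle$assays)
assays <- build_assay_groups(bundle$assays, conc, summarized)
matches <- match_structures(
  data.frame(query_key = bundle$drugs$structure_key,
             names = bundle$drugs$names, stringsAsFactors = FALSE),
  bundle$reference_structures)
rep_act <- representative_activities(summarized, bundle$drugs, assays,
                                     matches)

write_tsv(summarized, "results/summarized_activities.tsv")
write_tsv(conc, "results/concordance.tsv")
write_tsv(assays[, c("assay_id", "group_id", "is_preferred")],
          "results/assay_groups.tsv")
write_tsv(matches, "results/structure_matches.tsv")
write_tsv(rep_act, "results/representative_activities.tsv")

n_groups <- length(unique(assays$group_id))
cat(sprintf("%d replicate rows -> %d summarized pairs -> %d representative records\n",
            nrow(bundle$activities), nrow(summarized), nrow(rep_act)))
cat(sprintf("%d assays merged into %d assay groups (%d concordant pairs of %d evaluable)\n",
            nrow(assays), n_groups, sum(conc$concordant),
            sum(conc$evaluable)))
cat(sprintf("structure matches: %s\n",
            paste(names(table(matches$level)), table(matches$level),
                  sep = ":", collapse = " ")))
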