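#!/usr/bin/env Rscript
# Compile per-drug exposure (3rd-quartile summaries, free Cmax), classify
# each representative activity as on-target / known off-target /
# unpublished off-target, compute safety margins, and flag physiologically
# relevant activities (measured free margin <= 10).

library(targetadr)

bundle <- read_bundle("results/bundle")
rep_act <- read_activity_table("results/representative_activities.tsv")
assays <- merge(bundle$assays[, setdiff(names(bundle$assays),
                                        c("group_id", "is_preferred"))],
                utils::read.delim("results/assay_groups.tsv"))
rep_act$assay_group_id <- assays$group_id[match(rep_act$assay_id,
                                                assays$assay_id)]

exposure <- compile_exposure(bundle$exposure)
ext_sum <- summarize_external(bundle$external_activities)
classed <- classify_activities(rep_act, assays, parse_moa(bundle$drugs),
                               ext_sum)
margins <- margin_table(classed, exposure)
prom <- compute_promiscuity(rep_act)

write_tsv(exposure, "results/exposure_summary.tsv")
write_tsv(ext_sum, "results/external_summaries.tsv")
write_tsv(margins, "results/margins.tsv")
write_tsv(prom, "results/promiscuity.tsv")

cat(sprintf("free Cmax available for %d of %d drugs\n",
            sum(!is.na(exposure$cmax_free)), nrow(exposure)))
has_m <- !is.na(margins$free_margin)
cat(sprintf("%d drug x assay-group free margins computed\n", sum(has_m)))
med <- tapply(margins$free_margin[has_m & margins$qualifier == "="],
              margins$activity_class[has_m & margins$qualifier == "="],
              median)
cat("median measured free margin by class:",
    paste(names(med), round(med, 1), sep = "=", collapse = ", "), "\n")
phys <- table(margins$activity_class[margins$physiological])
cat("physiological activities (free margin <= 10):",
    paste(names(phys), phys, sep = "=", collapse = ", "), "\n")
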