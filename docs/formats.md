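# Table formats

All tables are UTF-8, tab-separated with a header row; missing values are
empty strings; concentrations are micromolar. Readers live in `R/io.R`
(`read_activity_table()`, `read_assay_table()`, ...); `read_bundle()` /
`write_bundle()` handle a whole directory.

## activities.tsv
One row per substance × assay result (replicate-level or summarized).

| column | type | notes |
|---|---|---|
| drug_id | chr | drug form identifier |
| substance_key | chr | 27-character three-block hashed structure key |
| assay_id | chr | |
| qualifier | chr | `=` measured, `>` censored at the stored value |
| ac50 | num | > 0, micromolar |
| n_summarized | int | optional; replicates averaged |
| n_total | int | optional; all replicates (≥ n_summarized) |
| is_representative | lgl | optional |

## assays.tsv
`assay_id`, `target_gene`, `mode` (binding/inhibition/agonist/antagonist),
`species`, `protein_class`, `event`, `format`, `readout`, `max_conc`
(10 or 30), optional `group_id`, `is_preferred` (exactly one per group).

## drugs.tsv
`drug_id`, `parent_id` (empty = itself), `structure_key`, `names`
(pipe-separated synonyms), `moa` (pipe-separated `GENE:action` pairs),
`is_active_metabolite`.

## exposure.tsv
Long format: `drug_id`, `quantity` (`cmax_tot` in µM or `ppb_pct` in
percent bound), `value`, optional `binding_label` (albumin/glycoprotein
rows are excluded from PPB summaries), optional `source`.

## adr_annotations.tsv
`drug_id`, `term_code` (PT), `source` (SIDER/FAERS), optional `positive`,
optional `lrt` + `lrt_threshold` (FAERS disproportionality score and
drug-specific threshold; positive ⇔ lrt ≥ multiplier × threshold).

## meddra_edges.tsv
`child_code`, `parent_code`, `child_level`, `parent_level` with levels in
{PT, HT, HG, SOC}, strictly increasing along every edge; the hierarchy is
a DAG (multi-parent terms allowed).

## external_activities.tsv
`drug_id`, `gene`, `value`, `type` (`ac50` in µM or `single_conc` in %),
`qualifier`, `source`.

## reference_structures.tsv
`reference_id`, `key`, `names` — the external structure table that
`match_structures()` resolves drug keys against.

## ground_truth.tsv (synthetic bundles)
`assay_id`, `target_gene`, `term_code`, `effect`, `decoy_assay_id`,
`decoy_target` — the planted causal map used for recovery scoring.

## Main outputs (under results/)
`assay_groups.tsv` (assay_id, group_id, is_preferred),
`representative_activities.tsv`, `margins.tsv` (margins, activity class,
physiological/indeterminate flags), `training_sets.tsv` +
`training_labels.tsv`, `associations.tsv` (one row per tested
assay-group × measure × cutoff × term × source),
`cutoff_selection.tsv`, `nonredundant_pairs.tsv` (retained/eliminated
with coefficients), `prior_model_classes.tsv`, `explanations.tsv`
(six criterion flags per drug–target–ADR triple).
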