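# targetadr

Mining target–adverse-drug-reaction (ADR) associations from in vitro
secondary pharmacology panels.

Secondary pharmacology panels profile drugs against batteries of
biochemical and cellular assays, reporting qualified AC50 values
(`=` measured, `>` right-censored at the top tested concentration, 10 or
30 µM). This package implements the analysis chain that turns such panel
data, human exposure estimates and clinical ADR annotations into a
de-confounded set of target–ADR associations, for safety pharmacologists
and computational toxicologists who want to benchmark or extend
panel-based ADR prediction:

1. **Replicate summarization** — per substance × assay, the geometric mean
   of measured AC50s (qualifier `=`), or the largest censoring level when
   everything is censored (`>`).
2. **Assay groups** — protocols for one target and mode are merged when
   concordant (mutual active-detection sensitivity ≥ 0.5, Pearson *r* ≥ 0.7
   on ≥ 10 measured log AC50 pairs); groups are connected components of the
   concordance graph, and one representative record per drug × group is
   chosen (active metabolite over parent, better structure match, preferred
   assay).
3. **Safety margins** — per-drug exposure summarized as the 3rd quartile,
   free Cmax = (100 − PPB%)/100 × Cmax(tot), margin = AC50/Cmax with
   qualifier propagation; measured free margins ≤ 10 flag physiologically
   relevant activities, split into on-target, known and unpublished
   off-target classes.
4. **ADR training sets** — per MedDRA-style term (PT/HT/HG) and source
   (label-mined, or pharmacovigilance scores at LRT ≥ 5× the drug-specific
   threshold), with hierarchy-aware negatives that exclude drugs positive
   for sibling terms.
5. **Univariate scan** — Kruskal–Wallis *p* and ROC AUC on truncated
   activity measures (AC50, total margin, free margin), one truncation
   cutoff selected per assay group × measure, gates *p* ≤ 1e−06 ∧
   AUC ≥ 0.7 (systematic) and *p* ≤ 0.001 ∧ AUC ≥ 0.6 (literature-style,
   with PT→HT→HG hierarchy expansion).
6. **Sparse de-confounding** — per ADR term, an L1-penalized logistic
   model over all significant assay × measure pairs, 1-SE penalty selection
   over 50 leave-20%-out trials, retention rule coefficient < −0.08;
   correlated redundant assays are eliminated.
7. **Explanations** — a six-criterion filter flagging unpublished potent
   activities (< 5 µM) that plausibly explain a drug's known ADRs.
8. **Synthetic data** — a generator with censored log-normal potencies,
   polypharmacology blocks, correlated decoy targets and a planted causal
   target→ADR map, so the whole chain is testable without any downloads.

## Worked example

Generate a small synthetic study (300 drugs, 16 assays, 3 planted causal
target→ADR pairs) and run the full pipeline:

```r
library(targetadr)

summarize_ac50(c(">", ">"), c(1, 30))
#> $qualifier
#> [1] ">"
#> $value
#> [1] 30
#> $n_summarized
#> [1] 2
#> $n_total
#> [1] 2

cfg <- sim_config(n_drugs = 300, n_assays = 16, duplicate_assay_targets = 2,
                  n_pt = 20, n_ht = 8, n_hg = 4, n_soc = 2, n_causal = 3)
bundle <- generate_bundle(cfg, seed = 42)
res <- run_pipeline(bundle, pipeline_config(n_trials = 25))

sig <- res$scan$significant
head(sig[order(sig$kw_p),
         c("assay_group_id", "measure", "cutoff", "term_code", "source",
           "kw_p", "roc_auc", "n_pos", "n_neg")], 3)
#>    assay_group_id measure cutoff term_code source         kw_p   roc_auc n_pos n_neg
#> 6   grp_assay_005    ac50     30     PT002  FAERS 1.173303e-26 0.9223784    50   185
#> 24  grp_assay_007    ac50     30     PT003  SIDER 7.688540e-23 0.9032513    43   206
#> 9   grp_assay_005    ac50     30     PT002  SIDER 2.921625e-22 0.8557728    60   179
```

Each row is one tested association: drugs positive vs negative for the
term were compared on the truncated activity measure; `kw_p` is the
unadjusted Kruskal–Wallis *p*, and `roc_auc` > 0.5 means more potent
drugs are likelier to carry the ADR. The sparse stage then removes
redundant margin-based echoes of the same assays (e.g.
`grp_assay_005 free_margin` eliminated in favor of its AC50), and the
planted map is recovered exactly:

```r
res$recovery[c("precision", "recall", "n_predicted", "n_planted")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $n_predicted
#> [1] 3
#> $n_planted
#> [1] 3
```

## Analysis workflow

The `analysis/` scripts run the same chain as numbered steps over a
default 800-drug bundle, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # bundle + planted causal map
Rscript analysis/02_summarize_and_group.R # summarization, assay groups
Rscript analysis/03_margins.R             # exposure, margins, classes
Rscript analysis/04_adr_training_sets.R   # hierarchy-aware pos/neg sets
Rscript analysis/05_univariate_scan.R     # KW/AUC scan, cutoff selection
Rscript analysis/06_multivariate.R        # 1-SE lasso de-confounding
Rscript analysis/07_prior_model.R         # prior-likelihood classifier
Rscript analysis/08_explanations.R        # six-criterion ADR explanations
```

Input/output table schemas are described in `docs/formats.md`; the
methods and every tunable threshold are documented in
`vignettes/target-adr-mining.Rmd`.

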