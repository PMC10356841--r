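---
title: "Mining target-ADR associations from secondary pharmacology panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining target-ADR associations from secondary pharmacology panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetadr)
```

## The problem

In vitro secondary pharmacology panels profile drugs against a battery of
biochemical and cellular assays to anticipate clinical adverse drug
reactions (ADRs) driven by unintended target engagement. Two obstacles
stand between a panel readout and a defensible target-ADR claim. First,
the raw material is messy: AC50 values are right-censored at the top
tested concentration, replicated across runs, lots and salt forms, and
split across protocol generations for the same target. Second, drugs are
promiscuous: activities at related targets are correlated, so a
univariately significant off-target association may only be a shadow of
the true causal target. This package implements the full chain from
qualified AC50 tables to a de-confounded set of target-ADR associations,
together with a synthetic-data generator that plants a known causal map
so the chain can be validated end to end.

## Qualified values and replicate summarization

Every AC50 (micromolar throughout) carries a qualifier: `=` for a
measured value, `>` for a censored one whose true value exceeds the
stored top concentration (10 or 30 uM depending on the assay). Replicates
of one substance in one assay collapse to a single record: if any
replicate is measured, the geometric mean of the measured values with
qualifier `=`; if all are censored, qualifier `>` at the largest
censoring level. `n_summarized`/`n_total` preserve the audit trail.

```{r}
summarize_ac50(c(">", ">"), c(1, 30))
```

## Assay groups

Protocol changes (radioligand swaps, outsourcing, readout technology)
create multiple assays per target and mode. Assays measuring the same
thing are merged by concordance on shared compounds: qualitative
agreement as mutual sensitivity >= 0.5 for detecting actives (measured
AC50 < 10 uM; censored results count as inactive regardless of level),
quantitative agreement as Pearson r >= 0.7 on log AC50 over at least 10
measured/measured pairs, and at least 10 shared compounds to evaluate a
pair at all. Concordant pairs are edges; groups are connected components,
so a chain A-B, B-C merges all three even if A-C could not be evaluated.
Within a group the assay with the most results is preferred; ties resolve
to the smallest assay id so reruns are reproducible. The per-drug record
used downstream is chosen by fixed precedence: active-metabolite results
represent the parent drug, then better structure-match quality, then the
preferred assay, then a lexicographic tie-break.

## Exposure and safety margins

Heterogeneous Cmax and plasma-protein-binding (PPB) measurements are
summarized per drug as the 3rd quartile (75th percentile, linear
interpolation between order statistics — the rule is stated explicitly
because quantile conventions differ), after excluding PPB rows reported
as albumin or glycoprotein binding, which track poorly with whole-plasma
values. Free Cmax is the unbound fraction times total Cmax,
`(100 - PPB%)/100 x Cmax_tot`; we interpret the percent-bound input as a
fraction — the only reading consistent with the invariant
`cmax_free <= cmax_tot`.

A safety margin is AC50 divided by exposure and inherits the AC50's
qualifier. A measured free margin at or below 10 flags the activity as
potentially physiological. A censored margin above 10 can never be
physiological; a censored margin at or below 10 is genuinely
indeterminate (the true margin may lie either side of the threshold) and
is flagged separately rather than silently counted either way.

Each drug x assay-group activity is classed as on-target (assay target
among the drug's mechanism-of-action annotations, with mode matching:
functional assays require the same action type; GPCR and nuclear-receptor
binding/inhibition assays exclude agonist drugs but retain antagonists,
whose binding and functional readouts track each other), known off-target
(external resources report a median AC50 below 10 uM, or a
mode-mismatched MOA annotation exists), or unpublished off-target.

## ADR training sets

Label-mined annotations arrive as boolean positives per preferred term
(PT). Pharmacovigilance annotations arrive as a disproportionality score
(LRT) with a drug-specific threshold; a drug is positive when the score
reaches 5x its threshold (2x supported as a lenient alternative). Sources
are never pooled: every association is tested per source.

Positives roll up the ontology: a drug is positive for a high-level term
(HT) or high-level group (HG) iff it is positive for a descendant PT.
Negatives are hierarchy-aware so that a drug causing a clinically similar
reaction is never labeled a negative: for a PT, drugs positive for the
term or any sibling PT under its HTs are excluded; for an HT, the term or
any sister HT under its HGs; for an HG, any PT beneath it. Multi-parent
terms (the ontology is a DAG) use the union of sibling sets over all
parents. Each (term, source) set therefore partitions the drug universe
into positives, negatives and excluded drugs; a set is eligible for
testing with at least 10 positives and 50 negatives.

## Univariate association testing

Censored measures need a common ceiling before rank statistics make
sense. For a cutoff c: measured values above c are truncated to c,
censored values at or above c are kept at c (their rank is correct), and
censored values *below* c are excluded — their true value could fall on
either side. Cutoffs are 10/30 uM for AC50, 2/10 for total margin,
10/100 for free margin; for the systematic scan one cutoff per assay
group and measure is fixed first — the one yielding the most associations
passing the gate, ties resolved to the higher cutoff — so that the number
of tests stays controlled, while literature-style classification keeps
the cutoff giving the smallest p.

The test statistics are the Kruskal-Wallis (KW) p (rank H statistic with
tie correction, chi-square approximation with one degree of freedom;
identical distributions give p = 1; p values are deliberately not
adjusted — the stringent gate plays that role) and the ROC AUC in its
Mann-Whitney form. The AUC score is the *negated* log10 activity, so
AUC > 0.5 always means "more potent drugs are likelier to carry the
ADR"; with the raw activity as score the reported direction would invert,
contradicting how AUC thresholds are interpreted everywhere downstream.
The AUC is invariant to monotone transforms of the score, and swapping
the groups maps it to its complement while leaving the KW p unchanged.

Two gates are used: systematic discovery requires p <= 1e-06 and
AUC >= 0.7; literature-style evaluation requires p <= 0.001 and
AUC >= 0.6, with 0.001 < p <= 0.05 classed as marginal. A caution on the
chi-square approximation: at tiny group sizes (total n <= 10) it deviates
from the exact permutation distribution by up to ~0.1 on the p scale —
irrelevant at the n >= 60 the eligibility rules guarantee, but worth
knowing when comparing against enumeration oracles.

When a literature term fails to validate, the chosen PT may simply be the
wrong lexical handle for the clinical concept. Classification therefore
expands outward: sibling PTs under the same HT (distance 1), then PTs
sharing only an HG (distance 2), visiting candidates in order of
increasing p, accumulating the test count, and stopping at the first term
meeting the significance criteria. Distance-2 matches can pair clinically
opposite effects, so they are emitted flagged unconfirmed, pending
analyst review.

## Sparse multivariate de-confounding

Activities at related targets are correlated, so several assays can pass
the univariate gate while explaining the same variation in ADR risk. For
each (term, source) with more than one significant (assay group, measure)
candidate, a design matrix of log10 truncated values is assembled —
variables covering fewer drugs than 70% of the best-covered variable are
dropped, remaining holes are median-imputed — and an L1-penalized
logistic model is fit along a 50-value penalty path. Every penalty is
scored by 50 trials of leave-20%-out cross-validation (stratified by
class, since rare ADRs would otherwise produce empty holdout classes);
the chosen penalty is the largest whose mean holdout AUC is within one
standard error (of the mean) of the best penalty's — the sparsest model
statistically indistinguishable from the best. glmnet standardizes
predictors internally and reports coefficients on the original log10
scale, which is the scale the retention rule is stated on.

A variable is retained when its coefficient is below -0.08 — a 10-fold
potency increase raising the ADR odds by more than ~20%. Positive
coefficients (activity apparently protective) are zeroed: they arise
almost exclusively as compensation when another measure of the same assay
carries a large negative coefficient. Everything else is recorded as
eliminated, with the model that supplanted it. Single-candidate terms
bypass modeling.

Two behaviors of this selector are worth documenting. With predictors
carrying the causal signal, selection is sharp: a planted causal variable
is retained alone in >= 90% of seeds against nine noise variables, and a
decoy correlated at r = 0.8 with the causal assay is eliminated in ~95%
of seeds at n = 600. On pure noise, however, the 1-SE band (SE of a mean
over 50 trials is narrow, ~0.01 in AUC) occasionally admits a non-null
model, and a stray variable slips past the coefficient rule in roughly a
quarter of seeds; the retained sets stay small (mean below one variable).
This is an intrinsic property of the 1-SE rule with a tight band, not of
the implementation.

A companion prior-likelihood model asks which associations this dataset
could validate at all: features are low percentiles of the assay's
truncated AC50 distribution, counts of results at or below 0.1, 0.5 and
1 uM (the thresholds are configurable; sub-micromolar probes are the
informative range for these panels), training-set sizes, and
system-organ-class membership dummies (multi-SOC terms set several). A
1-SE lasso logistic model on AC50-only significance labels then assigns
likely-significant / likely-non-significant classes at probability 0.5.

## Explaining known ADRs with unpublished activities

A candidate (drug, target, ADR) triple is flagged when all six criteria
hold: (1) measured AC50 below 5 uM at a target absent from the external
resources; (2) the drug is positive for the ADR in at least one source;
(3) the target-ADR association is significant (p <= 0.001, AUC >= 0.6) on
at least one measure; (4) on the most significant such measure the drug
sits in the top three quartiles of potency (value at or below the 75th
percentile) among assay-active, ADR-positive drugs — excluding only the
weakest quartile; (5) no mechanism-of-action target of the drug is
significantly associated with the same ADR; and (6) every known
off-target activity of the drug associated with the ADR is at least
10-fold weaker. Quartiles are computed per (assay, measure, term) triple
rather than pooled across measures, whose scales are not comparable.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with a planted ground truth for recovery scoring. Latent log10 potencies
per drug x target are normal with mean 2 and SD 1 (median 100 uM; ~16% of
pairs active below 10 uM, a realistic panel hit rate), correlated within
polypharmacology blocks via a shared latent factor. Replicates add 0.2
log10 units of noise — consistent with merged-protocol correlations above
0.7 — and censor at the assay's top concentration, so the observed
fraction of `>` records matches the configured log-normal tail. Drugs are
tested in 85% of assays; 70% carry a mechanism-of-action target at which
they are potent (log10 AC50 ~ N(-0.5, 0.5)); 5% have an active-metabolite
form. Exposure is log-normal total Cmax (median ~0.3 uM) with
Beta-distributed PPB (~80% bound), several measurements per drug, and
occasional albumin-labeled rows to exercise the exclusion. The ontology
is a balanced PT/HT/HG/SOC tree with 5% of PTs given a second parent. A
subset of true activities (30%, plus all MOA pairs) appears in
external-resource records, defining which activities count as published.

ADR labels are drawn per source from a logistic model with baseline
log-odds -3.5 (~3-7% prevalence per term, with 2% per-source label flips
modeling source discordance) and effect 4.5 per 10-fold potency gain at
the planted causal target — the strength of a well-validated
pharmacological ADR driver, and enough for planted pairs to clear the
discovery gate (AUC ~ 0.8) at the default 800 drugs. The potency entering
the label model is the *summarized measured* AC50 of the causal assay;
censored or untested drugs contribute baseline risk only. This choice is
deliberate: if labels were driven by the latent true potency instead, a
correlated decoy target would carry genuine conditional information about
drugs whose causal measurement is censored, noisy or missing, and
eliminating it would be statistically wrong — the de-confounding property
the generator exists to test is only well-posed when the planted effect
acts through the measured value.

What the generator does not emulate, and passing tests therefore do not
establish for real data: the lexical and structural irregularity of the
real ADR ontology; reporting biases, indication confounding and
duplicate-report pathologies of spontaneous-report data; text-mining
errors in label-derived annotations; dose-dependent and idiosyncratic
ADRs with no potency relationship; and panels whose causal target is
absent altogether (where no method can deselect its correlates).

## Determinism and problem sizes

All randomness flows from explicit seeds: a bundle is byte-identical for
identical config and seed, the cross-validation selector restores the RNG
state it found, and per-term model seeds derive deterministically from
the master seed. Tie-breaks (preferred assays, representative records,
cutoff selection) are resolved lexicographically or upward, never by
iteration order. The test suite exercises the full pipeline at the
default 800-drug/40-assay conditions, the de-confounding experiment at
600 drugs x 20 seeds, and the null-calibration scan at ~36,000 tested
triples; hierarchy and negative-set oracles run on randomized ontologies
of up to a few hundred nodes with brute-force enumeration as the
reference.

## Limitations

Assay-group construction depends on compound overlap and cannot merge
protocols never run on common chemistry. The sparse selector arbitrates
between correlated targets only when both are on the panel and measured
for overlapping drugs; median imputation shrinks, but does not remove,
the advantage of better-covered assays. The explanation criteria inherit
every upstream threshold, so their output is a ranked shortlist for
expert review, not a causal claim.
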