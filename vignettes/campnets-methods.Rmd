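---
title: "Methods: membrane-protein interaction prediction and cancer network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-protein interaction prediction and cancer network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campnets)
```

# The model

`campnets` predicts interaction partners of integral plasma-membrane
proteins (MPs) by interolog transfer: a curated interaction A–B in any
species serves as a template, and a human pair A′–B′ is a candidate when
A′ and B′ are homologs of A and B. The method's assumptions are the
classical interolog ones — interacting pairs tend to be conserved, and
conservation of the *interacting region* (here, the MP's cytoplasmic
region, the part that transduces signals into the cell) matters more than
global similarity — augmented with evidence quality, multi-species
support and network context.

## The six components

Each component is normalized to [0, 1] so the integrated score
`S_SIM = S_irs + S_qul + S_jss + S_rank + S_es + S_topo` lies in [0, 6].

* `score_irs(SI, L, Q_d)`: geometric compromise between alignment
  identity and region coverage, `sqrt(SI * L/Q_d)`. `L/Q_d` is clipped at
  1 because a local alignment can extend past the annotated region.
* `score_qul(x_m, x_t, x_r)`: evidence counts capped at 2 — one
  independent confirmation is worth a lot, the tenth is not. When one
  PSI-MI term is a subclass of another within the same template only the
  child is counted, preventing double counting of a method and its
  specialization.
* `score_jss`: per-protein `-log10` E-value ratios normalized by the
  self-alignment E-value (the best score attainable for that protein
  length), combined as a geometric mean. Ratios are clipped to [0, 1]
  because parse-time flooring of underflowed E-values can otherwise push
  a ratio past 1.
* `score_rank(r, r_max)`: log-scale rank discount among the candidates of
  one template. Ranks are fractional (average on ties), descending by
  `S_jss`; `r_max` is that template's candidate count. A lone candidate
  scores 1.
* `score_es`: sum over source organisms of normalized evolutionary
  distance times `min(m_f, 2)/2` — support observed twice in a distant
  organism is stronger evidence of conservation than one observation in a
  close relative. The sum is clipped to [0, 1]; with many organisms the
  raw sum can exceed 1 and the clip keeps the stated component range.
  Distances are consumed already normalized; `normalize_tree_distances()`
  divides raw tree distances by the maximum pairwise distance, and a
  cross-species template uses the mean distance to its two organisms.
* `score_topo`: `sqrt((C/N) * D)` with `D = 1 - (R_B - 1)/R_max`, the
  candidate's fractional degree rank (rank 1 = highest degree). The rank
  normalization, rather than raw degree, avoids a handful of promiscuous
  proteins dominating; `R_max` is taken from the supplied network rather
  than fixed, so the score adapts to any interactome slice. A protein
  absent from the network is ranked last.

## The two-stage search

`predict_partners()` first selects templates hit by any cytoplasmic
region of the MP (the hit side becomes the MP-side template protein),
then enumerates homologous pairs passing a per-protein gate
(E ≤ 1e-10) and a joint gate (geometric-mean E ≤ 1e-40). When several
(region, template) combinations support the same partner, the maximum
`S_SIM` is reported and the attached component scores are those of the
maximizing combination; the maximum (rather than a sum or mean) keeps the
score within [0, 6] and reflects that one strong line of transfer
evidence suffices. Default retention thresholds are 3.6 for
reported-interaction templates and 3.7 for direct physical templates,
both overridable.

## Template curation

Direct physical templates require (a) an experimental detection method
(`MI:0045` or a descendant), (b) a direct-interaction type (`MI:0407` or
a descendant), and (c) representative detection-method reliability
scores summing to at least 6, which excludes interactions supported only
by a single high-throughput screen (scored ≤ 5). Scores live in an
editable YAML map (`inst/extdata/reliability.yaml`) anchored at
crystallography = 10 and genetic interference = 0; unlisted terms inherit
from the nearest scored ancestor. The negative set takes homolog-derived
candidate pairs that are not reported interactions and whose gene-
ontology relative specificity similarities fall below 0.4; the printed
rule is disjunctive (`or`), and because the corresponding positive
criterion overlaps it logically, a conjunctive `and` mode is provided —
the package defaults to `or` as printed and asserts neither as intent.
Pairs missing an RSS value are excluded outright.

# Enrichment, permutation null, and meta-analysis

Differential expression uses a per-gene Welch two-sample t test on log2
values with Benjamini–Hochberg adjustment and the DEG contract
|log2FC| ≥ 1, adjusted P ≤ 0.05. The moderated-t machinery of dedicated
expression packages is intentionally not wrapped here: downstream stages
consume only the DEG contract, and the plain Welch test keeps the module
self-contained and easy to reason about in the power analyses. Co-
expression is Pearson correlation over tumor samples only (the pathway
regulation being modeled is a tumor phenomenon), pairwise-complete with
at least 3 shared samples, thresholded at |r| ≥ 0.5 — a conventional
large-effect cutoff, configurable.

A community–pathway association counts cross pairs between the
community's involved genes (its DEG members) and the pathway's DEG
members: `n` is the cross-product size minus identical-gene pairs, `x`
the co-expressed pairs among them, and `M`, `N` the analogous counts
against the union of all pathways' DEG members. Counting is over ordered
combinations, so a gene present in both sets contributes symmetric
combinations consistently to numerator and denominator. The enrichment P
is the upper hypergeometric tail (`hyper_tail_p()`), tested against
exact enumeration in the suite for all population sizes up to 30.

The empirical P shuffles partner labels across the pooled partner
multiset of all communities, preserving each community's size and
sampling without replacement, with the add-one convention
`(1 + #{shuffled ≥ observed})/(B + 1)` so it is never exactly zero.
Because the pool is a multiset, shuffled communities can contain repeated
labels; a valid null calibration must therefore draw its "observed"
communities from the same pool (the acceptance suite does exactly this).
One-sided P values convert to z-scores with a floor of 1e-16 (keeping
`qnorm` finite) and combine across cancers by Stouffer's unweighted
`sum(z)/sqrt(k)`; pan-cancer enrichment is called at meta-z > 1.64 and a
second-level Stouffer combination yields a global meta-z. Degrees in the
filtered community-by-pathway matrix are summarized with hubs at the top
25% and a degree exponent fitted by discrete power-law maximum
likelihood at `x_min = 1` (a log–log least-squares alternative is
available for comparison); community profiles cluster by average-linkage
agglomeration on `1 − Pearson r`, cut to 4 clusters by default.

# Prognosis

Per-gene statistics come from univariate Cox proportional-hazards fits
(Efron ties) on 10-year survival — follow-up beyond 120 months is
censored at the horizon. The combined score of a gene set is
`MV_t = Σ_j w_j E_j(t)` with `w_j = +1` when the gene's hazard ratio is
≥ 1 (ties to +1) and −1 otherwise; expression enters on the stored log2
scale without re-standardization. When at least 75% of patients have
negative MV, the reverse coefficient flips the sign (`CS = −MV`) so a
predominantly protective set is not misread as low expression; sets with
26–74% negative MV are flagged `mixed_sign` as directionally ambiguous.
Stratification splits at the median or scans every observed CS value in
the interquartile 25–75% band for the minimum two-group log-rank P. The
scan's minimum is reported without multiplicity correction, matching
common practice; the test suite documents the consequence — under a
null simulation the best-cutoff false-positive rate sits well above the
nominal 5%, while the median policy is calibrated. Note also that the
per-gene weights are estimated on the same cohort that is stratified;
this in-sample reuse is faithful to the procedure being modeled but
optimistic for prospective use.

# The synthetic generators

`make_interactome_fixture()` emulates the inputs of the prediction
stage: a human proteome with MPs carrying cytoplasmic regions, templates
in three source organisms at normalized distances 0.25/0.65/0.8, and
alignment hits whose E-values are generated directly as a function of
planted identity and protein length plus log-normal noise (the scorer
consumes E-values, not sequences, so no aligner is run). True partners
carry high-identity region hits, strong homology, evidence-rich
templates (sometimes duplicated within an organism, exercising the
`m_f` cap) and shared network neighbors; decoys pass both homology gates
with weak signal, so the score — not the gates — must separate them.

`make_expression_survival_fixture()` generates log2 expression as
baseline N(8, 1) plus planted differential shifts (default |log2FC| = 2,
alternating sign), single-factor co-expression blocks among tumor
samples with loading `sqrt(target_r)` (so two block genes correlate at
`target_r` in expectation, default 0.7), and unit Gaussian noise.
Survival is exponential with log hazard `Σ β_g (x_g − mean)` and
independent uniform censoring. `make_campnets_fixture()` wires these
into one world: a planted community and pathway sharing a co-expression
block and DEG status, null communities supplying the permutation pool,
and a prognostic coefficient (β = 0.4) on four community genes.

What the generators do **not** emulate: realistic sequence evolution,
count-level RNA-seq noise (values are Gaussian on the log2 scale), batch
effects, correlated censoring, or the scale of real corpora (hundreds of
thousands of templates, 20k genes, thousands of tumors). Passing tests
therefore demonstrate correctness of the computations and recoverability
of planted structure at desk scale, not the field performance of the
method on real data.

# Numerical choices and degenerate inputs

* E-values printed as `0.0` are floored at 1e-180 at parse time so
  `-log10` stays finite; the scoring operations themselves do not floor
  legitimate small E-values (only nonpositive inputs).
* `S_jss` ratios and `S_es` sums are clipped to [0, 1].
* `empirical_p` never returns 0 (add-one convention); `meta_z` floors P
  at 1e-16.
* Zero-variance genes: P = 1 in DEG calling, skipped with a warning in
  co-expression, flagged without estimates in Cox fits, dropped with a
  warning before clustering.
* An MP without an annotated cytoplasmic region yields an empty
  prediction with a warning; a template without self-alignment hits is
  skipped with a warning.
* A degenerate (constant) combined score is an error in stratification;
  a median equal to the maximum falls back to the next observed cutoff
  so both groups are non-empty.
* All stochastic stages take an explicit seed and are bit-reproducible.

# Problem sizes used by the test suite

The suite runs the full pipeline at deliberately small sizes chosen so
that planted effects are unambiguous: interactome fixtures with 3 MPs ×
(5 true + 5 decoy) partners, expression fixtures of 100–200 genes with
20–300 tumor samples, permutation tests at B = 50–1000, 200-repeat null
calibrations, and 2000-repeat stratification calibration at n = 50.
These sizes keep each property interpretable (e.g. ±2% on a 5% false-
positive rate) while the whole suite completes in well under a minute
per file.

# Known limitations

* The enrichment universe (`M`, `N`) uses the union of pathway gene
  sets; a per-pathway multiset variant would weight multi-pathway genes
  differently, and the choice is documented rather than resolved.
* Reliability scores for detection methods are anchors plus inheritance,
  not a complete curated table; users with a full PSI-MI scoring table
  can supply their own YAML.
* The best-cutoff log-rank P is optimistic (see above) and should be
  interpreted as a screening statistic.
* Cross-validation of the prognostic weights is out of scope; weights
  and stratification share the cohort.
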