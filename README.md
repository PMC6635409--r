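# campnets

Membrane proteins (MPs) sit at the cell surface, transduce signals through
their cytoplasmic regions, and are heavily targeted in oncology — yet their
interaction partners are under-represented in curated PPI databases.
`campnets` implements an interolog-based prediction and analysis stack for
this problem: it scores candidate MP–partner pairs against curated
interaction templates from other species, assembles the resulting MP partner
communities, links them to pathways through co-expression enrichment in
tumor expression data, and evaluates the prognostic value of the resulting
gene sets against survival outcomes. It is aimed at computational biologists
who want to run or study this method on their own template/expression/
clinical tables, and it ships a seeded synthetic-data generator so the whole
pipeline runs and is tested without any external downloads.

## The integrated similarity score

A candidate pair (A′–B′, where A′ is the MP) inferred from a template
interaction A–B is scored by six components, each in [0, 1]:

    S_SIM = S_irs + S_qul + S_jss + S_rank + S_es + S_topo      (0 to 6)

- **S_irs = sqrt(SI × L/Q_d)** — interacting-region similarity: alignment
  identity SI and aligned length L of the MP's cytoplasmic region (length
  Q_d) against a template protein.
- **S_qul = (x_m + x_t + x_r)/6** — template quality from the counts of
  detection methods, interaction types and PubMed references, each capped
  at 2 (with PSI-MI child terms representative over their ancestors).
- **S_jss** — geometric mean of the −log10 E-value ratios of A→A′ and
  B→B′, each normalized by the protein's self-alignment E-value.
- **S_rank = 1 − log10(r)/log10(r_max)** — the candidate's fractional rank
  by S_jss among all candidates of the same template.
- **S_es = Σ_f E^f × min(m_f, 2)/2** — evolutionary conservation: the
  normalized evolutionary distance to each source organism, weighted by its
  capped template count, clipped to [0, 1].
- **S_topo = sqrt((C/N) × D)** — shared interaction partners C of the MP
  (degree N) and the candidate, weighted by the candidate's normalized
  fractional degree rank D in the target-species network.

Candidates must pass per-protein (E ≤ 1e-10) and joint (geometric-mean
E ≤ 1e-40) homology gates; per partner the maximum S_SIM over all
supporting (region, template) combinations is reported, thresholded at 3.6
(reported templates) or 3.7 (direct physical templates).

Downstream, a community–pathway association in one cancer is scored by the
upper hypergeometric tail over co-expressed DEG cross pairs (counts x, n
against pathway DEGs; M, N against all pathway DEGs), with an empirical P
from 1000 size-preserving partner-label permutations; per-cancer P values
combine across cancers by Stouffer's unweighted Z; gene sets are collapsed
to a per-patient combined score CS = MV × RC with MV = Σ w_j E_j
(w_j = ±1 by hazard ratio) and stratified for Kaplan–Meier/log-rank
analysis at a median or best 25–75% cutoff.

## Worked example

```r
library(campnets)

ix <- make_interactome_fixture(seed = 1)       # planted homology structure
cand <- predict_partners("MP1", ix$proteome,
                         exclude_self_templates("MP1", ix$templates),
                         ix$hits, ix$network, ix$distances, threshold = 3.6)
head(cand, 5)
#>    partner s_irs s_qul s_jss s_rank  s_es s_topo s_sim
#> 1 MP1_POS2 0.922 1.000 0.762      1 0.650  0.465  4.80
#> 2 MP1_POS3 0.912 1.000 0.712      1 0.650  0.465  4.74
#> 3 MP1_POS1 0.898 0.833 0.863      1 0.650  0.465  4.71
#> 4 MP1_POS5 0.930 1.000 0.807      1 0.125  0.465  4.33
#> 5 MP1_POS4 0.927 0.833 0.799      1 0.125  0.465  4.15
```

All five planted true partners of `MP1` pass the 3.6 threshold, with the
component columns showing why: near-identity region alignments (`s_irs`),
evidence-rich templates (`s_qul = 1` at the caps), strong normalized
homology (`s_jss`), top similarity rank, multi-organism support (`s_es`)
and shared network neighbors (`s_topo`). Against the planted labels the
score separates positives from decoys with AUC 1.0 on this fixture.

```r
fx <- make_campnets_fixture(seed = 1)          # wired pipeline fixture
cm <- fx$communities[[1]]
enrichment(cm, "planted_pathway", fx$degs, fx$coexpr, fx$pathways)
#> x=220 n=220 M=301 N=361  p=2.1e-29  involvement=28.7
empirical_p(cm, "planted_pathway", fx$communities, fx$degs, fx$coexpr,
            fx$pathways, B = 1000, seed = 1)$empirical_p
#> [1] 0.000999  (= 1/1001: the observed score beat every shuffle)
```

All 220 community–pathway DEG cross pairs are co-expressed (the fixture
plants one latent co-expression block over both gene sets), so the
hypergeometric tail is tiny and no shuffled community matches it. The same
community's involved gene set separates survival:

```r
st  <- per_gene_cox(fx$expr, fx$clinical)
gs  <- involved_genes(cm, fx$degs$gene[fx$degs$deg])
cs  <- combined_score(fx$expr, st, gs)
stratify(cs, fx$clinical, policy = "best")
#> log-rank p = 2.9e-11, HR = 9.57 (4.39-20.88)
```

A command-line wrapper is installed at `inst/cli/campnets`
(`campnets simulate|curate|predict|degs|enrich|prognosis|assay`); every run
writes a `manifest.json` with option and output checksums.

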