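---
title: "Methods: co-abundance dysbiosis analysis of honeybee gut microbiota activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-abundance dysbiosis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutnetdys)
```

## The problem and the data model

Honeybee workers carry a low-diversity, highly structured gut microbiota
whose members (Lactobacillus, Bifidobacterium, Gilliamella, Snodgrassella,
Frischella, and a tail of non-core and trace genera) occupy distinct gut
sections. Sublethal neonicotinoid exposure is suspected to disrupt not just
who is present but how members' *activities* covary — the community's
wiring. This package quantifies that disruption from 16S rRNA
transcript-derived **activity tables**: samples x ASVs matrices of
non-negative counts in which a count is proportional to a taxon's share of
ribosomal transcripts in that sample, a proxy for transcriptional activity
rather than cell abundance.

The experimental layout the pipeline expects (and that its generator
emulates) is a caged dose-response study: four treatment groups (0, 0.1, 1
and 10 ppb clothianidin in sucrose syrup), five cages of 200 bees per group
followed for 28 days with daily mortality records, daily syrup weighings,
weekly removals of 20 bees per cage, and RNA sampling at day 7 of three gut
sections (midgut, ileum, rectum) with two replicate pools per cage — 120
samples, 10 per gut-section x dose condition.

## Per-condition co-abundance networks

The core procedure runs independently in each of the 12 conditions:

1. **Genus aggregation.** ASV counts are summed over ASVs assigned to the
   same genus. ASVs resolved only above genus stay in their own
   `unassigned_<rank>_<name>` bucket — merging them into a named genus would
   fabricate activity; fully unresolved ASVs pool into `unassigned`.
2. **Occurrence filter.** A genus enters the screen only if present in
   strictly more than 70% of the condition's samples (8 of 10 in the full
   design). Correlations estimated from genera that are mostly absent are
   dominated by zero ties. Subsets with fewer than 4 samples are refused.
3. **Spearman screen.** Per-sample relative activities are rank-correlated
   for every retained genus pair (average ranks on ties). Two-sided p values
   use the t approximation `t = rho*sqrt((n-2)/(1-rho^2))` with `n-2`
   degrees of freedom (`p = 0` at `|rho| = 1`); a Monte-Carlo permutation
   mode exists and is used by the test suite as an independent oracle.
   Genera constant across the subset would yield undefined correlations;
   they are removed from the testing family (and logged), so the family size
   `m` counts only defined pairs.
4. **Dual correction and the edge rule.** Benjamini–Hochberg and Bonferroni
   adjustments are both computed across the `g(g-1)/2` family, and an edge
   requires `|rho| >= 0.4` **and** `p_BH < 0.05` **and** `p_Bonf < 0.05`.
   The conjunction is deliberately redundant (Bonferroni dominates BH); it
   mirrors the screening convention this pipeline standardizes, and a
   `require_bonferroni = FALSE` switch relaxes it to BH-only. Retained
   genera with no significant partner stay in the network as degree-0 nodes.

Correlating **proportions** rather than raw counts makes the edge set
invariant to per-sample sequencing depth — with ranks the two inputs differ
only when depths differ. The choice has a price discussed under
*Limitations*: proportions are compositional.

## Topology metrics and network comparison

Metrics follow the Cytoscape NetworkAnalyzer conventions, sign-agnostic and
unweighted: degree (DG); neighborhood connectivity (NC), the mean degree of
a node's neighbors; and closeness centrality (CC), the reciprocal of the
mean shortest-path length from a node to the nodes reachable from it
(per-component, not Wasserman–Faust normalized; degree-0 nodes score 0 on
both NC and CC by convention). Distributions of a metric between two
networks are compared with a two-sided Mann–Whitney U test (normal
approximation with tie correction, no continuity correction); the
comparison grid covers every within-section dose pair. No multiplicity
correction is applied across the grid by default — each comparison is
reported as a single p value — with an optional BH column.

## Dysbiosis signatures

For each exposed condition vs its section control the signature records:
node counts and signed edge counts of both networks; per genus, the
correlation partners gained (neighbors only in the exposed network) and
lost (only in the control network) — both the partner lists and their
counts, since "a gain in correlations" can be read per edge or per partner;
the activity direction, classified as up/down/stable with a ±10% band on
the ratio of summed relative activities (the band is a fixed, documented
operationalization of "variable across concentrations"); the taxon class;
and a keystone flag. **Low-activity taxa** are genera contributing less
than 0.01% of the condition's total activity *and* present in fewer than 3
of 10 samples — the conjunction is strict, so a trace genus present in half
the samples is non-core, not low-activity. **Keystone** is operationalized
as degree and neighborhood connectivity jointly in the top quartile of the
network's nonzero-degree nodes (quantile configurable); the term is
narrative in the field, and an explicit rule makes the narrative testable.

## Alpha diversity and differential activity

Chao1 (`S_obs + F1(F1-1)/(2(F2+1))`) is computed on raw integer counts —
it is undefined on normalized data and the implementation refuses
non-integers — and Shannon diversity in nats. No rarefaction is applied;
per-sample depths are available to judge comparability. Group comparisons
chain a tie-corrected Kruskal–Wallis test, pairwise Dunn z statistics on
the pooled ranks, and BH adjustment across the pairwise family; with two
groups the Dunn p equals the Kruskal–Wallis p exactly, which the tests
assert. Sections are pooled by default (`stratify_section = TRUE` stratifies).

Differential activity per ASV and section x dose vs control is a fully
specified, deliberately simple statistic (not a negative-binomial GLM):
median-of-ratios size factors computed within the two-arm subset (with the
"poscounts" fallback when no taxon is positive everywhere), signed
`log2((mean_exposed + 0.5)/(mean_control + 0.5))` on normalized counts, a
two-sided Wilcoxon rank-sum p, and BH across the subset's ASV family with
significance at adjusted p < 0.05. It is antisymmetric under arm swap and
invariant to per-sample depth rescaling up to the pseudocount perturbation;
both properties are tested exactly. The scientific readout downstream —
the signature — does not depend on the DE engine's sophistication.

## Taxonomic assignment

ASVs are assigned from BLAST tabular hits (outfmt 6 with subject taxids):
if the best hit by bitscore exceeds 98% identity ("above" read strictly),
its full seven-rank lineage is assigned; otherwise the lowest common
ancestor of the top 50 hits' lineages — the deepest rank prefix on which
all agree, unweighted. Missing intermediate ranks inherit the parent name
with an `unclassified_` prefix so rank walks never gap; an all-empty
lineage is the explicit "unassigned" sentinel. LCA is commutative,
associative and non-deepening under added lineages, all property-tested.

## Survival and feeding

Kaplan–Meier curves are computed directly from the aggregated per-cage-day
ledger (`S(t)` as the product of `1 - d_i/n_i` over event days), which makes
the estimate manifestly invariant to how one day's deaths split across
cages; the weekly 20-bee samplings are right-censored on their day, leaving
the risk set after that day's deaths. Median survival is the first event
day with `S <= 0.5`, NA if never reached. Group contrasts use the standard
one-degree-of-freedom log-rank statistic. The test suite cross-checks both
against the `survival` package on per-subject expansions of the same
ledgers. Proportional-hazards regression is intentionally out of scope (an
off-the-shelf model; the ledger export lets external tools fit it).

The feeding statistic is the cage's measured syrup mass divided by the mean
of bees alive at the start and end of the day [g/bee/day]. Exposed-vs-
control contrasts default to Wilcoxon rank-sum over cage-day values; a
signed-rank mode paired by day (cages averaged within group) is available,
since pairing conventions differ between labs. A per-day Kruskal–Wallis
across groups is also reported.

## The synthetic study generator

The generator is first-class, tested code; its defaults *are* the study
conditions above.

**Activity.** Per condition, genus activities are drawn through a Gaussian
copula: latent normal vectors with a target correlation structure, mapped
through per-genus lognormal marginals `exp(meanlog_section +
log(2)*dose_effect + sdlog*z)`. Spearman targets convert to latent Pearson
correlations via `r = 2 sin(pi rho / 6)`; if planting makes the matrix
indefinite it is repaired to the nearest correlation matrix, and the run
aborts if repair moves any target by more than 0.05 (the default planted
set uses disjoint pairs, which are always definite). Because the marginal
map is monotone, planted rank correlations survive to the genus activities
— but not automatically to *proportions*: dividing by a strongly varying
sample total distorts rank correlations (compositional closure; a planted
−0.95 can appear as −0.4). The generator therefore gives the dominant
`unassigned` pool a small lognormal sd, so each sample's total is nearly
constant and proportions are approximately monotone in each genus's
activity. Each genus is split into 1–4 ASVs by fixed Dirichlet weights,
scaled to a negative-binomial sequencing depth (mean 25,000, dispersion 5 —
fixed, unremarkable defaults) and rounded. Rare genera (default Ralstonia,
Devosia, Leifsonia) are injected in at most 2 of 10 samples per condition
at ~2e-5 relative activity, below the low-activity ceiling by design.

**Dose effects** (log2 shifts of mean activity at nonzero doses) encode the
qualitative exposure phenotype: Frischella down (−1), Bifidobacterium up
(+0.8), Snodgrassella down (−0.5), Gilliamella dose-dependent (−0.2, −1.6,
+0.7 at 0.1, 1, 10 ppb), and the dominant unassigned pool mildly down
(−0.5) so exposed communities are more even — alpha diversity rises under
exposure, matching the direction this kind of study reports. The default
planted-edge set keeps four strong positive associations in controls, of
which only one persists under exposure alongside one new negative edge, so
exposed networks lose positive wiring — the headline dysbiosis pattern.

**Survival.** Daily deaths are binomial per cage under per-dose hazards.
The defaults solve `(1-h)^t = 1/2` at 50%-mortality days 16, 20, 22 and 22
for 0.1, 1, 0 and 10 ppb — the inverted dose-response in which the lowest
dose is deadliest: h = 0.0425, 0.034, 0.031, 0.0315. Weekly samplings are
right-censored; whether sampled bees should instead be excluded from the
cohort is ambiguous in practice, and censoring is the convention chosen
here. **Feeding** is per-bee intake x mean alive + truncated Gaussian noise,
with the 1 ppb group's intake highest (0.062 g/bee/day vs 0.050 control);
with zero noise the feeding-rate statistic inverts the generator exactly,
which the tests assert.

**Determinism.** One master seed fans out to fixed per-stage child seeds
(`seed*1000 + stage`), so a stage rerun in isolation reproduces its
in-pipeline draws and identical seed + config reproduce byte-identical
artifacts and manifest digests.

## Screen calibration: what the planted truth shows

Two calibration experiments quantify the screen's operating characteristics
at the study's per-condition sample size (n = 10):

- **Recovery**: two disjoint planted correlations of ±0.95 among four
  screened genera over a near-constant dominant background; across 20
  seeds the full chain recovers planted edges with the correct sign ~90–95%
  of the time.
- **Null control**: the same panel with nothing planted; the fraction of
  screened pairs reported as edges stays far below 0.05 (Bonferroni
  controls family-wise error).

The panel is deliberately compact. With the Bonferroni clause enforced, the
critical |rho| at n = 10 grows with the family size — roughly 0.81 at 10
pairs but 0.87 at 45 pairs — so detection power for even a 0.95 planted
correlation falls substantially on large panels. The calibration isolates
the per-pair operating characteristic rather than conflating it with panel
size; users screening many genera at n = 10 should expect the conjunction
rule to be very conservative, which is also why real studies at this design
size report tens, not hundreds, of edges. Edges touching the background
pool are excluded from the null tally: the background's proportion is
deterministically anti-monotone in the sample total, so those correlations
are a property of closure, not a screening error.

## What the generator does not emulate

Passing tests on synthetic data demonstrate that the implementation does
what it claims under known truth — not that real data satisfy the
assumptions. The generator does not reproduce: the taxonomic richness of
real ASV tables (hundreds of ASVs, database-dependent assignment); zero
inflation and dropout beyond the occurrence structure modeled; strong
compositional variance (its background pool deliberately buffers closure,
which real communities need not do); batch, cage and section-adjacency
effects; or chemistry (bioaccumulation and degradation of the pesticide are
out of scope). Absolute edge counts from real studies are therefore not
reproduction targets; the structural counts (12 networks, 120 samples,
4000 bees) and the estimators' operating characteristics are.

## Numerical choices and degenerate inputs

- Ties: average ranks everywhere (Spearman, Kruskal–Wallis/Dunn tie
  corrections, Mann–Whitney tie-corrected variance).
- `|rho| = 1` maps to p = 0 (the t statistic diverges).
- Constant genera leave the correlation family; constant ASVs get p = 1 in
  the Wilcoxon stage; all-zero samples are dropped at ingestion with a
  warning; all-zero ASV columns are suppressed from differential output.
- Counts are stored as doubles; integrality is enforced only when raw
  tables are ingested and where the estimator requires it (Chao1).
- Occurrence and low-activity thresholds generalize strictly (`> 0.7N`,
  `< 0.3N`) so the canonical 8-of-10 / fewer-than-3-of-10 behavior is
  preserved at other subset sizes.
- TSV outputs format numerics to 6 significant digits for stable digests;
  the edge-TSV round trip preserves the signed edge set exactly.
- Orientation of ingested tables is fixed samples-in-rows; the transpose is
  accepted only when metadata proves the columns are samples.

## Problem sizes used by the tests and acceptance script

The suite exercises the full 120-sample design end to end; oracle
equivalence runs 200 random graphs (n ≤ 30) against a brute-force
BFS/Floyd–Warshall implementation and a 1e5-draw permutation oracle for the
screen's p values; calibration experiments use 20 seeds each; survival
checks use cohorts of 1000–4000 bees. These sizes were chosen so the whole
suite and the acceptance script each complete in minutes on one core while
keeping every Monte-Carlo margin wide.

## Known limitations

Plain Spearman on proportions is not a compositionality-aware estimator
(SparCC/SPIEC-EASI address that); it is standardized here because it is
what this analysis chain specifies, and the closure caveat is documented
above. The t approximation for Spearman p values is approximate at n = 10
(the permutation mode quantifies the difference). The dual-correction edge
rule is conservative by construction. Cox regression, beta diversity,
read-level processing (quality control, denoising, chimera removal) and
BLAST itself are out of scope: the pipeline consumes a finished ASV table
and, optionally, finished BLAST hits.
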