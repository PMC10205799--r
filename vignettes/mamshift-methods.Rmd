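---
title: "Methods: MAM module scoring and cross-stage ancestor inference"
author: "mamshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAM module scoring and cross-stage ancestor inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model of the data

`mamshift` analyses a staged single-cell RNA-seq time course of
pressure-overload (TAC) cardiac hypertrophy: five stages at 0, 2, 5, 8 and
11 weeks after surgery (0w = normal, 2w = hypertrophy with preserved
ejection fraction, 5w = reduced ejection fraction, 8w/11w = heart failure).
Cells carry a stage label, a major-type label (CM, EC, FB, MP, T, GN) and,
within cardiomyocytes, a subtype label (CM1–CM11). Clustering and annotation
are treated as pluggable inputs — the package consumes labels, it does not
re-derive them (`attachLabels()` merges an external label table; a
convenience path exists but is deliberately not part of any validated
result).

Four computations form the core:

1. **Module scoring** of the mitochondria-associated ER membrane (MAM) gene
   program per cell, with expression-bin-matched control genes.
2. **Ancestor-voting conversion inference** between consecutive stages by
   top-k Spearman correlation.
3. **Rule-based subcluster selection** gating which subtypes and conversion
   edges enter trajectory analysis.
4. **Dynamics summaries**: subtype proportions per stage, score/proportion
   coupling, and gene trends along a deterministic pseudo-order.

A synthetic-cohort generator with a planted ground-truth ledger makes each
step testable end to end; no external data are required.

## Module scoring with binned controls

The score of cell $j$ for gene set $S$ is

$$\mathrm{score}_j \;=\; \frac{1}{|S|}\sum_{g \in S} x_{gj}
\;-\; \frac{1}{|C|}\sum_{c \in C} x_{cj},$$

where $x$ is log-normalized expression
($x_{gj} = \log(1 + \mathrm{count}_{gj}/N_j \cdot 10^4)$) and $C$ is a pool
of control genes matched to the set genes by overall expression level: all
genes are ranked by dataset-average expression and cut into `nBins = 24`
equal-frequency bins (ties broken by gene id so binning is deterministic);
each set gene contributes `nCtrl = 100` control genes sampled without
replacement from its bin. Control draws use a per-gene seed derived from the
user seed and the gene identifier, which makes the result reproducible *and*
invariant to the order in which set genes are listed.

Two deliberate choices differ from the common implementation of this
scheme:

* **Set genes are excluded from control pools.** A control pool containing
  the scored genes themselves dilutes the contrast; exclusion also gives the
  scheme an exact invariant (a set gene equal to its bin-mates plus a
  constant $c$ scores exactly $c$) that the test suite checks to 1e-12.
* **Small bins fall back to the whole bin** (minus set genes) with a
  warning, rather than failing. On simulated universes of ~1200 genes every
  bin is smaller than `nCtrl`, so scoring is effectively deterministic
  there; on real-sized annotations (>15k genes) sampling is active.

The packaged default set is the 13-gene MAM program (Mfn1, Mfn2, Bcap31,
Pacs2, Tespa1, Hspa9, Itpr3, Sigmar1, Vapb, Fis1, Vdac, Mcu, Ptpip51).
"Vdac" and "Ptpip51" are not standard mouse symbols; `moduleScore()` drops
absent genes with a warning and records them, and `readGeneSet()` accepts
GMT or plain-text overrides.

A property worth knowing: with bin-matched controls, *composition changes
are themselves a signal*. If cell-type composition shifts across stages,
marker genes inside control bins shift with it, and per-stage mean scores
acquire small but statistically detectable offsets even when no program is
planted. The null test therefore holds both the score offsets at zero and
the composition constant; users comparing stage means on real data should
keep this coupling in mind.

## Ancestor voting and conversion edges

For every cardiomyocyte of stage $s$, Spearman correlations are computed to
**all** cells of stage $s-1$ over a gene universe (default: the top 500
highly variable genes of the combined two-stage matrix; `genes = "all"`
switches to the full universe). The `k = 5` most correlated cells are its
*potential ancestors*; their subtype labels are combined by plurality vote.
Edge support$(A \to B)$ over the transition is the number of stage-$s$ cells
of subtype $B$ whose vote is $A$; supports conserve the number of validly
voted cells exactly.

Determinism required several tie-break rules the method's verbal description
leaves open; all are fixed and tested:

* correlations are rounded to 12 decimals before ordering, so
  mathematically tied values (duplicated cells) tie exactly regardless of
  floating-point summation order;
* ties at the top-k cutoff break by cell id lexicographic order;
* vote ties break by larger summed correlation, then lexicographically;
* cells of zero rank variance give undefined correlations and are excluded
  (counted, never silently dropped).

On instances of ≤50 cells per stage the vectorised implementation (average
ranks + centred cross-products) is checked for exact equality against a
brute-force per-pair reference built on `stats::cor(method = "spearman")`.

## Subcluster selection rules

Three conjunctive rules gate trajectory analysis, each applied with audited
boundary semantics:

1. a subtype is retained iff its fraction of CM cells **exceeds** 10% at
   some stage (strict: a subtype at exactly 10% everywhere is excluded);
2. an edge is retained iff its support is **at least** 10 (an edge with
   exactly 10 supporting cells passes);
3. an edge must not conflict with the proportion change over its
   transition. The default ("lenient") reading of conflict: the
   descendant's fraction strictly fell while the ancestor's strictly rose.
   A stricter variant — descendant fraction must be non-decreasing — is one
   configuration switch away (`consistency = "strict"`).

Every excluded subtype and edge is reported with the rule(s) it failed.
Self-edges ($A \to A$) encode persistence rather than conversion; they can
be retained by the rules but are excluded from the stage-ordering DAG and
from planted-edge precision/recall evaluation.

`stageOrderGraph()` peels the collapsed conversion DAG into layers of
current sources (a deterministic substitute for a trajectory-embedding
ordering, which is out of scope); cycles among distinct subtypes are
reported as errors, never broken silently.

## Dynamics

`stageProportions()` reports exact per-stage subtype fractions (absent
subtypes as 0). `scoreProportionCorrelation()` couples stage-mean MAM score
to the summed CM2+CM3 fraction with a Spearman correlation; with only five
stages a significance test would be meaningless, so the result carries a
permanent small-n caveat flag and no p-value. `orderedGeneTrend()` orders
cells by stage (within stage by decreasing module score — a deterministic
pseudo-order standing in for pseudotime), smooths with a partial-window
rolling mean so all smoothed values are finite, and classifies direction
from the sign pattern of first differences of stage means with a dead zone
of 5% of the dynamic range (configurable): `flat`, `rising`, `falling`,
`rise-then-fall`, or `mixed` for patterns matching none of these.

## The synthetic cohort generator

`simulateCohort()` draws counts from a gamma-Poisson (negative binomial)
model: per-gene baseline log-means (log-normal around `baselineMean = 1`),
marker-gene elevations for each major type (40 genes, +1.5 on the log
scale) and each subtype (40 genes, +2.0), a CM-restricted MAM elevation
(`mamBaseCM = 1`) with per-stage offsets peaking at 2 weeks
(0, 0.8, 0.5, 0.2, 0), per-cell log jitter (sd 0.35), uniform library-size
targets (2000–8000 counts), and shared dispersion 0.3. Cells are
apportioned to subtypes by largest-remainder rounding of the schedule
(deterministic composition; a multinomial mode exists behind
`assignMode = "multinomial"`).

The default schedule encodes the subtype switch the inference is designed
to detect: CM2 falls from 30% to 5% of CM cells and CM3 from 25% to 5%,
while CM9 rises from 2% to 28% and CM10 from 2% to 24%; the remaining seven
CM subtypes share the residual mass and the non-CM composition is constant.
Conversions are planted as 60 cells per transition for CM2→CM9 and
CM3→CM10: each converting descendant's latent log-mean profile is a convex
mixture of a specific ancestor cell's profile (weight 0.7) and its own
subtype baseline, so per-cell ancestry is recoverable from the counts.
Mfn1 and Hspa9 carry declining per-stage offsets that *replace* the MAM
stage offset for those two genes — otherwise the 2w-peaked program would
mask the planted decline; the remaining eleven set genes carry the peak.

Two generator parameters deserve comment. No published effect size exists
for the MAM program's rise and decline, so the offsets above are chosen for
testability (a peak clearly separated from noise at ~2000 CM cells/stage)
rather than biological calibration. And subtype identity (40 markers at
+2.0) is set strong enough that rank-correlation voting can recognise a
*non-converting* cell's own subtype across stages — the premise the voting
method rests on; at substantially weaker identity, votes of non-converting
cells degrade toward the previous stage's composition and spurious edges
appear. What the generator does **not** emulate: doublets, ambient RNA,
batch effects, read-level noise, or realistic gene-gene correlation beyond
the planted structure — passing tests show the algorithms recover planted
structure under NB noise, not that the biological claims hold on real data.

## Problem sizes and numerical choices

Validation runs use the emulated study scale: 5 stages × 3333 cells (~2000
CM cells per stage) over a 1200-gene universe, with recovery properties
averaged over five seeds; unit tests use ~250 cells/stage cohorts. At these
sizes the planted conversion edges are recovered with precision and recall
1.0, and support conservation is exact. All randomness is explicitly
seeded; RNG use is localised so library calls do not perturb the caller's
stream. The one numerical tolerance of note is the 12-decimal rounding of
correlations before ordering (see above); everything else is exact
arithmetic or standard double precision.

## Known limitations

* Subtype labels are inputs; mislabelled inputs propagate directly into
  votes and edges.
* The ancestor pool is all previous-stage cells while votes are tallied for
  CM cells only; a CM cell may therefore vote a non-CM ancestor subtype,
  which rule 1 will subsequently exclude (such subtypes never exceed 10% of
  CM fractions).
* The five-point score/proportion correlation is descriptive only.
* Trajectory embedding (pseudotime geometry) and downstream enrichment or
  regulon analyses are out of scope.
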