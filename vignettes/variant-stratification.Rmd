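---
title: "Stratifying HNF1A missense variants from multi-dimensional functional data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying HNF1A missense variants from multi-dimensional functional data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnf1astrat)
```

## The problem

Missense variants in *HNF1A* span a phenotypic continuum: some are fully
benign, some modify the risk of polygenic type 2 diabetes, and some cause
HNF1A-MODY, an early-onset, dominantly inherited, sulfonylurea-responsive
form of monogenic diabetes. Getting the call right changes treatment and
family counselling, but most sequence-detected variants arrive as variants
of uncertain significance (VUS). Functional follow-up produces a
multi-assay profile per variant — transactivation on two promoter/cell
contexts (rat albumin in HeLa cells, *HNF4A* P2 in INS-1 cells), protein
abundance from western blots, nuclear localization from fractionation
blots, and, for a subset, DNA binding by EMSA — and the question becomes
how to turn that multi-dimensional profile into a position on the
benign → T2D-risk → MODY continuum, and then into an auditable
reclassification decision.

`hnf1astrat` implements this stratification as a pipeline of small,
testable stages: data polishing, principal component analysis, k-means and
Ward hierarchical clustering with a validity-index vote, tanglegram
comparison of two laboratories' dendrograms, reference-variant zone
annotation, and an allele-frequency-aware rule engine that formalizes the
registry re-evaluation logic. A synthetic two-laboratory generator with
known latent classes makes every stage testable without access to the
original assay tables, which are not deposited.

## Shape of the package

The pipeline has one fitting-style entry point, `stratify_variants()`,
which returns a classed fit (`hnf1a_strat`) with `print`, `summary` and
`plot` methods, in the idiom of classical modelling packages. `predict`,
`residuals` and `simulate` methods are deliberately absent: the object is
an unsupervised stratification of a fixed variant panel, not a predictive
model — there is nothing meaningful to predict for a new observation
without re-fitting, and simulation belongs to the explicit generator
(`generate_panel()` and friends), not to the fit. The surrounding stages
are plain functions so that each can be driven and tested on its own;
`run_pipeline()` orchestrates them end to end with a JSON manifest and is,
together with `simulate_datasets()`, the scripting interface of the
package.

## Data model and polishing

Functional tables are long/tidy: one row per (variant, laboratory, assay
variable, replicate), because replicate counts differ between variants and
assays. Three normalization levels exist in practice — raw instrument
reads, internal-control-normalized ratios (Renilla luciferase for
transactivation, beta-tubulin/actin for abundance, the nuclear:cytosolic
ratio for localization), and wild-type-normalized summaries. Only the
internal-control-normalized level is accepted for multivariate analysis:
raw data are not harmonized within assays, and wild-type normalization
imposes an interpretation on the data before clustering has seen it. The
other two levels can be read and inspected but `polish_dataset()` rejects
them.

Polishing is: drop EMSA variables (DNA binding was measured for only a
subset of variants, so keeping it would make the variable set ragged),
aggregate replicates (arithmetic mean by default; the replicate SDs are
retained as metadata, never clustered), attach the two position scores,
and zero-center and unit-variance scale every column (sample SD, n−1
denominator, matching conventional standardized PCA). Constant columns are
rejected by name rather than silently dropped.

The two position scores encode the well-established position–phenotype
correlations:

* **Isoform score** (exon band): exons 1–6 are present in all HNF1A
  isoforms (weight 3), exon 7 in two (weight 2), exons 8–10 only in the
  hepatocyte-dominant isoform (weight 1). A variant expressed mainly in
  liver dilutes its beta-cell impact, so the beta-cell-relevant exons are
  weighted higher.
* **Domain score** (residue band): the DNA-binding/dimerization region
  (residues 1–287, weight 2) tolerates mutation poorly; the
  transactivation domain (288–631, weight 1) is more tolerant.

The numeric weights are declared conventions of this package — the
ordering is what matters, and both maps are overridable through
`polish_config()`. Exon numbers are taken from the annotations as
supplied; for synthetic data they come from a shipped approximate
residue→exon map of the canonical 10-exon gene model (`hnf1a_exon_map()`),
which respects the anchor points that matter downstream (the DNA-binding
region falls in exons 1–4, residues ≥ 488 in exons 8–10). For real data
the exon is an input, not derived: transcript-accurate exon mapping is out
of scope.

EMSA is not discarded entirely: `emsa_candidates()` reports which variants
would warrant DNA-binding follow-up (residue in the DNA-binding domain, or
any transactivation activity below 50% of wild-type), with missing
transactivation values flagged rather than dropped.

## Decomposition and contributions

`pca()` is a covariance-matrix PCA via `stats::prcomp` on the already
standardized matrix (equivalent to correlation PCA; standardization stays
in the polish stage so the decomposition is pure). Two conventions make
the output deterministic across platforms: each loading vector is flipped
so its largest-magnitude entry is positive, and variance ties are left in
original column order. `select_components()` applies the strict
cumulative-variance rule: the smallest m whose leading components explain
*more than* the threshold (default 0.85).

`variable_contributions()` reports, per component, 100 × squared loading
(unit-norm loadings make each component sum to 100), and an overall
contribution that pools the retained components weighted by their variance
shares. Both views are exposed because they answer different questions:
the per-component table shows which variable drives which axis; the pooled
number summarizes how much of the retained structure a variable owns. The
pooled metric has a property worth knowing: since every standardized
column carries total variance 1, pooling over *all* components gives every
variable the same contribution, so the pooled ranking is really a ranking
of how completely the retained components capture each variable — a
variable whose residual noise axis happens to be retained is ranked above
an equally informative variable whose residual lands in the dropped tail.
The acceptance suite tracks this sensitivity (see *Known limitations*).

## Clustering

k-means (`km_cluster()`) runs Lloyd iterations from k-means++
initializations, keeps the best of `n_init = 25` restarts by
within-cluster sum of squares, repairs empty clusters by reseeding with
the point farthest from its centroid, and asserts on every run that the
objective never increases across iterations. It is implemented in the
package rather than delegated because the initialization and repair
behavior are part of the contract; `stats::kmeans` (Lloyd) serves as an
independent cross-check in the tests, and an exhaustive-partition oracle
verifies global optimality on small instances.

The number of clusters is chosen by majority vote (`optimal_k()`, ties to
the smallest modal k) over eight validity indices: mean silhouette width,
Calinski–Harabasz, Davies–Bouldin, the gap statistic (uniform reference
over the bounding box, B = 50 seeded draws, one-standard-error rule), a
Hartigan-style elbow (the k whose own split gain most exceeds the next
one's), Krzanowski–Lai, C-index and point-biserial correlation. The set
deliberately mixes maximization-type and successive-difference-type
indices, emulating the breadth of the large index families conventionally
used for this decision; it is pluggable in the sense that the individual
index functions are small and independent.

Hierarchical clustering is Ward.D2 (`stats::hclust` on Euclidean
distances; merge heights are on the distance scale,
`sqrt(2·|A||B|/(|A|+|B|)) · ||mean_A − mean_B||`), applied to the
coordinates of exactly the components retained by `select_components()`.
`compare_linkages()` scores ward against complete, single and average
linkage by how cleanly the cut partition separates wild-type from
MODY-reference variants (adjusted Rand index against the reference
dichotomy). A brute-force Ward implementation that recomputes the merge
cost over all cluster pairs at every step backs the tests.

## Tanglegrams and entanglement

Two laboratories produce two dendrograms over a shared benchmark subset.
After `restrict_to_shared()` (pruning to the shared leaves, collapsing
unary nodes, preserving merge heights), the quality of their alignment is
the entanglement coefficient

$$E = \frac{\sum_s |r_A(s) - r_B(s)|^L}{\sum_i |i - (n+1-i)|^L},$$

the rank-displacement sum normalized by its value for a reversed order, so
E ∈ [0, 1] with 0 for identical leaf orders and 1 for exactly reversed
ones. L defaults to 1.5, the convention of the tanglegram method family.

Branch rotations are semantics-free (a dendrogram is the same clustering
under any child ordering), so `untangle()` searches rotations to minimize
E. The search exploits a structural fact: whatever happens inside a
subtree, its leaves occupy a contiguous block of positions, so with one
tree's order held fixed the optimal rotation of the other is computable
exactly by a post-order dynamic program over (node, block offset). For
small shared sets (≤ 8 internal nodes) the package enumerates every
rotation of one tree with the DP response of the other — the global joint
optimum; larger trees use alternating one-sided optimization from seeded
multi-start rotations. A naive accept-if-better child-swap pass was
evaluated first and discarded: it stalls in local minima several-fold
above the exhaustive optimum even on 6-leaf trees, and fails to reach 0 on
rotation-compatible tree pairs. Externally reported coefficients for this
kind of two-laboratory comparison depend on the underlying assay values
and on layout-search internals, so no historical value is asserted
anywhere; the package reports its own coefficient alongside the
brute-force optimum where the leaf count permits.

## Zones, frequency bands, and the rule engine

Clusters are annotated by the reference variants they contain: only
wild-type members → BENIGN; only type 2 diabetes risk controls →
INTERMEDIATE_T2D_RISK; only MODY controls → DAMAGING_MODY; conflicting
roles → MIXED, never silently resolved; reference-free clusters inherit
the zone of the nearest annotated centroid and are flagged as inherited.

gnomAD allele counts are banded with inclusive thresholds: ≤ 2
(AF < 0.0008%) is compatible with an ultra-rare MODY-causing allele;
3–121 (AF < 0.04%) matches low-frequency type 2 diabetes predisposing
alleles; above that is too frequent for either. Allele fractions are
accepted as a fallback where counts are absent.

The reclassification itself was expert curation in the original studies;
here it is a declared, ordered, first-match rule list (`default_rules()`)
so that every decision is reproducible and traceable. R1 downgrades
class-4/5 variants that cluster in benign or intermediate zones and are
too frequent for MODY (the ACMG BS1 logic: an allele frequency greater
than expected for the disorder is strong benign support). R2 downgrades
class-4/5 variants that *do* cluster as damaging but sit in the
hepatocyte-dominant exons 8–10 and are not ultra-rare — impaired protein,
diluted beta-cell relevance. R3 downgrades class-4/5 calls when a
co-occurring pathogenic variant explains the phenotype. R4 demotes
class-3 (VUS) variants to likely benign when they cluster benign or
intermediate, or damaging-but-liver-band, and are not ultra-rare — the
liver-band arm is required to reproduce the documented registry outcomes,
where VUS-level liver-band variants with impaired function were moved to
likely benign rather than kept at VUS. R5 retains (and marks as
supported) class-4/5 calls for ultra-rare damaging-zone variants in the
beta-cell-relevant exons. Everything else is retained unchanged. MIXED
zones and missing attributes abstain with an UNREVIEWED flag; no rule ever
moves a classification toward pathogenic. The evidence trace lists every
rule evaluated for every variant.

`registry_report()` turns per-variant proposals into registry-level
impact: counts and percentages of the overlap set and of the full
registry, reported raw and rounded to the nearest integer.

Two curated overlap tables ship with the package
(`registry_fixture("UK")`, 31 variants; `registry_fixture("NORWAY")`, 19
variants). Rows for the narratively documented variants carry their
reported attributes; the remaining rows are constructed to be consistent
with their retained classifications and are flagged per row in the
`provenance` column. They are a partly synthetic stand-in for registry
tables that are not public, and the file names say so.

## The synthetic generator

`generate_panel()` emulates the two-center design: each laboratory
measures its own exome-detected variants (default 40 per laboratory)
plus a shared benchmark subset (default 5), with 3 biological replicates
per variant and assay (the original replicate counts are not published;
3 is the field's convention for these assays). `generate_references()`
adds the common battery: two wild-type backgrounds (Ile27 and Leu27), six
MODY-positive controls drawn from the damaging profile, and two type 2
diabetes risk controls from the intermediate profile. The wild-type
constructs carry no mutated residue, so their position scores are pinned
to the most tolerant band. `generate_registry()` assigns 5-tier classes
correlated with the latent truth (configurable misclassification rate)
and class-conditional allele counts (damaging ≤ 2 by default).

Three latent classes drive the panel. Class means are fractions of
wild-type anchored to the reported activity ranges (roughly 30%–110% for
transactivation): WT_LIKE at 1.0 everywhere; INTERMEDIATE at 0.6
transactivation, 0.8 protein expression and localization; DAMAGING at 0.3
transactivation, 0.5 expression and localization. Noise is multiplicative
log-normal throughout, because the readouts are strictly positive ratios:
mean-one replicate noise, and a per-(laboratory, assay) batch factor
(sdlog 0.15) shared between the panel and the reference battery so that
both experience the same batch effect. Replicate noise is assay-specific:
sdlog 0.12 for the transactivation variables (dual-luciferase ratios with
an internal Renilla control are comparatively precise) and 0.20 for the
blot-based variables (densitometric quantification carries a visibly
higher coefficient of variation) — consistent with the observation that
protein abundance and localization rarely flagged variants that
transactivation did not.

Residue positions are drawn class-conditionally over four bands
(DNA-binding 1–287, early transactivation 288–414, exon 7, exons 8–10):
damaging variants concentrate in the mutation-intolerant
DNA-binding/dimerization region (90%), while functionally tolerant
variants sit predominantly in the late, hepatocyte-dominant exons, with a
minority in exon 7. This is the domain-mutation-tolerance premise of the
position scores themselves, expressed in the generator; it also means
that in synthetic data the position scores are genuinely informative
about class, as they are in reality.

What the generator does *not* emulate: assay-specific biological
idiosyncrasies (variants whose DNA-binding defect is invisible to
transactivation), missing values, within-class activity continua beyond
the log-normal spread, clinical covariates beyond class and frequency,
and sequence-level effects. Passing recovery tests on this generator
therefore shows that the pipeline recovers planted multivariate class
structure under realistic noise — not that real *HNF1A* panels contain
exactly three classes, nor that any particular laboratory's historical
cluster memberships would be reproduced (that would require the original
per-variant assay values, which are not public).

## Seeding and determinism

One root seed expands into named substreams (panel, references, registry,
laboratory batch factors), so each generator is independently
reproducible and the batch factors agree between the panel and the
reference battery. All stochastic analysis steps (k-means restarts, gap
reference draws, untangle restarts) take explicit seeds;
`run_pipeline()` derives everything from the seed in its configuration
and writes a manifest (configuration, seed, package version, artifact
hashes) sufficient to reproduce a run byte-for-byte.

## Numerical choices

Standardization tolerance 1e-9 on column means and SDs; PCA checked
against a direct eigendecomposition at 1e-8; Ward heights against the
brute-force oracle at 1e-9; strict-decrease acceptance in the untangle
search at 1e-12 to keep it independent of summation order; Ward and
k-means tie-breaks are deterministic (first index / first-restart wins).
Degenerate inputs fail loudly: all-identical points, constant columns,
fewer than two rows or shared leaves, k outside (1, n).

The test-suite problem sizes are chosen to make the oracles exhaustive
yet fast: Ward oracle on 100 random fixtures with n ≤ 8; exhaustive
k-means partitions at n ≤ 7, k ≤ 3; all 2^(n−1) rotation configurations
per tree at n ≤ 8; and a 20-seed recovery study on the default panel.

## Known limitations

* Under the default synthetic conditions the validity-index vote often
  reports finer structure than the three planted classes: the two ordinal
  position-score columns, once standardized to unit variance, place
  within-class minorities one or more level-gaps away from their
  class-mates, and several indices legitimately read those lattice
  displacements as additional clusters. The adjusted-Rand recovery at
  k = 3 is robust to this; the vote is not, and the acceptance suite
  tracks both.
* The pooled contribution ranking is sensitive to which residual axes the
  cumulative-variance rule happens to retain (see *Decomposition*); the
  per-component table is the stable view.
* The rule engine reproduces documented registry decisions; it is a
  formalized stand-in for expert review, not a validated clinical
  classifier, and it abstains rather than guesses whenever its inputs are
  unresolved.
* Exon assignment for real data is the caller's responsibility; the
  shipped residue→exon map is approximate and used for synthetic data.

## A minimal run

```{r example, eval = FALSE}
library(hnf1astrat)

cfg <- run_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "hnf1a_run")

summary(res$fits$Oxford)     # variance shares, contributions, k vote, zones
res$tanglegram               # cross-laboratory alignment of shared variants
res$report                   # registry-level reclassification impact

# the curated registry worked example
uk <- registry_fixture("UK")
proposals <- reclassify(uk)
registry_report(proposals, n_registry_total = registry_size("UK"), "UK")
```
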