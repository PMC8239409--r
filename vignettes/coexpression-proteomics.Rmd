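---
title: "Protein co-expression modules from treatment-control proteomics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein co-expression modules from treatment-control proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexprot)
```

coexprot implements a complete label-free proteomics analysis for designs
that contrast treated and control samples: the in vitro setting is cardiac
microtissues exposed to three anthracyclines (doxorubicin, epirubicin,
idarubicin) at a therapeutic and a toxic dose over seven harvest timepoints
(2–336 h), and the in vivo setting is cardiac biopsies from heart-failure
patients grouped by anthracycline exposure. This vignette explains the
models and procedures, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the methodology left genuine freedom.

## From peptides to a protein matrix

LC-MS quantification reports one intensity per peptide ion, so a peptide
observed in several charge states (2+ to 7+) or modification states
appears several times. **Consolidation** sums these variants per sample —
total-ion-current logic on the linear scale; a consolidated cell is missing
only if every variant is missing. Summation (rather than, say, the maximum)
is a deliberate choice: variant rows split one analyte's signal, and only
their sum is proportional to abundance. The synthetic peptide generator
constructs variants that partition the peptide total, so consolidation is
exactly lossless there and the choice is pinned by tests.

**Protein inference** applies three rules in this order: proteins whose
peptide set is contained in another protein's set are redundant under
Occam's razor and removed (identical sets keep the lexicographically
smaller accession — a deterministic, arbitrary tie-break); peptides still
shared between retained proteins are ignored; proteins with fewer than two
remaining peptides fail identification. The order matters: subset removal
must see the full peptide sets, because after shared-peptide removal all
sets are disjoint and no subset relation survives.

**Hi3 quantification** ranks each protein's peptides by their mean
intensity over the samples in which they were observed (missing cells are
excluded from the mean rather than treated as zero, which would punish
peptides censored in a few samples), takes the top three (ties again
lexicographic), and averages their present values per sample before log2
transformation. Whether the original Top3 aggregate is a mean or a sum is
ambiguous in common practice; the mean is the default here because it keeps
proteins comparable when fewer than three peptides are available, and the
sum is available via `hi3_quantify(..., aggregate = "sum")`. On noise-free
peptides the mean differs from the true protein profile by a per-protein
additive constant on the log2 scale, which is irrelevant to every
downstream correlation-based step and checked to 1e-9 in the tests.

## Preprocessing

Proteins matching multiple UniProt identifiers are dropped
(`drop_ambiguous_ids()`), then proteins missing in strictly more than half
the samples are removed; zero-variance profiles (including proteins with
fewer than two present values) are removed with them because they carry no
correlation information. A protein missing in exactly half the samples is
kept — the filter is strict-greater.

Normalization is purely additive per sample on the log2 scale, so
within-sample differences between proteins are preserved exactly. The
time-course scheme works in two stages. First the controls: the reference
set is the proteins observed in *every* control sample, and each control is
shifted so its reference-set median equals the median of the controls'
medians. Then each treatment group — one (compound, dose, timepoint) cell —
is put on the scale of its matched controls: the common set is the proteins
present in all of the group's samples and all same-timepoint normalized
controls, the target is the median of those controls' medians over the
common set, and each treated sample is shifted to hit the target exactly.
"Every treatment" is resolved as each (compound, dose) pair per timepoint,
the grain at which roughly three control replicates stand against three
treated replicates; a compound-only grain would pool doses with different
exposure kinetics. The biopsy scheme is the one-stage analogue: the core
set is the proteins present in every sample and all samples are shifted to
the median of the per-sample medians over it. The median of per-sample
medians (not a pooled grand median) is used in both schemes for symmetry;
the median of an even-length vector is the mean of the central pair.
Normalized values are standardized to six decimals (round half-to-even) so
results are bit-stable across platforms.

## The signed network and module detection

The co-expression network is built from Pearson correlations over
pairwise-complete observations — after the 50% filter every pair retains
enough shared samples, and pairs with fewer than three shared observations
fall back to zero correlation. The signed adjacency
$a_{ij} = ((1 + r_{ij})/2)^\beta$ sends anti-correlated proteins toward
zero adjacency instead of conflating them with positively correlated ones.
The soft-threshold diagnostic reports, per candidate power, the mean
connectivity $\bar k$ and a scale-free fit index: connectivities are
binned into ten equal-width bins, empty bins dropped, and
$\log_{10}(\text{frequency})$ regressed on $\log_{10}(\bar k_{\text{bin}})$;
the unsigned $R^2$ and the slope are reported separately so a positive
slope cannot masquerade as a good scale-free fit.

Topological overlap
$\omega_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$ with
$\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$ smooths the adjacency through
shared neighbours; `1 − ω` is the clustering dissimilarity, verified
against a brute-force triple-loop oracle to 1e-12 on random instances.
Average-linkage clustering builds the protein dendrogram.

**Hybrid dynamic tree cut.** Modules are detected as coherent branches
rather than by a fixed-height cut. The implementation follows the published
idea — branch criteria on a normalized height scale plus a medoid-style
assignment stage — with the `deep_split` level (0–4) mapped to a maximum
core scatter of 0.64/0.73/0.82/0.91/0.95 and a minimum gap of three
quarters of the remaining headroom; heights are normalized between the 5th
percentile of merge heights and a cut height of 99% of the dendrogram top.
A branch is a candidate module when it holds at least `min_cluster_size`
(30) proteins, the mean of its lowest merge heights (its core scatter)
stays under the ceiling, and it hangs below its attachment point by at
least the minimum gap; candidates are reported at the highest level at
which they stay coherent, and a branch point joining two candidate lineages
splits them. Numerical equivalence with any particular reference
implementation is explicitly not a goal — recovery of planted structure is
the contract, and the acceptance suite holds the cut to an adjusted Rand
index of at least 0.8 on six planted modules under 20% intensity-dependent
missingness.

The assignment ("PAM-like") stage places each leftover protein with the
module of smallest average dissimilarity, ignoring dendrogram position.
The gate is cluster-relative by default: a protein joins only if its
average dissimilarity to the module does not exceed the loosest current
member's. An absolute gate on the normalized height scale proved fragile —
on realistic data the distance between background proteins and a module is
only slightly below the dendrogram top, so any fixed threshold either
absorbs noise into modules or strands genuine members; the self-calibrating
rule needs no tuning and keeps sub-threshold planted blocks grey, where
they belong. A numeric `pam_gate` restores the absolute behaviour if
desired.

**Eigengenes, merging, membership.** A module eigengene is the first right
singular vector of the module's standardized protein × sample submatrix;
missing cells are filled with the protein's own mean before z-scoring — a
deterministic choice that avoids an imputation-model dependency and biases
the eigengene toward no effect, never toward one. The sign is oriented
along the module's average standardized profile, and flipping every
protein flips the eigengene. Modules whose eigengenes are closer than 0.25
in `1 − cor` are merged iteratively (the merged module keeps its largest
constituent's label, colors are re-assigned by size at the end); the loop
is bounded by the initial module count and in practice converges in one or
two rounds. Module membership is `kME = cor(protein, eigengene)` over
pairwise-complete samples (undefined below three shared observations), and
the *weighted proteins* of a module are its members with `kME ≥ 0.8` —
inclusive, so a protein exactly at the threshold counts.

## Module selection, enrichment, integration, hubs

The study-level question — which modules react to treatment — is answered
visually in practice (eigengene bar plots, module PCA). To make that step
deterministic and testable, `select_affected()` applies a quantitative
proxy: a module is treatment-affected when the standardized eigengene
contrast (treated minus control over the pooled SD) reaches 1.0 in
magnitude, **or** when treated and control samples separate on the
module's first two principal components with a mean silhouette width of at
least 0.25. Both thresholds are configuration-exposed; the defaults give
exact recovery of a single planted affected module in at least 90% of
seeds while returning an empty set under the null in at most 10% — the
operating point the acceptance suite pins.

Over-representation uses the hypergeometric upper tail against a
background that defaults to the post-filter protein universe of the
analyzed dataset (not a whole proteome, which would inflate every
enrichment), with Benjamini-Hochberg adjustment — the standard reading of
"q-value" — and a pass at `p < 0.01` and `q < 0.01`. Disease-catalogue
annotation tables, per module: protein count, catalogue overlap, weighted
count, and weighted-and-catalogue count.

Integration is set algebra by design: proteins analyzed in both datasets,
weighted in at least one, weighted in both; the headline percentage is
rounded to one decimal, the network disease percentage to two. Log2 fold
changes are group-mean differences against matched controls
(same-timepoint controls for the time course — doses are not pooled; the
no-cancer patient group for biopsies), with missing cells excluded from
means and a cell left undefined whenever a group has no present value —
emitted as an empty cell, never as zero. The high-expression filter keeps
proteins strictly above log2 = 10 in *all* samples with no missing values.
The interaction network is induced on the query set only ("non-adding":
no neighbour expansion), self-loops and duplicate edges dropped, orphans
removed with a reported count, and hubs called at 30 or more unique
neighbours — unique neighbours, not interaction records, since a
multi-database edge list can repeat a pair. Interaction provenance is an
input file, not a live service query: database snapshots cannot be
version-pinned years later, and a fixed edge list keeps runs reproducible.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions. `generate_invitro_design(3)` reproduces the 139-sample layout
exactly: a full factorial of three drugs × two doses × seven timepoints
with three replicates plus 21 controls, the toxic idarubicin arm truncated
at 168 h and reduced to two replicates at 2 h and 24 h. The replicate
reduction is read as applying to the toxic dose — the reading under which
the printed total 139 is arithmetically exact (21 + 42 + 42 + 21 + 13);
the source text does not name the dose, and the interpretation is
configurable. `generate_biopsy_design()` reproduces the 16-biopsy cohort
(8 control, 6 anthracycline-treated, 2 other-treatment).

Planted modules are latent templates: standard-normal per-sample variation
plus an additive treatment shift of 2 log2 units on the affected modules
(the first two by default, with opposite signs — one up-, one
down-regulated). Restricting the effect to a couple of modules is not
cosmetic: a shift shared across many modules is a common latent factor
that correlates their templates and makes the planted partition
unidentifiable to *any* correlation-based method, contradicting the
generator's own contract that distinct modules be near-orthogonal. Member
proteins load on their template at 0.9 with Gaussian noise of SD 0.436,
giving a planted template correlation (planted kME) of about 0.90;
baselines are Uniform(8, 14) log2 units so that the log2 > 10
high-expression filter is exercised nontrivially. Missingness is
intensity-dependent by default (rank-based weights steeply favouring low
intensities, with the censored-cell count fixed so the realized rate
matches the target exactly up to rounding); MCAR is retained for clean
statistical tests. PPI graphs plant a configurable number of hubs wired to
at least the hub degree over a Poisson-mean background; disease sets
sample a fraction of chosen modules plus a background sprinkle. Every
generator consumes one integer seed under a locally scoped RNG — global
RNG state is never touched, and identical seeds give byte-identical
output.

What the generator does **not** emulate: peak detection and spectral
identification (the pipeline starts at a peptide intensity table),
retention-time structure, batch effects beyond additive sample shifts,
correlated (block) missingness, heavy-tailed noise, and
pharmacokinetic exposure profiles. Passing tests on this generator
therefore demonstrate algorithmic correctness and statistical operating
characteristics under a clean log-normal co-expression model — not
robustness to every artefact of real LC-MS data.

## Problem sizes and tolerances used by the test suite

The suites run at desk scale by choice: module recovery uses six planted
modules of 60/45/35/25/20/10 proteins on a 48-sample design (the
replicate-1 subset of the full design plus one control) across five seeds;
selection specificity uses three modules of 50/40/35 on the full
139-sample design across twenty seeds; oracle checks use 50 random
networks of 5–20 nodes (TOM, tolerance 1e-12) and 25 random enrichment
instances with backgrounds up to 500 (exact summation, 1e-12).
Normalization postconditions are verified to 1e-9 before rounding. Note
that three of the six planted recovery modules (25/20/10) sit below the
minimum module size of 30 on purpose — they must dissolve into grey, and
weighted-protein recall is accordingly measured over the detectable
modules; no correct implementation can recall members of modules below its
own detection floor.

## Known limitations

* The tree cut is a faithful re-implementation of the hybrid branch-cut
  idea, not a numerical clone of any reference implementation; partitions
  can differ in edge cases even where planted-structure recovery agrees.
* Pairwise-complete correlations are not positive-semidefinite in general;
  with ≤50% missingness after filtering this is benign, but extreme
  missingness patterns could produce inconsistent dissimilarities.
* Unsigned and "signed hybrid" networks, robust correlations (e.g. biweight
  midcorrelation) and block-wise decomposition for very large feature sets
  are out of scope.
* The eigengene mean-imputation understates variance for heavily censored
  proteins; their kME is correspondingly conservative.
* Selection thresholds (effect 1.0, silhouette 0.25) are calibrated on the
  generator's clean model; on real data they are starting points to be
  inspected, not oracles.
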