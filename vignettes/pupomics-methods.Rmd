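---
title: "Methods: from dam-pup microbiota transfer to integrated taxa-lipid-gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dam-pup microbiota transfer to integrated taxa-lipid-gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupomics)
```

`pupomics` models a common design in early-life microbiome research: mouse
dams receive an antibiotic prenatally, postnatally, during both periods, or
not at all (groups AC, CA, AA, CC), and their pups are profiled at
breastfeeding (BF), on chow diet (CD) and after a high-fat diet challenge
(HFD) across three measurement layers — genus-level 16S abundances, lipid
intensities, and gene expression. This vignette documents the statistical
procedures, their assumptions, the tunable parameters, and the design
choices made where the design was genuinely open.

## Transfer fidelity

A dyad pairs a dam's baseline community with her pup's breastfeeding
community via a shared dyad ID. A taxon counts as *shared* (a transfer
event) when its relative abundance reaches the presence threshold in both
members. The threshold defaults to `1e-4` relative abundance: with a
threshold of exactly zero, "shared" would be decided by sequencing-depth
noise at trace abundances, so a small positive floor is used and is
configurable for sensitivity analysis. Shared counts are monotone
non-increasing in this threshold.

Fidelity is summarised two ways: matched Bray–Curtis distances (each dam to
her own pup) and pooled distances (all dam × pup combinations within a
group). Matched distances are a subset of the pooled set; under genuine
dyad structure their mean falls below the pooled mean. Exposure arms are
compared with a Wilcoxon rank-sum test of matched distances against the CC
arm, which requires at least two dyads per arm.

Dams carry the timepoint label BF in the metadata: the allowed timepoint
vocabulary is the pup-centric {BF, CD, HFD}, and the dam's baseline sample
is identified by `generation = "dam"` plus the dyad ID, so no separate
"pregnancy" timepoint label is needed for pairing.

## Diversity and ordination

*Alpha diversity.* Observed richness counts nonzero features. Chao1 uses
the bias-corrected form `S_obs + F1(F1 − 1)/(2(F2 + 1))` in all cases. The
classic `F1²/(2F2)` form is undefined at `F2 = 0`; the bias-corrected form
handles that boundary without a special case, at the cost of diverging
slightly from the classic estimator when doubletons exist. This is a
deliberate, documented choice; whether a given study used bias correction
or a rarefied depth is often unstated, so the implementation picks the
well-defined variant and says so.

*Beta diversity.* Bray–Curtis, `BC(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ)`, is
computed on relative abundances by default (profiles are normalised before
comparison; a flag uses raw values). The computation is delegated to
`vegan::vegdist`. Two all-zero samples have no defined dissimilarity and
raise an error rather than a silent NaN.

*PCoA.* Classical scaling via `stats::cmdscale`: Gower double-centering of
`−D²/2`, eigendecomposition, coordinates scaled by the square root of the
positive eigenvalues. Bray–Curtis is semimetric, so negative eigenvalues
occur; they are reported unchanged, never corrected (no Cailliez or
Lingoes adjustment), and the proportion explained is taken relative to the
positive part of the spectrum. Requested axes beyond the positive spectrum
are zero-filled so that degenerate inputs (all-identical samples) still
return coordinates.

*PERMANOVA.* One-way, distance-based pseudo-F: with `SS_total` the sum of
squared dissimilarities over all pairs divided by n, and `SS_within`
accumulated within groups, `F = (SS_between/(a − 1))/(SS_within/(n − a))`.
The p-value is `(1 + #{F_perm ≥ F_obs}) / (1 + n_perm)` under free label
permutations (the study design has no strata within a timepoint, so no
restricted permutation scheme is offered). The permutation draw is
governed by an explicit seed, and `n_perm = "exact"` enumerates every
distinct label arrangement — feasible for the small per-group sizes where
exactness matters, and the form used to verify the sampled path. The
implementation is intentionally self-contained so the enumeration and
seeding contracts hold; `vegan::adonis2` serves as an independent
cross-check in the test suite, where the pseudo-F agrees to numerical
precision.

*Rank-sum test.* `stats::wilcox.test` supplies both paths: exact
enumeration when the combined sample size is at most 12 with no ties, and
the tie-corrected normal approximation with continuity correction
otherwise.

## LEfSe-style differential abundance

The screen keeps the two published decision stages. Stage 1 is a per-taxon
Kruskal–Wallis test across all groups at α = 0.05, deliberately without
multiplicity correction, matching the published algorithm's behaviour.
Stage 2 rescales each sample to a sum of 10⁶, then estimates an effect
size by bootstrapping: in each of 30 rounds, two-thirds of each class is
subsampled and a linear discriminant (`MASS::lda`) is fitted over the
surviving taxa; each taxon's round effect is the mean of (a) its unit-norm
LD1 coefficient scaled by the projected class separation and (b) its raw
class-mean difference. The reported score is `log10(1 + mean |effect|)`,
and taxa with score > 2 are returned, labelled with the group of highest
mean abundance. With more than two groups, the maximum pairwise effect is
used (one-vs-all reduction), and no within-class subclass stage exists —
the cohort design has no subclasses, a documented simplification of the
canonical tool. When a bootstrap subsample makes the within-class
covariance singular, that round falls back to the raw mean difference.

Exact numeric parity with the reference LEfSe implementation is not
promised — the reference's effect-size arithmetic has several unstated
conventions — but decision parity on well-separated cases is part of the
test contract: a planted 10-fold genus shift at n = 10 per group is
recovered with the correct enrichment label in ≥ 95 of 100 seeds, and the
stage-1 pass rate under a null of independent taxa stays within 2
percentage points of α.

Samples are internally sorted by (group, sample ID) before bootstrapping so
that jointly permuting the table and the labels cannot change the result.

## PLS-DA and the ratio + VIP lipid screen

The lipid screen reads "the first two principal components of the PLS-DA"
as the first two PLS latent variables — VIP is defined only for PLS
components, so a PCA reading would leave VIP undefined. The model is PLS1
via NIPALS: class labels coded ±1 and centered, predictors autoscaled,
weights `w_a` unit-norm, scores `t_a = X_a w_a`, X deflated by `t_a p_aᵀ`
per component, convergence tolerance 1e-10 (for a univariate response
NIPALS converges in one pass; the iteration cap of 500 is kept for the
general contract). Zero-variance features cannot be autoscaled; they are
dropped with a warning before fitting and assigned VIP 0.

VIP is `VIP_j = sqrt(p Σ_a SSY_a w_ja² / Σ_a SSY_a)` with
`SSY_a = q_a²(t_aᵀt_a)`. Because every weight vector has unit norm,
`Σ_j VIP_j² = p` holds algebraically, and the suite asserts it to 1e-8 on
random fits. The test oracle for scores and weights is an independent
solver that extracts each weight as the dominant eigenvector of the
cross-covariance outer product — the SVD route to PLS1 — rather than the
NIPALS recursion.

A lipid is flagged for a contrast (an exposed group vs CC within HFD) when
its linear abundance ratio r is < 0.66 or > 1.2 **and** VIP > 1, with
strict inequalities on all three boundaries; direction is "elevated" iff
r > 1.2. The ratio numerator is the exposed group; a group mean of exactly
zero is replaced by a pseudocount of half the smallest positive value in
the table, and nonzero means are never perturbed, so documented examples
such as "means 2 vs 1 → r = 2" hold exactly. Each contrast is screened as
its own two-class PLS-DA rather than one pooled multi-group model: the
pooled alternative exists in the field, but the per-contrast form matches
how fold changes against CC are defined and keeps the VIP interpretable
per comparison.

## Lipid nomenclature and cognate matching

The parser accepts `CLASS(C:D)` shorthand with arbitrary internal spacing
and resolves trivial fatty-acid names through a bundled, user-extensible
TSV (`behenic acid → FA(22:0)`; a stated composition that contradicts the
lookup is an error, not silently trusted). Canonical form is `CLASS(C:D)`
and parsing canonical output is idempotent.

Cognate matching pairs an LPC with a fatty acid when their sum
compositions (total carbons : double bonds) are equal. Note the chemistry
caveat: PLA2 hydrolyses the sn-2 ester of a glycerophospholipid, so the
true released fatty acid of a mixed-chain PC would generally *not* share
the lyso product's composition; matching on composition equality follows
the worked usage in the field (behenic acid (22:0) paired with LPC (22:0))
and is the rule implemented, with sn-position bookkeeping declared out of
scope. The co-elevation filter then keeps pairs in which both members are
flagged "elevated" in the same contrast — the candidates plausibly
produced by sPLA2-X action.

## Network integration

Edges come in four layers. Taxon–lipid edges keep Spearman ρ > 0.3,
positive only; lipid–gene edges keep |ρ| > 0.4 of either sign; both
thresholds are strict inequalities. Cognate edges attach fatty-acid nodes
to their LPCs, and literature gene–gene edges are inputs — never inferred —
added only between genes already present (a dangling curated edge is a
warning, not an error, because curation lists routinely exceed the
expression table). Correlation p-values (t approximation) are reported for
transparency but never used for edge selection; selection is on ρ alone.
Layer invariants are re-asserted at assembly time, so an out-of-threshold
edge cannot enter a network.

Correlations for a group's subnetwork are computed over the focal group
pooled with CC at the HFD timepoint by default. With five samples per
group in a typical cohort, group-only Spearman ranks are extremely coarse
(n = 5 admits only 120 orderings); pooling with the reference doubles n
while preserving the contrast's biological signal. A group-only mode is
available where the pooled assumption is unwanted.

The pruning pass implements the "hidden unless co-expressed" display rule:
when co-elevated cognate pairs are supplied, LPC nodes without a
co-elevated cognate fatty acid are removed with their incident edges, and
nodes left isolated are dropped. Pruning never adds nodes, and summary
counts (LPC nodes, fatty-acid nodes, correlation edges) are monotone
non-increasing under it.

Genes can be pre-filtered to MASLD-relevant processes (ER stress,
apoptosis, inflammatory response, PI3K-AKT, TNF-MAPK, PPAR signalling) via
a gene → pathway map before entering the correlation layer.

## The synthetic-data generators

The multi-omics generator draws a latent Gaussian copula whose correlation
matrix carries the planted taxon–lipid–gene blocks. A planted value ρ is
interpreted as the *target Spearman correlation* of the output: the copula
is parameterised with Pearson `r = 2 sin(πρ/6)`, the exact bivariate-normal
relation between the two coefficients, so downstream rank statistics
recover the planted number (verified numerically in the suite: planted
0.7 at n = 200 is recovered within ±0.1). The taxon–gene leg of a chain is
set to `r²`, the value consistent with conditional independence given the
lipid. Because arbitrary planted blocks can be mutually inconsistent, the
matrix is projected to the nearest positive-definite correlation matrix by
eigenvalue clipping at 1e-8 before sampling. Marginals are log-normal with
a feature-specific location drawn once per cohort (`meanlog ~ N(3, 1)`,
`sdlog = noise_sd`, default 0.5): heavy-tailed like real intensity data and
strictly monotone, so rank correlations pass through unchanged. Group fold
multipliers are applied on the linear scale to match the screening scale
of the abundance ratio.

The dyad generator draws each dam's composition from a Dirichlet
distribution (concentration 0.5 by default — uneven, realistically
dominated communities) and derives the pup by independent per-taxon
dropout at the group's rate, multiplicative log-normal jitter (sd 0.2,
keeping pups near their dams without exact copying) and renormalisation.
Default dropout rates (CC 0.05, AC 0.1, CA 0.4, AA 0.5) encode the
qualitative finding that postnatal exposure removes roughly half of the
maternally present taxa while control dyads transmit nearly everything;
the literature reports no numeric dropout rates, so these are calibration
choices of the generator, stated once and not tuned. A dropout
probability of 1 leaves an all-zero pup, which is deliberately left
unnormalised.

Both generators take a single seed, use one local RNG per call, and never
touch the global RNG state; identical configs give byte-identical tables.

What the generators do *not* emulate: sequencing depth and compositional
count noise (abundances are continuous intensities), zero inflation beyond
dyad dropout, chimeras or ASV-calling artefacts, longitudinal dependence
across timepoints, and batch effects. Passing tests therefore demonstrate
correctness of the statistical machinery on clean planted structure, not
robustness to every artefact of real sequencing data.

## Numerical and reproducibility choices

- Ties in any rank computation use average ranks.
- Strict `>` at every published threshold (0.3, 0.4, 0.66/1.2, VIP 1,
  LDA 2); boundary values never pass.
- The pipeline derives one sub-seed per stage as a stable hash of
  (master seed, stage name), so inserting a stage cannot reshuffle the
  randomness of the others; the run manifest records the config hash and
  seed, and identical configs reproduce artifacts byte-identically.
- Missing cells in input TSVs are errors, not zeros: the zero-vs-missing
  distinction changes Spearman ranks, so it must be made explicitly by the
  data producer. Transposed tables are declared with a flag, never
  guessed.
- Test and acceptance problem sizes are chosen to keep the planted effects
  comfortably detectable at small n: 4 × 25–50 samples for copula
  recovery, 10 samples per group for the LEfSe and lipid screens, 6 dyads
  per group (the cohort size of a typical litter study) for transfer
  separation, and 100-seed repetitions for all rate estimates.

## Known limitations

- The LEfSe stage reproduces decisions, not the reference tool's exact
  scores; cross-tool score comparisons should allow for that.
- PERMANOVA is one-way without strata; factorial designs need an external
  tool (e.g. `vegan::adonis2`).
- Cognate matching ignores sn-position, as discussed above.
- The headline cohort-specific counts of a real study (numbers of DE
  lipids, per-group network sizes) depend on upstream raw-data processing
  outside this package's scope (ASV calling, LC-MS identification, RNA-seq
  quantification); the package reproduces the decision rules and their
  behaviour on planted truth, not those dataset-specific totals.
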