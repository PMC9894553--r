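---
title: "Methods: phylogenetic comparative analysis of tissue-biased expression"
author: "exprphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative analysis of tissue-biased expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprphylo)
```

# Overview

`exprphylo` implements a comparative-transcriptomics pipeline for
tissue-biased gene expression across a species phylogeny. Its inputs are
per-library transcript abundances (TPM), library metadata (species,
individual, tissue), a rooted bifurcating species tree, a transcript →
homology-group map with optional reference gene symbols, and optionally a
table of known gene–gene interactions. The pipeline has six analysis
stages:

1. **Normalization** — TPM → TPM10k → natural log; averaging over
   homology groups, then over replicate individuals.
2. **Differential expression** — a per-species negative-binomial Wald
   test between a focal tissue and carcass, and a cross-species "core
   cohort" of consistently upregulated parent genes.
3. **Variance partitioning** — per-gene two-factor ANOVA splitting
   expression variance into tissue, species, and residual components,
   over nested clades or all species pairs, with TVG/SVG calls.
4. **Expression bias** — per-individual log ratios of focal to reference
   tissue, averaged as above, giving a genes × species bias matrix.
5. **Ancestral reconstruction** — maximum-likelihood Brownian-motion
   (BM) states at internal nodes, per-branch scaled changes, and
   qualitative gain/loss calls.
6. **Coevolution networks** — Pearson correlation of scaled changes over
   equivalent branches between all gene pairs, compared against
   interaction annotations and thresholded into networks.

A synthetic-data module generates full datasets with known ground truth
so that every stage is testable without any external download.

# Data model and conventions

Expression lives in a `TissueExpr`, a `SummarizedExperiment` whose
`colData` records species (4-letter codes, matched case-insensitively),
individual, and tissue (ovary / head / carcass / whole). Because every
species has its own reference transcriptome, a combined matrix needs a
marker for "this transcript is not in that species' reference": such
cells are `NA` and all averaging and testing ignores them. Negative
values are invalid before the log transform; all files are plain UTF-8
TSV.

Trees are `BranchTree` objects wrapping an `ape::phylo`. The pipeline
requires a rooted, strictly bifurcating tree with positive branch
lengths; ultrametricity is assessed with relative tolerance 1e-6 on the
tip-depth spread. The `2n - 2` edges of an n-tip tree receive stable
integer ids by pre-order traversal with children visited in alphabetical
order of their smallest descendant tip — a convention chosen only for
determinism (any stable rule would do); it is invariant to rotations of
the input newick, which is tested by permuting child order in the file.

When a gene lacks data for some species, its tree is pruned and branches
are matched back to the full tree by their (parent, child) endpoints,
identified through descendant tip sets. An edge created by collapsing a
path through a removed node has no full-tree equivalent and contributes
to no branch. This is the conservative reading of "equivalent branches":
a gene only informs a branch whose two endpoint nodes both survive its
pruning.

# Normalization

TPM is a within-library unit and not comparable across references of
different sizes, so each value is rescaled to
$\mathrm{TPM10k} = \mathrm{TPM} \times n_{\mathrm{ref}} / 10^4$ with
$n_{\mathrm{ref}}$ the reference size of that library's species. We take
$n_{\mathrm{ref}}$ to be the number of homology-group-collapsed genes
with at least one expressed transcript in the species (the count is
overridable per species): "genes in the reference" is ambiguous between
transcripts and collapsed genes, and the collapsed count is the unit the
rest of the pipeline works in.

Values are natural-log transformed exactly once. Zeros have no finite
log and are masked to `NA` rather than pseudocounted — no pseudocount
belongs at this step; the bias ratio below has its own. Group averages
are arithmetic means of member transcripts per library; replicate
averages are means over individuals per (species, tissue). A cell with
no finite contributor is `NA`, never zero. Averaging is
permutation-invariant and is tested against direct recomputation.

# Differential expression

The DE stage is a deliberately simple, fully documented
negative-binomial Wald test; it is *not* a reimplementation of any
shrinkage-based package, and the pipeline downstream consumes only its
log2 fold changes and adjusted p-values. Per transcript, with replicate
abundances in two tissues:

* dispersion $\phi$ (Var $= \mu + \phi\mu^2$) is moment-estimated per
  group as $(s^2 - \bar x)/\bar x^2$, pooled with degree-of-freedom
  weights and floored at 1e-8;
* the effect is $\log_2\!\big((\bar x_f + 0.5)/(\bar x_r + 0.5)\big)$;
* its delta-method variance is
  $\sum_i (1/(\bar x_i + 0.5) + \phi)/n_i$ (natural-log scale, rescaled
  to log2), giving a two-sided normal Wald p;
* Benjamini–Hochberg adjustment runs across all tested transcripts, and
  calls use `padj < 0.01` by default.

Transcripts with all-zero counts in both tissues are excluded and
reported. Swapping the tissues negates the effect and preserves the
p-value; BH monotonicity is tested.

**Calibration and power.** On null NB count data at the generator's
default conditions (per-transcript means lognormal(3, 1.5), $\phi = 0.1$,
3 vs 3 replicates, 2,000 transcripts) the BH-significant fraction at
$\alpha = 0.01$ is about 0.5% (seed-to-seed range roughly 0.2–1.2%). Two
caveats are worth knowing. First, with three replicates the moment
estimate of $\phi$ is noisy, and occasionally near zero for a transcript
whose replicates happen to agree; such transcripts can reach extreme
Wald statistics, which is why the null fraction is not far below the
nominal level. Second, a 2-fold effect at these settings is detected
with BH-adjusted sensitivity of only ~15–20% (raw-p sensitivity ~40%):
$\mathrm{SE}(\widehat{\ln FC}) \geq \sqrt{2\phi/n} \approx 0.26$ at
$n = 3$, so $\ln 2$ effects are intrinsically borderline. The
power-recovery test asserts sensitivity above a pilot-calibrated floor
(10%) rather than an aspirational one. Finally, the test is calibrated
on the *count* scale; on TPM-rescaled values the Poisson component of
the NB variance floor is no longer meaningful and the test becomes
mildly anti-conservative (~3% at nominal 1% in our pilots) — a
limitation shared by any count model applied to rescaled abundances.

The **core cohort** collects parent genes with at least one transcript
significantly upregulated in the focal tissue in at least `min_species`
species (default 10 of 12). The source material is inconsistent between
"ten or more" and "more than ten"; we default to the operational
"ten or more" form and expose the threshold.

The **atlas enrichment** rule reproduces a reference-atlas convention:
per-tissue FPKM over whole-body FPKM with a pseudocount of 2 on empty
values; a gene is ovary-enriched when ovary is the argmax excluding the
head/brain/eye compartment, and head-enriched when that compartment wins
once ovary is excluded. The two calls are not mutually exclusive by
construction.

# Variance partitioning

For each gene the replicate- and group-averaged log TPM10k values — one
value per (species, tissue) — enter a sequential (type-I) two-factor
ANOVA with tissue first and no interaction term; reported proportions
are each factor's sum of squares over the total. Because the averaged
design is balanced with one observation per cell, the sequential
decomposition is order-invariant, which the tests assert by comparing
tissue-first and species-first fits. Genes with a missing cell or zero
total SS are excluded and reported. The implementation computes the sums
of squares directly from marginal means; `anova(lm(...))` serves as the
independent oracle in the tests (agreement to 1e-9).

A gene is *highly variable* when residual variance is below 25% (the
default rule) or, under the stricter variant, when a single factor
explains at least 75%; the two rules disagree for genes like
(0.7, 0.2, 0.1) and both are available because the source definitions
differ. Highly variable genes are SVGs when the species proportion is at
least twice the tissue proportion, TVGs in the converse case, otherwise
"neither"; TVG and SVG are mutually exclusive.

`cladeSweep()` runs the partition over named clades (checked for
monophyly, with offending tips named) or over all species pairs — 66
analyses for 12 species. On data simulated with a fixed tissue effect
and BM species divergence, the species proportion rises and the tissue
proportion falls with clade depth, mirroring the crossover behaviour the
method is designed to expose; this is a seeded property test.

# Expression bias and ancestral reconstruction

Bias is quantified per individual as
$B = \ln\!\big((\mathrm{TPM10k}_{\mathrm{focal}} + 0.01) /
(\mathrm{TPM10k}_{\mathrm{ref}} + 0.01)\big)$ — the ratio is computed
per library pair *before* any averaging, then averaged over group
members and replicates. The 0.01 pseudocount makes the all-zero case
exactly $B = 0$ (equal expression), and ratios cancel
individual-specific counting efficiency. Fragmentation also largely
cancels: a fragment's numerator and denominator share its split weight,
so group-averaged bias of fragmented genes matches unfragmented runs
within sampling error (tested).

Ancestral states are the maximum-likelihood values under Brownian
motion: the node assignment minimizing
$\sum_{\mathrm{edges}} (v_{\mathrm{child}} - v_{\mathrm{parent}})^2 /
\ell$, equivalently the GLS solution under the BM covariance; the BM
rate cancels from the point estimates, and no measurement-error term is
included. The implementation is a two-pass Gaussian message-passing
scheme, linear in the number of nodes. It is verified to 1e-8 against a
brute-force solve of the normal equations on 200 random 4–8-tip trees,
and against an established fast reconstruction from the installed
phylogenetics stack. Reconstruction requires more than three tips with
data; genes below that are skipped and reported. Reconstructed values
are convex combinations of tip values and lie within their range.

The **scaled change** on a branch is
$(v_{\mathrm{child}} - v_{\mathrm{parent}})/\ell$; a 12-tip tree yields
22 such values per full-data gene. Qualitative **shifts** are branches
on which the reconstructed bias crosses zero (gain: $\leq 0$ to $> 0$;
loss: the converse), and `rankSwings()` reports the largest
$|v_{\mathrm{child}} - v_{\mathrm{parent}}|$ per direction with
deterministic (gene, branch) tie-breaking. Under null BM, sign changes
fall preferentially on long branches (rank-correlation property test).

# Coevolution networks

For genes represented across all species, every pair's Pearson
coefficient is computed over the 22 equivalent branches. The reported
comparison count follows the $G^2$ convention (all ordered pairs
including self), the only convention under which 1,143 genes give
1,306,449 comparisons; the distinct unordered count is also emitted.
Outlier filtering removes whole gene rows containing any change more
than two sample standard deviations (n − 1 denominator) from the mean
over all matrix entries; with zero overall SD nothing is removed.

Interaction classes (physical / enhancement / suppression) are compared
to a fresh random sample of 5,000 unknown-pair coefficients with a
Welch two-sample t-test (pooled-variance optional), repeated 100 times;
the maximum p over repeats is reported, plus one enhancement-vs-
suppression test. Unknown pairs exclude labeled pairs only, not all
pairs touching labeled genes; pairs collapsing into a single homology
group are dropped. Networks take all partners of a focus gene with
$|r|$ *strictly* greater than the threshold (default 0.825), keeping the
sign.

## The null distribution of evolutionary correlations

A point that matters for interpretation: the per-branch scaled changes
are **not** 22 exchangeable data points. True BM increments divided by
branch length have variance $\sigma^2/\ell$ — strongly heteroscedastic
on any ultrametric tree, whose branch lengths necessarily vary — and
reconstruction makes the 22 entries mutually correlated because adjacent
branches share estimated node values. Consequently the null spread of
$r$ between independent genes is wider than the classical 22-point
Pearson null: in seeded simulations the SD of null $r$ is ~0.30–0.41
(coalescent or balanced trees alike) against the classical 0.218,
i.e. roughly 8–11 effective data points. The acceptance suite contains a
Kolmogorov–Smirnov check of pipeline null correlations against the
classical 22-point form, and it fails by design of the statistic — we
keep it as an honest negative alongside a passing machinery-level check
(on matrices of i.i.d. changes the correlation stage matches the
classical null exactly). Practically, this widened null is a good reason
for the very high 0.825 edge threshold, and network edges should be read
as ranked hypotheses, not calibrated significance calls.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: 12
species on an ultrametric coalescent-shaped tree of depth 1.0 (relative
time), 3 tissues (ovary / head / carcass), 3 replicate individuals, and
homology groups that may be fragmented into 2–4 transcripts per species.
Defaults, fixed once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 12 | tips of the simulated tree |
| `tree_depth` | 1.0 | root-to-tip depth, relative time |
| `n_genes` | 500 | homology groups |
| `de_fraction` | 0.1 | genes with true ovary bias at the root |
| `ovary_bias` | ln 2 | root bias of those genes (2-fold) |
| `sigma2` | 1.0 | BM rate of log bias per unit time |
| `rho` | 0.9 | BM correlation of the correlated pairs |
| `n_correlated_pairs` | 20 | pairs evolving under bivariate BM |
| `baseline_log_mean`, `baseline_log_sd` | 3, 1.5 | lognormal carcass abundance |
| `nb_dispersion` | 0.1 | NB dispersion, Var $=\mu+\phi\mu^2$ |
| `fragmentation_prob` | 0.1 | chance a transcript splits into 2–4 fragments |

Log bias evolves from its root value by Gaussian increments of variance
`sigma2 × branch length`; correlated pairs receive increments with
correlation `rho` on every branch (bivariate BM). Carcass expectation is
drawn log-normally per gene; ovary expectation is
$\mu\, e^{\mathrm{bias}}$; head mirrors carcass unless head bias is
switched on (one contrast suffices to exercise the machinery, so head
bias is off by default). Fragment expectations are a Dirichlet split of
the parent's and sum to it exactly before sampling; counts are
NB-sampled and each library is rescaled to sum to $10^6$, so emitted
values are genuine TPM. The same configuration and seed give
byte-identical output.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: read-level artifacts (mapping,
GC, length biases), assembly errors beyond count-level fragmentation,
incomplete orthology or wrong homology grouping, library-preparation
batch effects, unequal replicate numbers, and any departure of bias
evolution from homogeneous-rate Brownian motion (no OU pull, no rate
shifts, no punctuation). Recovery results (e.g. mean $\hat r \approx
0.9$ for $\rho = 0.9$ pairs at the bias-tip level) are conditional on
the BM model being exactly true. Passing count-level noise through the
whole pipeline attenuates evolutionary correlations substantially
(to ~0.15 at default depths in our pilots) because short-branch scaled
changes amplify measurement noise — a real-data caveat inherent to the
method, visible here because the generator provides ground truth.

# Numerical choices and problem sizes

Ties in swing ranking break by (gene, branch); argmax ties in the atlas
rule take the first tissue in column order; ultrametricity tolerance is
relative 1e-6; dispersion floor 1e-8; constant genes (zero total SS) and
zero-variance genes (undefined $r$) are excluded and reported rather
than patched. Degenerate inputs — polytomies, non-positive or missing
branch lengths, unknown tissue labels, duplicate transcripts, self-pairs
— are hard errors or logged drops as documented per function.

Test and acceptance runs use problem sizes chosen to make sampling error
small relative to the asserted margins while keeping the suite quick:
10,000 genes for BM closed-form checks, 2,000 transcripts for DE
calibration, 200 disjoint pairs for null-distribution checks, 200
random trees for oracle equivalence, and a 500-gene / 12-species /
20-correlated-pair end-to-end run. The acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities from scratch
at these sizes under a user-supplied seed.

# Known limitations

* One BM rate per gene, no measurement-error term in the reconstruction:
  rate heterogeneity or tip error will bias scaled changes, particularly
  on short branches.
* The DE stand-in has no dispersion shrinkage or outlier handling and
  ignores individual pairing; it is honest about being underpowered for
  2-fold effects at 3 replicates.
* Evolutionary correlations have a wide, tree-shape-dependent null (see
  above) and the edge threshold is a practical screen, not an error-rate
  guarantee.
* Branch matching after pruning discards merged edges; genes with many
  missing species contribute little to the correlation stage by design.
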