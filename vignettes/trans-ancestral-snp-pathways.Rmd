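---
title: "From ancestry-stratified SNP lists to molecular pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ancestry-stratified SNP lists to molecular pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppath)
```

## The problem

Association studies of systemic lupus erythematosus (SLE) on immune-focused
genotyping arrays yield hundreds of SNPs per ancestral cohort — on the order
of 750 in European-ancestry (EA) and 700 in Asian-ancestry (AsA) analyses —
of which only a handful are shared between ancestries. Individually these
variants explain little; the scientific question is which *molecular
pathways* the ancestry-specific genetic architectures converge on, because
pathway-level differences (for example elevated oxidative-stress and
mitochondrial programs versus a dominant interferon response) are candidate
explanations for ancestry-linked differences in disease severity.

`snppath` implements that inference chain as a tested pipeline:

1. **SNP functional categorization** and a two-proportion *z*-test contrast
   of category fractions between ancestries.
2. **SNP-to-gene mapping** through a four-tier evidence cascade — eQTL
   targets (E-genes), regulatory-element targets (T-genes), coding
   consequences (C-genes), and a closest-proximal-gene fallback (P-genes) —
   after excluding the HLA region.
3. **Category over-representation** of the predicted gene sets against
   functional and cell-type annotation libraries.
4. **Protein-interaction network analysis**: induced subnetworks, a
   connectivity-enrichment gate, MCODE molecular-complex clustering,
   cluster metastructures, and comparison against random gene cohorts.
5. **Single-sample signature scoring** of expression matrices with a
   KS-like weighted random walk, followed by Welch *t*-tests (case versus
   control) and simple linear regressions against clinical covariates
   (SLEDAI, anti-dsDNA, C3).

External resources (GTEx-style eQTL catalogues, enhancer-target atlases,
coding annotation, the STRING interactome) enter as *tables*, never as live
queries, so every run is reproducible and testable offline.

## Models and statistics

### Two-proportion z-test

For counts $c_a/n_a$ and $c_b/n_b$ the statistic is the pooled form
$z = (\hat p_a - \hat p_b)\,/\,\sqrt{\hat p(1-\hat p)(1/n_a + 1/n_b)}$
with two-tailed normal p-value and **no continuity correction**, matching
the test as it is conventionally reported for SNP category contrasts.
Category flags use raw $p < 0.05$ without multiplicity adjustment — that is
the published reporting rule for these per-category panels — but
Benjamini–Hochberg columns are emitted alongside for transparency. When the
pooled proportion is 0 or 1 the statistic is defined as $z = 0$, $p = 1$.

### The evidence cascade

E, T and C lookups are *independent*: one SNP may contribute genes in all
three classes. P is strictly a fallback, assigned only when a SNP has no
E/T/C link, which makes "no SNP holds both a P and another assignment" an
invariant rather than a convention. All predicted genes are treated as
equal entities downstream regardless of evidence class. Coordinates are
1-based with fully closed intervals; the HLA exclusion window
(chr6:28014374–33683352) removes SNPs at both endpoints inclusive. Proximal
distance is 0 inside a gene and the gap to the nearest interval end
otherwise; equidistant ties resolve lexicographically by gene symbol. A
gene is *trans-ancestral* ("shared") exactly when SNP support covers every
ancestry, via any evidence class.

### Over-representation

Each category is scored by the one-sided exact hypergeometric tail on the
2×2 table over the annotation library's own universe (not the genome — the
library defines its coverage), with the sample odds ratio $ad/bc$. A
category is *enriched* when OR > 1 and $-\log_{10} p > 1.33$. The
$-\log p$ threshold is read as base-10 ($p \lesssim 0.0468$, consonant with
the ubiquitous 0.05 convention); a natural-log reading would imply
$p < 0.26$, inconsistent with everything else in the reporting style. The
test is one-sided for over-representation because depletion is never
reported in this analysis style; the direction of a sub-unity odds ratio is
still visible in the signed heat table.

### Network stage

Subnetworks are induced on the query genes with edges at or above a
STRING-style combined score (default 400, the "medium confidence"
convention; analyses in this style rarely state their cut, so it is exposed
as configuration). The connectivity gate tests whether the subnetwork has more
edges than a degree-preserving null predicts: the expected edge count is the
Chung–Lu approximation $\lambda = \sum_{u<v} \min(1, k_u k_v / 2m)$ with
degrees and $m$ from the background network, and the p-value is the upper
Poisson tail at the observed count. The platform's internal null is not
published in closed form, so this documented approximation stands behind
the verbatim gate rule ($p < 10^{-16}$, strict). On dense synthetic
backgrounds the gate is conservative; the pipeline records the gate outcome
in its report and proceeds, leaving enforcement to the analyst.

MCODE is implemented from scratch: vertex weight = (highest k-core number)
× (density of that core) over the closed neighborhood, zero below degree 2;
complexes grow breadth-first from the highest-weight unassigned seed,
absorbing neighbors whose weight is at least $(1 - 0.2)$ × seed weight;
post-processing drops complexes without a 2-core and the haircut restricts
members to the complex's 2-core. All tie-breaks (seed selection, traversal,
ranking) are lexicographic by vertex name so output is deterministic.
Parameters default to the standard plugin values (degree cutoff 2, node
score cutoff 0.2, k-core 2, max depth 100, haircut on, fluff off).

**A property of the canonical expansion rule worth knowing.** The
inclusion threshold is relative to the *seed's* weight. In graphs where two
dense modules have near-equal vertex weights, a single cross edge suffices
to absorb the second module into the first complex (the far endpoint clears
the threshold, and from there the whole module follows). On real
interactomes, weight heterogeneity usually prevents this; on homogeneous
planted-partition benchmarks it is endemic. Concretely, at 3 planted
modules of 8 vertices (within-module edge probability 0.9, background
0.01), the expected ~1.9 cross edges per graph merge or fragment modules
often enough that adjusted-Rand recovery of the planted partition at the
0.9 level is reached only in a minority of replicates. The corresponding
acceptance check is asserted at its stated level and fails for this
documented reason; the disjoint-clique recovery and brute-force
vertex-weight checks pin down that the implementation, not the arithmetic,
is canonical.

Cluster metastructures report size, intra-cluster and inter-cluster edge
counts, with the edge-conservation identity (intra + pairwise inter +
unclustered-incident = total) asserted on every computation. Comparison to
an equally sized random gene cohort uses Welch's *t* per metric. With a
handful of clusters per network, a *per-replicate* Welch test at
$p < 0.001$ is statistically out of reach (Satterthwaite df ≈ 2), so the
random-null acceptance check takes the population-level form such
comparisons use in practice: the direction (real clusters larger, more
intra-connected) must hold in at least 90% of replicates, and the Welch
test at $p < 0.001$ is applied to the cluster populations pooled across
replicates.

### Single-sample scoring

The scorer follows the GSVA algorithm. Per gene, an expression-level
statistic is the kernel CDF of each observation against the gene's own
distribution — Gaussian kernel with bandwidth $s_i/4$, floored at $10^{-8}$
for constant genes, or the empirical CDF under `kcdf = "ecdf"`. Per sample,
genes are ranked by decreasing statistic (ties lexicographic by gene label)
and symmetrized as $r = |p/2 - \text{rank}|$. A KS-like walk runs down the
ranked list with in-set steps $r^\tau$ (normalized within the set, default
$\tau = 1$) and out-of-set steps $1/(p - m)$. The score is the *magnitude
difference*: largest positive plus smallest negative walk deviation, which
is bounded in $[-1, 1]$ — the documented default of the reference tool for
this scoring method (the max-absolute-deviation summary is available as an
option).

Two invariance facts shape the tests. Under the empirical-CDF kernel the
scores depend on within-gene ranks only, so they are *exactly* invariant to
any strictly monotone per-gene transformation. Under the Gaussian kernel
the statistic values change under non-affine monotone maps and cross-gene
orderings can flip, so exact invariance holds for affine maps only; the
suite asserts each kernel's own guarantee. Similarly, negating the matrix
reverses every ranking exactly, but the even-length symmetric rank
$|p/2 - t|$ is not perfectly mirror-symmetric, so score signs flip without
exact magnitude preservation; the sign-flip is asserted on well-separated
instances.

Degenerate contracts: a set covering all genes scores 0 (no out-of-set
steps exist) and is flagged; a sample with completely tied statistics (a
constant matrix) scores 0 for every set; sets with fewer than `min_set`
mapped genes are skipped with a warning.

### Downstream tests

Welch's *t* uses the Satterthwaite approximation with a documented fallback
when both groups have zero variance (exact equality: $p = 1$ if means
agree, else $p = 0$). Regressions are ordinary least squares with the
slope's two-tailed *t*-test; $R^2$ equals the squared Pearson correlation.
The panel report flags sets at Welch $p < 0.05$ and supports
active-subgroup filters (e.g. SLEDAI ≥ 6) for the regression grid, with
the subgroup's $n$ reported.

## The synthetic world

The generator defaults *are* the reported study-scale conditions wherever
such values exist: 757 EA and 700 AsA SNPs with 20 shared; roughly 70%
non-coding and 8% coding variants; 54 functional and 30 cell-type
annotation categories; a chromosome-6 exclusion window at the stated
coordinates. Where no value is reported, one realistic choice was made and
fixed:

* **Ancestry contrast in ncRNA.** AsA ncRNA fraction 12% versus EA 6% — a
  twofold contrast in the reported direction, sized so the two-proportion
  test detects it with high power at the given cohort sizes.
* **Lookup hit rates.** eQTL 0.45 (between the reported ~29% EA and ~60%
  AsA rates), regulatory 0.07 (~105 of ~1450 SNPs), coding links for
  missense/nonsense SNPs with probability 1 (the ~3% consequence frequency
  reproduces the reported ~44 coding SNPs). Targets per hit are
  $1 + \text{Poisson}(2)$, matching the ~3 genes-per-eQTL ratio implied by
  the printed totals.
* **Interactome.** 400 nodes carrying 5 node-disjoint planted modules of 12
  genes (within-module edge probability 0.8) on a background of density
  0.05, chosen to mirror a medium-confidence STRING network's density;
  scores are uniform on 400–1000. Modules are planted on SNP-linked genes,
  emulating the empirical tendency of disease genes to form dense
  interaction modules.
* **Expression.** The matrix spans the full 2000-gene universe, 20 cases
  versus 20 controls, gene baselines uniform on log2 6–10, i.i.d. Gaussian
  noise (SD 1), and two planted signatures of 25 genes shifted by
  δ = 1.0 log2 units in cases. Planted sets are mutually disjoint and the
  ten decoy sets are drawn from unshifted genes, so decoy flags measure the
  false-positive rate. The genome-scale matrix matters scientifically, not
  just computationally: per-sample rank scoring makes unshifted sets
  anti-enriched when a large fraction of the matrix is shifted, and that
  compositional artifact only vanishes when planted signatures are a small
  fraction of profiled genes — the regime of real arrays.
* **Metadata.** SLEDAI-, anti-dsDNA- and C3-like covariates are linear in
  the first planted signature's true activity (the per-sample mean
  baseline-centred expression of its genes) plus Gaussian noise, with C3
  coupled negatively, mimicking the clinical directionality.

What the generator does **not** emulate: linkage disequilibrium, allele
frequencies or genotypes (inputs are post-association SNP lists);
heavy-tailed or count-distributed expression; batch structure; correlated
gene-gene noise; heterogeneous PPI degree distributions. A green test
therefore establishes correctness of the pipeline's computations and
recoverability of planted structure under idealized noise — not performance
on real cohorts.

## Numerical choices

* Sub-seeds per generator stage are fixed offsets from the master seed, so
  every stage is independently reproducible, and all generators restore the
  caller's RNG state.
* Gene symbols are synthetic tokens (`G000001`, …) that cannot collide with
  real symbols; gene coordinates tile 22 chromosomes of 40 Mb in
  non-overlapping 20 kb intervals.
* All stochastic tests are either fixed-seed or rate-based over many seeds
  with bounds set from the designed power, never from observed runs.
* The run report is written with fixed JSON digits and no timestamps or
  absolute paths, making end-to-end byte-determinism testable.

## Known limitations

* MCODE module merging on weight-homogeneous graphs, described above.
* The connectivity gate's Chung–Lu/Poisson null is an approximation to the
  interaction platform's unpublished model; the gate threshold is kept
  verbatim but the absolute p-values are not comparable to the platform's.
* The enrichment false-positive rate of the one-sided exact test is below
  its nominal level on small universes (discreteness), so calibration
  checks bound it from above.
* Cluster-to-overall-function grouping is a configurable label map; the
  default splits generated categories evenly and carries no biological
  meaning.
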