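---
title: "Selection scans in structured populations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans in structured populations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

sweepscan detects genomic regions under recent positive selection from
SNP allele frequencies in a set of related populations (typically
livestock breeds genotyped on a dense array). This vignette explains the
statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the design decisions taken where more than one reasonable
construction exists.

## The drift model and the kinship matrix F

All scan statistics rest on a Gaussian approximation of genetic drift.
Each SNP segregates in an ancestral population at frequency $p_0$;
populations then drift independently along the branches of a rooted tree
whose branch lengths are measured in drift units (the Reynolds /
coancestry scale). To first order, the vector $p$ of present-day
population frequencies satisfies

$$ p \sim \mathcal{N}\!\left(p_0 \mathbf{1},\; p_0 (1 - p_0)\, F \right), $$

where $F_{ij}$ is the length of tree path shared by the root-to-$i$ and
root-to-$j$ branches. `kinship_from_tree()` computes $F$ as this
path-sum; a star tree yields a diagonal $F$, and
$F_{ii} + F_{jj} - 2F_{ij}$ always reproduces the tree distance between
leaves $i$ and $j$.

When $F$ must be estimated from data, `estimate_kinship()` chains
Reynolds distances, neighbour joining, outgroup rooting and pruning. Two
conventions matter:

* **Scale.** The pairwise Reynolds distance estimates the *average* of
  the two populations' drift from their common ancestor, i.e. *half* the
  additive tree distance. Distances are therefore doubled before tree
  fitting so that the resulting $F$ sits on the same scale as the drift
  covariance above. This is verified in the test suite both by branch
  length recovery against the generating tree and, more stringently, by
  the type-I error of the FLK scan run with the estimated $F$.
* **Rooting.** The tree is rooted at the midpoint of the outgroup's
  terminal branch, and the outgroup is pruned before $F$ is computed:
  drift shared by the whole ingroup above its most recent common
  ancestor is common to every population and carries no differentiation
  signal, so the ingroup MRCA is taken as the ancestral reference.
* **Negative NJ branches** are clamped to zero with the deficit shifted
  onto the sibling branch, the usual practical convention.

`fit_local_tree()` re-estimates all branch lengths of the fixed global
topology from distances computed in a single genomic region, by
non-negative least squares of leaf-to-leaf path lengths. With a binary
root only the sum of the two root-child branches is identified from
leaf-to-leaf distances; the fitted sum is split in the global tree's
proportions, which makes the refit exactly reproduce the global tree
when given its own distances. An elongated terminal branch in a local
tree is the classic signature of a population-specific sweep.

## Quality control and relatedness

The QC chain runs in a fixed order — sample missingness, monomorphic /
low-MAF SNPs, SNP missingness, then a per-population exact
Hardy–Weinberg screen at an FDR threshold — so that each removed item has
one well-defined reason and re-filtering a filtered table removes
nothing. Relatedness is handled per population on a VanRaden genomic
relationship matrix: the off-diagonal coefficients are modelled as a
normal mixture, and related pairs are declared only when (i) model
selection prefers two components over one (with a single bulk nothing is
flagged), (ii) the pair sits above the unrelated bulk by more than three
of its standard deviations, and (iii) the running local false-discovery
rate of the flagged set stays below the target FDR. One member of each
flagged pair is removed greedily (most-connected first, lexicographic
ties). Kinship coefficients are only comparable within a population —
across breeds they measure structure, not pedigree — hence the
per-population application.

## The FLK test

FLK scores each SNP by the Mahalanobis distance of the frequency vector
from its best (generalised least squares) neutral prediction:

$$ T_{FLK} = (p - \hat p_0 \mathbf{1})^\top
   \left[\hat p_0 (1 - \hat p_0)\, F^*\right]^{-1} (p - \hat p_0 \mathbf{1}),
   \qquad
   \hat p_0 = \frac{\mathbf{1}^\top (F^*)^{-1} p}{\mathbf{1}^\top (F^*)^{-1} \mathbf{1}}. $$

Under neutrality $T_{FLK}$ is approximately $\chi^2$ with $n-1$ degrees
of freedom for $n$ populations (one degree is spent estimating
$p_0$). Two practical points:

* **Sampling correction.** Allele frequencies are estimated from finite
  samples, and the binomial sampling variance is *not* drift; the
  covariance actually used is
  $F^*_{ii} = F_{ii} + (1 - F_{ii}) / (2 n_i)$ with $2 n_i$ the
  population's mean non-missing allele count. At 20 diploids per
  population this term is comparable to the drift variance itself, and
  omitting it more than doubles the mean statistic. The correction is a
  no-op when exact frequencies are supplied.
* **Residual approximation error.** Even with the true $F$, the statistic
  is $\chi^2_{n-1}$ only up to the noise of $\hat p_0$ entering the
  variance term: $T_{FLK} = \chi^2_{n-1} \times p_0(1-p_0) / \hat
  p_0(1-\hat p_0)$, with the second factor an independent, mean-one-ish
  multiplier. At 8 populations and realistic drift this keeps the mean
  statistic within about 2% of $n-1$ and the nominal 5% type-I error
  within [0.04, 0.06], but a Kolmogorov–Smirnov test on tens of
  thousands of SNPs can resolve the residual non-uniformity for some
  random trees. This is a property of the statistic itself, not of the
  implementation; no correction is applied because the first-order
  variance-bias correction overshoots in the presence of boundary
  truncation of frequencies.

SNPs with estimated ancestral minor allele frequency below 5% are
removed before testing (`maf_threshold`), matching the model's premise
that scanned SNPs were polymorphic in the ancestral population.
Significance is controlled by q-values: Storey's method with the cubic
smoothing-spline estimate of $\pi_0$ by default (the scan's standard),
Benjamini–Hochberg as the fallback; the scan default FDR is 1% for FLK
and 5% for hapFLK.

## The haplotype-cluster model and hapFLK

hapFLK extends FLK to haplotype information without requiring known
phase. Haplotypes are modelled as mosaics of $K$ latent clusters along
the chromosome: a hidden Markov chain stays in its current cluster with
probability $1-\rho_s$ between adjacent SNPs or jumps and re-draws the
cluster from local weights $\alpha_{\cdot s}$; cluster $k$ emits the B
allele at SNP $s$ with probability $\theta_{ks}$. Unphased genotypes use
the product chain over an ordered cluster pair. Parameters are fitted by
EM with exact forward–backward E-steps in both chains (the diploid
E-step is validated against a brute-force enumeration of the
$K^2$-state pair HMM in the test suite).

Numerical choices:

* $\theta$ is floored at $10^{-4}$ and the cluster weights at $10^{-6}$
  to prevent absorbing states. The weight M-step maximises the expected
  complete-data log-likelihood over the floored simplex exactly
  (water-filling); a plain floor-and-renormalise projection is not the
  constrained maximiser and can break the EM monotonicity guarantee,
  which the package asserts at every iteration.
* Initialisation seeds $\theta$ from a k-means clustering of the
  sequences. This keeps cluster labels globally coherent along the
  chromosome; with a random start, EM converges readily to solutions in
  which two clusters swap identities partway along the chromosome,
  which leaves the likelihood almost unchanged but ruins the
  interpretability of $\theta$ (and parameter-recovery error triples).
  A random start remains available (`init = "random"`).
* The per-interval jump probability is a free parameter per interval
  with no distance dependence, the simplest variant of the model; K is a
  configuration input (the reference analysis uses $K = 30$ for a dense
  array, chosen externally by cross-validation).

Cluster frequencies $q_{pk s}$ (mean posterior membership per
population) play the role that allele frequencies play in FLK. The
hapFLK statistic stacks the centred population-by-cluster matrix and
scores it against the Kronecker covariance
$F \otimes (\mathrm{diag}(q_0) - q_0 q_0^\top)$ using the Moore–Penrose
pseudoinverse on the cluster factor, whose simplex constraint makes it
singular. With $K = 2$ this reduces *exactly* to biallelic FLK on
cluster-1 frequencies, which the test suite asserts at $10^{-8}$; this
equivalence is the main guard on the quadratic-form construction. The
statistic is averaged over `n_em_runs` independent EM fits (default 5).

Because the cluster process is only an approximation of real haplotype
structure, hapFLK p-values are not taken from a parametric null. A
scaled $\chi^2$ ($c \cdot \chi^2_d$) is fitted to the genome-wide
empirical distribution and p-values are upper-tail probabilities of
$T/c$. The fit matches robust quantiles — $d$ from the quartile ratio
(scale-free), $c$ from the median — so that an upper tail of true
signals cannot perturb it; trimmed moment matching was rejected because
removing the top 1% of a $\chi^2$ sample biases its variance by about
−14% and the recovered degrees of freedom by about +12%, outside the
package's own 10% recovery requirement.

## Selection-signature regions and gene ranking

Significant SNPs at most 1 Mb apart on a chromosome are chained into one
selection signature; region boundaries are the span of member SNPs (not
extended by the gap). Regions are annotated with genes when they contain
at least `min_snps` significant SNPs (10 for the single-SNP scan, 5 for
the haplotype scan, reflecting the scans' different per-SNP power).
Genes overlapping the region span are ranked by the distance from the
gene midpoint to the best (smallest p-value) SNP; ties break to the
smaller position or gene id so that every output is deterministic.
`compare_region_sets()` classifies regions of two scans as shared or
private by any base-pair overlap and reports merged-span counts and mean
lengths.

## Quantifying allelic heterogeneity

For a detected signature, the package asks how many *independent*
selected variants the region contains. SNP selection follows fixed
rules: all SNPs with $p < 0.001$, at least the 10 and at most the 40
smallest p-values. The FLK signal of SNP $s$ is decomposed into loadings
on the orthogonal drift components,
$w_s = \Lambda^{-1/2} U^\top (p_s - \hat p_{0s}\mathbf 1) / \sqrt{\hat
p_{0s}(1-\hat p_{0s})}$ with $F = U \Lambda U^\top$, so that
$\lVert w_s \rVert^2$ equals the SNP's FLK statistic exactly (asserted
at $10^{-8}$ on every scan in the test suite). The cosine similarity of
loading rows is the between-test correlation matrix $R$: in a region it
captures correlation due both to linkage and to shared population
history.

A fine-mapping configuration model is then applied to signed scores $z$:
a causal configuration $c$ has likelihood
$\mathcal N(z; 0, R + \lambda^2 R D_c R)$ and prior
$\gamma^{|c|}(1-\gamma)^{m-|c|}$, truncated to at most `m_max` (default
10) variants. The posterior over $|c|$ is computed by exact enumeration
up to 5·10^4 configurations and otherwise by a seeded Metropolis sampler
(bit-flip and swap proposals, 10% burn-in, likelihoods cached per
configuration), which matches enumeration within 0.1 posterior-mean
units on all testable cases. The reported heterogeneity measure is the
posterior mean number of variants; a region is flagged heterogeneous
when that mean reaches 2 or at least two SNPs have marginal inclusion
probability above 0.5.

Three choices here were genuinely open and deserve comment:

* **Score construction.** FLK is unsigned and its square root has null
  mean square $n-1$, not 1. The default score is
  $z_s = \pm\sqrt{T_s/(n-1)}$: score *ratios* between SNPs then equal
  the loading-norm ratios, which is exactly the quantity the cosine
  matrix describes, and the null mean square is 1. The alternative
  p-value-to-normal transform (`score = "zscore"`) is better calibrated
  marginally but breaks that ratio consistency for strong signals, and
  in practice drives the configuration model to absorb the discrepancy
  by adding spurious variants.
* **Signs.** Scores are oriented by their projection on the first
  principal loading component and then relaxed to agree with $R$ within
  each correlated block. The first component orients only the dominant
  block; a second, orthogonal signal block would otherwise receive
  near-random signs, destroying precisely the coherence that makes a
  second variant detectable.
* **Prior scale.** $\gamma = 0.05$ and $\lambda = 2$ are the pipeline
  defaults on this score scale, favouring specificity: most detected
  signatures harbour a single swept haplotype, and a false
  heterogeneity call is the costlier error. `causal_posterior()` itself
  defaults to the conventional $\gamma = 0.01$, $\lambda = 5.2$
  appropriate for standard-normal scores.

At desk scale (8 populations, 20 diploids each) the evidence for a
*second* variant in an orthogonal population direction is typically only
2.5–3 standard deviations per region, so single-sweep regions are
classified reliably (posterior mean well below 1.5) while the
recognition rate of genuine two-variant regions is modest at these
defaults; raising $\gamma$ buys sensitivity at a direct cost in
single-sweep specificity. With many more populations and LD-level
information the discrimination sharpens, which is the regime the
original analysis operated in.

## The synthetic-data generator

`simulate_dataset()` and its components generate data with the exact
statistical structure the scans assume, plus controlled violations:

* **Neutral drift**: ancestral frequencies uniform on [0.1, 0.9] by
  default, emulating the intermediate-frequency ascertainment of SNP
  arrays; per-branch truncated-normal increments with variance
  $p_0(1-p_0)\,\ell$ (the drift model itself), or Wright–Fisher binomial
  resampling with `Ne` diploids per branch as a cross-check. The default
  study conditions are 8 populations, total tree length 0.2 drift units
  and 20 diploid samples per population, mirroring a livestock breed
  panel.
* **Sweeps** are instantaneous frequency displacements at chosen loci in
  chosen populations, optionally with a hitchhiking profile that moves
  flanking SNPs only part of the way to the target; the canonical hard
  sweep drives a previously uncommon allele (ancestral frequency below
  ~0.4) to fixation, and the power scenarios select such loci — a
  "sweep" of an allele already near fixation is invisible to any
  frequency-based method.
* **Mosaic haplotypes**: K founder haplotypes, founder weights drifting
  on the logit scale along the tree (which keeps the simplex valid
  without rejection sampling), mosaic switching at a per-interval rate
  and a small allele copy error. `fix_founder_window()` plants a
  haplotype-level sweep.
* **Related pairs**: duplicated genotypes (GRM coefficient near 1) and
  half-sib-like pairs gene-dropped from one shared parent (near 0.25).

What the generator does *not* emulate: background LD between neutral
SNPs (frequencies are independent given the tree), gene conversion and
mutation, ascertainment interacting with population structure, genuine
selective trajectories (a logistic trajectory would add a time
dimension without changing the final frequency pattern the scans see),
and admixture other than the explicit introgression event. Passing
tests therefore demonstrate correctness of the statistics under their
own model and robustness to sampling noise, not performance under every
complication of real data.

## Problem sizes and determinism

The test-suite simulations use 300–20,000 SNPs, 2–8 populations and
20–200 sequences per dataset; the full suite and the acceptance script
each run in a few minutes on one core. Every generator and every
stochastic algorithm takes an explicit seed, and fixed seeds make all
outputs bit-reproducible; tie-breaks throughout (best SNP, gene ranks,
greedy relatedness removal) are positional or lexicographic so that no
output depends on hash or sort instability.
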