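---
title: "Benchmarking local convolutional networks for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking local convolutional networks for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcgp)
```

## The problem

Genomic prediction estimates phenotypes or breeding values of
unphenotyped individuals from genome-wide SNP dosages, using a model
trained on a phenotyped reference set. The workhorse methods are linear:
GBLUP, which places a covariance proportional to a genomic relationship
matrix on the genetic values, and Bayesian whole-genome regressions such
as BayesA. Neural networks are an attractive alternative for very large
panels — computing time grows linearly in the number of individuals —
but the standard architectures sit at two unsatisfying extremes. A fully
connected first layer (MLP) links every SNP to every node and is
massively overparameterized for n << p data; a shared convolution (CNN)
is parameter-thrifty but assumes the same allele sequence has the same
effect wherever it occurs, which contradicts how array SNPs relate to
genes. The *local convolutional layer* (LCL) resolves this: the input is
cut into windows of `k` adjacent markers (stride `s`) and each window
gets its own affine filter,

$$h_w = \mathrm{ReLU}\Big(\sum_{i=1}^{k} W_{w,i}\, x_{(w-1)s+i} + b_w\Big),$$

so effects are region-specific while the parameter count stays near one
per SNP. `lcgp` implements the LCL and its surrounding benchmark — MLP
and CNN baselines, GBLUP/EGBLUP/BayesA, a genotype and trait simulator,
and a repeated cross-validation harness — so the comparison can be run
at desk scale with no external data.

## The genotype simulator

`simulate_genotype_panel()` emulates a dense breeding population in two
stages.

**Founder haplotypes.** Each marker receives a target allele frequency
drawn uniformly from `allele_freq_range` (default 0.1–0.9, mimicking an
LD-pruned array with intermediate frequencies). Along a chromosome,
haplotype alleles follow a first-order Markov chain: with probability
`ld_strength` (default 0.9) a haplotype copies its previous allele,
otherwise it draws Bernoulli(target frequency). This produces local LD
that decays geometrically with marker distance — the one feature of real
panels that matters for the locality argument of the LCL — while keeping
chromosomes independent. Because every marginal frequency is a convex
combination of targets, realized frequencies stay inside the requested
interval.

**Random mating.** The founder haplotypes (default 470, paired into 235
diploid founders; pairing order is seed-determined) are recombined into
offspring: each offspring draws two parents uniformly with replacement
and one gamete from each; gametes are crossover mosaics with a
Poisson(chromosome length in Morgans) crossover count and uniform
crossover positions. Allele frequencies are conserved in expectation and
the founder LD is inherited. The genetic map is equidistant with 1
Morgan per chromosome — a deliberate simplification; nothing downstream
depends on map irregularity.

What the simulator does *not* emulate: coalescent-exact LD, mutation,
selection, multi-generation pedigrees, population structure and fixed
effects. Tests that pass on these panels therefore speak to the methods'
behaviour under dense relatedness and local LD, not to any particular
real population. The default desk-scale configuration is 2,000
individuals × 3,000 markers on 10 chromosomes; the full-scale benchmark
configuration (10,000 × 34,595) is available but optional.

## Trait architectures

Six architectures span the benchmark: 10 or 1,000 additive QTLs, 10 or
1,000 non-linked epistatic QTL pairs, and 10 or 1,000 *linked* epistatic
pairs whose markers sit at most 5 marker indices apart.
"5 SNPs apart" is interpreted as index distance on the ordered map
within one chromosome, since arrays are ordered by position and the
constraint is stated in SNP counts. Epistatic pairs carry a full 3×3
effect table over the dosage combinations (0,0)…(2,2), used as-is with
no marginalization into additive components; pairs are sampled
disjointly so no marker enters two QTLs. Effects are all-equal,
standard gaussian, or gamma (shape 0.4, scale 1, random sign — the
gamma parameters are a package choice; the absolute effect scale is
irrelevant after heritability scaling). The reported benchmark
convention is equal effects for additive traits and gaussian effects for
epistatic ones, which is what `simulate_trait()` defaults to.

**Heritability.** `apply_heritability()` adds i.i.d. Normal(0, σ²ₑ)
residuals with σ²ₑ = Var(g)·(1−h²)/h², where Var is the realized
(population) variance of the simulated genetic values — not a
theoretical expectation — so the realized h² concentrates tightly on the
target at any n (±0.02 at n = 10,000 in the test suite). h² = 1 yields
exactly zero residuals. A direct consequence used throughout: the
correlation between any predictor and the phenotype is bounded by
√h² (`pa_ceiling()`), e.g. 0.707 at h² = 0.5.

**Correlated traits.** `correlated_traits()` gives all traits one shared
set of additive QTL positions and builds per-trait effect vectors as
linear mixtures of i.i.d. gaussian vectors. A plain Cholesky mixture of
the *effect vectors* attains the target correlation only in expectation;
in a highly related panel the dosage covariance has low effective rank,
and we observed spurious realized genetic correlations up to ±0.24
between nominally independent traits. The mixture therefore first
whitens the realized covariance of the raw genetic values and then
applies the Cholesky factor of the equicorrelation target, so realized
pairwise genetic correlations equal `rho` exactly in-sample. Residuals
stay independent across traits, diluting the phenotypic correlation
below the genetic one, as in real data.

## Linear baselines

**GBLUP.** The VanRaden relationship matrix is
G = ZZᵀ / (2Σpⱼ(1−pⱼ)) with Z the dosage matrix centered by twice the
allele frequency. Frequencies are computed on the full panel (training
and prediction individuals together), the common single-G practice;
this is stated explicitly because it affects predictions. Monomorphic
markers drop out of numerator and denominator. REML uses the spectral
shortcut: the training block of G is rotated into the eigenbasis of the
intercept-orthogonal space, reducing the restricted likelihood to a 1-D
function of λ = σ²ₑ/σ²g, maximized by `optimize()`
(golden-section/parabolic) on log λ ∈ (−10, 10) — bounds that cover
heritabilities from ~5·10⁻⁵ to ~0.99995. Predictions for all
individuals use the cross block: ĝ = G[·, train](G_train + λI)⁻¹(y−μ̂).
A fixed-λ override supports fitting at a known heritability and makes
the full-shrinkage limit (λ → ∞ ⇒ ĝ ≡ 0) directly testable. The test
suite verifies the exact equivalence with marker-based ridge regression
(RR-BLUP) to 1e−6 on random instances.

**EGBLUP.** Adds a second genetic component with covariance H = G∘G,
the Hadamard square, the standard kernel for pairwise marker-by-marker
interactions. The restricted likelihood is profiled over σ²ₑ and the
intercept and maximized over the two variance ratios on a 5×5 log-scale
grid refined by Nelder-Mead. With the epistatic component switched off
the fit delegates to the single-kernel spectral solver, so the nesting
is exact rather than approximate.

**BayesA.** Each marker effect has its own variance with a
scaled-inverse-χ²(ν, S) prior (scaled-t marginal). The single-site Gibbs
sampler is written in C++ with residual updating and uses R's RNG, so
chains are bit-reproducible under a seed. Hyperparameters follow the
standard rule: ν = 4 and S chosen so the prior expected marker variance
explains half the phenotypic variance,
S = 0.5·Var(y)·(ν−2)/(ν·2Σpq); the residual prior is
scaled-inverse-χ²(4) with prior mean 0.5·Var(y). Defaults are 5,000
iterations with 1,000 burn-in; the trend checks in the test suite use
shorter, empirically stable chains (1,200/240).

## Network design and training

`network_spec()` declares one of three classes: MLP (FCLs only), CNN
(one shared-filter convolution in front of the FCLs, no pooling) or
LCNN (one LCL). Baselines use kernel = stride = 10, one CNN filter, two
64-node hidden layers, one linear output. Parameter accounting is exact:
a shared k = 10 filter costs 11 parameters; an LCL costs
n_windows·(k+1) with n_windows = ⌊(p−k)/s⌋+1; an FCL from a to b nodes
costs ab + b. Windows follow the "valid" rule — markers beyond the last
full window are dropped — matching the window arithmetic and avoiding
padding artifacts at chromosome ends. One CNN filter is the default
because it is the only count consistent with the 11-parameter filter
arithmetic; it is configurable.

Training choices, all package defaults where the protocol is silent:
raw 0/1/2 dosages in, per-trait training-mean-centered phenotypes out;
MSE loss (unweighted sum over traits for multi-trait heads); Adam with
learning rate 1e−3 and batch size 64; dropout 0.3 after each *hidden*
layer (not the input — dropping raw SNPs would destroy the locality the
LCL exploits); seeded Glorot-uniform initialization. Two training
protocols: `early_stop_validation` trains up to 50 epochs, evaluates
the validation predictive ability after each epoch and restores the
weights of the best epoch (earliest on ties — epoch selection is by
validation *predictive ability*, not validation loss); `fixed_epochs`
runs exactly 25 epochs and ignores validation data entirely, the
protocol of choice when panels are too small to spare a validation set.
An epoch whose validation predictions are constant has undefined
correlation and is never selected. A non-finite loss aborts with the
epoch index. The LCL forward/backward pass is evaluated by a
gather-and-group-sum scheme (a fixed sparse window-sum operator), which
keeps training in BLAS/sparse products with no per-window loops; it is
verified against a triple-loop reference to 1e−10.

## Evaluation protocol

`make_split()` draws the fitting set (default 80%) and carves out the
validation set; with n = 10,000 and validation 1,000 this yields the
7,000/1,000/2,000 protocol. `training_size_grid()` pairs fitting sizes
(100…8,000) with validation sizes (20…1,000) exactly, the validation
share being deliberately larger for small panels; remaining individuals
all go to the test set. `run_benchmark()` draws a fresh split per
repeat, fits every model on the identical split, and scores on the
identical test set. No fitting or epoch-selection code path ever
receives test phenotypes — the interface only passes train/validation
data — and a corruption test asserts this. Cells report the mean
predictive ability with a normal-theory 95% CI (mean ± 1.96·SE across
repeats); across-repeat SE was chosen over bootstrap for its
transparency at 10–25 repeats. Seeds: repeat r uses master + r for the
split and master + 10,000·m + r for model m, so models are comparable
within repeat and deterministic models are bit-reproducible. A failing
model is recorded per cell without aborting the sweep.

The trend checks in `tests/testthat/test-acceptance.R` run at sizes
chosen as a deliberate compromise between statistical resolution and
desk-scale runtime: a 2,600 × 3,000 panel; orderings at fitting sizes
100 (20 validation) and 2,000 (300 validation) with 10 repeats and the
early-stopping protocol; and a heritability sweep (h² ∈ {0.1, 0.5,
0.8}) at fitting size 500 with the fixed-25-epoch protocol across all
six model classes. Absolute predictive abilities at these sizes are
lower than at the full 10,000 × 34,595 scale; the assertions are
therefore on orderings and monotonic trends, which were stable across
the seeds we examined, not on absolute values, which depend on the
founder LD of the panel being emulated.

## Conventions and degenerate inputs

Marker indices are 1-based everywhere inside the package (R's native
convention); positions are 1-based at the VCF boundary as the format
requires. Dosage matrices must be complete with entries in {0, 1, 2};
the readers impute missing calls to the marker's rounded mean dosage
and report the count, and reject markers missing in every sample. A
GRM over all-monomorphic markers, a constant genetic-value vector, a
zero-variance prediction vector and an early-stopping call without a
validation set are all rejected or reported as missing rather than
silently coerced.

## Known limitations

* The simulator's LD is qualitative: real array panels are LD-pruned
  with unknown thresholds, so only orderings and trends — not absolute
  predictive abilities — transfer.
* EGBLUP's two-ratio REML surface is optimized by grid + Nelder-Mead;
  for near-degenerate components the two variance ratios are weakly
  identified (predictions are stable, the split between σ₁² and σ₂² less
  so).
* Multi-trait linear mixed models, dominance, G×E, fixed effects and
  pedigree-based single-step extensions are out of scope.
* The networks are CPU-only by design; at desk scale this is not a
  constraint, and the parameter accounting is hardware-independent.
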