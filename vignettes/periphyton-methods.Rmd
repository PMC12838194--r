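---
title: "Models and methods behind the periphyton package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the periphyton package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periphyton)
```

This vignette explains the statistical machinery in the package: what each
model assumes, which knobs matter, how the synthetic-data generators relate
to real amplicon and qPCR data, and where the genuinely open design choices
were and how we resolved them. It states no empirical result beyond what the
test suite and the bundled example code compute.

## The scientific setting

Periphyton — the surface-attached microbial mat of paddy soils — mixes a
small set of abundant taxa (relative abundance above 1%) with a long tail of
rare ones (below 0.01% in every sample). A culture-based "filtration" system
regrows periphyton under optimized medium and temperature so that abundant
taxa persist while rare taxa decline; comparing the cultivated community
with the naturally collected one then separates what abundant taxa do for
diversity, assembly and nutrient cycling from what the rare tail does. The
package implements every quantitative stage of that comparison plus
generators that make the whole chain testable without sequencing data.

## Response-surface optimization of the cultivation system

The cultivation experiment is a three-level, three-factor Box–Behnken design:
soil extract (0/10/20 % v/v), mineral solution (0.5/1.0/1.5 %), and culture
temperature (26/30.5/35 °C), coded to ±1. With five replicated centre runs
the design has 17 runs; each coded column satisfies $\sum x_i = 0$ and
$\sum x_i^2 = 8$, and each pairwise product column $\sum (x_i x_j)^2 = 4$.
The response (abundant-species richness) is modelled by the full quadratic

$$Y = \beta_0 + \sum_i \beta_i X_i + \sum_i \beta_{ii} X_i^2 +
      \sum_{i<j} \beta_{ij} X_i X_j ,$$

fitted by ordinary least squares **on the coded scale only** — the coded
information matrix is well conditioned and its structure is what makes the
ANOVA reproducible; natural-unit answers come from decoding points, never
from refitting.

**Type III sums of squares.** Each term's partial SS is
$\beta_j^2 / c_{jj}$, with $c_{jj}$ the corresponding diagonal of
$(X'X)^{-1}$. On this design that reduces to $8\beta^2$ for linear terms,
$4\beta^2$ for interactions and $(80/19)\beta^2$ for quadratics (the
quadratic block of $X'X$ is not diagonal, which is also why the nine partial
SS need not add up to the model SS). Pure error comes from the centre
replicates; lack of fit is the residual remainder, tested against pure error.
This is the decomposition standard response-surface software prints, so a
published coefficient vector plus the design suffices to re-derive a
published ANOVA table — `anova_from_coefficients()` does exactly that, and
`eq2_coefficients()` ships the cultivation study's published polynomial as a
convenience input.

**Constrained optimization.** The optimum over the coded cube $[-1,1]^3$ is
found by exhaustive face decomposition: all $3^3$ assignments of each
coordinate to $\{-1, +1, \text{free}\}$ are solved in closed form (stationary
point of the restricted quadratic), feasible candidates are compared, and a
dense grid pass confirms the winner. No iterative optimizer, hence no
convergence knobs and no tolerance interactions with the flat directions a
near-singular Hessian can produce. For the published polynomial the
maximizer puts the mineral solution and temperature at their low bounds
(0.5 %, 26 °C) and the soil extract at an interior coded +0.467 (≈14.7 %).
The study that motivated this package states 10 % soil extract alongside the
same mineral and temperature optima; the model itself does not reproduce
that coordinate (its face-stationary point is ≈14.7 %), so
`optimize_response()` reports the model optimum and flags which coordinates
sit on the boundary — both numbers are worth reporting, and the discrepancy
is plausibly a practical rounding to the centre level rather than a model
output.

## Abundance classes and diversity

Rare OTUs are those below 0.01 % relative abundance **in every sample**.
"Abundant" is stated in the literature only as "above 1 %", which is
ambiguous between any-sample, all-sample and mean-abundance readings; we
default to **mean relative abundance > 1 %** — the dominant convention in
the abundant/rare partitioning literature — and expose the any-sample rule
via `rule = "any"`. Both cuts are arguments.

Alpha diversity implements the classic closed forms: Shannon entropy on
natural logs; Chao1 as $S_{obs} + F_1^2/(2F_2)$ with the bias-corrected
$F_1(F_1-1)/2$ fallback when no doubletons exist; ACE with the standard
rare/abundant split at $k = 10$ (our ACE agrees with vegan's to numerical
precision, which the tests use as a cross-check; our Chao1 is deliberately
the classic form rather than vegan's bias-corrected variant, so its oracle
values are hand-computed). Rarefaction is a single subsample without
replacement at a fixed seed, defaulting to the minimum sample total.
Contribution ratios are ratios of group means (cultivated over control,
×100); the alternative mean-of-pairwise-ratios reading is not implemented
because pairing of cultivated and control samples is not defined in this
design. Group comparisons of phylum proportions use Welch's t-test with the
Welch–Satterthwaite CI and no multiplicity correction by default (raw p
values are the convention in the STAMP-style figures this mirrors);
Benjamini–Hochberg is one flag away.

## The Sloan neutral community model

Under neutral assembly with migration, a taxon whose source-pool relative
abundance is $p$ has a locally beta-distributed relative abundance
$x \sim \mathrm{Beta}(Nm\,p,\ Nm(1-p))$, so its detection probability above
a limit $d$ is $1 - I_d(Nm\,p, Nm(1-p))$. `fit_ncm()` estimates the single
parameter $Nm$ by least squares of observed occupancy on that prediction
across OTUs (log-spaced bracket scan over $Nm \in [1, 10^7]$ plus
golden-section refinement), reports $R^2$ about the mean occupancy, and
bootstraps OTUs (the regression's unit of observation) for a percentile CI.

**Detection limit.** The common convention sets $d = 1/N$ (one read at the
mean depth $N$). Occupancy, however, is observed through binomial read
sampling: the probability of at least one read among $N$ is
$1-(1-x)^N$, a smooth ramp whose median sits at $x = 1 - 2^{-1/N} \approx
\ln 2 / N$, not at $1/N$. A hard threshold at $1/N$ therefore
under-predicts detection and the fit compensates by inflating $Nm$ — on
data whose occupancy genuinely arises from read sampling we measured a
systematic +20–30 % bias in $\hat m$, versus within ±7 % at the
sampling-consistent threshold. The package defaults to
$d = 1 - 2^{-1/N}$ and leaves `d` configurable for the $1/N$ convention.

**Prediction bands and partitioning.** The 95 % band around the predicted
frequency is a Wilson binomial interval computed from the rounded integer
detection count $\mathrm{round}(\hat q\, n)$ of $n$ samples. Rounding
matters at the extremes: occupancy lives on the $1/n$ grid, and a Wilson
interval evaluated at a continuous $\hat q \to 1$ has an upper limit just
below 1 that excludes the only achievable value, misclassifying every
near-ubiquitous OTU. With the count-rounded form the bands have ~94 % exact
binomial coverage at the simulation conditions used in the tests, and
`partition_otus()` labels OTUs above/within/below. The "share of explained
variance attributable to abundant OTUs" has no canonical formula in the
literature that motivated it; we define it as the abundant OTUs' share of
the regression sum of squares, $100\sum_{ab}(\hat q_i - \bar q)^2 /
\sum_{all}(\hat q_i - \bar q)^2$ — one defensible reading, flagged as such.

## βMNTD and βNTI

For samples $k, l$ with within-sample relative abundances $f$,

$$\beta\mathrm{MNTD}(k,l) = \tfrac12\Big[\sum_{i\in k} f_{ik}
  \min_{j\in l} d_{ij} + \sum_{j\in l} f_{jl} \min_{i\in k} d_{ij}\Big],$$

with $d$ the patristic distance. Abundance weighting is the default (the
convention of the null-model framework this follows); presence-only weights
are a flag. The null model shuffles taxon labels across **all** tree tips,
leaving abundances with their samples, and all sample pairs share one
shuffle sequence per run so a seed fully reproduces the output. βNTI is the
per-pair standardized effect; $|\beta\mathrm{NTI}| > 2$ is read as
deterministic (selection-driven) assembly. 999 shuffles is the default (the
motivating study does not state its count; 999 is the field's default).
Pairs whose null never moves — e.g. two samples with identical taxon sets,
where every nearest-taxon distance is zero under any relabelling — are
flagged undefined by a range test on the null draws (a variance test is
numerically unreliable at this scale) and excluded from summaries. The
kernel is compiled (Rcpp); a pure-R double loop is kept in the test suite as
the independent oracle, and group summaries use a two-sided Welch t-test
between the two groups' βNTI values, matching the study's global choice of
t-tests.

## Gene-chip quantification

Ct values above 31 cycles are treated as non-detections, and a gene is kept
within a group only when detected in at least two-thirds of that group's
replicates — reconstructions of common SmartChip practice (the motivating
study defers its QC details to prior work), both exposed as arguments.
Relative copies follow the perfect-efficiency convention of 10/3 cycles per
decade, anchored so Ct = 31 maps to 1; absolute copies rescale by each
sample's independently quantified 16S copy number. The functional
proportion of a gene is 100 × (mean cultivated absolute abundance) / (mean
control absolute abundance) — ratio of means, not mean of ratios, for
stability at small replicate counts — with a delta-method standard
deviation. Proportions are deliberately **not** capped at 100 %: whether
the exactly-100 % entries in published figures of this kind reflect capping
is unknowable from the outside, and capping would destroy the invariance of
the ratio to the Ct threshold. The threshold cancels whenever both groups
pass QC, which the tests assert.

## What the generators emulate — and what they do not

All generators are pure functions of (parameters, seed); one master seed
derives fixed per-stage substreams.

* `simulate_source_community()`: lognormal (default sd 1.5, a typical soil
  rank-abundance spread) or log-series source pools.
* `simulate_neutral_metacommunity()`: per sample, composition
  $\sim \mathrm{Dirichlet}(Nm\,p)$ and counts
  $\sim \mathrm{Multinomial}(N, \cdot)$. The Dirichlet-multinomial has
  exactly the beta marginals the Sloan model fits, so it tests the
  estimator without simulating birth–death–immigration dynamics.
* `simulate_selected_metacommunity()`: one Brownian trait on a Yule tree
  (depth scaled to 1), Gaussian niche weights
  $w_i \propto p_i e^{-(t_i - e)^2 / 2\sigma^2}$; small $\sigma$ is strong
  phylogenetically conserved selection, $\sigma \to \infty$ recovers
  neutral multinomial sampling.
* `simulate_genechip()`: cultivated Ct = control Ct − (10/3)·log₁₀(fold) +
  Gaussian noise (default 0.3 cycles, a standard qPCR error scale), with a
  16S row and constant absolute 16S copies; 15 replicates per group by
  default, mirroring a 3-technical × 5-subsample chip layout.

What they do **not** emulate: sequencing error and chimeras, compositional
biases of PCR, spatial or temporal autocorrelation between samples,
multiple source pools, and phylogenetic signal in *abundance* (the tree and
the source abundances are independent unless selection couples them). A
green test suite on these generators therefore says the estimators are
correct and calibrated under their own assumptions — not that real
periphyton is neutral or that real chips are noise-free.

## Numerical choices and problem sizes

Tolerances: design/ANOVA identities at 1e-6 to 1e-9 (exact linear algebra);
the Nm bracket is $[10^0, 10^7]$ with a 60-point log scan before
refinement, and an estimate pinned at a bracket end is an error, not an
answer. Degenerate inputs error early with the offending record named:
duplicate ids, samples without metadata, zero-total samples, missing branch
lengths, occupancy with zero variance, a missing or duplicated 16S row.

The test suite runs its calibrations at deliberately desk-sized conditions:
neutral recovery at 300 OTUs × 50 samples × depth 10⁴ over 20 seeds; βNTI
null calibration at 80 taxa × 21 samples (210 pairs) × 999 shuffles;
occupancy-curve checks at 200 samples. These sizes were chosen as the
smallest at which the sampling error of the checked quantity is comfortably
below the asserted tolerance.

## Known limitations

* The NCM fit is the occupancy-regression formulation, not an exact
  likelihood; $R^2$ can be negative under strong selection and is reported
  as such.
* The βNTI null shares one shuffle sequence across pairs, so pairs are not
  independent draws from the null — fine for per-pair inference and for
  fractions, but not for treating all pairs as an i.i.d. sample.
* Phylum extraction expects `p__`-prefixed or second-field lineages;
  exotic taxonomy strings fall back to the second rank.
* The pipeline is single-process by design; its stage "caching" is simply
  deterministic regeneration from the seed plus a hash manifest.
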