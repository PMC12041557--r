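---
title: "Scanning gene family sizes for life-history associations on a phylogeny"
author: "phyloFamScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning gene family sizes for life-history associations on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloFamScan)
```

## The question and the model

Across mammals, maximum lifespan potential (MLSP — the longest recorded
lifespan of any individual of a species) varies by two orders of magnitude and
co-varies with body mass, relative brain size, gestation time and age at
sexual maturity. One genomic correlate of interest is gene family size: the
number of member genes a homologous family has in each species' genome, which
grows and shrinks by duplication and loss. A genome-wide association scan asks,
for every family, whether its size tracks a trait across species.

Species are not independent samples: close relatives resemble each other
because of shared ancestry. The package therefore fits each family with
phylogenetic generalized least squares (PGLS) under a Brownian-motion model of
trait evolution,

$$ y = X\beta + \varepsilon, \qquad \varepsilon \sim
   \mathcal{N}(0,\ \sigma^2 V), $$

where $y$ is the family's gene-count vector across species, $X$ is an
intercept plus one or two trait columns, and $V_{ij}$ is the shared branch
length from the root to the most recent common ancestor of species $i$ and $j$
on an ultrametric species tree. The estimator is the closed form
$\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$, computed through a Cholesky
whitening of $V$ shared across all families, which makes a 4,000-family scan a
single set of matrix operations.

Reporting conventions are a deliberate hybrid that matches `nlme::gls` with
`method = "ML"`: the residual rate $\sigma^2$ and the log-likelihood are
reported at the maximum-likelihood scale $e^\top V^{-1}e/n$, while standard
errors use the unbiased scale $e^\top V^{-1}e/(n-k)$, so that with $V = I$
(a star phylogeny) the coefficients, standard errors, $t$ and $p$ values
reproduce textbook OLS exactly. No additional covariance parameters (Pagel's
$\lambda$, Ornstein–Uhlenbeck) are estimated: the covariance is pure Brownian.

Per coefficient, the effect size is the $t$-to-partial-correlation conversion

$$ r = \frac{t}{\sqrt{t^2 + \mathrm{df}}}, $$

which is sign-preserving, bounded in $(-1, 1)$, and the standard
correlation-scale effect size for a single GLS coefficient. Families are
called *expanding* when $r > 0$ and the Benjamini–Hochberg adjusted $q$ falls
below $\alpha$ (default 0.05), *contracting* when $r < 0$ and $q < \alpha$,
and *none* otherwise; BH is applied within each predictor across all scanned
families. Both raw $p$ and $q$ are always reported, so either reading of a
"$p < 0.05$" threshold is available downstream.

## Preprocessing and its thresholds

* **Genome completeness.** Species are kept when their BUSCO-style
  completeness fraction is *strictly greater* than the threshold (default
  0.80) — "higher than 80%" is an exclusive bound.
* **Family filter cascade** (applied to the retained species): a family is
  kept when (i) its counts vary across species, (ii) it has at least
  `minMaxCount` (default 3) genes in some species, and (iii) it is present
  (count ≥ 1) in at least `ceiling(presenceFraction × n)` species (default
  0.80), which excludes lineage-specific families. The ceiling means the
  presence rule is never satisfied vacuously; the three predicates commute and
  the cascade is idempotent.
* **Traits.** Raw trait values (MLSP in years, masses in grams, times in
  days) are log10-transformed before use as predictors. *Relative brain size*
  is the residual of an ordinary (non-phylogenetic) least-squares regression
  of log10 brain mass on log10 body mass — the standard allometric residual;
  the choice of OLS rather than PGLS for this step follows established
  practice for defining encephalization residuals. The residual is used as a
  predictor as-is, since it already lives on the log scale.
* Species present in only some inputs are dropped to the common set with a
  warning, so each analysis runs on its own species intersection.

## Trait–trait correlations

Correlations among traits are assessed with Felsenstein's phylogenetically
independent contrasts, computed by the pruning recursion (contrast
$(x_L - x_R)/\sqrt{v_L + v_R}$ at each internal node, variance-weighted
ancestral values, branch-length extension $v_Lv_R/(v_L+v_R)$). Contrast signs
are arbitrary, so the correlation is computed through the origin, and the test
uses $t = r\sqrt{\mathrm{df}/(1-r^2)}$ with df = (number of contrasts) − 1;
the through-origin slope costs the one degree of freedom. Polytomies are
combined pairwise in deterministic lexicographic order of each child clade's
smallest tip label — equivalent to resolving them with zero-length internal
edges — so any rooted tree with $n$ tips yields exactly $n-1$ contrasts. A
trait with zero contrast variance produces a flagged `degenerate` result, not
a silent zero.

## Enrichment machinery

GO terms are treated as opaque labels (no ontology-graph propagation). A
family inherits the union of its member genes' terms; lifting happens
*before* term-frequency filtering, because the filter thresholds are defined
at the tested level: terms on fewer than 50 families (family-level analyses)
or fewer than 200 genes (gene-level analyses) are excluded.

Enrichment of a focal set is measured against a resampling null: the observed
proportion of focal elements carrying a term is compared with its mean and
standard deviation over 1,000 equally sized uniform samples drawn from the
background *without replacement* (a random sample of the background is a
subset; with-replacement sampling is available behind a flag). The statistic
is $z = (\mathrm{obs} - \mu_{\mathrm{null}})/\mathrm{sd}_{\mathrm{null}}$ with
a two-sided standard-normal $p$ and BH correction across terms; direction
(over/under) is reported separately, and an empirical rank $p$ is included as
a diagnostic column. Terms whose null standard deviation is zero are flagged
degenerate: $p = 1$ if the observation equals the null mean, else floored at
$1/\mathrm{n_{samples}}$. Results are bit-reproducible given the seed.

Overlap with curated gene lists uses Pearson's chi-square without continuity
correction on the 2×2 table of (in list) × (in focal set) over a harmonized
background — the study background intersected with the list's own background
when one is provided. The reported fold is log2(observed/expected) of the
in-list, in-focal cell; any expected cell below 1 flags the result unreliable
while still reporting it.

## Leave-one-out sensitivity analysis

To quantify each species' influence, the two-predictor scan is refit $n$
times, each time with one species removed (tree pruned, covariance rebuilt on
the pruned tree). The family universe is frozen at the full-data filter stage
— re-filtering per iteration would change the universe and make effect sizes
incomparable across drops. For the families significant in the full-data scan,
the refit effect sizes $r$ are compared with the full-data $r$ over the same
families by Cohen's $d$ (pooled-SD standardized mean difference) and a
Wilcoxon rank-sum test; Wilcoxon $p$-values are BH-adjusted across the $n$
species before flagging. A species is flagged influential when $|d|$ exceeds
0.2 (a small effect) or its adjusted Wilcoxon $q$ falls below $\alpha$.

The comparison pairs the LOO $r$ vector against the full-data $r$ vector over
the reference-significant families. Other pairings are conceivable (e.g.
refit-significant families only); this one yields one $d$ and one Wilcoxon
$p$ per species, keeps the two samples on a common family set, and makes $d$
values comparable across species. Families that become degenerate after a
removal (zero count variance) are excluded pairwise.

The Wilcoxon implementation enumerates the exact two-sided $p$ when the
combined sample size is at most 12 and there are no ties, and otherwise uses
the normal approximation with midranks, tie correction and continuity
correction.

## The synthetic-data generator

Every stage is validated against data with known ground truth, generated at
the conditions the analysis targets:

* **Tree**: a pure-birth (Yule) tree rescaled to unit root-to-tip height —
  ultrametric by construction, with the imbalanced shapes and short internal
  edges typical of dated mammal phylogenies. Default 46 retained species plus
  6 low-quality decoys (completeness below 0.80) so the completeness filter
  has work to do.
* **Traits**: multivariate Brownian motion with a single-factor cross-trait
  correlation structure — each trait's correlation with MLSP is its factor
  loading (body mass 0.6, relative brain size 0.7, gestation time 0.7, age at
  sexual maturity 0.8), so the implied correlation matrix is positive
  semi-definite by construction and matches the observed trait–MLSP
  correlation structure. Latent values map monotonically to positive raw
  units (MLSP roughly 1–200 years, masses in grams, times in days) purely for
  I/O realism.
* **Family counts**: each family's latent size is
  $\mathrm{baseline} + b\,x + u$ with $u$ Brownian on the tree, rounded and
  clipped at zero. For a planted fraction (default 5% of 4,000 families) the
  slope $b$ is calibrated so the noncentrality of the slope $t$-test matches
  a target effect size (default $r = 0.6$):
  $\delta = r\sqrt{\mathrm{df}/(1-r^2)}$ and
  $b = \delta\,\sigma\sqrt{[(X^\top V^{-1}X)^{-1}]_{22}}$. When downstream
  analysis will drop species, the calibration is computed on the retained
  subset — Brownian marginals make the noise model consistent under
  subsetting. Rounded clipped Gaussians (rather than Poisson draws) keep the
  Gaussian PGLS model correctly specified, so parameter-recovery checks are
  sharp; the baseline (10) and Brownian residual SD (3 per unit height) are
  chosen so that rounding noise (variance 1/12) is about 1% of the residual
  variance and clipping at zero is negligible. This makes the synthetic
  family sizes larger than typical Ensembl families — a deliberate trade of
  literal realism for a correctly specified recovery benchmark; a Poisson
  mode exists as a misspecification stress test.
* **Annotations, gene lists, expression**: terms are assigned at family level
  with a base probability (planted terms at odds multiplied by a configurable
  factor, default 8, in associated families) and genes inherit their family's
  terms, so the gene→family lift round-trips. Gene lists include focal genes
  at elevated odds; expression tables are log-normal with 1 + Poisson
  transcript counts, and focal genes receive a multiplicative (1 + shift)
  factor.
* **Outlier species** (for sensitivity-analysis testing) have their counts
  shifted upward in associated families. The shifted species should carry a
  long terminal branch: an outlier on a very short branch is so heavily
  weighted by $V^{-1}$ that it inflates every family's residual variance and
  extinguishes the scan itself — which is phylogenetically sensible but not
  the influence scenario being tested.

All generators are pure functions of their arguments and a seed, and restore
the caller's RNG state.

What the generator does **not** emulate: birth–death gene gain/loss dynamics
(family sizes evolve as a continuous latent, not by discrete duplication and
loss events), lineage-specific families, overdispersed or zero-inflated
counts, dependence between families, GO-graph structure among terms, or
cross-species expression data. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under its own model; they do
not certify behaviour under the model violations real Ensembl/AnAge data may
carry.

## Numerical choices

* $V$ is factored by Cholesky; if the factorization fails (e.g. duplicated
  zero-length tips) a 1e-10 diagonal jitter is added with a warning.
* Numerically perfect fits (relative residual sum of squares below 1e-24) are
  resolved by convention: a coefficient indistinguishable from zero gets
  $t = 0,\ p = 1$; any other coefficient carries infinite evidence
  ($|t| = \infty$, $p = 0$, $r = \pm 1$).
* Ultrametricity is checked with relative tolerance 1e-6 on root-to-tip
  depths and violations warn rather than error — GLS is defined for any
  positive semi-definite covariance.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; trees are
  parsed and written with `ape` (15 significant digits on output, so a
  write/read round trip preserves pairwise distances to numerical precision);
  rank tests delegate to `stats::wilcox.test` under the exact/approximate
  switching rule above.
* Newick input validation rejects missing branch lengths, duplicate or empty
  tip labels, and malformed strings, naming the offending token.

## Validation scale

The test suite validates the stack at desk scale, chosen to keep the full run
in minutes on one CPU: GLS–OLS equivalence on 100 random star-phylogeny
designs; exact agreement with the closed-form estimator on a 3-taxon tree and
with `nlme::gls` under a Brownian correlation; type-I calibration on 2,000
null families and 2,000 null contrast correlations on 46-tip trees (nominal
5% within ±1.5%); recovery of planted $r = 0.6$ effects (median within
±0.05, power ≥ 80% and empirical FDR ≤ 7% at BH $q < 0.05$ on a 5%-associated
mixture of 4,000 families); planted GO terms ranked first with $q < 0.05$ at
odds 8 and uniform $p$ at odds 1 (KS at 1% over 200 repetitions);
leave-one-out stability on homogeneous data (max $|d| < 0.2$, all Wilcoxon
$q > 0.05$) and detection of a planted outlier as the largest $|d|$; and
exact checks of the BH step-up, chi-square, filter-cascade and Wilcoxon
enumeration examples worked by hand.

One behaviour of the synthetic study is worth flagging: because every planted
family receives a positive slope against the same trait, the per-species
*total* gene count is strongly trait-associated in synthetic bundles, unlike
the no-association scenario the total-count control is designed to detect.
The control regression is therefore validated separately on null simulations
(its $p$ is uniform), and its value on a planted bundle simply reflects the
aggregated planted signal.

## Limitations

Only the Brownian covariance is supported — no $\lambda$, OU, or measurement
error; raw integer counts are modelled as Gaussian, which is an approximation
(adequate for the moderately large families the filters retain, questionable
for families of size 0–2); the two-sided Z-score convention and the
degenerate-sd rule in the resampling enrichment are package conventions where
several defensible choices exist; and the leave-one-out pairing of refit
versus full-data effect sizes is one documented interpretation of an
ambiguous procedure. The expression comparison is a two-group rank test on
one species' data and carries no cross-species normalization.
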