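---
title: "Methods: the coefficient of intrinsic dependence for gene set association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coefficient of intrinsic dependence for gene set association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidgsaa)
```

## The measure

Let `X` be an `N x p` predictor gene-set block and `Y` an `N x q`
target block over the same `N` samples.  The coefficient of intrinsic
dependence (CID) asks: *does the distribution of the target block
change across sample subgroups defined by the predictor block?*

1. **Subgrouping.** The samples are partitioned into `K` subgroups by
   agglomerative complete-linkage clustering of the rows of `X` under
   Euclidean distance (`subgroup_by_clustering()`; seeded k-means and
   self-organizing-map backends are provided as alternatives).
2. **Empirical cdfs.** For a point `y` in target space, the marginal
   empirical cdf is `G(y) = (1/N) * #{j : Y[j, ] <= y componentwise}`,
   and the conditional cdf of subgroup `s` with members `M_s` is
   `G_s(y) = (1/n_s) * #{j in M_s : Y[j, ] <= y}`.  The comparison is
   non-strict in every coordinate.
3. **Aggregation.** Evaluating at the observed samples,

   ```
   CID = (1 / C(N)) * (1/N) * sum_i  sum_s (n_s / N) * (G_s(Y[i, ]) - G(Y[i, ]))^2
   ```

   with `C(N) = (N^2 - 1) / (6 N^2)`.

Because the weighted average of the conditional cdfs is the marginal
cdf, the inner sum is a *variance* of the conditional cdf values
around their mean — zero exactly when all subgroups share one target
distribution (empirically), and growing as the conditional
distributions separate.  Only ranks enter the computation, so the CID
is invariant under strictly increasing per-gene transformations of
`Y` and insensitive to outliers in scale: it detects mean shifts,
variance changes, and any other distributional movement across
subgroups.

### The normalizing constant, and an exact [0, 1] alternative

`C(N) = (N^2 - 1) / (6 N^2)` is the exact value of
`mean_i G(Y[i,]) (1 - G(Y[i,]))` when the target is univariate with
distinct values: then `G(Y[(k),]) = k/N` for the order statistics and

```
(1/N) sum_k (k/N)(1 - k/N)  =  (N^2 - 1) / (6 N^2),
```

and since the conditional-cdf variance at a point is bounded by the
Bernoulli variance `G(1 - G)`, the constant makes the CID land
exactly at 1 in the fully dependent univariate case (distinct target
values, singleton subgroups):

```{r unit-case}
y <- matrix(rnorm(12), 12, 1)
cid(y, subgroup_assignment(1:12))$value
```

For **multivariate** targets, however, ties in the componentwise
order make `mean_i G(1 - G)` data dependent, and it can exceed
`C(N)`: with the fixed constant the CID can legitimately exceed 1 on
small clustered instances (values around 1.4 occur at `N = 5`,
`q = 2`).  `cid()` therefore offers two normalizers:

* `normalizer = "fixed"` (default): divides by `C(N)`.  Comparable
  across pairs of the same cohort and the convention used throughout
  the package's pipelines; the toy example below yields 0.425 under
  it.  Range `[0, 1]` is guaranteed for univariate targets only.
* `normalizer = "empirical"`: divides by the observed
  `mean_i G(Y[i,])(1 - G(Y[i,]))`.  This is the sharp bound of the
  numerator, so `CID ∈ [0, 1]` holds for *every* input, at the cost
  of a data-dependent denominator.

Permutation p-values are identical under either choice — the
normalizer is a constant within a dataset, and the test statistic's
ordering across permutations is unchanged.

### Worked example

Five samples, three predictor genes, two target genes:

```{r toy}
X <- rbind(r1 = c(-0.38,  0.27,  1.82),
           r2 = c(-0.24,  0.36,  0.94),
           r3 = c(-0.32, -0.36, -0.62),
           r4 = c(-0.05,  0.25,  0.37),
           r5 = c( 0.05,  0.09,  0.02))
Y <- rbind(r1 = c( 0.17, 1.88),
           r2 = c( 4.33, 1.83),
           r3 = c(-0.87, 0.61),
           r4 = c(-2.37, 0.43),
           r5 = c( 2.55, 2.03))
asg <- subgroup_by_clustering(X, K = 3)
split(rownames(X), asg$labels)
cid(Y, asg)
```

The complete-linkage tree at `K = 3` groups {r1, r2}, {r3}, {r4, r5};
the marginal ecdf at the five samples is (0.6, 0.6, 0.4, 0.2, 0.8);
accumulating the weighted squared discrepancies gives per-sample
contributions (0.04, 0.04, 0.14, 0.06, 0.06) and
`CID = 0.068 / 0.16 = 0.425`.

## Permutation inference

`permutation_pvalue()` builds the null by breaking the sample linkage
between the blocks:

* **CID**: the predictor block is clustered *once*; each of the `B`
  iterations randomly permutes the subgroup labels across samples
  (partition sizes fixed) and recomputes the statistic.  The
  indicator matrix `L[i, j] = 1{Y[i, ] <= Y[j, ]}` is precomputed, so
  each permutation costs one `rowsum()` — about 0.1 s for `B = 1000`
  at `N = 100`.
* **Rival measures** (canonical correlation, discretized
  Kullback–Leibler and Hellinger divergences, projection pursuit
  regression): the rows of `X` are permuted and the full statistic
  recomputed, including re-clustering where the measure conditions on
  subgroups.

The p-value is the fraction of null statistics that beat or tie the
observed one (one-sided; smaller-is-better for the PPR residual sum
of squares).  No `+1` correction is applied, so `p = 0` is possible
and the test is slightly anti-conservative at `p` near `1/B`; with
`B = 1000` the measured type-I error stays inside the binomial band
around 0.05 (see below).

For all-pairs screening, `adjusted_cid()` standardizes each
predictor's column of the raw `G x G` CID matrix by its median and
(unscaled) median absolute deviation; adjusted values above 3.5 mark
a target set as unusually dependent on that predictor relative to the
predictor's typical association level.

## Regularized canonical reduction

With 10 or more genes in a block, the multivariate ecdf at `N` around
50–150 becomes too coarse.  `reduce_pair()` replaces such a pair by
the scores of its first (at most) 3 ridge-regularized canonical
variate pairs: coefficients maximize `cor(X a, Y b)` under unit
variance measured by `S_XX + lambda_x I` and `S_YY + lambda_y I`,
computed from the symmetric eigenproblem of
`(S_XX + l1 I)^{-1/2} S_XY (S_YY + l2 I)^{-1} S_YX (S_XX + l1 I)^{-1/2}`.
Ridge penalties make the computation well-posed when a block has more
genes than samples.  Penalties come from leave-one-out
cross-validation over the grid `{1e-4, 1e-3, 1e-2, 1e-1, 1}`
(standardizing inside each fold; ties resolved toward the smallest
total penalty).  A grid-search oracle over unit coefficient vectors
verifies the eigen solution in the test suite.

## Simulation models and their calibration

Two generators drive the package's benchmarking
(`run_power_study()`).

**Linear model.** `X` is `N x p` standard normal,
`u = rowSums(X) / sqrt(p)`, and each of the `q` target genes is
`rho * u + sqrt(1 - rho^2) * e` with exchangeable intra-set error
correlation `s`.  `rho = 0` gives exact independence and is the
type-I null.

**Nonlinear model.** Six independent Uniform(0, 1) predictors and a
bivariate target:

```
Y1 = 10 sin(pi (2 X1 - 1)(2 X2 - 1)) + e1      (mean signal)
Y2 = exp(32 (X3 + X4 - 1)) * e2                (variance signal)
```

with `e1, e2` standard normal; `(X5, X6)` is independent of `Y` and
serves as the null pair.  Both signal forms were *calibrated for the
benchmark setting* `N = 100`, `K = 5`:

* The mean signal uses the centered product `(2 X1 - 1)(2 X2 - 1)`.
  By sign symmetry, `Y1` is exactly uncorrelated with every linear
  combination of `X1` and `X2`, so canonical correlation — which can
  only see linear projections — stays near the nominal level
  (measured power ~0.1–0.2), while conditioning on predictor-derived
  subgroups exposes the strong mean separation (CID power 1.0 with
  every replicate at `p = 0` in calibration runs).  An uncentered
  product (`sin(pi X1 X2)`) would leak a large linear component and
  make the linear rival succeed for the wrong reason.
* The variance rate constant 32 makes the spread of `Y2` differ
  dominantly *between* subgroups rather than within them.  Because
  the CID is rank-based, the power of a pure scale family saturates
  as the rate grows — the rank structure becomes rate-invariant — and
  the residual failures are replicates in which the complete-linkage
  clusters of the uniform `(X3, X4)` cloud happen to mix variance
  levels.  A systematic scan (rates 2–96, normal and uniform noise,
  sigmoid/step/product modulations) put the plateau at power
  0.93–0.97 for `R = 100` replicates with `B = 1000`; the adopted
  constant sits on that plateau.  Rates below ~8 leave the signal
  largely undetectable (power 0.28 at rate 2).  The ~3–7% residual
  miss rate is a structural property of conditioning on a clustering
  of uniform predictors, not of the amplitude, and is the main known
  limitation of this benchmark design.

Measured behavior at `N = 100`, `K = 5`, `B = 1000`, `R = 100`,
nominal level 0.05 (seeds 1–3 of `scripts/acceptance.R`):

| quantity                          | measured    |
|-----------------------------------|-------------|
| linear-null type-I error          | 0.02 – 0.08 |
| nonlinear (X5, X6) type-I error   | 0.03 – 0.10 |
| CID power on (X1, X2)             | 1.00        |
| CID power on (X3, X4)             | 0.93 – 0.94 |
| both detected in same replicate   | 0.93 – 0.94 |
| CanCor power, max of both signals | 0.20 – 0.32 |

`Y2`'s dynamic range spans many orders of magnitude by construction;
this is harmless to rank-based statistics but makes the target look
extremely heavy-tailed to moment-based ones — deliberate, as the
benchmark contrasts the two families, but worth keeping in mind if
the generator is reused elsewhere.

## Pipelines, sizes and numerical choices

* **Unsupervised screening** fixes `K = 3` (robust for cohorts of a
  few dozen arrays) and computes all `G (G - 1)` directed values — a
  186-set collection yields 34,410 CIDs; at `N ~ 100` this runs in
  minutes because the indicator matrix of each target block is built
  once per block.
* **Supervised testing** sets `K = max(2, round(N / 10))` (60 → 6,
  48 → 5, 152 → 15) and reports the permutation p-value at
  `B = 1000`; cohorts under 20 samples trigger a warning, as `K`
  would fall below 2 before clipping.
* **Reduction** applies when either block has ≥ 10 genes, keeping
  `min(3, p, q)` variate pairs.
* Deterministic reproducibility: every replicate, pair and test
  derives its own substream from a master seed (`derive_seeds()`),
  so serial and parallel schedules agree, and helpers restore the
  caller's RNG state.
* Missing values are handled at pair extraction (`extract_pair()`):
  drop the gene (default), drop the sample, or reject.

## Limitations

* The CID is directional (predictor → target); `symmetric_cid()`
  averages the two directions when an undirected summary is wanted.
* The fixed normalizer can exceed-1 on small multivariate instances
  (see above); use `normalizer = "empirical"` when a strict `[0, 1]`
  range matters.
* Power on variance-type signals depends on the clustering of the
  predictor block; conditioning on complete-linkage clusters of
  roughly uniform predictors leaves a few percent of replicates
  undetectable regardless of signal strength.
* The discretized KLD/HD rivals are estimated on `r^q` cells and
  degrade quickly as `q` grows; they are included for comparison, not
  recommended for use.
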