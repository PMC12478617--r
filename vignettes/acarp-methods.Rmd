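---
title: "Aggregated conditional-covariance tests of monotone homogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated conditional-covariance tests of monotone homogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acarp)
```

## The model and the hypothesis

The monotone homogeneity (MH) model for binary items assumes a single
real-valued latent variable $\theta$ such that (i) items are conditionally
independent given $\theta$ and (ii) every item response function
$P(X_j = 1 \mid \theta)$ is nondecreasing. MH is the nonparametric umbrella
over the Rasch and 2PL models: rejecting MH falsifies unidimensional
monotone measurement itself, not a particular parametric shape.

MH implies *conditional association*: increasing functions of any item
subset have nonnegative covariance given any function of the remaining
items. The testable consequence used here is pairwise: for items $i, j$ and
a conditioning variable $Z_{ij}$ built from the *other* items,

$$ \mathrm{E}\,\mathrm{Cov}(X_i, X_j \mid Z_{ij}) \ge 0 . $$

A markedly negative conditional covariance for some pair is evidence
against unidimensionality. Crucially, the power of this check depends on
the conditioning variable. A plain rest score (Rosenbaum's case 5) is blind
to violations generated by independent latent dimensions; conditioning on
*regression-predicted* item scores — CARP, "conditioning on added
regression predictions" — is, to date, the only partial test of conditional
association known to detect them. This package aggregates the per-pair CARP
statistics into a single omnibus test of MH.

## Pairwise statistics

For each of the $K = J(J-1)/2$ item pairs:

1. **Split.** Subjects are split once into a training sample (default 30%)
   and a test sample; the same split serves every pair.
2. **Predictor.** On the training rows, the joint target $X_i + X_j$ is
   regressed by ordinary least squares on the $J-2$ remaining items. For a
   linear fit this is identical to summing separate predictions of $X_i$
   and $X_j$, so one fit per pair suffices. Rank-deficient designs get the
   minimum-norm solution (a constant remaining item simply receives weight
   zero).
3. **Groups.** Test subjects are binned into $C = 10$ decile groups of the
   predicted score. Binning uses midranks, so tied scores always share a
   group and the realized number of groups can drop below $C$; a single
   group is flagged degenerate.
4. **Statistics.** With $n_c$ subjects and item-one counts $m_{ic}, m_{jc}$
   in group $c$, the mean conditional covariance (MCC) is
   $T/N_{\mathrm{test}}$ with $T = \sum_c n_c \widehat{\mathrm{Cov}}_c$,
   and the Mantel–Haenszel (stratified hypergeometric) variance is
   $$ \hat V = \sum_c \frac{m_{ic}(n_c - m_{ic})\, m_{jc}(n_c - m_{jc})}
      {n_c^2 (n_c - 1)} . $$
   The standardized statistic is $Z = (T + 0.5)/\sqrt{\hat V}$, where $0.5$
   is Rosenbaum's continuity correction (a flag; see below), and the
   p-value is the left normal tail. Pairs with $\hat V = 0$ on the test
   sample are excluded from every aggregation, with $K$ reduced
   accordingly.

Training-sample MCCs, needed for preselection, are computed the same way
with the predictor applied to the training rows themselves. Whether the
training MCC should instead borrow the test-sample deciles is genuinely
open; the self-contained version was chosen because it keeps the training
and test samples strictly separated, which is what makes preselection valid.

## Covariance of the pairwise statistics

Aggregation needs the $K \times K$ covariance $\Sigma$ of the statistic
vector. Three estimators are available, and the second letter of each test
code picks one:

* **Identity (I).** $\Sigma = I_K$ for the standardized $Z$s. Within a
  decile group the latent variable is nearly pinned down, items are close
  to independent Bernoulli variables, and standardized statistics of
  near-independent tables are asymptotically uncorrelated. The identity is
  never offered for raw MCCs, whose scales differ across pairs.
* **Moments (M).** A delta-method plug-in that treats group labels and
  sizes as fixed. Writing the MCC numerator as a sum of within-group
  centered cross products $u^{(p)}_n$, independence across subjects gives
  $$ \widehat{\mathrm{Cov}}(\mathrm{MCC}_p, \mathrm{MCC}_q) =
     \frac{1}{N^2}\Big( \textstyle\sum_n u^{(p)}_n u^{(q)}_n -
     \sum_n \bar u^{(p)}_{c_p(n)} \bar u^{(q)}_{c_q(n)} \Big), $$
  which uses only sample moments of the items and their products. Treating
  the groups as fixed ignores the correlation between group assignment and
  the item scores; the estimator is validated in the test suite against a
  brute-force oracle (the empirical covariance of MCC vectors across
  thousands of independently simulated data sets) and against the
  bootstrap. The $Z$-scale version rescales entry $(p,q)$ by
  $N^2/\sqrt{\hat V_p \hat V_q}$, the linearization $Z \approx N \cdot
  \mathrm{MCC}/\sqrt{\hat V}$.
* **Bootstrap (B).** Test rows are resampled with replacement ($B = 1000$
  by default) and the statistic recomputed per pair. The training-fitted
  predictors and, by default, the decile cut-points of the original test
  sample are held fixed: the conditioning rule is part of the statistic's
  definition, and only the test data are resampled. Recomputing cut-points
  per resample is available behind a flag. Resamples where a pair is
  degenerate enter as missing values under pairwise-complete covariance; a
  pair degenerate in more than 10% of resamples is dropped.

Estimated matrices can be indefinite in finite samples; `repair_psd()`
raises the smallest eigenvalue to a jitter of $10^{-10}$ before any
Cholesky factorization.

## Aggregation: the 20 omnibus tests

The statistic vector $x$ (MCCs or $Z$s) is aggregated in eight ways; the
last two letters of a test code name the aggregation.

**Cone projection (LR, CL).** $x$ is projected onto the nonnegative cone
under the Mahalanobis metric of $\Sigma$:
$\bar\chi^2 = \min_{\theta \ge 0} (x-\theta)' \Sigma^{-1} (x-\theta)$.
The problem is whitened with the Cholesky factor of $\Sigma$ and solved as
nonnegative least squares; under the identity it reduces to clipping
negative coordinates, and the implementation is checked against an
exhaustive active-set oracle. The **LR** test compares $\bar\chi^2$ to its
least-favorable null distribution, a mixture of chi-squares whose weights
$w_k$ are the probabilities of $k$ negative coordinates in a
$N(0, \Sigma)$ draw. For general $\Sigma$ the weights are estimated by
Monte-Carlo counting (default $M = 10^4$ draws, seeded); under the identity
they are exactly $\mathrm{Binomial}(K, 1/2)$ and the closed form is used —
the one place the implementation substitutes an exact quantity for a
Monte-Carlo one. The **CL** (conditional likelihood-ratio, Wollan–Dykstra)
test conditions on the number $D$ of binding zero coordinates of the
projection and compares $\bar\chi^2$ to $\chi^2_D$; with $D = 0$ it never
rejects, ignoring the small conditioning-probability factor. For general
$\Sigma$, $D$ is taken to be the number of binding constraints (which
equals the count of negative statistics under the identity); the elided
alternative reading ($K$ minus the face dimension) coincides in that case.

**Preselection (PS, PP, PB).** The training sample selects the pairs with
negative training MCC; because training and test samples are independent,
test-sample p-values over the selected set can be combined as if the set
were fixed a priori. **PS** is the standardized partial sum
$\sum_S x / \sqrt{\sum \Sigma_S}$ against the normal left tail; **PP** is
Fisher's product $-2\sum_S \ln p$ against $\chi^2_{2K_S}$; **PB** is
Bonferroni $\min(1, K_S \min_S p)$.

**Conditionalization (CS, CP, CB).** Pairs with test p-value below
$t = 0.5$ are kept and their p-values divided by $t$; if the raw p-values
are uniform, the corrected ones are uniform given selection. With the
continuity correction on, $p < 0.5$ is not exactly $\mathrm{MCC} < 0$ — the
selection is deliberately defined on the p-value, not the MCC sign.
**CS** is the Stouffer sum $\sum \Phi^{-1}(\tilde p)/\sqrt{K'}$, **CP**
Fisher's product on the corrected p-values, **CB** Bonferroni. These
combiners ignore correlations between pairs, which is why they are only
registered with the identity covariance. Corrected p-values of exactly zero
are clamped at $10^{-300}$ before logs, with a message.

Crossing statistic, covariance, and aggregation gives the 20 meaningful
codes: `{MB, MM, ZB, ZM} x {LR, CL, PS}` plus
`ZI x {LR, CL, PS, CS, CP, CB, PP, PB}`. Empty selections yield $p = 1$ and
no rejection. The default level is $\alpha = 0.05$ throughout.

## The simulator

`simulate_irt()` draws from a compensatory two-dimensional 2PL,
$P(X_j = 1 \mid \theta) = \mathrm{logit}^{-1}(a_{j1}\theta_1 +
a_{j2}\theta_2 + b_j)$, with $\theta$ bivariate standard normal and
uncorrelated, intercept parametrization, and no 1.7 scaling constant.
Scenario `dim0` sets all discriminations to zero (items i.i.d.
Bernoulli(1/2) at $b = 0$); `dim1` loads every item on dimension 1 (MH
holds); `dim2` splits items evenly over the two dimensions (dimension 1
takes the extra item for odd $J$), so between-dimension pairs violate
unidimensionality while every within-dimension margin still looks monotone.
Parameters are fixed constants or drawn uniformly per item. The random-case
default ranges — $a \sim U(0.5, 2)$, $b \sim U(-1, 1)$, $J$ uniform on
$\{3, \dots, 30\}$, $N$ uniform on $[250, 2500]$ — are this package's
standing choices for "realistic IRT variety" and are ordinary config
arguments, so other bounds can be dropped in.

What the generator does *not* emulate: correlated latent dimensions, more
than two dimensions, polytomous or missing responses, guessing asymptotes,
or non-logistic response shapes. Passing Type I error and power checks
under this generator therefore says nothing about, e.g., robustness to
correlated traits — the tests' validity argument (conditional association
under MH) is model-free, but the power figures are specific to these
alternatives.

## The experiment harness and reproducibility

`run_rejection_grid()` crosses designs with test codes, computing the
pairwise statistics once per replication and applying every requested
aggregation to them. One master seed spawns an independent seed per
replication up front, so results are identical regardless of execution
order; each replication seed further splits into simulation, split, and
aggregation streams. Replications where a test cannot be computed (all
pairs degenerate — possible with tiny $J$ and extreme intercepts) are
recorded as missing and removed from that cell's denominator, with the
count reported. `pvalue_diagnostics()` produces sorted p-value-versus-rank
series (uniform p-values sit on the diagonal; supra-uniform curves bow
above it), and `summarize_binomial_dominance()` checks whether per-cell
rejection counts are stochastically dominated by the
$\mathrm{Binomial}(n_{\mathrm{reps}}, \alpha)$ reference.

The shipped presets are reduced but honest versions of the four benchmark
grids (`?preset_designs`): the zero-dimensional small corner at 1000
replications per cell, the unidimensional $a = 1$ grid and the
two-dimensional $a = 1.7$ power grid at 100, and 20 random unidimensional
cases at 50. These sizes give Monte-Carlo standard errors of about 0.007
(1000 reps) to 0.03 (50 reps) on a rejection proportion near 0.05, which is
tight enough to distinguish nominal behaviour from inflation; full-scale
runs are a matter of raising `n_reps`.

## Numerical choices

* Conditioning scores are rounded to 9 decimals before binning, so scores
  equal up to floating-point noise are always treated as tied; decile
  boundaries are otherwise arbitrary at the $10^{-16}$ level.
* Group tallies are accumulated in double precision (the MH variance
  products overflow 32-bit integers for groups of a few hundred subjects).
* The NNLS projection tolerance is the solver default (`pracma::lsqnonneg`);
  binding constraints are detected at tolerance $10^{-8}\max(1, \|x\|_\infty)$
  jointly on the coordinate and its Lagrange multiplier.
* The continuity correction defaults **on**, matching the primary Type I
  error studies; the ablation grids switch it off. Per pair,
  $p_{\mathrm{on}} \ge p_{\mathrm{off}}$ always. For the preselected
  aggregates that ordering carries over per replication exactly; for the
  conditionalized ones it can fail in boundary cases (the shift can move a
  pair out of the $p < t$ selection, and Fisher's statistic is not monotone
  under removal of a weak p-value), though cell-level rejection rates still
  order in practice — the tests assert exactly this split.
* Degenerate pairs are excluded and logged rather than imputed; an analysis
  in which *every* pair is degenerate errors out and is recorded as a
  missing replication by the harness.

## Known limitations

Single train/test split (no aggregation over splits); binary items only;
the moments estimator ignores the randomness of group assignment, which is
visible as mild misestimation in small samples; the conditionalized
combiners assume near-independence of the pairwise statistics and are
therefore only offered with the identity covariance; and power against
alternatives with more than two latent dimensions is unexplored here.
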