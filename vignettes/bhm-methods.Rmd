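---
title: "Joint low- and high-order functional network estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint low- and high-order functional network estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhmnet)
```

## The estimation problem

A subject's parcellated rs-fMRI recording is a matrix $X \in \mathbb{R}^{n
\times p}$: $n$ time points by $p$ regions of interest (ROIs). After each
column is centred and scaled to unit norm (`normalize_signals()`), the
*low-order* functional network is the correlation matrix

$$\widehat W = X^\top X, \qquad \widehat w_{ij} = x_i^\top x_j,$$

the sample Pearson correlation of every ROI pair. Low-order edges measure
signal-level synchrony. A *high-order* network instead connects two ROIs
when their **connection profiles** agree: the correlation's-correlation
(CC) network centres and normalises the columns of $\widehat W$ and
correlates them, $\widehat H = \widehat W^\top \widehat W$
(`cc_network()`). High-order structure is informative precisely when group
differences live in the pattern of connections rather than in single edges.

CC is a fixed two-step recipe. The Bayesian high-order model (BHM)
implemented here replaces it with a joint estimator: the low-order matrix
$W$ is given a matrix-variate normal prior with a shared row/column
covariance $\Omega$, and the maximum-a-posteriori problem

$$J(W,\Omega) \;=\; \min_{W,\Omega}\; \|W - X^\top X\|_F^2
 \;+\; \lambda\left[\operatorname{tr}(\Omega^{-1} W \Omega^{-1} W^\top)
 + p \log\lvert\Omega\rvert\right]$$

is solved for both matrices at once (`fit_bhm()`). $W$ is the Bayesian
low-order network; $\Omega$, the prior covariance that best explains the
co-fluctuation of the edges of $W$, is the Bayesian high-order network.

### Coefficient convention

Published statements of this model are not mutually consistent about
constant factors: the prior's $\tfrac12$ appears on the trace term in one
place, is absent from the $\Omega$-subproblem, and the printed gradient of
the $W$-subproblem implies yet another factor. We fix one convention — the
objective above, with coefficient 1 on the trace — because it makes four
things simultaneously exact:

* the $\Omega$-subproblem is $\min_\Omega \operatorname{tr}(\Omega^{-1} W
  \Omega^{-1} W^\top) + p\log|\Omega|$;
* the $W$-gradient is $2W - 2X^\top X + 2\lambda\,\Omega^{-1}W\Omega^{-1}$;
* the $W$-update solves $W + \lambda\,\Omega^{-1}W\Omega^{-1} = X^\top X$;
* with $\Omega = I$ the update collapses to the shrunk correlation
  estimator $W = X^\top X/(1+\lambda)$ with the *same* $\lambda$.

Any residual factor is a reparametrisation of $\lambda$, which is
cross-validated anyway; `bhm_objective()` documents the implemented form
and the monotonicity tests are written against it.

## The alternating optimisation

Starting from $W_0 = X^\top X$ and $\Omega_0 = I$, each outer iteration
performs:

**Step 1 (high-order).** The $\Omega$-subproblem is solved by iterating the
fixed-point map

$$\Omega \leftarrow W^\top \Omega^{-1} W + \delta I$$

until it converges (`update_omega()`; relative change below `1e-9`,
capped at `omega_inner_iters = 500` applications). The ridge $\delta I$
keeps every iterate positive definite. Applied *once* from $\Omega = I$
with $\delta = 0$ the map returns exactly $W^\top W$ — the classical CC
matrix — so CC is recovered as the first iterate of the model's high-order
network; on atlas-scale inputs ($p \approx 80$–$160$, $n = 175$) the two
correlate above $0.99$, the residual difference being the column centring
of the second correlation pass, a $1/p$-order correction.

Why iterate to the fixed point rather than apply the map once per outer
cycle? The scalar analogue of the map is $x \mapsto d^2/x + \delta$, whose
derivative at its fixed point is close to $-1$ when $\delta$ is small: it
converges, but as a *damped oscillation*. Interleaving single applications
with $W$-updates makes the joint objective oscillate too (about one hundred
transient increases on a typical $p = 20$, $n = 50$ fit at
$\lambda = 10^{-2}$), whereas driving the map to its fixed point inside
each outer step restores a cleanly decreasing objective (strictly
decreasing on a $\lambda \in \{10^{-4},10^{-3},10^{-2}\}$ by ten-seed
grid) and cuts outer iteration counts from hundreds to well under thirty.
Single-application behaviour remains available
(`bhm_config(omega_inner_iters = 1)`) and is how the CC correspondence is
exercised; `fit_bhm()` aborts with a diagnostic if the objective ever rises
by more than $10^{-6}$ relative, which that configuration reliably
triggers at moderate $\lambda$.

**Step 2 (low-order).** With $\Omega$ fixed the subproblem is an
unconstrained convex quadratic solved in closed form in the eigenbasis
$\Omega = U \Lambda U^\top$:

$$\tilde W_{ab} = \frac{\tilde S_{ab}}{1 + \lambda/(\Lambda_a \Lambda_b)},
\qquad \tilde S = U^\top (X^\top X)\, U,$$

an anisotropic shrinkage: edge directions aligned with small-eigenvalue
directions of $\Omega$ (weak high-order support) are shrunk hardest. The
stationarity residual of the returned matrix is at machine precision, and
as $\lambda \to 0$ the fit collapses to the plain correlation network.

Convergence of the outer loop is declared when the larger of the relative
Frobenius changes of $W$ and $\Omega$ falls below `tol = 1e-5` (cap 100
iterations). Both matrices are re-symmetrised after every update to
suppress floating-point drift. $\delta$ defaults to $0.1$; $\lambda$ has
no default inside `bhm_config()` and is selected by the pipeline's inner
cross-validation over $\{10^{-4},10^{-3},10^{-2},10^{-1},1\}$.

## Baseline estimators

* `pc_network()` — plain correlation; unit diagonal, entries clamped to
  $[-1,1]$.
* `shrunk_pc_network()` — $X^\top X/(1+\lambda)$, the ridge/Gaussian-prior
  shrinkage of every edge; identical to `pc_network()` at $\lambda = 0$.
* `sr_network()` — sparse representation: each ROI regressed on all others
  under an L1 penalty $\|x_i - \sum_{j\ne i} w_{ij} x_j\|^2 + \lambda
  \sum_{j\ne i}|w_{ij}|$, diagonal clamped to zero, solved by cyclic
  coordinate descent (convergence when the largest coefficient change in a
  sweep is below $10^{-8}$, cap $10^4$ sweeps). The output is asymmetric
  and is symmetrised by $(W + W^\top)/2$ — the least-committal choice —
  before feature extraction.
* `soft_threshold_network()` — Laplacian-prior analogue: entrywise
  two-sided soft thresholding $\operatorname{sign}(s)\max(|s|-\lambda,0)$
  of the correlations. The thresholding rule is stated in its one-sided
  positive form in parts of the literature; the two-sided form is the
  unique minimiser of the per-edge objective $\tfrac12 w^2 - sw +
  \lambda|w|$ (the $\tfrac12$-scaled least squares under which the rule is
  exact) and treats negative correlations symmetrically, which matters
  because negative edges carry discriminative weight in this setting.
  Note the convention difference from `sr_network()`, whose penalty is
  applied to the unscaled residual sum of squares (threshold $\lambda/2$).
* `cc_network()` — the two-pass correlation above. All $p$ columns,
  including the diagonal entries, enter the second correlation; excluding
  the diagonal is a defensible variant, but no exclusion rule is standard
  and keeping the full profile makes $\widehat H$ exactly the correlation
  matrix of the stored connectivity columns.

## The synthetic cohort generator

`simulate_cohort()` draws the data the estimators assume, no more:

1. a block-diagonal group template (compound symmetry: `within_block_corr`
   inside blocks, default two equal blocks at $r = 0.5$);
2. group 1's template adds `effect_size` (default $0.3$) to `effect_edges`
   (default 10) randomly chosen between-block edges — the planted
   discriminative ground truth, recorded in `truth_edges`;
3. each subject perturbs its group template by a symmetrised matrix-normal
   draw with row/column covariance equal to the group-0 template
   (`truth_omega`; this is what gives the planted two-block high-order
   structure that the fitted $\Omega$ should recover) at scale
   `subject_sd` (default $0.05$), projected back to a unit-diagonal
   positive definite matrix by eigenvalue clipping at $10^{-6}$ plus
   diagonal rescaling;
4. $n = 175$ i.i.d. Gaussian time points per subject (the length of a
   typical single-site recording), $40$ subjects per group.

The generator reproduces the *correlation structure* assumptions only.
Real BOLD signals are temporally autocorrelated, non-stationary and
subject to motion and physiological artefacts; none of that is emulated,
so passing tests certify the estimators and the pipeline logic, not
preprocessing robustness. Defaults keep $p = 20$ rather than an atlas's
160 so that whole-cohort simulations run in seconds; properties that
genuinely depend on width (the CC correspondence above) are tested at
$p = 80$.

## Classification pipeline

Edge weights are the features: the $p(p-1)/2$ strictly-upper-triangular
entries in lexicographic order (`vectorize_upper_triangle()`; a 160-ROI
network yields 12720 features). Selection is a two-sample pooled-variance
t-test per edge (`ttest_select()`; Welch behind a flag), fitted on
training subjects only; the classifier is a linear SVM with $C = 1$ and no
feature standardisation by default. Evaluation is leave-one-out over
subjects with an inner leave-one-out on each training set to pick the
estimator hyper-parameter (and optionally the selection threshold) by
inner accuracy, ties resolved toward the smallest value. Confusion counts
accumulate over outer folds into accuracy, sensitivity and specificity,
with group 1 as the positive class. When a fold selects no edge at the
requested threshold, the single smallest-p edge is used (with a warning)
so the classifier stays defined. `parameter_sweep()` re-runs the protocol
with the swept value held fixed; its "best over the grid" headline is
optimistic — the grid is chosen on the same data — and is reported as
such.

### A calibration caveat: balanced leave-one-out anti-learning

On a *balanced* null cohort the default protocol is not at chance — it is
reliably **below** it. Raw correlation-edge features have standard
deviation around $0.1$; with $C = 1$ and no standardisation the SVM cannot
buy enough margin to use them and degenerates to a majority vote over the
training set. Under leave-one-out the held-out subject is always in the
training *minority* (9 versus 10), so the majority vote is always wrong:
measured mean accuracy over label permutations is $0.00$–$0.14$ depending
on cohort. This is a known artefact of cross-validating near-chance
classifiers on balanced data, and it disappears under either class
imbalance (the vote then lands on the fixed majority class) or feature
standardisation (`scale_features = TRUE`, which restores a non-degenerate
fit; measured permutation means $0.43$–$0.52$). The package's calibration
tests therefore standardise features; the default stays unstandardised to
match the conventional protocol, and a dedicated test pins the
anti-learning behaviour itself so a regression cannot silently change it.

## Numerical choices, in one place

* Normalisation: centre first, then scale to unit norm, per column;
  zero-variance columns are rejected by ROI index.
* $n = 2$ time points are allowed (correlations become $\pm 1$); $n = 1$
  is rejected.
* Positive definiteness is established via Cholesky wherever it is
  assumed; failures name the offending iterate.
* PD projection (synthetic module): eigenvalue clipping at $10^{-6}$ then
  unit-diagonal rescaling, iterated to 100 steps; alternating projections
  would be overkill at these sizes.
* Coordinate descent (`sr_network()`): threshold $\lambda/2$ on the
  partial residual correlation, convergence at $10^{-8}$ max coefficient
  change; with very short series (collinear regressors) the contraction is
  slow and comparisons against the grid-search oracle are run at tighter
  tolerances.
* Inner-loop tie-breaks: smallest hyper-parameter, then smallest
  threshold; `which.max` on a grid ordered ascending.
* All randomness is seeded; cohorts are bitwise-reproducible functions of
  their spec, and `evaluate_loocv()` is deterministic for a fixed cohort.

## Known limitations

* MAP point estimation only; no posterior uncertainty on $W$ or $\Omega$,
  and the row/column covariances are constrained equal
  ($\Omega_1 = \Omega_2$), which is what symmetry of $W$ justifies.
* The $\Omega$ fixed-point map is a heuristic solver of its subproblem —
  its fixed point is not the subproblem's exact stationary point (the
  exact one carries an extra $1/p$ scale) — but it preserves the CC
  correspondence at iteration one, the overall scale trades off against
  the cross-validated $\lambda$, and the joint objective decreases
  monotonically in practice; the divergence guard turns any exception into
  a hard error rather than a silent drift.
* Accuracies measured on synthetic cohorts say nothing about real rs-fMRI
  preprocessing, scanner or site effects.
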