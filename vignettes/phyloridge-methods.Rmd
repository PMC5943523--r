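---
title: "Branch-wise evolutionary rates by phylogenetic ridge regression: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-wise evolutionary rates by phylogenetic ridge regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloridge)
```

## The model

phyloridge assigns every branch of a rooted, time-calibrated phylogeny its
own rate of phenotypic change. Write $y$ for the vector of tip phenotypes of
one trait and $a_0$ for the phenotype at the root. The difference between a
tip and the root is the sum of per-branch transformations accumulated along
the root-to-tip path,

$$y_i - a_0 = \sum_{b \in \text{path}(i)} \beta_b \, l_b,$$

with $l_b$ the branch length (time) and $\beta_b$ the rate (trait units per
time unit) on branch $b$. Collecting the path structure in the tip-to-branch
matrix $\mathbf{L}$ (entry = branch length if the branch is on the tip's
root path, else 0; `pr_tip_path_matrix()`), the rates of all branches are
estimated jointly by ridge regression,

$$\hat\beta = (\mathbf{L}^\top \mathbf{L} + \lambda \mathbf{I})^{-1}
  \mathbf{L}^\top y,$$

and ancestral states follow from the analogous node-to-root path matrix
$\mathbf{L}'$ as $\hat a = \mathbf{L}' \hat\beta + a_0$. The penalty
$\lambda$ is essential, not cosmetic: a rooted binary tree has $2N - 2$
branches but only $N$ tips, so the unpenalized system is singular, and
$\lambda > 0$ both regularizes it and prevents the perfect tip fit that
would make ancestral states meaningless. With several traits (here,
relative-warp scores), each trait column is solved with the same $\lambda$,
one $\beta$-vector per branch; the scalar evolutionary rate of a branch is
the Euclidean norm of that vector.

### The root and why the data are centered

The regression measures transformations *relative to the root phenotype*,
but the root value is not part of the ridge system. We estimate it first as
the generalized-least-squares mean of the tips under Brownian motion
(weights from the shared-path covariance, `pr_root_estimate()`), center $y$
on it, and add it back to the ancestral estimates. Without centering, the
penalized solution absorbs the root value into the coefficients of the basal
branches, shrinking estimated rates toward an arbitrary origin. Whether the
original formulation centers this way or fits the root jointly is not
something we assert; the GLS-centering is this package's documented choice.

### Choosing the penalty

No selection rule for $\lambda$ comes with the model, so the package uses
the standard ridge answer: k-fold (default 5) cross-validated prediction
error of tip phenotypes, over a 30-point log-spaced grid from $10^{-6}$ to
$10^3$, with the fold assignment fixed by a seed. Held-out tips are
predicted as root + $\sum \hat\beta_b l_b$ along their path, refitting both
root and coefficients without them. Exact ties are broken toward the larger
(more shrinking) penalty. On Brownian data at $N = 100$ this reconstructs
tip values with correlation above 0.99, which is the sanity floor the test
suite enforces (r > 0.9).

## Locating rate shifts

Branch-wise ridge rates describe *where* evolution was fast; deciding
whether a clade's elevation is real is done on a different footing, by
multi-rate Brownian model comparison:

1. every clade with at least `min_size` tips (default 5) is scored with its
   maximum-likelihood Brownian rate $\hat\sigma^2 = z^\top C^{-1} z / n$
   (subtree GLS-centered data, subtree covariance), averaged across traits;
   ML rather than REML is used because only the ordering matters here;
2. the top `n` nodes (default 3) — or, alternatively, the number of
   topologically distinct candidate groups found by bootstrapped
   average-linkage clustering of the candidates' patristic distances, with
   k chosen by mean silhouette — define the search set;
3. all $2^n$ shift combinations (including the no-shift model) are fitted by
   restricted maximum likelihood and compared by likelihood-ratio tests
   ($\chi^2$, df = difference in regime count, $\alpha = 0.05$); the winner
   is the most complex model that beats every nested simpler model, with
   pure Brownian motion as the fallback.

Branches are assigned to the regime of their nearest enclosing shift node
(stem branch included), so nested shifts are legal and the regimes always
partition the tree. A shift at the root is rejected: it would leave the
background regime empty and is indistinguishable from rescaling.

The multivariate fit uses a proportional model: one tree covariance
$V = \sum_r m_r C_r$ (background multiplier fixed at 1) shared by all
traits, and a common across-trait covariance concentrated out of the REML
likelihood at its analytic optimum $\hat R = E^\top V^{-1} E/(n-1)$. This
keeps regime multipliers identifiable at realistic sample sizes and the
nested likelihood-ratio tests exact; fully free per-regime trait covariance
matrices are out of scope. For a single trait and a single regime the
likelihood reduces to the closed-form Brownian REML value, and the
implementation agrees with `phytools::brownieREML` to numerical precision —
the test suite uses both as independent oracles.

### What the calibration tests do and do not show

For a *fixed* clade the likelihood-ratio test is exactly calibrated: across
null simulations its statistic matches the $\chi^2_1$ reference and rejects
5% of the time at $\alpha = 0.05$. The *search*, however, tests the clades
that ranked highest among dozens of overlapping candidates, and the selected
maximum statistic rejects considerably more often than the nominal level —
in our null simulations the no-shift model is retained in roughly 60% of
replicates rather than 95%. This selection effect is inherent to the
rank-then-test design with per-test $\alpha$; we report it rather than
silently correct it, because the decision rule (per-comparison $\alpha$,
$\chi^2$ df = regime difference, most-complex-winner ladder) is part of the
method's specification. Users who need family-wise control should treat a
selected shift as a candidate for confirmation, e.g. on new traits, rather
than as a calibrated discovery. Power, by contrast, is excellent: a tenfold
rate shift in a 20-tip clade of a 100-tip tree is recovered to within one
edge of the true node in ~90% of simulations.

A related, measured caveat: the top-*ranked* single candidate is usually a
small subclade *inside* the true shifted clade (small clades have the
noisiest $\hat\sigma^2$), not the shifted clade's root itself. The model
comparison step corrects this — enumerating combinations of the top three
candidates lets the full clade win on likelihood — which is why ranking is
only a search heuristic, never the inference.

## Trajectory angles

Each branch's $\hat\beta$-vector has a direction in trait space. The net
direction of change from an ancestor to a species is the plain vector sum of
the branch vectors along the node-to-tip path (the resultant,
`pr_resultant()`), and two directions are compared by
$\theta = \arccos\left(A \cdot B / |A||B|\right)$, clipped against rounding
and reported in degrees. `pr_trajectory_angles()` measures every grouped
species against a reference direction at a chosen ancestor. The reference is
by default the *ancestral phenotype vector* at that node (its estimated
position in trait space, matching the "angle from the origin" reading); the
ancestor's own branch rate vector is available via `reference = "branch"`
because the choice is substantive and should be explicit.

Group divergence is tested by shuffling species' group labels within each
pair of groups (default 10,000 shuffles): one-tailed, large observed mean
difference = divergent trajectories, with the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$ so p-values are
never zero and are reproducible from the seed. What is shuffled is the
per-species angle labels — the species-level exchangeability reading — not
the branch rates themselves. Against exhaustive enumeration (groups of 3 and
4, 35 splits) the Monte-Carlo p agrees within sampling error, and under the
null the p-value distribution is uniform by a Kolmogorov–Smirnov check.
Note the test treats species as exchangeable within the pair; it does not
correct for phylogenetic autocorrelation of angles among close relatives
beyond what the rate model already absorbed.

## Phylogenetic uncertainty

Because branch-wise rates inherit the tree, the package re-runs the rate
comparison across randomized trees: a fraction of tips (default 0.5) is
pruned and reattached within a bounded topological neighbourhood — the new
attachment branch's child must lie within `max_dist` edges of the tip's
parent, where `max_dist = 2` is the default and 3 a commonly used
alternative; both are exposed because the two values are both defensible and
the choice matters. Reattachment happens at the temporal midpoint of the
target branch (a deterministic placement given the draw) with the tip's own
age preserved; draws that would create a non-positive pendant branch are
redrawn, and a tip with no feasible target is left in place with a warning
rather than silently forced. Independently, a fraction of internal node ages
(default 0.5) is redrawn uniformly between the parent's age and the oldest
daughter's age, parents before children, which is exactly the interval that
keeps every branch positive. Every randomized tree is re-validated against
all tree invariants.

Per replicate the summary is $\Delta$ = mean |rate| of the focal clade's
branches (MRCA of the focal tip set, stem included) minus the mean over all
other branches. The report gives the $\Delta$ distribution, the fraction of
replicates with $\Delta > 0$ and a one-sided sign test for a positive
median — the sign test is this package's documented stand-in for an
unspecified "statistically higher" claim. One property worth knowing when
reading it: the randomization keeps the trait data fixed, so $\Delta$
concentrates near its fixed-tree value; the spread across replicates
reflects tree uncertainty only, not sampling noise in the phenotypes.

## Geometric-morphometric preprocessing

The trait block consumed upstream is built from 2-D landmark
configurations:

* **GPA** (`pr_gpa()`): centering, scaling to unit centroid size, iterative
  optimal rotation to the consensus (proper rotations only, via the SVD of
  the cross-covariance), convergence when the consensus moves < 1e-10, cap
  100 iterations. The aligned set is finally rotated to the consensus'
  principal axes with a fixed sign convention, so results are deterministic
  and order-invariant.
* **Relative warps** (`pr_relative_warps()`): principal components of the
  aligned coordinates after tangent-space projection at the consensus — the
  warp weight exponent is 0, the convention under which relative-warp
  analysis coincides with a PCA of Procrustes-aligned data and under which
  $k$ 2-D landmarks give exactly $2k - 4$ axes of nonzero variance (two
  centering constraints, one size, one rotation; 14 axes for 9 landmarks).
  "Total Procrustes variance" in the output is the dispersion of these
  tangent-space coordinates, which the axis variances sum to exactly.
* **Species means**: with `by_species = TRUE` the aligned coordinates are
  averaged per species *before* the ordination, since downstream tips are
  species; averaging scores after ordination is available through
  `pr_species_means()` when the other order is wanted. Which order the
  original workflow used is unknown; the flag makes the choice visible.
* **Allometry** (`pr_size_correct()`): per-axis ordinary least squares of
  scores on log centroid size, residuals returned with slopes and $R^2$;
  `pr_size_regression()` reports the log-centroid-size vs external
  log-body-size check.

Semilandmarks, sliding, 3-D configurations and deformation-grid graphics
are out of scope.

## The synthetic world

All tests and the acceptance script run on generated data, so the
generators define the study conditions:

* trees: coalescent-shaped random topologies rescaled to a fixed depth
  (default 50 time units, a primate-like order of magnitude), with an
  optional fraction of tips truncated to positive ages to emulate fossils;
* traits: multivariate Brownian motion accumulated branch-wise (default 4
  traits, background rate 1, root 0), with a designated clade's rate
  multiplied (default conditions for shift studies: 100 tips, a 20-tip
  clade, multiplier 10);
* landmarks: a 9-landmark jaw-profile-like consensus, isotropic Gaussian
  landmark noise (sd 0.05 in consensus units), an optional two-group mean
  shift (0.15 units on two landmarks, i.e. three times the noise sd), then
  random rotation, translation and scaling — exactly the nuisance variation
  GPA removes, and nothing else.

These are deliberately idealized: no measurement error, no within-species
variation beyond landmark noise, no non-Brownian dynamics, isotropic and
landmark-independent noise. Passing tests therefore demonstrate correctness
of the algorithms under their own assumptions, not robustness of the
biology; with real morphometric data the Brownian and isotropy assumptions
do real work.

## Numerical choices, sizes and degenerate inputs

Linear algebra goes through Cholesky factorizations; the ridge system falls
back to an explicit error naming the remedy (`lambda > 0`) when singular.
Regime multipliers are optimized on the log scale (Brent for one shift,
Nelder–Mead with tight relative tolerance for several). Cosines are clipped
to $[-1, 1]$ before `acos`. Zero vectors (a species whose path rates cancel
exactly, or an all-identical clade) raise errors rather than returning
NaN-contaminated results. Polytomies and non-positive branch lengths are
rejected at parse time — the path-matrix algebra needs a fixed branch set,
and how the original tree handled either case is unstated.

Simulation-backed checks in the test suite and acceptance script use 20
replicates of the 100-tip shift condition, 100 randomized-tree contract
checks, 1,000 null permutation datasets at 199 shuffles, and 200 power
datasets; those sizes were chosen to make sampling error small relative to
the asserted margins while keeping a full run in the low minutes on one
CPU.
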