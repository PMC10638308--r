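---
title: "Exact Shapley values for RBF-kernel SVMs on binary fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Shapley values for RBF-kernel SVMs on binary fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbfshapley)
```

## The problem

Support vector machines with the Gaussian radial basis function (RBF)
kernel are a workhorse of molecular property prediction, where compounds
are encoded as binary fingerprints: long 0/1 vectors whose positions stand
for substructural features. The models are accurate but opaque, and the
standard remedy — Shapley values from cooperative game theory — is in
general exponentially expensive: the exact value of feature $f$ is

$$\phi_f = \sum_{\mathcal{S} \subseteq \mathcal{F} \setminus \{f\}}
  \frac{|\mathcal{S}|!\,(|\mathcal{F}|-|\mathcal{S}|-1)!}{|\mathcal{F}|!}
  \bigl(v(\mathcal{S} \cup \{f\}) - v(\mathcal{S})\bigr),$$

a sum over all coalitions of the other features. Approximations such as
KernelSHAP replace this sum with a local surrogate model, which for RBF-SVMs
can correlate poorly with the exact values. This package computes the exact
values in closed form, exploiting the special structure of the RBF kernel on
binary inputs.

## The kernel game and its closed forms

For binary vectors, every feature of a pair $(x, y)$ falls into one of three
classes: *intersecting* (active in both; $I$ of them), *symmetric
difference* (active in exactly one; $D$ of them), or inactive in both.
Features with equal values contribute nothing to the squared Euclidean
distance and each symmetric-difference feature contributes exactly 1, so

$$K(x, y) = e^{-\gamma\,\|x-y\|^2} = e^{-\gamma D},
  \qquad \gamma = \tfrac{1}{2\sigma^2}.$$

The game explaining one kernel evaluation takes the coalition value of a
feature subset $\mathcal{S}$ to be the kernel evaluated as if only the
features in $\mathcal{S}$ existed: $v(\mathcal{S}) = e^{-\gamma N_d}$ with
$N_d$ the number of symmetric-difference members of $\mathcal{S}$, and
$v(\varnothing) = 0$ by the usual convention. Two structural facts collapse
the exponential sum:

* the value function depends only on the *counts* $(N_i, N_d)$ of a
  coalition, never on which particular features it contains, so coalitions
  can be enumerated as count classes with multinomial multiplicities; and
* the players are the **union** features only. Features inactive in both
  vectors never change $v$; they are dummy players with $\phi = 0$ and are
  never materialised. The player count of the game is $I + D$, not the
  fingerprint length.

An intersecting feature changes $v$ only when it joins the empty coalition
(lifting $v$ from 0 to 1), which immediately gives

$$\phi_{f_+} = \frac{(I+D-1)!}{(I+D)!} = \frac{1}{I+D},$$

independent of $\gamma$ and always positive. A symmetric-difference feature
changes $v$ in every coalition; grouping its sum into the empty coalition,
coalitions of intersecting features only, and mixed coalitions yields the
three-term expression implemented in `phiSymmetricDifference()`:

$$\phi_{f_-} = e^{-\gamma}\frac{1}{I+D}
 + \bigl(e^{-\gamma}-1\bigr)\sum_{N_i=1}^{I}\binom{I}{N_i}
   \frac{N_i!\,(I+D-N_i-1)!}{(I+D)!}
 + \sum_{N_i=0}^{I}\sum_{N_d=1}^{D-1}
   \bigl(e^{-\gamma(N_d+1)}-e^{-\gamma N_d}\bigr)\binom{I}{N_i}
   \binom{D-1}{N_d}\frac{(N_i+N_d)!\,(I+D-N_i-N_d-1)!}{(I+D)!}.$$

The cost is $O(I \cdot D)$ per $(I, D)$ pair — quadratic in the union size,
which for real fingerprints is typically orders of magnitude below the
fingerprint length. Exchangeability within each class means a whole pair
explanation costs two scalar evaluations.

By efficiency, the values sum to the kernel value:
$I\,\phi_{f_+} + D\,\phi_{f_-} = e^{-\gamma D}$ whenever $I + D \ge 1$.

## From kernels to SVM predictions

The decision function is
$\mathrm{dist}(x) = b + \sum_n w_n K(x, V_n)$ over support vectors $V_n$
with signed dual weights $w_n$ (the product of class label and coefficient,
as fitted libraries expose it). Shapley values are additive across games, so
the distance attribution of feature $f$ is
$\phi_f = \sum_n w_n\,\phi_{f,n}$ with $\phi_{f,n}$ the pair-level value of
$f$ for $K(x, V_n)$. The bias is carried as an additional feature whose
Shapley value is $b$ itself, making the decomposition exact:
$b + \sum_f \phi_f = \mathrm{dist}(x)$.

A consequence worth emphasising: a feature *absent* from the test instance
but active in support vectors generally receives a nonzero attribution —
absence is informative, and the method quantifies it.

Platt scaling, $p(x) = (1 + e^{A\,\mathrm{dist}(x)+B})^{-1}$, has a logit
that is linear in the distance, $\mathrm{logit}(p) = -A\,\mathrm{dist}(x) -
B$. Log-odds attributions are therefore the distance attributions scaled by
$-A$, and the instance-independent term $-(A b + B)$ plays the role of the
expected value. Probabilities themselves are not linear in the distance and
admit no such transfer; explanations on the probability scale are out of
scope. The Platt sign convention above is fixed; `extractModelSpec()` maps
libsvm's `probA`/`probB` (same convention) directly.

## Numerical choices

* **Log-space combinatorics.** Every factorial/binomial ratio is evaluated
  through `lchoose`/`lfactorial` and exponentiated per summand. Individual
  binomials overflow doubles near $I + D \approx 170$, while every full
  summand is bounded by 1; log space makes the computation stable to union
  sizes beyond $10^5$ (`logCoalitionWeight()` exposes the primitive).
* **Summation order.** The mixed term accumulates with outer loop over
  $N_d$ and inner loop over $N_i$ in plain double precision. Validation
  against enumeration shows agreement at the $10^{-15}$ level for union
  sizes up to 15, far inside the $10^{-10}$ bound asserted in the tests.
* **Memoisation.** Pair values depend only on $(I, D, \gamma)$; they are
  cached in the package environment. An SVM explanation touches one cache
  entry per support vector, and repeated instances against the same model
  reuse entries across calls.
* **Efficiency tolerances.** Identities are asserted as
  $|\text{gap}| \le 10^{-8}(1 + |\text{total}|)$. A purely relative bound
  is unattainable when $\gamma D$ is large: $e^{-\gamma D}$ underflows
  toward $10^{-33}$ while cancellation in the sum leaves residues near
  machine precision.
* **Degenerate pair.** If both vectors are all-zero, $K = e^0 = 1$ but the
  game has no players and $v(\varnothing) = 0$; no attribution can sum to 1.
  `explainKernelPair()` returns an empty attribution flagged `degenerate`,
  and the SVM explainer counts and warns about such pairs rather than
  inventing an allocation.
* **$\gamma$ vs $\sigma$.** Both parameterisations are accepted;
  $\sigma$ is converted once ($\gamma = 1/2\sigma^2$) and only $\gamma$ is
  stored.

## The validation oracle

`exactShapleyEnumeration()` recomputes pair values by brute force, in two
deliberately different routes: `"counts"` sums the raw (unsimplified)
Shapley formula over coalition count classes with multiplicities, and
`"subsets"` enumerates every individual coalition by bitmask and scores
every player separately — verifying, rather than assuming, that features
within a class are exchangeable. The subset route is capped at 15 players
(exponential blow-up guard; default cap 20 for the count route).
`validateClosedForm()` packages the standard experiment — 20 random
vectors over a 15-feature universe at $\gamma = 1$, all 190 pairs — and
reports the maximum absolute deviation (observed near $5\times10^{-16}$)
and the Pearson correlation (1) between closed-form and enumerated values.

## Synthetic data: what it emulates and what it does not

`generateRandomVectors()` draws each bit independently as Bernoulli
(`density`); `generateToySvm()` assembles random support vectors, signed
dual weights in $\pm[0.1, 2]$, a small bias, and Platt parameters with
$A < 0$ (so larger distances mean higher positive-class probability — the
orientation fitted calibrations take in practice). The default density of
0.5 gives the canonical uniform random binary vector and is what the
validation experiment uses; real fingerprints are much sparser and
correlated (substructures co-occur), and toy dual weights are not the
solution of any margin optimisation. Passing tests therefore demonstrate
the *mathematics* — exactness, efficiency, additivity, stability — on
arbitrary binary inputs; they do not demonstrate chemical plausibility of
any particular explanation. For real models, `extractModelSpec()` lifts a
fitted `e1071::svm` (RBF kernel, `scale = FALSE`, binary inputs) into the
same representation, with decision values reproduced to machine precision.

Problem sizes used by the test-suite: unions up to 15 for oracle
equivalence (exhaustive enumeration grows as $2^n$), 1000+ random pairs
and 500+ model/instance cases for the efficiency sweeps, and union sizes
50–400 for the quadratic-cost check — small enough to run in seconds while
exercising every regime of the formulas, including counts far beyond
factorial overflow in the log-weight test.

## Limitations

* Binary features only. Integer- or real-valued vectors change the
  distance decomposition and need different closed forms.
* Gaussian RBF only; other radial kernels (e.g. Laplacian) are not covered.
* Binary classification; multiclass decision functions and regression SVMs
  are out of scope.
* Explanations are exact for the *model*, not causal statements about
  chemistry; correlated fingerprint bits share credit in ways that reflect
  the kernel, not mechanism.

## A worked example

```{r}
x <- denseToSparse(c(1, 0, 0, 1, 0))
y <- denseToSparse(c(1, 0, 1, 1, 1))
ex <- explainKernelPair(x, y, kernelParams(sigma = 1))
ex
perFeature(ex)
```

Two intersecting features at $1/(I+D) = 0.25$ each, two
symmetric-difference features at $-0.0661$ each, summing to
$e^{-1} = 0.368$ — the kernel value. `coalitionWorkTable()` exposes every
coalition class behind these numbers, and the command line
(`inst/cli/rbfshapley`) prints the same tables with `--show-work`.
```
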