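# rbfshapley

Exact, closed-form Shapley values for the Gaussian RBF kernel between
binary feature vectors, and exact per-feature explanations of RBF-kernel
SVM predictions built on them.

## Why

In cheminformatics (and wherever binary descriptors meet kernels), SVMs
with the RBF kernel predict well but explain nothing. Shapley values are
the principled attribution — each feature's average marginal contribution
over all coalitions — but cost `O(2^|F|)` in general, so practitioners fall
back on approximations like KernelSHAP, which can correlate poorly with the
exact values for RBF-SVMs. On *binary* vectors, however, the RBF kernel has
special structure that makes exact Shapley values cheap.

For a pair of binary vectors with `I` intersecting features (active in
both) and `D` symmetric-difference features (active in exactly one):

```
K(x, y) = exp(-gamma * ||x - y||^2) = exp(-gamma * D),   gamma = 1/(2 sigma^2)
```

Taking the coalition value of a feature subset S to be the kernel over S
(with `v({}) = 0`), the coalition value depends only on the counts
`(N_i, N_d)` of S, and the game's players are the union features only.
The exact values collapse to:

- intersecting feature: `phi = 1/(I + D)` (gamma-free, positive);
- symmetric-difference feature: an exact three-term sum over coalition
  count classes, `O(I*D)` to evaluate, computed in log space
  (`phiSymmetricDifference()`).

Per-feature values sum to the kernel value exactly (efficiency). For a full
SVM, additivity gives `phi_f = sum_n w_n * phi_{f,n}` over support vectors,
the bias acts as an extra feature with `phi_b = b`, and Platt-scaled
log-odds attributions are the distance attributions scaled by `-A` with
expected value `-(A*b + B)`. Features *absent* from a test instance but
present in support vectors carry generally nonzero attributions.

A brute-force coalition-enumeration oracle (count-class and bitmask
routes) validates the closed forms at small union sizes.

## Worked example

```r
library(rbfshapley)
x <- denseToSparse(c(1, 0, 0, 1, 0))
y <- denseToSparse(c(1, 0, 1, 1, 1))
ex <- explainKernelPair(x, y, kernelParams(sigma = 1))
ex
#> PairExplanation: I = 2, D = 2, kernel = 0.367879
#>   phi per intersecting feature:   0.25
#>   phi per sym-difference feature: -0.0660603
#>   sum of Shapley values: 0.367879
perFeature(ex)
#>           0           2           3           4
#>  0.25000000 -0.06606028  0.25000000 -0.06606028
```

The two features shared by `x` and `y` (positions 0 and 3) each contribute
`1/(I+D) = 0.25` to the kernel value; the two features present in only one
vector (positions 2 and 4) each contribute −0.0661. The four values sum to
`exp(-1) = 0.368`, the kernel value itself; position 1, inactive in both,
is a dummy player and is omitted (exactly zero).

Explaining a model prediction (a bundled toy model over 15 features):

```r
m <- readModelSpec(system.file("extdata", "toy_model.json", package = "rbfshapley"))
v <- readSparseVectors(system.file("extdata", "example_instances.txt",
                                   package = "rbfshapley"))[[1]]
explainSvmLogodds(m, v)
#> ModelExplanation: 14 features, distance = -0.306646 (bias -0.421048)
#>   logodds = -0.488168, probability = 0.380325, expected value = -0.572493
```

Per-feature log-odds values (`@perFeatureLogodds`) plus the expected value
reconstruct the logit to machine precision; their signs say which features
pushed this prediction toward or away from the positive class.
`extractModelSpec()` converts a fitted `e1071::svm` (RBF kernel,
`scale = FALSE`) into the same JSON-serialisable form, reproducing libsvm's
decision values and Platt probabilities.

A command-line interface is installed at
`system.file("cli", "rbfshapley", package = "rbfshapley")` with
subcommands `explain-pair` (with `--show-work` coalition tables),
`explain-model`, and `validate`.

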