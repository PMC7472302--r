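---
title: "Weighted evidential regression: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted evidential regression: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wevreg)
```

## The model

`wevreg` implements regression with Dempster–Shafer belief functions.  The
training set $L = \{(x_i, y_i)\}_{i=1}^n$ is treated as a collection of
*evidence* about the target value of a query $x$: each example supports the
hypothesis "$y$ is near $y_i$" with a strength that decays with the distance
between $x$ and $x_i$.  A final, distinguished piece of evidence is the
observed target *domain* $[y_{\inf}, y_{\sup}]$ itself, which absorbs
whatever belief the individual examples cannot claim — the model's own
ignorance.

Distances use a per-feature weighted Minkowski metric
$$d_w(x, x') = \Big(\sum_k |w_k\,(x_k - x'_k)|^p\Big)^{1/p}, \qquad
p \in [1, 2],$$
and are converted to similarities by a radial-basis discount
$\phi(d) = \exp(-d^2/\gamma)$.  Only the $k$ nearest neighbours $N(x)$ carry
evidence; all other examples contribute exactly zero mass, which reduces the
cost of a prediction from quadratic to roughly linear in $n$.  Combining the
discounted evidence by Dempster's rule gives, for $i \in N(x)$,
$$m_i(x) = \frac{1}{K}\,\phi_i \prod_{h \ne i} (1 - \phi_h), \qquad
m^*(x) = \frac{1}{K} \prod_{i} (1 - \phi_i),$$
with $K$ the normalization making all masses sum to one.  The Pignistic
transformation turns this belief structure into a point prediction and an
interval:
$$\hat y = \sum_i m_i y_i + m^* \tfrac{y_{\sup} + y_{\inf}}{2}, \qquad
[\hat y_* , \hat y^*] = \Big[\textstyle\sum_i m_i y_i + m^* y_{\inf},\;
\sum_i m_i y_i + m^* y_{\sup}\Big].$$
The interval width is exactly $m^* (y_{\sup} - y_{\inf})$: a query far from
all evidence gets $m^* \approx 1$ and an interval covering the whole observed
target range, a query on top of a training point gets a near-degenerate
interval.  This is the package's interpretability contract — `predict()`
always returns the bounds and the ignorance mass alongside the fit.

## Learning the feature weights

The weights $w$ are the second interpretability device: they are learned, not
set, and a feature's weight measures how much it contributes to finding
*relevant* neighbours.  Training minimizes the leave-one-out mean squared
error
$$L_w = \frac{1}{n} \sum_i (y_i - \hat y^{(-i)})^2,$$
where $\hat y^{(-i)}$ predicts row $i$ from the other $n - 1$ rows under the
current metric.  The gradient is computed analytically by chaining through
the Pignistic expectation, the mass combination, the discount kernel and the
metric; terms outside each row's neighbour set vanish.  Internally the
implementation uses the odds parameterization $r_i = \phi_i/(1-\phi_i)$,
under which $\hat y = (c + \sum_i r_i y_i)/(1 + \sum_i r_i)$ with $c$ the
domain midpoint — algebraically identical to the mass form, numerically
stabler, and with a compact derivative.  Each epoch:

1. recomputes all neighbour sets under the current weights (the metric has
   changed),
2. evaluates the LOO predictions and the loss,
3. takes one full-batch Adam step (moment decays 0.9/0.999, $\epsilon$ =
   1e-8; plain gradient descent available),
4. clips the weights at zero — the metric and the scaled-space k-NN search
   presuppose $w \ge 0$.

The returned weights are the state whose measured loss was smallest, not the
last state: the loop records the loss of the state it evaluated, so the
stored optimum and its loss always correspond to each other.  Training runs
a fixed number of epochs; the only early exit is a non-finite loss, which is
an error, not a convergence signal.

Weight-based feature selection (`rank_and_select()`) keeps features whose
weight exceeds 1, the common starting value: anything that *grew* under
training was worth separating neighbours by.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | 20 | evidence-set size.  Large enough to pool several neighbours' targets, small enough that a prediction costs $O(nq + k q)$ rather than $O(n^2 q)$. |
| `gamma` | grid-searched | discount radius (squared-distance units of the normalized space).  Selected from 10 log-spaced points in $[10^{-3}, 10]$ by LOO MAE at the all-ones weights; distances do not depend on $\gamma$, so the whole grid is scored from one distance matrix.  Held fixed while the weights are learned. |
| `alpha` | 0.1 | Adam learning rate. |
| `epochs` | 100 | fixed epoch budget; the best intermediate state is kept, so extra epochs cannot hurt the returned model. |
| `p` | 2 | Minkowski exponent, restricted to $[1, 2]$; values below 2 behave better under heavy distance concentration and can be chosen by validation-MAE grid over $\{1, 1.25, 1.5, 1.75, 2\}$ if desired. |
| `form` | `"exp_sq"` | discount variant.  Two closely related forms circulate, $\exp(-d^2/\gamma)$ and $\exp(-d/\gamma^2)$; the analytic weight-learning gradient implemented here is the derivative of the squared-distance form, so that form is the default and the raw-distance variant is offered as an alternative (its own consistent gradient is implemented too). |

Features are min–max normalized to $[0, 1]$ with training-set statistics —
without a common scale the weights would not be comparable across features —
and query values outside the training range are clipped into $[0, 1]$.

## The kernel baseline

`wknn()` is the ablation comparator: identical metric, neighbour search and
weight-learning loop, but the prediction is the kernel-weighted neighbour
mean $\sum_j y_j e^{-d_j/\beta} / Z$ — no mass combination, no ignorance
term.  Its kernel uses the raw distance (as that estimator is conventionally
written), while the evidential discount uses the squared distance; the two
are deliberately not unified.  The radius $\beta$ occupies the same
configuration slot as $\gamma$, and by default an unset $\beta$ is chosen by
the *evidential* grid criterion, so the baseline runs with the same
configuration the evidential model would use on the same data — the
benchmark's shared-configuration convention.  Tuning the kernel's own LOO
MAE instead (`gamma_rule = "kernel"`) systematically picks much smaller
radii: LOO favours a sharply local kernel, which then generalizes worse.

## Synthetic benchmarks

Two seedable generators emulate high-dimensional sparse tabular regression,
where a handful of features carry signal and hundreds are decoys:

* **`make_linear()`** — Gaussian design min–max normalized per column, 5 of
  $q$ features with nonzero Gaussian coefficients, additive output noise of
  sd 1.  The coefficient scale (`coef_sd = 100`) follows the magnitude
  convention of the standard random-linear-regression generator used in
  benchmark practice; with unit-scale coefficients the sd-1 output noise
  would swamp the signal entirely and no regressor could beat the mean
  predictor, contradicting the premise of a learnable benchmark.
* **`make_friedman()`** — all features uniform on $[0, 1]$, response
  $10\sin(\pi x_0 x_1) + 20(x_2 - 0.5)^2 + 10 x_3 + 5 x_4$ plus sd-1 noise;
  features beyond the first five are pure decoys.

Outputs are min–max scaled to $[0, 1]$ over the generated sample (the scaled
targets are what the error metrics are reported on), and the scaling is
shared across CV folds so fold errors are comparable.  The presets in
`synthetic_presets()` fix the study conditions: 200 or 5000 samples, 500
features, 5 relevant, noise sd 1.

What these generators do *not* emulate: mixed-type or categorical features,
missing values, heavy-tailed or zero-inflated targets, correlated feature
blocks, and concept drift — all typical of the administrative-claims data
this method family targets.  Passing the synthetic suite therefore
demonstrates the estimator's mechanics (mass calculus, gradient, feature
recovery), not clinical-data performance.

## Evaluation protocol

`repeated_kfold()` runs 5-fold cross-validation five times (25 validation
folds) with seeded shuffles and reports the median and standard deviation of
each metric across folds.  All model selection — the $\gamma$ grid and the
weight learning — happens inside each training fold; validation rows are
never touched before scoring.  Estimator failures on a fold are recorded in
the report and surfaced as warnings, never silently dropped.  The package's
own acceptance script and tests exercise the 200-sample presets, where the
full protocol runs in a few minutes on one CPU; the 5000-sample presets use
the same code path and are provided for larger experiments.

## Numerical choices

* The discount is capped at $1 - 10^{-12}$, so duplicated rows (distance 0)
  cannot drive $1 - \phi$ to zero and make the normalization $0/0$.
* Mass product sequences $\prod_{h \ne i}(1 - \phi_h)$ are computed with
  prefix/suffix products, never by dividing a total product; if the products
  underflow entirely, the computation switches to the equivalent odds form,
  which cannot underflow to an indeterminate state.
* Neighbour ties at equal distance are broken by ascending row index, making
  every search deterministic and reproducible.
* Leave-one-out target bounds $[\min y_{-i}, \max y_{-i}]$ are recomputed per
  left-out row, consistent with each row being predicted from the other
  $n - 1$ examples only.
* The LOO loss is piecewise smooth in $w$ — it kinks where a perturbation
  swaps a neighbour in or out.  The analytic gradient is the within-piece
  derivative; the test suite validates it against central finite differences
  at points verified to be differentiable (neighbour sets stable under the
  probe step), which is the standard way to gradient-check piecewise-smooth
  objectives.
* The interval identities (width $= m^*(y_{\sup}-y_{\inf})$, midpoint
  property) hold exactly in exact arithmetic; in floating point they are
  verified to $10^{-12}$ on the unit target scale, since subtracting
  near-equal bounds when $m^*$ underflows makes bit-exact equality
  unattainable.

## Known limitations

* Training cost is $O(n^2 q)$ per epoch (LOO distance matrix); the 5000-row
  presets are accordingly much slower to *train* than to predict.  Weight
  learning on very large sets calls for subsampling or mini-batch variants,
  which this package does not implement.
* With hundreds of irrelevant features the initial (all-ones) metric suffers
  distance concentration; the weight learning has to dig the signal out, and
  with far more decoys (beyond several hundred) it can fail to.
* MAPE is undefined for zero targets and refuses them explicitly.
* The domain interval $[y_{\inf}, y_{\sup}]$ is the *observed* target range;
  queries whose true value falls outside it cannot be covered by the
  prediction interval.
* $\gamma$ is selected once, at the all-ones weights, and not re-tuned as the
  metric evolves; learned weights can partially compensate (scaling all
  weights is equivalent to rescaling $\gamma$), but a joint search is not
  attempted.
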