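# wevreg — weighted evidential regression

`wevreg` is an R package for regression with **Dempster–Shafer belief
functions**, aimed at tabular prediction problems — the motivating
application is forecasting individual healthcare costs from claims
histories — where a point estimate alone is not enough: users need to know
*how much evidence* backs each prediction, and *which features* the model
considered relevant.

Each training example $(x_i, y_i)$ is a piece of evidence about a query's
target.  Evidence strength decays with the weighted distance
$d_w(x, x_i) = (\sum_k |w_k (x_k - x_{ik})|^p)^{1/p}$ through a
radial-basis discount $\phi = \exp(-d^2/\gamma)$, and the $k$ nearest
neighbours' evidence is pooled by Dempster's rule into masses $m_i$ plus a
**domain mass** $m^*$ — the belief left to the whole observed target range
$[y_{\inf}, y_{\sup}]$, i.e. the model's ignorance.  The Pignistic
expectation gives the prediction and its bounds:

$$\hat y = \sum_i m_i y_i + m^*\,\frac{y_{\sup}+y_{\inf}}{2},
\qquad \hat y^{*} - \hat y_{*} = m^* (y_{\sup} - y_{\inf}).$$

The per-feature weights $w$ are learned by gradient descent (Adam) on the
leave-one-out MSE with an analytic gradient, so after fitting they rank the
features by how much each one contributed to finding relevant neighbours;
features whose weight exceeds the starting value 1 form an embedded feature
selection.  A weighted k-NN kernel regressor (`wknn()`) with the identical
metric and training loop is included as the ablation baseline, plus seedable
synthetic benchmark generators and a repeated k-fold evaluation harness.

## Worked example

Fit on a 200-row Friedman benchmark with 50 features, only 5 of which enter
the response:

```r
library(wevreg)

d <- generate_synthetic(synthetic_spec("friedman", 200, 50, seed = 1))
model <- wevreg(d$x, d$y, k = 20, alpha = 0.1, epochs = 100)
model
#> Weighted evidential regression model: 200 examples, 50 features
#>   k = 20, gamma = 10, p = 2, learned weights (best loss 0.007422 at epoch 40)
```

Predictions come with bounds and the ignorance mass; the interval is wide
exactly when the training set has little to say about a query:

```r
set.seed(42)
xnew <- matrix(runif(3 * 50), 3, 50, dimnames = list(NULL, colnames(d$x)))
predict(model, xnew)
#>     fit   lwr   upr uncertainty
#> 1 0.803 0.801 0.806     0.00543
#> 2 0.628 0.625 0.632     0.00633
#> 3 0.573 0.571 0.575     0.00446
```

The learned weights recover the five relevant features and zero out the 45
decoys; `rank_and_select()` applies the weight-above-1 selection rule:

```r
rank_and_select(model)
#> feature_ranking: 5 of 50 features above threshold 1
#>  feature   weight selected
#>       f2 3.380734     TRUE
#>       f3 2.995428     TRUE
#>       f1 2.719091     TRUE
#>       f0 2.454207     TRUE
#>       f4 1.938959     TRUE
#>       f5 0.000000    FALSE
#> ...
```

Cross-validated performance under the standard protocol (5-fold, repeated
five times; median ± sd across the 25 validation folds):

```r
repeated_kfold(d$x, d$y, "wevreg", folds = 5, repetitions = 5, seed = 1,
               k = 20, alpha = 0.1, epochs = 100)
#> Repeated 5-fold cross-validation, 5 repetition(s) (wevreg, seed 1)
#>   mae        median 0.0711  (sd 0.0106)
#>   r_squared  median 0.7889  (sd 0.0535)
```

An MAE of 0.071 is on the min–max-scaled target, i.e. about 7% of the
observed target range; R² ≈ 0.79 says the evidential predictions track most
of the target variance despite the 45 decoy features.

A command-line front-end wrapping these functions (generate / fit / predict
/ evaluate / select-features / benchmark) lives at `inst/cli/wevreg.R`.

## Further reading

The methods vignette
(`vignettes/weighted-evidential-regression.Rmd`) documents the model and its
assumptions, the training procedure, every tunable parameter, the numerical
safeguards, and what the synthetic benchmarks do and do not demonstrate.
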