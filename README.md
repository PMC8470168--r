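# fiberknn

Predicting the dietary fiber content of packaged foods from their
nutrition information panel.

## The problem

Fiber labeling is voluntary on packaged foods in most countries, so
roughly half of all products print no fiber value — which makes it hard
for consumers to pick high-fiber products and for policy makers to
monitor fiber in the packaged food supply. What *is* nearly always
printed are six nutrients: total sugar, carbohydrate, protein, saturated
fat, total fat, and sodium. Products with similar nutrient panels tend
to have similar ingredient profiles, and hence similar fiber content.
`fiberknn` turns that observation into an automated imputation method
for nutrition researchers and food-supply monitors.

## The method

Each product is represented by six mutually exclusive nutrient features
per 100 g or 100 mL: total sugar, starch (carbohydrate − sugar),
protein, saturated fat, unsaturated fat (total − saturated fat), and
sodium. Features are min–max normalized with training-set extrema,
`X' = (X − X_min)/(X_max − X_min)`. The distance between products x and
y is the Manhattan distance

```
d(x, y) = Σ_{i=1..6} |x'_i − y'_i|
```

and a query's fiber is the inverse-distance weighted average of its
k = 8 nearest neighbors *within the query's own food category*:

```
Q = Σ_j w_j q_j / Σ_j w_j ,   w_j = 1/d_j
```

where `q_j` is the j-th closest product's labeled fiber. Hyperparameters
(k, metric, weighting) are chosen by five-fold cross-validated R² on the
training set. Because brands cluster near-identical formulations, the
train/test split allocates whole brands, never individual products. The
distance to the first neighbor, `d1`, serves as a confidence proxy:
predictions with `d1 > 0.08` are flagged for cautious interpretation.
Predicted fiber can also be banded into the Health-Star-Rating density
classes (negligible < 0.9, low < 3.7, medium < 7.3, high ≥ 7.3 g per
100 g/mL).

A synthetic packaged-food-supply generator with known ground truth
(Dirichlet compositions per category, log-normal sodium, a linear
fiber relation with controllable noise, brand clustering, and logistic
fiber-reporting masking biased toward high-fiber products) makes the
entire pipeline testable without any proprietary data.

## Worked example

```r
library(fiberknn)

## simulate a small packaged-food supply with known ground truth
sim <- generate_supply(supply_spec(make_default_profiles(5),
                                   n_per_category = 400, seed = 2024))
supply <- sim$observed

## keep the fiber-reporting products, split by brand, fit, evaluate
reporters <- supply[!is.na(supply$fiber), ]
sp <- brand_grouped_split(reporters, seed = 2024)
model <- fit_fiber_knn(sp$train)
preds <- predict(model, sp$test)
metrics_report(sp$test$fiber, preds$predicted_fiber)
#> <metrics_report> overall (n = 274)
#>   R2 = 0.978  MAE = 0.439 g  rho = 0.968
#>   density classification accuracy = 0.828
```

R² = 0.978 says the model explains ~98% of the fiber variance on
held-out brands of this (low-noise, synthetic) supply; MAE is the mean
absolute prediction error in grams per 100 g/mL. Every prediction is
explainable by the neighbors that produced it:

```r
explain(preds, "SYN000004")
#> prediction for SYN000004: 10.67 g fiber per 100 g/mL (d1 = 0.2245, CAUTION: distant neighbor)
#>  neighbor_id    category distance weight_share  fiber exact_match
#>    SYN000312 cereal_like   0.2245       0.1788 11.487       FALSE
#>    SYN000037 cereal_like   0.3206       0.1252  9.909       FALSE
#>    ...
```

Supply-level monitoring pools reported and predicted values and
quantifies reporting bias:

```r
summ <- supply_summary(supply, model)
summ[summ$category %in% c("cereal_like", "juice_like", "Total"),
     c("category", "n_total", "pct_reporting", "median_reported",
       "median_predicted", "median_all")]
#>     category n_total pct_reporting median_reported median_predicted median_all
#>  cereal_like     400          91.2          10.057            9.895     10.014
#>   juice_like     400          31.2           0.586            0.572      0.578
#>        Total    2000          54.0           4.212            1.227      3.619
attr(summ, "comparison")$p_value
#> [1] 2.776831e-68
```

Products that report fiber are markedly higher in fiber than those that
do not (rank-sum p ≪ 0.001) — exactly the reporting bias the masking
model generates.

## Command line

The same workflow is scriptable via the bundled launcher:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fiberknn.R", package = "fiberknn"))')
Rscript $CLI simulate --out supply.csv --n-per-category 200 --seed 7
Rscript $CLI clean    --input supply.csv --out clean.csv --log exclusions.json
Rscript $CLI split    --input clean.csv --train-out train.csv --test-out test.csv --seed 7
Rscript $CLI fit      --input train.csv --model-out model.json
Rscript $CLI predict  --input test.csv --model model.json --out predictions.csv
Rscript $CLI evaluate --input test.csv --model model.json --out metrics.json
Rscript $CLI summarize --input clean.csv --model model.json --out summary.csv
```

Commands: `simulate | clean | split | tune | fit | predict | evaluate |
summarize`. Options may come from a JSON config file (`--config`); a
flag beats the file, the file beats the built-in default. Every output
carries `#` metadata headers (tool version, command, seed, input
digests).

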