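# nirselect

Wrapper feature selection for near-infrared (NIR) spectral classification:
a genetic algorithm (GA) picks the principal components (PCs) that make a
support vector machine (SVM) classify best, instead of simply taking the
top-variance components.

## The problem

NIR absorbance spectra (here: 2084 points spanning 12,000 to 3499 cm⁻¹,
with the hydrogen-group absorption bands near 4004, 4313, 4727 and
5163 cm⁻¹) are far wider than the number of samples a lab can collect, so
classification pipelines first compress them with PCA and then feed a
fixed number *k* of PC scores to a classifier. The usual habit is to take
the first *k* PCs — the ones with the largest eigenvalues ("most
information"). But variance is not discriminative power: components low
on the variance ladder can separate classes that the top components
cannot. `nirselect` implements the full workflow that makes this
observable and exploitable:

1. **Savitzky–Golay de-noising** — sliding least-squares polynomial
   smoothing (default: quadratic, 121-point window);
2. **Mahalanobis-distance outlier removal** — distance of each spectrum
   to the mean spectrum in a shrunk PC-score covariance, χ²-quantile
   threshold;
3. **PCA** by eigendecomposition of the covariance matrix, keeping the
   top 25 PCs as candidates;
4. **GA wrapper selection** of a fixed-cardinality PC subset: binary
   masks with exactly *k* ones evolve by fitness-proportionate (roulette)
   selection, one-point crossover and uniform mutation with a cardinality
   repair, under elitism; the fitness of a mask is the stratified
   *m*-fold cross-validated prediction accuracy of the classifier trained
   on the selected score columns;
5. **Binary-decision-tree multiclass SVM**: the class set is split
   recursively into two groups (2-means on class-mean scores, or listed
   order), one soft-margin RBF-kernel SVM per internal node, trained by a
   sequential-minimal-optimisation (SMO) dual solver written in C++;
6. **Evaluation** with the four per-class criteria — sensitivity
   γ_TP = n_TP/(n_TP+n_FN), specificity γ_TN = n_TN/(n_TN+n_FP),
   precision γ_PP = n_TP/(n_TP+n_FP), F1 γ = 2n_TP/(2n_TP+n_FP+n_FN) —
   plus overall prediction accuracy P_a = n_r/N_t, an 80/20 stratified
   train/test split, and grid search with 5-fold CV for the SVM pair
   (C, σ).

The binary SVM solves the dual

    min_α  ½ Σᵢⱼ αᵢαⱼyᵢyⱼK(xᵢ,xⱼ) − Σᵢ αᵢ
    s.t.   Σᵢ αᵢyᵢ = 0,  0 ≤ αᵢ ≤ C,       K(x,y) = exp(−‖x−y‖²/2σ²)

and predicts by the sign of g(x) = Σᵢ αᵢyᵢK(xᵢ,x) + b.

Because no public NIR dataset accompanies this workflow, the package
ships a **synthetic spectra generator** (`generate_spectra()`) that
emulates a four-region tobacco-leaf dataset: 38/144/70/80 samples per
class (332 total), smooth orthonormal latent directions on a known
variance ladder, class signal planted only in designated variance ranks
(by default 1, 6, 7, 8, 10, 11 — mostly *low*-information components),
plus baseline drift and detector noise. Ground truth is returned with
the data, so every pipeline stage is testable end to end.

## Worked example

```r
library(nirselect)

gen <- generate_spectra(synthetic_config(seed = 7))   # 332 x 2084 spectra
smoothed <- sg_smooth(gen$spectra)                    # SG, quadratic, 121
cleaned  <- remove_outliers(smoothed, n_components = 25)
pca    <- fit_pca(cleaned$spectra, k = 25)
scores <- transform_spectra(cleaned$spectra, pca)

split <- split_train_test(scores$labels, seed = 7)    # stratified 80/20
train <- score_set(scores$scores[split$train, ],
                   scores$labels[split$train], model = pca)

fit <- ga_svm(train, k = 6, params = svm_params(C = 2, sigma = 2),
              ga = ga_config(k = 6, pop_size = 40, max_generations = 30,
                             stagnation_limit = 12, seed = 7))
fit
#> GA-SVM classifier
#>   selected 6 of 25 PCs: 1, 5, 6, 7, 11, 24
#>   mask: 1000111000100000000000010
#>   CV accuracy (fitness): 0.928 after 26 generations
#>   information (explained variance) of selection: 42.8%
#>   SVM: C = 2, sigma = 2, 4 classes

pred <- predict(fit, scores$scores[split$test, ])
metrics(confusion(scores$labels[split$test], pred))
#>    class sensitivity specificity precision    f1
#> 1 class1       0.857       1.000     1.000 0.923
#> 2 class2       0.931       0.973     0.964 0.947
#> 3 class3       1.000       0.942     0.824 0.903
#> 4 class4       0.875       0.980     0.933 0.903
#> overall prediction accuracy: 0.924
```

The GA keeps PC 1 but otherwise reaches deep into the ladder (PCs 11 and
24); its six components carry only 42.8% of the spectral variance yet hit
92.4% test accuracy, while the first six PCs — 75.5% of the variance —
reach only 72.7% on the same split. `plot(fit)` draws the best/mean
fitness trace; `summary(fit)`, `coef(fit)` and `mask_string(fit$mask)`
expose the selection. `run_pipeline()` sweeps several subset sizes
(default 6–16) and writes the mask matrix, accuracy-by-k table and
per-class metrics as CSV; `sweep_ga_hyperparams()` produces fitness
traces across population sizes or operator rates. A thin command-line
wrapper lives at `inst/cli/nirselect.R`:

```sh
Rscript inst/cli/nirselect.R synth --seed 7 --out spectra.csv
Rscript inst/cli/nirselect.R run --input spectra.csv --out-dir results
```

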