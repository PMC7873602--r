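# renotex

CT-radiomics pipeline for predicting the pathological grade of clear cell
renal cell carcinoma (ccRCC) — the most common renal cancer — from a single
pre-contrast axial CT slice. The package is aimed at imaging researchers who
want a fully reproducible, testable implementation of the classic
texture-radiomics workflow: gray-level discretization, MaZda-style texture
features, intraclass-correlation reproducibility screening, and a
hierarchical stacked classifier, evaluated with ROC analysis. Because the
original patient images of the motivating study are not deposited, the
package ships a calibrated synthetic tumor-phantom generator that emulates
the published cohort (264 patients: 206 ISUP I–II "low grade", 58 ISUP
III–IV "high grade") so the whole chain can be exercised end to end.

## The method

Two blocks of per-patient features are combined:

* **Traditional radiological characteristics** — tri-axial tumor size,
  pre-contrast density CTpre (HU), nephrographic density CTpost, the
  enhancement CTpost − CTpre, and T stage.
* **Radiomic texture features** — 340 features from six families computed on
  the tumor ROI after μ ± 3σ windowing to 256 gray levels: histogram (11),
  gradient (5), autoregressive model (5), gray-level co-occurrence matrix
  (11 Haralick features × 4 directions × 5 distances, plus direction
  averages = 275), run-length matrix (20), and Haar wavelet subband
  energies (24).

Each block is reduced by an L1-penalized logistic model (LASSO; its linear
predictor is the block signature, the *Rad-score* for texture) and a random
forest on the selected features; a linear SVM fuses the two scores per block
(SVM1 = texture, SVM2 = traditional), and a second-level SVM (SVM3) fuses
the two block scores into the final grade score, binarized at the
Youden-optimal training threshold:

    texture X ──► LASSO (score 1) ─┐
                                   ├─► SVM1 (score 3) ─┐
    texture X ──► RF    (score 2) ─┘                   │
                                                       ├─► SVM3 (score 7) ─► call
    tradit. X ──► LASSO (score 4) ─┐                   │
                                   ├─► SVM2 (score 6) ─┘
    tradit. X ──► RF    (score 5) ─┘

Reader reproducibility of the features is quantified with ICC(2,1) from the
two-way ANOVA decomposition, banded poor/fair/moderate/good/excellent.

## Worked example

```r
library(renotex)

co          <- generate_cohort(n_low = 60, n_high = 20, seed = 42)
texture     <- extract_texture_features(co)         # 80 x 341 tibble
traditional <- extract_traditional_features(co, seed = 42)
split       <- split_cohort(co, seed = 42)          # stratified 3:1
tr          <- split$cohort == "training"

model <- fit_stacked_classifier(texture[tr, ], traditional[tr, ],
                                split$grade[tr], seed = 42)
model
#> <stacked_model> 60 training patients (15 high grade)
#>   texture block: 2 LASSO-selected features; traditional block: 5
#>   threshold (Youden, training Score 7): 1.0001

tidy(model)
#> # A tibble: 9 x 3
#>   block       term               estimate
#> 1 texture     (Intercept)          -3.18
#> 2 texture     grad.GrKurtosis       3.53
#> 3 texture     ar.Sigma              1.48
#> 4 traditional (Intercept)          -2.34
#> 5 traditional transverse_cm         1.49
#> ...
```

The texture signature picked up gradient kurtosis and the autoregressive
residual SD — heterogeneity measures, exactly the kind of feature the
phantoms encode grade with — while the traditional signature uses sizes and
CTpre. Scoring the held-out validation patients:

```r
pred  <- predict(model, texture[!tr, ], traditional[!tr, ],
                 patient_id = split$patient_id[!tr])
y_val <- split$grade[!tr]
auc_ci(pred$score7, y_val, B = 2000, seed = 1)
```

```
score3 (texture,  SVM1): AUC 1.0000 (95% CI 1.0000-1.0000)
score6 (tradit.,  SVM2): AUC 0.7600 (95% CI 0.5067-0.9600)
score7 (combined, SVM3): AUC 1.0000 (95% CI 1.0000-1.0000)
```

On synthetic phantoms the texture signal is deliberately strong, so the
combined model (SVM3) matches or beats the better block — the qualitative
ordering reported for the real cohort, where the combined model reached AUC
0.92/0.91 (training/validation). `autoplot(roc_points(pred$score7, y_val))`
draws the ROC curve; `run_end_to_end(run_config(...))` executes the whole
simulate → extract → reliability → train → evaluate chain with CSV/JSON
handoff and a checksum manifest.

## Package layout

* `R/cohort.R` — phantom generator, cohort assembly, split, mask perturbation
* `R/imaging.R` — discretization, slice selection, traditional measurements
* `R/texture.R`, `R/registry.R` — the six feature families and the pinned
  340-feature manifest (`inst/extdata/registry_340.json`)
* `R/reliability.R` — ICC(2,1)/ICC(3,1), bands, reproducibility report
* `R/modeling.R` — standardization, LASSO, RF, SVM fusions, stacked model,
  `tidy()`/`glance()` methods
* `R/evaluation.R` — AUC/ROC, bootstrap and DeLong CIs, threshold metrics,
  group tests, correlation matrix
* `R/pipeline.R` — staged end-to-end runner with manifest checksums
* `vignettes/renotex-methods.Rmd` — the full methods account: model
  assumptions, parameter defaults and units, numerical conventions, design
  choices, limitations
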