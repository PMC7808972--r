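# ramandx

Chemometric diagnostics for Raman microspectroscopy of biofluids.

Dried-drop Raman maps of biofluids (blood plasma, serum, ascitic
fluid) carry spectral fingerprints that separate ovarian-cancer
patients from benign controls. `ramandx` implements the full analysis
chain used for that kind of study:

* a **synthetic hyperspectral cohort generator** (Lorentzian band
  models, fluorescence baselines, per-spectrum gain, patient random
  effects, cosmic-ray spikes) with planted ground truth, so the whole
  chain is testable without patient data;
* **raw-map reduction**: unfolding, 10-spectrum block averaging,
  running-median spike removal;
* the three standard **preprocessing chains**: Savitzky–Golay
  smoothing + AWLS baseline correction + vector normalisation;
  SG + EMSC + AWLS; SG + first derivative;
* **PCA** and **NIPALS PLS** factor models;
* four **discriminant classifiers** on PCA scores or full spectra:
  PCA-LDA, PCA-QDA, PCA-SVM (RBF), PLS-DA;
* a leakage-safe **10-fold cross-validation** harness reporting, with
  case as the positive class (percentages),

  Accuracy = (TP+TN)/(TP+FP+TN+FN), Sensitivity = TP/(TP+FN),
  Specificity = TN/(TN+FP), F-score = 2·SENS·SPEC/(SENS+SPEC)

  (the sensitivity/specificity harmonic mean, not precision/recall F1);
* **biomarker identification** by matching peaks of the
  difference-between-mean (DBM) spectrum, case mean − control mean,
  against peaks of the PC1 loadings, with per-wavenumber ANOVA
  p-values and Wilks MANOVA on 3-D score plots.

## Worked example

Simulate the default cohort (18 case / 20 control patients, one
23 × 15 map each, 725–1813 cm⁻¹), reduce it, cross-validate PCA-LDA on
the EMSC + baseline chain, and identify biomarkers:

```r
library(ramandx)

cohort <- simulate_cohort(cohort_config(seed = 1))
sm <- remove_spikes(block_average(unfold_cohort(cohort), 10))

report <- cross_validate(sm, models = "pca_lda",
                         pipeline = "emsc_baseline", k = 10, seed = 1)
print(report)
#> Confusion counts: TP = 630  TN = 700  FP = 0  FN = 0 
#> Accuracy 100.0%  Sensitivity 100.0%  Specificity 100.0%  F-score 100.0%
#> Model: pca_lda  pipeline: emsc_baseline  k = 10  seed = 1 

pre <- apply_pipeline(sm, "emsc_baseline")
print(coincident_biomarkers(pre), digits = 3)
#>   wavenumber                 assignment     direction   p_value p_bonferroni
#> 1       1004   Phenylalanine (collagen) lower_in_case 2.23e-308    2.42e-305
#> 2       1334  CH3CH2 wagging (collagen) lower_in_case 2.23e-308    2.42e-305
#> 3       1448 CH2 deformation (collagen) lower_in_case 2.23e-308    2.42e-305
#> 4       1657         Amide I (collagen) lower_in_case 2.23e-308    2.42e-305
#>   dbm_magnitude loading_magnitude
#> 1        0.0867             0.121
#> 2        0.0967             0.138
#> 3        0.0978             0.140
#> 4        0.0940             0.135
```

The classifier separates the simulated classes perfectly (the planted
15% band attenuation is an easy target at 1330 pooled spectra), and
the DBM + PC1 coincidence rule returns exactly the four planted
collagen-associated bands, all with lower intensity in the case class
and ANOVA p ≪ 0.001 (underflowing p-values are reported at the
smallest representable double, an upper bound). `run_experiment()` drives the full grid
(3 pipelines × 4 models) and writes per-combination JSON reports, a
summary CSV and a biomarker table into a self-describing run
directory.

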