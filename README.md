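# earasym

Objective assessment of facial-paralysis severity in the eye region from
68-point facial landmark sequences.

Unilateral facial palsy attenuates voluntary movement on one side of the
face. Clinicians grade it with the Facial Nerve Grading Scale 2.0
(FNGS 2.0), scoring each facial region 1 (normal) to 6 (no movement) by
eye — slow and partly subjective. `earasym` replaces the visual judgement
for the eye region with a measurement: during an eye open–close task it
computes, per frame and per eye, an **amplified eye aspect ratio**

```
EAR_L,t = (||LM37 − LM41|| + ||LM38 − LM40||) / (2 ||LM36 − LM39||)
          × ||LM19 − LM33|| / ||LM27 − LM33||
```

(0-based iBUG landmark indices; the second factor — brow-to-nose-tip
distance over nose length — amplifies the bilateral contrast, since brow
motion is also asymmetric in palsy while the nose barely moves), and then
quantifies the **bilateral EAR difference** as the discrete Fréchet
distance between the left- and right-eye EAR curves: the minimum over
monotone traversals of both curves of the maximum pointwise gap. Larger
values mean more asymmetric eye movement; a nearest-class-median
classifier maps the value to an FNGS 2.0 eye score.

The package also provides

* in-plane tilt correction and the C/d face normalization frame,
* a trainable cascaded ensemble-of-regression-trees (ERT) landmark
  detector (`S^{t+1} = S^t + r_t(I, S^t)`, gradient-boosted trees on
  shape-indexed pixel-difference features) with NME evaluation,
  augmentation, hyperparameter grid search and incorrect-detection
  flagging,
* FNGS 2.0 bookkeeping (region scores → totals → grades I–VI), exclusion
  accounting, per-score medians, correlation and k-fold cross-validation,
* a seeded synthetic-patient generator (grade-dependent eyelid
  asymmetry, head sway, landmark jitter) and a procedural face renderer,
  so the entire pipeline is testable without clinical data.

## Worked example

```r
library(earasym)

# a synthetic patient: FNGS 2.0 eye score 4, affected left eye
pat <- simulate_patient(patient_config(grade = 4, affected_side = "left",
                                       seed = 42))
ec <- ear_curves(pat$sequence)          # tilt-corrects, then per-frame EAR
round(ec$left[1:5], 3)
#> [1] 0.569 0.545 0.501 0.526 0.503
round(ec$right[1:5], 3)
#> [1] 0.516 0.509 0.505 0.515 0.470
frechet_distance(ec$left, ec$right)     # bilateral EAR difference
#> [1] 0.3329122
```

The left (affected) eye stays near its open-eye EAR of ~0.55 while the
healthy right eye sweeps down to 0 at peak closure mid-sequence; the
Fréchet distance 0.33 summarizes that divergence. At cohort scale:

```r
cohort <- generate_cohort(15, base_seed = 1)   # 15 patients per score
report <- run_pipeline(cohort)
report
#> earasym pipeline report
#>   subjects: 90 ( 0 excluded )
#>   median bilateral EAR difference by eye score:
#>      1      2      3      4      5      6
#> 0.0381 0.0785 0.2131 0.3330 0.4369 0.4815
#>   correlation (EAR difference vs score): 0.9859
#>   10-fold CV accuracy: 0.9444
```

Median asymmetry rises strictly with the simulated eye score, the scalar
feature correlates with the score at r ≈ 0.99, and 10-fold
cross-validated nearest-median classification recovers the exact 6-class
score for ~94 % of subjects — on synthetic data whose generative model is
described in `vignettes/earasym-methods.Rmd`, along with what it does and
does not say about clinical data.

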