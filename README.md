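# dmnclass

Task-induced deactivation and default-mode-network (DMN) connectivity
analysis for blocked-design fMRI, with leave-one-out classification of
group membership — an R implementation of the classic
pseudo-resting-state workflow:

1. **Rest extraction** — excise fixation blocks from blocked runs,
   trimming the first 6 s of each rest block (hemodynamic return to
   baseline) and, for short (15-s) rest designs, appending the first 6 s
   of the following task block; concatenate into one per-subject series.
2. **Cleaning** — regress out six motion parameters, mean motion,
   gray/white/CSF/whole-brain means and per-session linear trends;
   optional Gaussian smoothing.
3. **Deactivation GLM** — HRF-convolved boxcar regression, rest-vs-task
   contrasts, random-effects group t tests, Benjamini–Hochberg FDR and
   Monte-Carlo cluster-extent thresholding.
4. **Connectivity** — seed-to-voxel Pearson r with Fisher z = atanh(r),
   a 3-seed averaged DMN map per subject (MPFC −1, 47, −4; PCC/PrC −5,
   −49, 40; left AG −45, −67, 36), and a 102-ROI z matrix (116-label
   atlas minus 14 exclusions; 102·101/2 = 5151 features).
5. **Classification** — leave-one-out L2 logistic regression on the
   connectivity features, sensitivity/specificity, exact binomial
   significance P(X ≥ k), X ~ B(n, p), and the top-0.5% most informative
   connections per class.

No scan data ship with the package: a **synthetic cohort generator**
builds a 13 + 14 two-group cohort (three blocked runs per subject, TR =
1 s, 17 rest blocks, 285 retained rest volumes) with a planted MPFC
connectivity deficit and attenuated DMN deactivation, so every stage is
testable offline.

## Worked example

```r
library(dmnclass)

# published-style per-group counts: 10/13 and 11/14 correct
pf <- data.frame(truth     = c(rep("asd", 13), rep("control", 14)),
                 predicted = c(rep("asd", 10), rep("control", 3),
                               rep("control", 11), rep("asd", 3)))
100 * sum(pf$predicted == pf$truth) / nrow(pf)   # 77.77778  -> 77.78%
compute_metrics(pf, "asd")
#> sensitivity specificity
#>   0.7692308   0.7857143                         -> 76.9% / 78.6%
binomial_significance(21, 27, 0.5)
#> [1] 0.002962306

# full pipeline on the synthetic cohort (roi mode, ~3 s)
res <- run_pipeline(pipeline_config(list(seed = 7)))
print(res)
#> LOOCV logistic regression: 27/27 correct (100.00%), sens 100.0%,
#>   spec 100.0%, binomial p = 7.451e-09
#> group MPFC-PCC z: t(25) = -7.97, p = 2.494e-08
```

The accuracy line reports the leave-one-out tally over all 27 synthetic
subjects and its exact binomial tail probability against chance 0.5; the
group line is the pooled two-sample t on per-subject MPFC–PCC Fisher z,
negative because the clinical-like group's planted coupling is weaker.
(At the default planted effect of 0.3 the synthetic cohort separates
more cleanly than real cohorts do.)

A command-line front end mirrors the stages
(`synthesize | demo | classify | connectivity`):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/dmnclass.R", package="dmnclass"))')" \
    demo --seed 7 --out demo_out
```

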