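# dyadsync

Dyadic inter-subject trajectory similarity (ISTS) of multi-voxel fMRI
patterns, with ordered-state HMM event segmentation and PLS-based
inference — an analysis pipeline for asking whether two people who share a
relationship also share the *trajectory* of their neural pattern states,
and whether that similarity tracks an outcome such as marital
satisfaction.

## The method

For one subject and one region of interest (ROI), the multi-voxel pattern
(MVP) at TR *t* is the vector of voxel activities *x<sub>t</sub>*. The
**pattern trajectory matrix** is the T × T matrix of Pearson correlations
M<sub>ij</sub> = corr(*x<sub>i</sub>*, *x<sub>j</sub>*): a description of
how the spatial response pattern evolves over time, invariant to overall
response amplitude. **ISTS** for a dyad is the Pearson correlation between
the two subjects' vectorized (strict upper-triangle) trajectory matrices.
The pipeline around it:

- **Null dyads** — a seeded derangement of wives against husbands (no one
  paired with their own spouse, no reuse) provides the random-pair class;
  **ISTS-Z** z-scores each ROI's ISTS across all dyad classes pooled.
- **Event segmentation** — an HMM whose K states are visited strictly in
  order (stay or advance, never return), isotropic Gaussian emissions on
  per-TR z-scored network patterns, fitted by exact EM; the number of
  events is selected by nested cross-validation on held-out
  log-likelihood.
- **Within-event ISTS** — trajectory similarity recomputed inside each
  event window (or movie clip), averaged across windows.
- **Inference** — whole-brain ANOVA / Welch t contrasts with Cohen's d;
  PLS-1 (the ROI-weight vector maximising covariance between weighted
  ISTS and satisfaction) with a 5,000-shuffle permutation test, 500
  bootstrap resamples for per-ROI z values, and Benjamini–Hochberg FDR.

A synthetic-cohort generator with known couple coupling *c*, known event
boundaries and satisfaction scores tied to coupling gives every stage a
ground truth; see the methods vignette
(`vignettes/dyadic-trajectory-similarity.Rmd`) for the generative model
and all modelling choices.

## Worked example

```r
library(dyadsync)

cfg <- synthetic_config(n_couples = 30, n_rois = 20, voxels_per_roi = 50,
                        n_trs = 100, n_events = 5,
                        coupling = seq(0.2, 0.8, length.out = 30),
                        satisfaction_slope = 10, satisfaction_noise_sd = 2,
                        seed = 70001)
sim <- generate_dyad_timeseries(cfg)

ists <- compute_ists_table(sim$dataset)
wb   <- whole_brain_average(ists)
y    <- sim$dataset$dyads$cmqi_score
cor(wb$mean_ists, y)
#> [1] 0.9768316
pls_permutation_test(ists$values, y, n_perm = 500, seed = 70001)$p_value
#> [1] 0.001996008
```

The whole-brain ISTS of each couple (mean over the 20 ROIs) correlates at
r ≈ 0.98 with the generated satisfaction score — coupling drives both, and
at this signal strength the pipeline recovers the link almost perfectly —
and the PLS-1 permutation p sits at the floor 1/(1+500) for 500 shuffles.
Segmenting the default-mode network into events and recomputing ISTS
within events then separates the satisfaction groups:

```r
dmn <- lapply(sim$dataset$subjects, function(s)
  network_features(sim$dataset, s, network = "DMN", level = "voxel"))
seg <- fit_event_hmm(average_subjects(dmn), K = 5)
wit <- within_event_ists_table(sim$dataset, build_event_windows(seg))
wwb <- whole_brain_average(wit)$mean_ists
cls <- sim$dataset$dyads$dyad_class
t.test(wwb[cls == "couple_high"], wwb[cls == "couple_low"])$statistic
#>        t 
#> 9.244374
```

The numbered scripts under `analysis/` run the same pipeline as a
five-stage narrative (simulate → ISTS → events → within-event → stats),
writing tables under `results/`.

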