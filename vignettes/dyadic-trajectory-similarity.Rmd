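---
title: "Dyadic trajectory similarity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic trajectory similarity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

# Overview

`dyadsync` implements a pipeline for relating the similarity of two
people's *multi-voxel pattern trajectories* to an outcome measured on the
dyad — the motivating application being married couples watching the same
naturalistic movie in the scanner, with marital satisfaction (a CMQI score,
threshold 60 for the high/low split) as the outcome. The pipeline has five
stages, each exposed as package functions and driven end-to-end by the
scripts under `analysis/`:

1. **Trajectory matrices.** For one subject and one region of interest
   (ROI), the multi-voxel pattern (MVP) at TR $t$ is the vector of voxel
   activities $x_t \in \mathbb{R}^V$. The pattern trajectory matrix is
   $M_{ij} = \mathrm{corr}(x_i, x_j)$, a $T \times T$ Pearson correlation
   matrix describing how the spatial response pattern evolves.
2. **ISTS.** Inter-subject trajectory similarity for a dyad is the Pearson
   correlation between the two subjects' vectorized trajectory matrices.
3. **Event segmentation.** An ordered-state hidden Markov model partitions
   network activity into a sequence of stable patterns ("events").
4. **Within-event ISTS.** Trajectory similarity recomputed inside each
   event window, then averaged.
5. **Inference.** Group contrasts (couples vs derangement-based random
   pairs; high vs low satisfaction), and a regional PLS-1 analysis with
   permutation and bootstrap inference.

# The similarity measure

## Vectorization

The trajectory matrix is symmetric with unit diagonal, so ISTS correlates
the **strict upper triangles** only. Including the diagonal would add $T$
constant 1s to both vectors and inflate every similarity toward 1;
including the lower triangle would double-count every entry without
changing the correlation. Entries are dropped pairwise-complete when a TR
had to be masked (see below).

## Degenerate patterns

A TR whose MVP is constant across voxels has no defined pattern
correlation. Such TRs have their trajectory row/column set to missing with
a warning rather than failing the whole ROI; fewer than 3 usable TRs is an
error. The same rule yields a missing ISTS (with a warning) when fewer
than 3 valid paired entries survive.

## Random pairs

The null class is a **derangement** of wives against husbands: every male
is paired with exactly one female who is not his wife, and no female is
reused. Sampling is by seeded rejection of uniform permutations, which is
exact (every derangement equally likely) and fast: the probability a
uniform permutation is a derangement approaches $1/e$, so a handful of
draws suffice. One derangement is drawn per analysis by default; the
number of couples must be at least 2 (no derangement of 1 exists).

## Normalization (ISTS-Z)

ISTS-Z z-scores each ROI's ISTS across dyads, pooling highly satisfied
couples, less satisfied couples and random pairs together, so the values
express relative similarity within the cohort. When condition-restricted
analyses are run (e.g. only TRs from one movie category), normalization is
performed within that condition. Restriction is applied by **masking TRs
before building the trajectory matrix**, not by masking the matrix
afterwards, so only within-condition temporal structure is compared.

# The synthetic cohort

Because the method's validity claims are statistical, the package ships a
generator whose every parameter is known. For each ROI:

$$ x^{(s)}_t = \mu_{e(t)} + \sqrt{c}\, u_t + \sqrt{1 - c}\, v^{(s)}_t + \varepsilon^{(s)}_t $$

where $\mu_k \sim \mathcal{N}(0, \sigma_{\mathrm{ev}}^2 I_V)$ are the $K$
event mean patterns ($\sigma_\mathrm{ev}$ = `event_contrast`), $e(t)$ the
event containing TR $t$, $u$ a couple-shared and $v^{(s)}$ a per-spouse
idiosyncratic fluctuation process, and $\varepsilon$ white noise with SD
`noise_sd`. The fluctuations are unit-variance Gaussian processes smoothed
with a 3-TR moving average (rescaled to unit variance) to mimic BOLD
autocorrelation, so the fluctuation variance decomposes exactly as
$c + (1 - c)$: the coupling $c \in [0, 1]$ is the fraction of fluctuation
variance shared within a couple, and the generator's variance budget is
$1 + \texttt{noise\_sd}^2$ per voxel.

Satisfaction scores are $60 + \beta \cdot \tilde c + \mathcal{N}(0,
\sigma_s^2)$ with $\tilde c$ the standardised coupling, $\beta$ =
`satisfaction_slope` in score units per SD of coupling, and classes follow
the threshold of 60. With $\beta = 0$ scores are independent of coupling
(a null pipeline); with $\sigma_s = 0$ score rank order equals coupling
rank order.

Defaults (30 couples, 20 ROIs of 50 voxels, 100 TRs, 5 events) are a
desk-scale stand-in for the full study geometry of 200 ROIs and ~400 TRs;
they were chosen once for statistical power of the recovery analyses, not
for physiological realism, and the generator deliberately omits
hemodynamic convolution, motion and drift. Consequently, passing tests
demonstrate that the *pipeline* recovers known coupling, event structure
and satisfaction associations under its own model assumptions — they do
not certify performance on real BOLD data, where autocorrelation
structure, artefacts and inter-subject anatomical variability are richer.

An important feature the generator *shares* with real naturalistic data:
the event scaffold is stimulus-locked, identical for **all** subjects, so
even random pairs show substantial ISTS. Couple-specific similarity rides
on top of that common component, which is why couple-vs-random contrasts
(not raw ISTS magnitude) are the meaningful readout, and why all recovery
tests are phrased as contrasts.

# Event segmentation model

The HMM has $K$ states visited strictly in order: from state $k$ the chain
stays or advances to $k + 1$, never returns. Emissions are isotropic
Gaussian around a per-state mean pattern with one shared variance,
computed on **per-TR z-scored** features (each TR's pattern standardised
across features, population SD), so only pattern shape — not global
amplitude — drives segmentation. Feature series are ROI-mean signals of a
network by default, with a voxel-level option; at desk scale small
networks (2 ROIs) need the voxel-level features, since a 2-dimensional
pattern carries a single degree of freedom after normalization.

Choices worth stating:

- **Transition rate fixed, not learned.** The advance probability is
  $K/T$ — the value under which the expected number of events in $T$ TRs
  is $K$. The ordered structure is the modelling constraint; learning stay
  rates at desk scale mostly overfits event lengths.
- **Start and end pinned.** The chain starts in state 1 and the
  likelihood conditions on ending in state $K$, so all $K$ events are
  visited and $K$ is interpretable as the number of events.
- **Exact E-step.** Forward-backward in log space (pairwise log-sum-exp;
  only two incoming transitions per state). Correctness is tested against
  exhaustive enumeration of all monotone state paths for small instances,
  and EM monotonicity (log-likelihood never decreases; tolerance $10^{-9}$)
  is asserted on every fit.
- **Deterministic initialisation.** States initially tile the run into
  $K$ equal contiguous blocks; fitting is therefore deterministic given
  the data, which makes the nested CV reproducible without seed juggling
  inside EM. Convergence: relative log-likelihood change below $10^{-6}$
  or 200 iterations. The emission variance is floored at $10^{-8}$.
- **Segmentation by posterior argmax**, not Viterbi, with a cumulative-max
  projection guaranteeing the no-return invariant (on clean data argmax is
  already monotone; the projection only guards pathological ties).
  Boundaries are the 0-based TRs where the assignment increments.
- **Optional split-merge refinement** (off by default): repeatedly merge
  the most similar adjacent pair of states while splitting the
  longest-duration event (keeping $K$ fixed), refit, accept on
  log-likelihood improvement. Helps when true event lengths are very
  uneven; the default initialisation is otherwise biased toward even
  tilings.

## Choosing the number of events

`select_num_states()` reproduces the nested scheme of the reference
analysis at configurable scale: each subject is held out in turn; the
remaining subjects are randomly split into training and validation sets in
the reference 27:8 proportion (8:3 at the desk scale of 12 subjects);
per-TR z-scored series are averaged within each set; every candidate $K$
(1–10 at desk scale, 1–100 available) is fitted on the training average
and scored by held-out log-likelihood on the validation average. $K^*$
maximises the mean validation curve across outer folds, ties going to the
smaller $K$. Group comparisons run the whole procedure independently per
group on the same seed.

# Within-event similarity

Event windows come either from the HMM segmentation (runs of constant
assignment) — following the reference design, the DMN segmentation fitted
on **all couples pooled** is applied to every ROI — or from a movie-clip
table. Windows shorter than 3 TRs are dropped (and counted): a 2-TR
window yields a single off-diagonal trajectory entry, from which no
correlation can be formed. Per-window ISTS values are averaged
**unweighted** by default (length-weighting available by flag), and
windows with undefined ISTS are skipped and counted.

One subtlety the tests encode: windows that span an event boundary contain
the stimulus-locked pattern change that every subject shares, which
*inflates* raw ISTS for couples and random pairs alike. Correct alignment
therefore shows up not as higher raw within-event ISTS but as a larger
**couple-minus-random contrast**, and that is the property asserted by the
alignment-sensitivity test.

# Inference

**PLS-1.** With $X$ the dyad × ROI ISTS matrix and $y$ the satisfaction
scores (column-centred), the first component's weight vector is the unit
vector maximising $\mathrm{cov}(Xw, y)$ — computed via the SVD of the
cross-covariance $X_c^\top y_c$, with the sign fixed so the score
correlates non-negatively with $y$. Raw ISTS enters by default (the
z-variant by flag). The permutation test shuffles $y$ (5,000 times at
reference scale) and compares the squared covariance explained, with the
add-one estimate $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$.
The bootstrap (500 resamples) refits PLS-1 on resampled dyads, aligns each
replicate's sign to the original weights — without which the sign
indeterminacy renders SEs meaningless — and forms $z = w/\mathrm{SE}$ per
ROI; regional significance is the two-tailed normal $p$ under BH-FDR at
0.05. Degenerate resamples (zero-variance $y$) are redrawn and counted.

**Group tests.** The whole-brain ANOVA is 2 (fMRI state) × 3 (marital
status: high, low, random) — the reference design names a "2 × 2" ANOVA
but lists three status levels; the three-level layout is the default here
and a couples-only 2 × 2 variant is available by flag. Pairwise contrasts
are Welch t-tests with Cohen's d (pooled-SD); satisfaction correlations
are Pearson, marriage-duration correlations Spearman, as in the reference
analysis.

# Data layout and reproducibility

Datasets live as plain text: one TSV matrix per subject × ROI written at
full `%.17g` precision (IEEE doubles round-trip exactly, so write/read is
the identity), TSV tables for the parcellation (200 ROIs / 7 networks in
the reference scheme), dyads, clips and condition masks, and a JSON
manifest. All TR indices on disk are 0-based with half-open intervals.
Every stochastic step takes an explicit integer seed; with fixed seeds the
generator is byte-reproducible and both result writing and CV fold splits
are deterministic.

# Problem sizes

The shipped analyses and tests run at desk scale: cohorts of 30 couples ×
20 ROIs × 50 voxels × 100 TRs for coupling and satisfaction recovery;
12-subject groups with $K$ candidates 1–10 for event-count selection; 500
null datasets × 200 permutations for calibration; exhaustive-enumeration
oracles at $T \le 6$, $K \le 3$. These sizes give the Monte-Carlo checks
comfortable margins (e.g. couple-vs-random Cohen's d ≈ 29 at coupling 0.6
against a required > 1) while keeping a full run in minutes.

# Known limitations

- The generator's noise model is white plus moving-average smoothing; no
  hemodynamic response function, physiological noise or motion.
- The event scaffold is shared across ROIs (one stimulus timeline), while
  real cortical event structure varies regionally; per-network ground
  truth would require a richer generator.
- PLS inference is single-component; multi-component and cross-validated
  predictive variants are out of scope.
- The HMM's isotropic emission is deliberate: full covariances are not
  identifiable at these feature dimensions and sample sizes.
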