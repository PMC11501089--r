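---
title: "Modeling individualized neural tuning with warp hyperalignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling individualized neural tuning with warp hyperalignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intune)
```

## The model

Two brains watching the same movie encode largely the same information,
but they lay it out differently on the cortical sheet, and they weight it
differently.  The individualized neural tuning (INT) model separates
these ingredients.  Each participant's z-scored response matrix
$B_p$ (time $\times$ vertex) is modeled as a linearly transformed group
template,

$$B_p = \hat B_p + E = M W_p + E,$$

where $M$ (time $\times$ vertex) is a functional template representative
of the training cohort and $W_p$ (vertex $\times$ vertex, sparse) is an
individual linear map.  Because $W_p$ is estimated by ridge regression
rather than constrained to an orthogonal rotation, it can scale and shear
— "warp" — the template's representational geometry, capturing
functional as well as topographic idiosyncrasy; we refer to this step as
warp hyperalignment (WHA).  The modeled responses are then factored into

$$\hat B_p = S\,T_p,$$

a stimulus matrix $S$ (time $\times$ k) shared by everyone, with
orthogonal unit-variance columns, and a tuning matrix $T_p$
(k $\times$ vertex) specific to the participant.  Rows of $S$ are
data-driven stimulus descriptors; columns of $T_p$ describe how each
vertex weights the shared basis of response profiles, independently of
which stimuli were used to estimate it.  The tuning matrix is the
model's individual-difference measure: it is fine-grained, stable across
independent data, and distinctive enough to identify participants.

## Template construction

The template is built per searchlight (all vertices within a 20 mm
radius of a center vertex; euclidean distance on the supplied
coordinates by default, geodesic along mesh edges optionally):

1. **Group PCA.**  Training participants' searchlight blocks are
   concatenated along vertices and decomposed by SVD.  We keep as many
   components as one participant has searchlight vertices, and divide
   the PC scores by $\sqrt n$ so the local template's total variance
   matches a single participant's rather than the $n$-fold
   concatenation.  (The alternative $1/n$ convention is available via
   `scaling = "n"`; $\sqrt n$ is the one that achieves the stated goal
   of variance preservation, since singular values of $n$ stacked
   copies grow as $\sqrt n$.)
2. **Orthogonal Procrustes.**  The PC scores are rotated into vertex
   space by the single orthogonal matrix that best aligns them with all
   training participants' blocks simultaneously (SVD of the summed
   cross-covariance).  Rotation leaves the representational geometry
   untouched and only makes the topography group-representative.
3. **Distance-weighted aggregation.**  Each vertex's final template
   profile averages its modeled profiles over all searchlights
   containing it with weight $(r - d)/r$ — 1 at the searchlight center,
   0 at the boundary.

SVD components have arbitrary sign; we fix each component's sign so its
largest-magnitude score is positive, which makes templates invariant to
participant ordering.  Rank-deficient searchlights (fewer time points
than vertices) keep their rank components and are zero-padded.

## Warp hyperalignment and k-fold bagging

$W_p$ is estimated searchlight-wise by ridge regression of the
participant's local data on the local template ($\lambda = 10^3$ by
default), aggregated column-wise (per target vertex) with the same
distance weights.  Entries that never share a searchlight are exactly
zero, so $W_p$ is sparse with the searchlight co-occurrence pattern.

To keep the transformation from overfitting, each local regression is a
bagged ensemble.  Time points are grouped into 10 s segments (segments
never span run boundaries), segments are assigned randomly to $k = 5$
folds, and each fold's model trains on a bootstrap (with replacement) of
the time points more than 10 s away from every held-out point — the
buffer prevents the model from exploiting hemodynamic autocorrelation.
The scheme is repeated 20 times and the $5 \times 20 = 100$ coefficient
matrices are averaged.  Every time point is held out in one fold per
repetition, so each point retains at least 20 out-of-bag models; the
out-of-bag machinery is what the descriptor-estimation ensembles (below)
use to select their penalty.  One fold plan is shared by all
searchlights and participants: this is faster, makes the Gram-matrix
factorizations reusable across participants, and removes an irrelevant
source of variation between vertices.

A Procrustes baseline (`fit_procrustes_baseline()`) implements the
classic rotation-only alignment under the identical searchlight scheme;
on geometry-warped synthetic cohorts its reconstruction error exceeds
WHA's, which is the motivating property of the warp.

## The stimulus basis and why it comes from the full series

$S$ is the left singular vectors of the column-concatenated modeled
responses of the training participants, rescaled to unit column
variance, with $k$ equal to the numerical rank (singular values below
$10^{-10}$ of the largest are discarded).  Unit variance keeps tuning
estimates on one scale regardless of how much data they come from;
orthogonality makes distances between tuning matrices proportional to
distances between modeled responses.

One design point deserves emphasis because it is easy to get wrong.  For
split-half analyses, each half's tuning matrix is estimated from that
half's rows of $S$ by minimum-norm least squares, and we re-fit $W_p$
from each half alone so the two estimates share no individual data.
The basis itself, however, must be computed from **full-series** modeled
responses (one $W$ per training participant, fit on all time points).
If instead the basis were built from per-half-refit modeled data, the
two halves' row spaces would be linearly independent whenever the
modeled halves have full rank — and then, by the CS decomposition of the
orthonormal singular-vector matrix, the row spaces of $S_{(1)}$ and
$S_{(2)}$ are *exactly orthogonal*: the two tuning estimates would be
uncorrelated by construction, for any data.  With the full-series basis
the dominant components span both halves and cross-half comparisons
behave as intended.  (In the noiseless low-rank limit the distinction
vanishes: $k$ equals the latent rank, each half has full column rank,
and both estimates recover the true tuning exactly.)

## Predictions

* **Category-selectivity maps.**  A condition's stimulus descriptor (a
  $k$-vector) is estimated by regressing training participants'
  contrast maps on their tuning features across concatenated vertices,
  with a bagged ridge ensemble: 5 folds over participants, 10
  repetitions (50 models), participants bootstrapped with replacement
  within each model, 4 localizer runs bootstrapped and averaged per
  drawn participant, and a single penalty chosen from 21 log-spaced
  values in $[10^{-2}, 10^2]$ by pooled out-of-bag squared error.  The
  predicted individualized map is `descriptor %*% T_p`.
* **Retinotopic maps.**  Phase-encoded traveling-wave runs are reduced
  per vertex to the Fourier component at the stimulus frequency (5
  cycles in 80 TRs by default); amplitude is $2|c|/n$ and phase is
  corrected for a 5 s hemodynamic delay ($360 \cdot 5/32 =
  56.25^\circ$).  Forward and reversed runs are combined by negating the
  reversed phases and circular averaging, which cancels residual delay.
  Because phase is circular, prediction operates on the linear encoding
  $x = A\cos\theta$, $y = A\sin\theta$ (two descriptor estimations), and
  the decoded map uses the two-argument arctangent — argument order is
  chosen so that decode(encode(m)) is the identity, which fixes the
  convention unambiguously.  Zero-amplitude vertices decode to phase 0.
* **Movie time points.**  Held-out rows of $S$ times the tuning matrix
  give predicted response patterns in the participant's own space.
  Patterns are compared after PCA reduction (components normalized by
  their training-set standard deviation; the PCA is fit on the test
  participant's measured first-half responses).  Binary classification
  scores a target against every foil (ties 0.5); multiclass
  classification requires the same-time-point correlation to be the
  strict maximum, with ties counted as errors — conservative for the
  headline accuracy.

## Reliability and distinctiveness metrics

Cross-half similarity between tuning matrices is the Pearson correlation
of their flattened entries.  All averaging of correlations happens on
Fisher-z values.  A participant's distinctiveness index is
$(z_\text{within} - \overline{z_\text{between}}) /
\mathrm{SD}(z_\text{between})$ computed from that participant's row of
the similarity matrix with the sample SD; as a z-statistic it converts
to an identification error rate $\Phi(-d)$.  Cronbach's alpha,
the Spearman–Brown prediction, and the expected correlation
$\sqrt{\rho_i\rho_j}$ between two noisy maps follow the classical
parallel-test model; `equivalent_localizer_minutes()` chains them to
express a predicted map's quality as an amount of localizer scanning
(the chain infers the predicted map's reliability as $r^2/\alpha$ and is
model-dependent — treat it as descriptive).  The searchlight
distinctiveness map repeats the index within each searchlight's vertices
and assigns the across-participant mean to the center.

## The synthetic cohort generator

`make_cohort()` draws a shared orthogonal unit-variance basis $S^\ast$
(t $\times$ k), a shared tuning component and individual components
combined as $T_p = \sqrt c\,T_\text{base} + \sqrt{1-c}\,T_p'$ so the
expected between-subject tuning correlation is exactly $c$, an optional
individual topographic warp (orthogonal mixing within vertex blocks, or
resampling from a smoothly displaced grid location), and i.i.d. Gaussian
noise.  Tuning entries have variance $1/k$ so the noiseless response
entries have unit variance; `noise_sd = 1` therefore means a
signal-to-noise ratio near 1, which we consider a fair "moderate noise"
setting for stimulus-locked cortical responses.  The default geometry is
a flat 20 $\times$ 20 grid with 3 mm spacing — searchlights behave like
those on a locally flat cortical patch, and distances are exact.  The
default conditions are 10 participants, 600 time points at TR 1 s, 400
vertices, rank 40, between-subject correlation 0.5.

What the generator does *not* emulate: hemodynamic convolution beyond
the retinotopy delay term, spatially correlated noise, inter-individual
differences in SNR, motion artifacts, and the folded cortical geometry.
Passing the synthetic benchmarks therefore demonstrates that the
algorithms are implemented correctly and behave as the model predicts
under its own assumptions — not that real fMRI data will reach the same
numbers.

Localizer fixtures follow the parallel-test model (true map
$s^\ast T_p$ plus i.i.d. run noise), so their Cronbach's alpha lands on
the Spearman–Brown prediction by construction.  Retinotopy fixtures are
noiseless-capable traveling waves whose phase and amplitude fields are
recovered exactly by the Fourier pipeline.

## Numerical choices and degenerate inputs

* Matrix orientation is time $\times$ vertex everywhere; I/O preserves
  it (delimited text, and GIFTI functional series with one map per time
  point).
* Zero-variance vertices (medial wall, masked) are zeroed and flagged,
  not dropped, so indices stay aligned with the geometry.
* Rank thresholds are relative ($10^{-10}$ of the largest singular
  value); the basis SVD is computed directly on the data matrix rather
  than via its Gram matrix, whose eigenvalue noise floor
  ($\sim \epsilon \cdot \sigma_1^2$) would corrupt that threshold.
* Degenerate Procrustes covariances return the identity with a warning;
  zero between-subject spread makes the distinctiveness index `Inf`
  with a warning; classification ties are 0.5 (binary) or wrong
  (multiclass).
* All randomness flows from one master seed through labeled substreams,
  so any stage can be re-run independently and reproducibly; fits are
  bit-identical under a fixed seed.

## Problem sizes used in the test suite

The packaged tests exercise every stage on miniature cohorts (typically
4 participants, 240 time points, a 6 $\times$ 6 grid, rank 8), and run
the full default synthetic conditions (10 participants, 600 time
points, 400 vertices) once, end to end, for the identification
benchmark.  The data-volume sweep is checked at 10 participants, 300
time points, and 100 vertices with per-half durations of 1.5 and 2.5
minutes.  These sizes were chosen so the whole suite completes in well
under half an hour on a single core while still leaving each claim
tested at a scale where its expected effect is unambiguous.

## Known limitations

* The warp fit materializes per-model Gram matrices over all vertices,
  which is the right trade-off up to a few thousand vertices but not at
  full-resolution cortical meshes; a blocked variant would be needed
  there.
* `equivalent_localizer_minutes()` relies on an inference chain the
  parallel-test model only approximately justifies for real localizers.
* Geodesic searchlights use exact Dijkstra per vertex, which is
  quadratic in mesh size; fine for patches, slow for whole hemispheres.
* The generator's between-subject correlation target applies to tuning
  matrices before z-scoring; column-wise normalization shifts realized
  correlations slightly (well within the tested tolerance).
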