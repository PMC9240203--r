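---
title: "Network homogeneity of the default-mode network: model, pipeline and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network homogeneity of the default-mode network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nethom)
```

## The statistic

Network homogeneity (NH) asks, for every voxel of a predefined functional
network, how coherent that voxel is with the rest of the network. For voxel
$i$ in a mask of $N$ voxels,

$$\mathrm{NH}_i \;=\; \frac{1}{N-1}\sum_{j \neq i} r\!\left(x_i, x_j\right),$$

the average Pearson correlation of its time series with *all other* in-mask
series (self-correlation excluded, hence the $N-1$ denominator). The mean
correlation is variance-stabilized with Fisher's transform,
$z_i = \operatorname{atanh}(\mathrm{NH}_i)$, and each subject's map is then
standardized (in-mask mean 0, SD 1) so that group comparisons contrast the
spatial *pattern* of homogeneity rather than each subject's global
correlation level. Both z-steps are kept explicit and separately testable
(`compute_nh_map()`, `standardize_nh_map()`).

Because $\sum_{j} r(x_i, x_j) = \tilde{x}_i^\top S$ with $\tilde{x}_i$ the
unit-norm standardized series and $S = \sum_j \tilde{x}_j$, the map costs
$O(NT)$ rather than the naive $O(N^2 T)$; the test suite verifies exact
agreement with the brute-force correlation-matrix oracle. $|\mathrm{NH}|$ is
clipped at $1 - 10^{-7}$ before `atanh` so degenerate inputs (identical
series) stay finite.

## The pipeline

`run_pipeline()` chains the stages of a standard resting-state NH study:

1. **Simulation** (`generate_cohort()`) — a seeded two-group cohort with
   known ground truth (below).
2. **Preprocessing** (`preprocess_subject()`) — discard the first 5 volumes;
   reject subjects exceeding 2 mm translation or 2° rotation (strict
   inequalities, so a peak of exactly 2 mm passes); regress out the six
   motion parameters and white-matter/CSF surrogate signals while
   *preserving the global signal*; smooth with an 8 mm FWHM Gaussian;
   linearly detrend and band-pass to 0.01–0.08 Hz with an ideal
   frequency-domain mask. The filter is an exact DFT mask rather than an
   IIR/FIR design: it matches common resting-state toolchain behaviour and
   makes the pass/stop contract exactly testable. Smoothing uses replicate
   (nearest-edge) padding, so constant volumes are invariant.
3. **DMN extraction** (`extract_dmn_mask()`) — group spatial ICA on the
   control group: per-subject temporal PCA, concatenation, second PCA to the
   model order, then fixed-point ICA (log-cosh negentropy, symmetric
   decorrelation). Components are z-scaled, sign-fixed to non-negative
   skewness, matched to a template by spatial correlation of $|z|$, and
   thresholded ($z > 1.5$ by default) into the network mask. The model
   order (default 20, the common low-order choice for real multi-network
   data) and threshold are configuration, recorded in the mask provenance,
   because no published convention fixes them. On synthetic cohorts, which
   carry a *single* structured network plus noise, orders above ~8 split
   that network across components and degrade the mask — the demonstration
   runs therefore configure order 8. Deflation-mode fixed-point iteration
   is the default: the most non-Gaussian (structured) components stabilize
   first and are unaffected by noise-only directions, whose negentropy
   objective is flat and which may legitimately fail to converge (a warning
   in pipeline use, an error under the strict API default). Back
   reconstruction to per-subject time courses is available but only the
   group map feeds the mask.
4. **NH and group statistics** — per-subject standardized NH maps; a pooled
   (Student) two-sample t map patients − controls; Gaussian-random-field
   cluster inference at voxel $p < 0.001$ (two-sided, run as two one-sided
   analyses at $p/2$) and cluster $p < 0.01$; cluster tables with peak
   world (MNI-style) coordinates via the image affine, 26-connectivity by
   default and smallest-linear-index tie-breaks for peaks, so reports are
   deterministic.
5. **Clinical statistics** — a demographics table (pooled t per numeric
   variable, Pearson χ² for sex), and uncorrected Pearson correlations
   between cluster-mean NH and clinical covariates in the patient group.
6. **Classification** (`cv_svm_grid()`) — an RBF-kernel SVM on cluster-mean
   NH features (increased-NH clusters by default), grid-searched over
   $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$ under leave-one-out
   cross-validation, with per-fold feature z-scoring fit on training folds
   only. Ties in accuracy resolve to the smaller $C$, then smaller
   $\gamma$. Accuracy, sensitivity (patients) and specificity (controls)
   come from pooled held-out predictions.

### GRF cluster-level inference

Smoothness is estimated from the standardized residuals of the group model
(per-subject maps minus their group mean): the variance $\lambda$ of first
spatial differences of each unit-variance residual map gives
$\mathrm{FWHM} = \sqrt{4\ln 2 / \lambda}$ per axis, with the discrete-grid
bias corrected by inverting the Gaussian-ACF relation
$m = 2(1 - e^{-\lambda/2})$ and a floor of one voxel. Resel counts
$R_0 \ldots R_3$ follow Worsley's point/edge/face/cube counting on the
actual mask. The expected number of suprathreshold clusters is
$E[m] = \sum_d R_d \rho_d(u)$ with the t-field Euler-characteristic
densities; cluster sizes follow the standard two-thirds-power exponential
form; a cluster of $k$ resels gets corrected
$p = 1 - \exp(-E[m]\,P(n \ge k))$. These are asymptotic approximations: at
desk scale the test suite requires the family-wise false-positive rate over
200 null cohorts to stay below 0.05 (the nominal two-direction level is
0.02), not to match it exactly.

## What the synthetic cohort emulates

No public data accompany the study this pipeline replicates, so the
generator (`cohort_spec()`, `generate_subject()`) is a first-class, tested
module. Each subject's voxel series is

$$y_v(t) = c_v\, s(t) \;+\; a_v\, u_{b(v)}(t) \;+\;
  \sqrt{1 - c_v^2 - a_v^2}\;\varepsilon_v(t) \;+\; d(t) + \ell(t),$$

- $s$: a subject-level **network signal**, built directly in the frequency
  domain with support confined to 0.01–0.08 Hz (out-of-band power is
  exactly zero, which the DFT oracle test checks);
- $c_v$: the **coupling weight** — `base_coupling` (0.5) inside the DMN-like
  ROI boxes, zero outside, shifted by ±`delta` (0.3) in designated effect
  ROIs *for patients only*, so in-band correlation between voxels is
  $c_i c_j$ and ground truth is known exactly;
- $u$: a **regional background field** — AR(1) node signals on a 4-voxel
  lattice, trilinearly interpolated and re-normalized, giving a stationary
  spatially smooth noise floor with ~12 mm correlation length. This term is
  essential: spatially independent noise is annihilated by 8 mm smoothing,
  after which baseline NH saturates near $r \approx 0.95$ and a coupling
  *increase* has no room to raise correlations — a regime real data never
  show. Its amplitude (0.8) keeps baseline in-network correlations near
  0.5 after smoothing;
- $\varepsilon_v$: unit-variance AR(1) voxel noise
  (`ar1_coefficient = 0.5`, a typical BOLD autocorrelation at TR 2 s);
- $d$: a linear scanner drift (amplitude 0.5 SD), removed exactly by
  detrending; $\ell$: small leak (0.1) of the white-matter/CSF surrogate
  signals into every voxel, so nuisance regression has something to remove.

Between-subject variability enters as a per-subject, per-ROI offset on the
coupling weights (`coupling_jitter = 0.07`, truncated to keep weights in
$(0,1)$). Without it every subject is statistically identical and group t
values grow without bound, at which point cluster inference happily detects
the smoothing halo around an effect rather than the effect itself. The
jitter scale was chosen so that, at the published design size
(n ≈ 20–43 per group), injected effects yield peak $|t|$ of roughly 5–8 —
the magnitude such studies actually report — and was frozen before the
acceptance simulations were run.

Motion traces are bounded random walks (step 0.05 mm/°, reflected at
±1.5), six columns: three translations in mm, three rotations in degrees,
matching the 2°-rotation screen directly. Phenotypes (age, sex, education,
illness duration, onset age, reaction time, MMSE) are drawn from the
published group summaries; illness duration is generated for patients only,
because the published control-column entry for that row is internally
inconsistent; clinical covariates are independent of the imaging signal by
default, matching the published null correlation finding.

**What the generator does not emulate:** hemodynamic response convolution,
cardiac/respiratory physiology, susceptibility dropout, scanner drift
nonlinearity, multi-site effects, or anatomical geometry — the "brain" is a
box grid with rectangular ROIs. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and calibrated under a plausible
correlation structure, not that the published biological findings would
replicate.

## Study conditions used by the test suite

Monte-Carlo checks run at desk scale, sizes chosen once:

- **Null calibration:** 200 cohorts, 10 vs 10 subjects, T = 120, a
  2,028-voxel box mask (13×13×12) inset one voxel from the volume edge —
  a brain mask never touches the volume boundary, and edge voxels have
  non-stationary NH variance that would corrupt a stationary-field
  calibration.
- **Effect recovery:** 50 seeds of `desk_cohort_spec()` — 20 vs 20
  subjects, T = 240 (the generator default; the in-band information of a
  ~9-minute TR-2 run is what makes recovery reliable), a 14×16×14 grid with
  six context boxes and two small effect ROIs (~7% of the ~400-voxel mask
  each, mirroring the proportion that significant clusters occupy in a
  whole-brain DMN mask). Both injected effects must be recovered with the
  correct sign and Dice > 0.5 in at least 90% of seeds.

A scaled-down configuration in which the effect ROI is a large fraction
(~20%) of the mask is *not* faithful: per-subject standardization then
redistributes the effect across the whole mask and the comparison degrades —
an instructive failure mode of NH-style statistics, not of the
implementation.

## Numerical choices

- Ideal DFT band mask; filtering is idempotent and linear to 1e−8, verified.
- `atanh` clip at $1 - 10^{-7}$; out-of-mask voxels are `NA` in memory and
  0 in written NIfTI, with the mask shipped alongside.
- Zero pooled variance at a voxel yields t = 0 with a warning rather than
  an error (it occurs for degenerate inputs only).
- ICA initialization is a seeded random orthogonal matrix; convergence
  tolerance 1e−6, maximum 200 iterations, error (with iteration count) on
  non-convergence. The unmixing sign is fixed by map skewness.
- Peak ties and cluster orderings resolve by smallest linear index so all
  reports are bit-reproducible; the single pipeline seed fans out to
  per-subject and per-stage seeds through a fixed integer hash.

## Worked example

```{r example, eval = FALSE}
library(nethom)

cfg <- run_config(seed = 1, out_dir = "demo_run",
                  cohort = desk_cohort_spec(seed = 1),
                  n_components = 8, z_threshold = 1.0)
man <- run_pipeline(cfg)

man$clusters            # Table-2-style cluster report
man$demographics        # Table-1-style group comparison
man$classification      # LOOCV SVM on cluster-mean NH features
```

## Known limitations

- GRF corrections are asymptotic; at very small masks or FWHM near one
  voxel they are only approximately calibrated (the suite bounds, not
  pins, the false-positive rate).
- The ICA model order and mask threshold have no published values; results
  depend on them, which is why both are recorded in the mask provenance.
- Whether NH is computed before or after smoothing changes its magnitude;
  the pipeline fixes the order (smooth, then filter, then NH) and exposes
  it in the configuration rather than varying it silently.
- The simulator's rectangular geometry makes cluster shapes unrealistically
  box-like; extent-based inference on real anatomy will differ in detail.
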