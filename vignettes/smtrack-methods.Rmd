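---
title: "Models and methods behind smtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smtrack quantifies the lateral diffusion of membrane receptors from
single-molecule tracking (SMT) data: TIRF movies of sparsely labeled
receptors at 10 Hz, reduced to per-molecule trajectories, per-trajectory
diffusion coefficients and anomalous exponents, motion-mode classes, and
population-level comparisons. This vignette explains the models, the
estimators, the synthetic-data generator used to validate every stage, and
the design decisions a maintainer would want to know about.

## The measurement model

A receptor labeled with a photostable organic dye appears as a
diffraction-limited spot. Its position in frame $t$ is the true position
plus localization error, modeled as independent Gaussian noise of standard
deviation $\sigma_{loc}$ per axis (default 0.03 µm, typical of bright
far-red dyes in TIRF). The time-averaged mean squared displacement of a
trajectory sampled at interval $\Delta t$ is

$$\mathrm{MSD}(n\,\Delta t) \;=\;
  \frac{1}{N-n}\sum_{i=1}^{N-n}
  \left\lVert \mathbf{r}_{i+n}-\mathbf{r}_i \right\rVert^2 ,$$

averaged over all ordered frame pairs. For 2-D Brownian motion
$\mathbb{E}[\mathrm{MSD}(\tau)] = 4D\tau + 4\sigma_{loc}^2$: the noise adds
a constant offset, which is why the diffusion-coefficient fit always
carries an intercept.

Three motion modes are modeled, following the standard taxonomy for
membrane receptors:

* **Brownian** — independent Gaussian steps of per-axis variance
  $2D\,\Delta t$; $\mathrm{MSD} \propto \tau$.
* **Confined** — Brownian steps reflected at a circular corral of radius
  $R$ about the start point (radial fold-back). The MSD bends over and
  plateaus at $R^2$ (the mean squared distance between two uniform points
  in a disk). A reflecting disk was chosen over soft (harmonic) confinement
  because the plateau has a closed form usable as a test oracle.
* **Directed** — Brownian steps plus constant drift $v\,\Delta t$ along a
  fixed heading; $\mathrm{MSD}(\tau) = 4D\tau + v^2\tau^2$, superlinear.

## Estimators

* `estimate_D()`: ordinary least squares of MSD on $\tau$ over the first
  `n_fit = 4` lags, $D = \text{slope}/4$. Short-lag fitting is the standard
  bias/variance compromise: it limits the curvature bias from confinement
  or drift while keeping enough pairs per lag. Negative slopes are clamped
  to zero and flagged. The intercept absorbs $4\sigma_{loc}^2$.
* `estimate_alpha()`: slope of $\log \mathrm{MSD}$ on $\log \tau$ over lags
  1–10 (capped at a quarter of the trajectory length). Non-positive MSD
  values are dropped; with fewer than three usable lags the exponent is
  undefined and the trajectory is excluded from classification (but kept in
  pooled D statistics — the per-line medians pool every trajectory).
* `classify_mode()`: $\alpha < 0.7$ confined, $\alpha > 1.3$ directed,
  otherwise Brownian, with exact threshold equality assigned to the middle
  class. `threshold_sweep()` re-classifies over the grid
  $0.5\text{–}0.9 \times 1.1\text{–}1.5$ and reports the largest change of
  each fraction, quantifying the robustness of the classification to the
  (inevitably somewhat arbitrary) threshold choice.

The TA-MSD itself is checked against a brute-force all-pairs enumeration
in the tests; pairs spanning closed linking gaps contribute to the lag
equal to their true frame difference.

## The synthetic generator and its calibration

The generator (`simulate_population()`) draws each trajectory's mode from
the requested fractions and its diffusion coefficient from a lognormal with
log-scale spread 0.5 around the mode's median (per-trajectory mobility
heterogeneity is a universal feature of SMT data). Two dimensionless shape
constants tie the confinement and drift strength to each trajectory's D:

$$R = \sqrt{0.7\,D\,\tau_0}, \qquad v = \sqrt{20\,D/\tau_0},
  \qquad \tau_0 = 1\ \mathrm{s}.$$

These values were fixed by a design study before the acceptance tests were
written: they place the three per-trajectory $\alpha$ distributions at
roughly $0.38 \pm 0.04$, $0.99 \pm 0.06$ and $1.61 \pm 0.03$ for 400-frame
tracks, i.e. well separated from both default thresholds *and* from every
grid point of the threshold sweep, which is what makes the classification
demonstrably threshold-robust. The default track length of 400 frames
(40 s at 10 Hz) is what that separation requires; with 100-frame tracks the
$\alpha$ spread roughly doubles and classification degrades gracefully.

**Calibration on the apparent scale.** The short-lag OLS estimator is not
mode-neutral: at the shape constants above it reads confined motion low
(median ratio $\approx 0.25$) and directed motion high ($\approx 3.5$),
simply because the MSD of those modes is curved where the line is fitted.
Published per-line medians are themselves MSD-fit estimates, so the presets
(`cell_line_preset()`) are calibrated *through the pipeline*: a seeded
bisection sets the overall D scale so that the pooled median of
pipeline-estimated D matches the published per-line median within 2%, and
the per-mode medians are set so the *apparent* (estimated) per-mode medians
sit in ratio 0.5 : 1 : 1.5 (confined : Brownian : directed) — ordered and
moderately separated, as per-mode medians appear in the source data. The
published figures give no numeric per-mode medians, so this ratio is a
repository decision. Two consequences worth knowing:

* the `true_D` columns of preset populations have a *higher* pooled median
  than the published value (the confined majority is read low), and
* calibrating on the true scale instead is not an option: it would push the
  apparent-D mixture into well-separated clusters whose pooled sample
  median falls in a density gap, making median-based statistics an order of
  magnitude noisier.

Calibration uses a fixed internal seed, is independent of user seeds, and
is cached per session. The patient-derived preset (PAAD-21010) has no
published mode fractions; it reuses the pipeline defaults (0.50, 0.30,
0.20) and carries a `fractions_printed = FALSE` flag.

## Imaging model and localization

`render_movie()` draws each live emitter as a pixel-integrated isotropic
Gaussian PSF ($\sigma$ = 0.12 µm by default, diffraction-limited for a
far-red dye at high NA) scaled to its expected photon count (1000/frame),
over a constant background (5 photons/pixel), with per-pixel Poisson noise.
Photobleaching is single-step: a geometric lifetime per emitter, after
which it is dark forever — the signature used to validate that a spot is a
single fluorophore. `count_bleach_steps()` finds steps by recursive binary
segmentation of the trace mean with a BIC-style penalty ($3\log n$ per
change point) and counts only downward jumps exceeding three times the
local noise; its false-positive rate on step-free traces is kept below 5%
by the penalty choice.

`detect_spots()` band-passes each frame with a difference of Gaussians
($\sigma$ and $2\sigma$), thresholds at 5 robust standard deviations (MAD)
above the median, takes 3×3 local maxima, and refines each candidate by a
Levenberg–Marquardt fit of the pixel-integrated Gaussian plus offset.
Failed fits and fitted widths outside $[0.5, 2]\times$ the PSF guess are
dropped rather than retried, keeping per-frame results deterministic. On
noiseless symmetric spots the localization bias is below $10^{-3}$ px; at
SNR ≈ 10 the error is ≈ 0.07 px.

At the working density of 0.2 spots/µm², about 5% of emitters are missed
per frame, almost entirely through PSF overlap of close pairs — two
emitters within ≈ 2–3 pixels merge into one (often width-rejected) spot.
This is physics, not a tunable: the detection-based density estimate
therefore runs a few percent below truth, well within its 10% QC band.

## Linking

`link_detections()` matches consecutive frames by the assignment that
minimizes total squared displacement (a Jonker–Volgenant-style Hungarian
solver in compiled code), with per-detection opt-out at cost $r_{max}^2$,
the classic formulation. Track ends are then joined to later track starts
across at most `gap_max` missing frames by ascending displacement cost
scaled by gap length. Frame pairs with more than 500 candidates fall back
to greedy matching with a warning. Defaults: $r_{max} = 2.5$ µm (4× the
r.m.s. frame displacement at $D = 1$ µm²/s, miss probability < 10⁻³),
`gap_max = 1`, `min_len = 20` frames (enough lags for a stable $\alpha$
window).

A known limitation: when two emitters pass within the PSF-merge radius,
their detections coalesce for a frame or two and the linker may swap their
identities on separation — no cost function on positions alone can resolve
this, and merge/split track topology is deliberately out of scope. Swap
probability accumulates with observation time; over 2-s movies (the mean
single-fluorophore track duration at a 5%/frame bleach rate) ground-truth
recovery is ≈ 0.85 mean per-trajectory Jaccard overlap, dropping to ≈ 0.7
for 5-s movies at the same density. Trajectory-level statistics in this
package are therefore most trustworthy when track durations are
bleaching-limited, as they are in the intended imaging regime.

## Population statistics

Per-line summaries use the **median** D (the published convention, robust
to the heavy right tail) with IQR, over at least 1000 trajectories by
default (the reporting convention for per-line statistics; overridable with
a warning). Group comparisons are one-way ANOVA with Tukey's HSD on
per-trajectory D; with thousands of trajectories per group the F-test's
normality assumption is immaterial (verified by a type-I-error property
test on null simulations). Perturbation effects are reported as percent
change of the median with a seeded percentile bootstrap (2000 resamples)
over trajectories. Mobility–phenotype association uses Pearson correlation
on per-line medians against externally supplied phenotype values
(wound-closure rates, transwell counts) — the package never computes
phenotypes from images.

## Cluster analysis

Super-resolution localization maps are clustered with DBSCAN (eps 0.05 µm,
min_pts 10 — typical dSTORM scales; written in plain R as no DBSCAN
implementation ships with the supported environment). Cluster size is the
radius of gyration, whose closed form for a 2-D Gaussian blob
($R_g = \sigma\sqrt{2}$) anchors the tests; convex-hull area is reported
alongside. Size distributions between samples are compared with a
two-sided Mann–Whitney test. No drift or blinking-multicount correction is
applied — inputs are assumed to be consolidated localizations.

## Numerical and degenerate-input conventions

* All positions are µm (origin top-left, y down); pixel $i$ spans
  $[i\,s, (i{+}1)\,s)$; frames are 0-based; CSV dialects are documented in
  the I/O help pages.
* One root seed per operation; every trajectory derives a child stream
  from it, so subsets reproduce independently of batch size or order.
  Identical spec + seed gives byte-identical outputs.
* Empty or constant images yield zero detections (not an error); empty
  trajectory files are an error naming the file; too-short trajectories
  are rejected naming the trajectory id; zero-variance inputs to the
  correlation are an explicit error rather than NaN.
* The confined reflection uses radial fold-back ($r \to 2R - r$); a step
  that would fold past the centre leaves the particle in place. At the
  step-to-corral ratios of the presets the stationary distribution is
  uniform in the disk to within the 10% plateau tolerance used in tests.

## What passing tests do and do not show

The generator reproduces the statistical structure the analysis relies on
— mode mixtures, lognormal mobility spread, localization noise, Poisson
camera counts, single-step bleaching, the working labeling density — so
the test suite demonstrates correct *recovery of known ground truth* under
that model. Real data add complications the generator deliberately omits:
membrane topography and hop diffusion, dye blinking, mode switching within
a trajectory, drift, and non-Gaussian PSF tails. Passing tests therefore
validate the estimators and their wiring, not the biological fidelity of
any particular dataset.

## Problem sizes used in the validation suite

Recovery checks run at 2000 trajectories per condition (100-frame tracks
for pooled-median recovery, 400-frame tracks for classification), 2000
bootstrap resamples, 200 replicate null ANOVAs, a 50-frame density-QC
movie and a 20-frame linking movie at 0.2 spots/µm², and 10⁴ trajectories
for ensemble closed-form checks — sizes at which every Monte-Carlo
tolerance in the suite is several standard errors wide.
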