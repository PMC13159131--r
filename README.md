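# smtrack

Single-molecule tracking (SMT) analysis of membrane receptor diffusion, in
R. The package implements the full quantitative pipeline used to study how
a receptor's lateral mobility on the plasma membrane relates to cell state:
subpixel spot localization in TIRF movies, trajectory linking,
time-averaged mean-squared-displacement (MSD) analysis,
diffusion-coefficient and anomalous-exponent estimation, classification
into confined / Brownian / directed motion, population statistics
(medians, ANOVA + Tukey comparisons, mobility–phenotype correlation,
perturbation percent-change with bootstrap intervals), and density-based
cluster analysis of super-resolution localizations. A synthetic
trajectory-and-movie generator with known ground truth makes every stage
verifiable without microscopy data.

It is written for quantitative microscopists and computational biologists
who have SMT movies or trajectory tables and want per-cell-line mobility
statistics with a validated, reproducible method.

## The core statistic

For a 2-D trajectory sampled at interval Δt, the time-averaged MSD at lag
τ = nΔt averages the squared displacement over all ordered frame pairs.
Two quantities are fitted per trajectory:

* **Diffusion coefficient** `D = slope/4` from ordinary least squares of
  MSD on τ over the first 4 lags (the intercept absorbs the localization
  noise term 4σ²loc);
* **Anomalous exponent** α, the slope of log MSD vs log τ over lags 1–10
  (MSD ∝ τ^α).

Motion is classified as confined (α < 0.7), Brownian, or directed
(α > 1.3); boundaries assign to Brownian and the classification is
verified to be robust across a threshold grid. Populations are summarized
by the **median** D and the mode fractions.

Calibrated presets (`cell_line_preset()`) reproduce published per-line
statistics for four pancreatic cell lines and one patient-derived primary
line — pooled median D of 0.07 (hTERT-HPNE), 0.10 (MIA PaCa-2), 0.13
(PANC-1), 0.18 (PaTu-8988t) and 0.11 µm²/s (PAAD-21010), with mode
fractions 68/20/12, 58/24/18, 50/29/21 and 44/32/24 — so the whole
pipeline can be exercised against known targets.

## Worked example

Simulate the metastasis-derived line, run the motion analysis, and compare
against an antibody-style perturbation that slows every molecule by 22%:

```r
library(smtrack)

spec <- cell_line_preset("PaTu-8988t", n_traj = 2000, seed = 42)
fits <- fit_motion(simulate_population(spec), dt = spec$dt)
summarize_population(fits, group_id = "PaTu-8988t")
#> Population 'PaTu-8988t': 2000 trajectories (2000 classified, 0 alpha undefined)
#>   median D = 0.1749 um^2/s (IQR 0.1842)
#>   mode fractions: confined 44.9%, brownian 32.2%, directed 22.9%

treated <- cell_line_preset("PaTu-8988t", n_traj = 2000, seed = 43,
                            d_scale = 0.78)
fits_t <- fit_motion(simulate_population(treated), dt = treated$dt)
pc <- percent_change(fits, fits_t, seed = 44)
round(c(pc$percent_change, pc$ci), 1)
#> [1] -17.5 -23.3 -13.4
```

The summary says: the pooled median diffusion coefficient is 0.175 µm²/s
(the preset's published target is 0.18), with 44.9% of trajectories
confined, 32.2% Brownian and 22.9% directed (targets 44/32/24). The
percent-change analysis estimates the simulated 22% reduction as −17.5%
with a 95% bootstrap interval of [−23.3, −13.4]; across seeds the point
estimate scatters around −22 with a standard error of about 2 points
(two medians of 2000 skewed values each enter the ratio).

Movies work the same way through `run_pipeline()`, which chains detection,
linking, motion analysis and the summary, and writes a report accounting
for every record filtered at each stage. A thin command-line wrapper with
the same stages as subcommands lives at `inst/cli/smtrack.R`.

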