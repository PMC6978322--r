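---
title: "Models and methods behind termcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind termcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(termcycle)
```

This vignette documents the models, the tunable parameters, the
synthetic-data generator, and the numerical and design choices made where
the procedure left room for judgement.  It is the companion to the test
suite: every quantitative claim here is one that the tests or
`scripts/acceptance.R` compute.

## 1. The physical picture

A transcription template is tethered to a coverslip at one end and observed
by TIRF microscopy in three channels: the DNA itself, a dye-labelled core
RNAP, and a transcript-hybridisation probe.  Because the evanescent field
decays exponentially with height, RNAP emission reports its distance from
the surface, hence its position along the DNA contour.  After the
transcript probe departs (termination), most RNAP molecules remain on the
DNA; they alternate between 1D diffusive sliding and stuck intervals, and a
fraction re-initiate transcription, usually antisense from an AT-rich,
promoter-like sequence near the terminator, retracing the elongation
intensity profile in mirror image with the *same* molecule-specific rate.

## 2. Calibration (module `calibration`)

The elongation phase is fit with `fit_elongation_decay()` to
$I(t) = I_P e^{-\lambda t} + I_{mn}$ by ordinary nonlinear least squares
(`minpack.lm::nlsLM`; the loss is not otherwise constrained by the
procedure, so OLS is assumed).  Starting values are derivative-free:
$I_{mn}$ from the trailing intensity level of the window, $I_P$ from the
first five frames minus that baseline, $\lambda$ from a log-linear
regression of the baseline-subtracted signal.  A non-converged fit is
flagged and refused by all downstream operations.

The elongation window is an input (it was chosen interactively in the
original analysis); `detect_elongation_window()` offers a probe-channel
change-point heuristic, but ground-truth windows are used in tests so that
window choice does not confound parameter-recovery results.

`compute_elongation_rate()` combines the fit with the known promoter and
terminator positions $z_P$, $z_T$ and the measured termination intensity
$I_T$.  Edge cases: $I_T \le I_{mn}$ is an error (the logarithm is
undefined — termination intensity at or below background);
$I_T - I_{mn} \ge I_P$ sends the rate to infinity and is flagged
`unphysical` rather than silently propagated.

`intensity_to_position()` inverts the calibration per frame.  Frames with
$I(t) \le I_{mn}$ are masked (`NA`), never extrapolated; if more than half
the requested frames are masked a warning is logged.  The algebraic
identities — $z(z_P$-intensity$) = z_P$, $z(I_T) = z_T$, and the
intensity→position→intensity round trip — hold to numerical tolerance
(asserted at $10^{-6}$ of template length, a pure algebra check).

**Down-tethered templates.**  For an inverted template the intensity rises
during elongation.  Rather than duplicating the algebra, the fit is run on
the time-reversed window (`orientation = "down"`) and the inversion anchors
at the terminator: $z = z_T - r\lambda^{-1}\ln(I_P/(I-I_{mn}))$.  Mirrored
simulations processed this way reproduce the up-orientation results
(tested).

## 3. Motion analysis (module `motion`)

`compute_msd()` computes the time-averaged single-trajectory MSD, binning
all frame pairs by their *true* time separation, so acquisition gaps
contribute to the lag they actually represent and absent lags simply drop
out.  `estimate_diffusion()` fits a straight line with free intercept
through the first ten lag points and reports $D = \mathrm{slope}/2$ (1D
convention).  The free intercept absorbs static localisation error;
negative fitted $D$ from noise is retained in histograms (it centres the
stuck mode) but never classifies as sliding.

`window_diffusion()` slides 50-s windows at a stride of one frame
(overlapping).  The stride is not dictated by the procedure; one frame is
the choice consistent with the windows-per-recording bookkeeping of the
source data — roughly 330 windows per recording, which matches ~700-second
records at 2-s frames.  Because "ten MSD points" only coincides with a 10-s
lag range at 1-s framing, the default lag range adapts to the trace's own
frame spacing (`max_lag = n_points ×` median frame interval).

`classify_sliding()` scores a molecule as sliding if any window reaches
$2.2\times10^4$ bp² s⁻¹, *inclusive* — the saddle between the stuck and
sliding modes of the windowed-D distribution.

**Confinement.**  On a 2.1-kb template, a walker with
$D \gtrsim 2\times10^4$ bp² s⁻¹ feels the boundaries within seconds: the
exact reflected-Brownian MSD shows the 10-point slope estimate recovers
only ~35–65% of the microscopic $D$ at 1–2-s framing.  Windowed estimates
on the short template are therefore *apparent* diffusion coefficients, as
they are in the experimental histograms.  For this reason the
parameter-recovery studies of the estimator itself (unbiasedness; the
bimodal-histogram mode test) are run in weak-confinement geometry — wide
templates, and 4-Hz framing for the mode test, where the per-window
estimator distribution is concentrated enough for its mode to sit at the
parameter.  These are study-design choices fixed a priori; the bounded-walk
saturation ($\mathrm{MSD} \to L^2/6$) is tested separately.

`classify_secondary_initiation()` operationalises the "visible antisense
elongation profile" pre-screen reproducibly: the post-termination RNAP
record is segmented into monotone swings by hysteresis (zigzag) with
amplitude threshold $3\times$ the calibration residual SD; swings lasting
at least 25% of the sense elongation duration are trimmed of their
post-completion plateau and fit to the mirrored exponential profile with
the offset pinned at the calibrated background (a two-parameter fit, which
stays well-conditioned on partial episodes).  A call requires the fitted
rate to fall in 0.002–0.04 s⁻¹, $R^2 \ge 0.8$, and episode-fit residuals
within $3\times$ camera noise (diffusive excursions fail the latter two).
Intensity moving back toward the promoter-proximal level is antisense;
a renewed decay is sense re-initiation; the earliest qualifying episode
sets the call, and the two calls are mutually exclusive per episode.

## 4. Kinetics (module `kinetics`)

`classify_departures()` classes each molecule by the RNAP-minus-probe
departure interval: within ±4 s (inclusive, the maximum frame gap of the
interleaved acquisition cycle) is "simultaneous"; censored RNAP departures
count as "after" (the spot outlived the movie).  Fractions carry binomial
s.e.m. $\sqrt{\hat p(1-\hat p)/n}$ and sum to one.

`fit_censored_exponential()` implements the closed-form censored MLE
$\hat k_{obs} = n_{unc}/\sum_i t_i$; tests verify it coincides with a
numeric likelihood maximiser to $10^{-8}$.  `correct_photobleaching()`
applies $k_{RNAP} = k_{obs} - k_{PB}$ (photobleaching and dissociation are
competing exponentials, so rates add) and reports $1/k_{RNAP}$ with a
seeded bootstrap over (duration, censored) records — 1000 resamples by
default — plus optional propagation of $k_{PB}$ uncertainty.
$k_{obs} \le k_{PB}$ yields a *flagged* infinite lifetime, not an
exception; $k_{PB}$ itself is an input, measured by a separate
photobleaching control in practice and supplied by simulator truth in
tests.

`drift_velocity()` evaluates $v_d = D F/(k_B T)$ with
$k_B = 1.380649\times10^{-2}$ pN·nm·K⁻¹ (the exact SI value).
`bp2_to_nm2()` converts diffusion coefficients with a configurable helical
rise: the canonical 0.34 nm/bp default, while the round-number conversion
pair $4\times10^4\,\mathrm{bp^2\,s^{-1}} = 4\times10^3\,\mathrm{nm^2\,s^{-1}}$
found in the literature implies $\sqrt{0.1}\approx0.316$ nm/bp; both are
supported and neither is asserted as intended.

## 5. Rend-seq (module `rendseq`)

Coordinates are 1-based inclusive internally (the R/Bioconductor
convention); BED (0-based half-open) and wig (1-based) are converted at I/O
by `rtracklayer`, and every track carries its convention tag.

* `filter_terminators()`: a terminator is eligible only if its nearest
  upstream and downstream genes share its orientation, excluding convergent
  contexts where 3′ peak shadows could mimic antisense 5′ ends.
* `compute_delta_S()` / `compute_delta_AS()`: $\Delta_S = \log_2 k_{max}$
  over a centred, inclusive 10-bp window on the terminator strand (3′
  track); $\Delta_{AS} = \log_2 k_{max2}$ over ±500 bp inclusive on the
  opposite strand (5′ track).  Whether these windows are centred or
  endpoint-inclusive is not dictated anywhere; centred inclusive is used
  and documented.  Ties resolve to the leftmost coordinate; $k_{max}=0$
  leaves $\Delta$ undefined (`NA`) and excludes the terminator from scatter
  summaries.
* `peak_zscore()` / `zscore_track()`: the peak-calling window is not
  restated by the source analysis (it comes from the Rend-seq tooling), so
  the default is a 50-nt flank each side excluding the centre ±2 nt, with
  the SD floored at the flank mean's Poisson SD $\sqrt{\max(\bar c, 1)}$ —
  the floor avoids divide-by-zero on flat flanks and anchors the scale to
  counting noise (a perfectly flat track scores z = 0).  All three numbers
  are configurable.  Strong peaks use z > 12, strict.
* `distance_profile()`: fraction (± binomial s.e.m.) of 200-nt windows at
  each signed distance (in the terminator's own orientation) containing an
  above-threshold antisense 5′ peak.
* `sample_control_locations()` / `control_replicates()`: uniform sampling
  without replacement from gene bodies inside runs of ≥3 same-orientation
  genes, >700 nt from every terminator; 100 replicates by default; the
  empirical p-value is $(1 + \#\{\mathrm{ctrl} \ge \mathrm{obs}\})/(1+R)$.
* `tss_information_content()`: per-position information $2 - H$ bits in a
  ±3-bp window around each start site (minus-strand windows are
  reverse-complemented), with the small-sample correction
  $3/(2 n \ln 2)$ subtracted by default.

## 6. The synthetic-data generator (module `synthetic_data`)

The generator emulates the statistical structure the analysis assumes, with
full per-frame ground truth, so every estimator can be tested for parameter
recovery.  Defaults are the study conditions:

| parameter | default | why |
|---|---|---|
| template, `z_P`→`z_T` | 2100 bp | the 2.1-kbp transcription unit |
| frame interval | 2 s | two-colour duty cycle; optional 4-s gap pattern |
| `lambda_mean`, `lambda_cv` | 0.01 s⁻¹, 0.3 | molecule-specific rates; lognormal keeps them positive (the distribution is not specified by the data, only its molecule-to-molecule spread) |
| `tirf_decay_bp` | `z_T − z_P` | couples λ to the elongation rate, r = λ·decay; gives r ≈ 21 bp/s at λ = 0.01 |
| `D_slide` | 3.5×10⁴ bp² s⁻¹ | upper mode of the windowed-D histogram |
| `p_stick`, `p_unstick` | 0.02, 0.05 per frame | slide/stick episodes of ~10²-s scale |
| `p_retain` | 0.87 | 87/100 molecules retained at termination |
| `p_antisense`, `p_sense_reinit` | 0.30, 0.02 | reverse motion in up to ~30% of ECs with free σ⁷⁰; sense re-initiation rare (<2%) |
| `k_RNAP` | 1/1140 s⁻¹ | post-termination lifetime ~1140 s |
| `k_PB` | 1/2400 s⁻¹ | not printed anywhere; chosen so ~95% of spots survive elongation, matching the observed 94% visible at termination |
| `hybridization_lag` | 10 s | probe detectability lag; unreported, exposed as a parameter |
| `antisense_start_sd` | 50 bp | antisense initiation near the terminator-proximal AT-rich region; configurable offset spread |

Photobleaching runs from the start of illumination and competes with
dissociation; only the first event is observable, which is exactly the
additivity $k_{obs} = k_{RNAP} + k_{PB}$ the correction assumes.  The drawn
secondary-initiation fate is retained in the ground truth even when RNAP
loss truncates the episode; `secondary_completed` records whether the
episode finished inside the observation.  Down-tethered templates are
generated by mirroring the intensity–position map.

The Rend-seq generator (`simulate_rendseq()`) plants 3′ sense spikes at
terminators and 5′ antisense spikes at configurable offsets on a Poisson
background; `synthetic_genome()` lays out operons in same-orientation runs
so both eligible (tandem) and ineligible (convergent) terminator contexts
and a non-empty control pool exist by construction.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: image-level effects (PSFs, spot overlap,
drift), transcriptional pausing (elongation is constant-rate by
assumption), sequence-dependent sliding, correlated or overdispersed
Rend-seq backgrounds, and peak shadows.  Parameter recovery here validates
the estimators under the stated generative model, not the microscopy.

## 7. Problem sizes and numerical choices

Tests and the acceptance script run at desk scale: cohorts of 60–80
molecules at 350–400 frames; 100-replicate lifetime-coverage and
random-control studies; ~2-Mb synthetic genomes with 300 terminators; 600
independent 50-s windows for the diffusion-mode study; 1000 random
instances for the MLE-oracle equivalence.  Bootstrap defaults: 1000
resamples (400 inside the coverage study), percentile CIs, all seeded.
Optimiser: `nlsLM` with up to 200 iterations and positivity bounds on
amplitudes and rates; episode fits pin the offset to the calibrated
background.  Ties and degenerate inputs: leftmost tie-breaking for peak
positions, earliest-episode tie-breaking for behaviour calls, flagged (not
thrown) unphysical lifetimes and rates, and errors with line numbers for
malformed trace files.

## 8. Known limitations

* The behaviour classifier is a reproducible surrogate for expert visual
  screening; its false-positive/negative trade-off is tuned by
  `amp_factor`, `min_r2` and `resid_factor`, and truncated episodes (RNAP
  lost mid-retrace) are detected on a best-effort basis.
* Windowed-D values on short templates are confinement-suppressed apparent
  coefficients; compare them against thresholds on the same footing, not
  against microscopic D.
* The flipping of RNAP orientation on DNA that antisense re-initiation
  implies has no observable in this data model and is not inferred.
* `Δ` quantities are raw log₂ peak counts; no library-size normalisation
  is applied, so cross-dataset comparisons require externally normalised
  tracks.
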