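# termcycle

Analysis of the alternative bacterial transcription cycle: what core RNA
polymerase (RNAP) does *after* intrinsic termination.  In single-molecule
TIRF experiments, RNAP released from its transcript usually stays bound to
the template DNA, switches between one-dimensional sliding and immobile
("stuck") states, and can re-initiate transcription — most often in the
antisense direction from a promoter-like sequence near the terminator.
`termcycle` implements the quantitative machinery for this analysis and a
genome-scale companion analysis of end-enriched RNA sequencing (Rend-seq)
tracks, plus seeded synthetic-data generators so the whole pipeline is
testable without any external data.

## Who this is for

Single-molecule biophysicists working with multi-channel fluorescence
intensity records of surface-tethered transcription templates, and
microbial genomicists asking whether intrinsic terminators are associated
with nearby antisense initiation in Rend-seq data.

## The models at the core

**Intensity-to-position calibration.**  Under TIRF illumination the
emission of a labelled RNAP decays exponentially with distance from the
coverslip.  With a constant elongation rate, the elongation phase follows

    I(t) = I_P exp(-λ t) + I_mn

where `I_P` is the promoter-proximal amplitude, `I_mn` the background and
`λ` the decay constant.  Writing `z(t) = r_RNAP t + z_P` for the position
along the contour and measuring the intensity at termination `I_T = I(t_T)`
(the moment the transcript probe departs), the elongation rate is

    r_RNAP = (z_T − z_P) / [ λ⁻¹ ln( I_P / (I_T − I_mn) ) ]

and any post-termination intensity maps back to position:

    z(t) = r_RNAP λ⁻¹ ln( I_P / (I(t) − I_mn) ) + z_P.

**Sliding.**  Post-termination motion is modelled as a bounded 1D random
walk.  Time-averaged MSD curves are computed in 50-s windows; a straight
line through the first ten lag points gives `D = slope/2`.  A molecule is
scored as sliding when any window reaches `D ≥ 2.2 × 10⁴ bp² s⁻¹`.
Antisense (or sense) secondary initiation is scored when a post-termination
intensity episode fits the mirrored elongation profile with a rate constant
in 0.002–0.04 s⁻¹.

**Lifetimes.**  Observed spot-loss times mix true dissociation with
photobleaching and right-censoring by the end of acquisition.  The
censored-exponential MLE is `k_obs = n_uncensored / Σ t_i`; the dissociation
rate is `k_RNAP = k_obs − k_PB` and the lifetime `1/k_RNAP`, with bootstrap
errors.

**Drift under force.**  The Einstein–Smoluchowski relation
`D = k_B T v_d / F` predicts how fast a sliding RNAP is dragged along DNA by
an optical-trap force.

**Rend-seq.**  At each terminator, sense termination is quantified as
`Δ_S = log₂(k_max)` (peak 3′-end count, same strand, 10-bp window) and
antisense initiation as `Δ_AS = log₂(k_max2)` (peak 5′-end count, opposite
strand, ±500 bp).  Peaks are called by z-score against local flanks
(threshold z > 12), distance profiles are built in 200-nt bins, and a
constrained random-location control (positions >700 nt from any terminator,
inside runs of ≥3 same-orientation genes) provides an empirical p-value.

## Worked example

```r
library(termcycle)

cfg <- trace_sim_config(seed = 7)          # 2.1-kb template, 2-s frames
sim <- simulate_trace(cfg)
fit <- fit_elongation_decay(sim$trace, c(sim$truth$t_start, sim$truth$t_T))
fit
#> Elongation decay fit  I(t) = I_P exp(-lambda t) + I_mn
#>   I_P = 789.4   I_mn = 117.8   lambda = 0.01918 /s
#>   window [20, 73.3468] s   residual SD 18.7   converged: TRUE

# measured RNAP intensity at termination (last elongation frames)
el <- sim$trace$time_s < sim$truth$t_T
I_T <- mean(tail(sim$trace$I_rnap[el], 3))
compute_elongation_rate(fit, I_T, z_P = 0, z_T = 2100)$r_RNAP
#> [1] 40.73863           # bp/s; this molecule's true rate is 39.37

drift_velocity(D = 4e3, F_pN = 3, T_K = 300, traversal_nm = 150)[
  c("v_d", "traversal_s")]
#> $v_d
#> [1] 2897.188            # nm/s: ~3e3 at one significant figure
#> $traversal_s
#> [1] 0.05177434          # a trapped slider exits ~150 nm of DNA in ~0.05 s
```

The fitted `λ` recovers this molecule's decay constant (truth 0.01875/s),
the elongation rate lands within 4% of the simulator truth, and the drift
prediction shows why a sliding post-termination RNAP that survives for
hundreds of seconds untouched appears to dissociate in well under a second
when held under a few piconewtons in a trap.

A full end-to-end run (trace cohort → calibration → motion → kinetics →
Rend-seq → JSON report) is one call:

```r
report <- run_pipeline("out", seed = 1, n_molecules = 20)
```

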