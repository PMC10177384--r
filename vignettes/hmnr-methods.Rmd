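---
title: "Methods: MEA analysis and the hMNR assay in hmnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA analysis and the hMNR assay in hmnr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmnr)
```

## The problem

Multi-well microelectrode arrays (MEAs) record extracellular voltages from
cultured neuronal networks — here, hiPSC-derived 3D neural cultures plated
onto 96-well plates with 8 electrodes per well, sampled at 12.5 kHz in
15-minute phases. Classical MEA endpoints (firing rate, bursts, network
bursts) integrate over whole electrodes and therefore miss the responses of
individual neurons with opposite pharmacology. The human
multi-neurotransmitter receptor (hMNR) assay addresses this by spike sorting:
each electrode's spikes are split into putative single neurons ("units"),
units are classified into neurotransmitter-receptor subtypes by their
firing-rate fold changes under identification agents, and test compounds are
then read out per subtype across cumulative concentrations.

`hmnr` implements the full chain — simulation, detection, sorting, metrics,
assay, statistics — with a ground-truth simulator in place of hardware, so
every stage is testable against known truth.

## Spike detection

Traces are band-pass filtered to 200–3000 Hz with a 4th-order Butterworth
applied forward and backward (zero phase, so trough times are unbiased).
A forward–backward pass squares the magnitude response, which would pull the
−3 dB points inside the nominal band by roughly 25% at the low edge; the
design edges are therefore pre-warped by solving the exact digital transfer
function (`uniroot` at design time) so the *combined* −3 dB points land on
200 and 3000 Hz.

The detection threshold is −6× a rolling robust estimate of the noise RMS:
the windowed median of |x| scaled by 1/0.6745. The median ignores the spikes
themselves, so thresholds track slow noise changes without being inflated by
activity. The window is 0.1 s by default: a rolling median over `k` samples
has relative standard deviation ≈ 1.17/√k, so 0.1 s (1250 samples) gives
~3% precision while a 10 ms window would fluctuate by ~10% and visibly
modulate the threshold. Negative-going crossings are aligned to the local
trough; events closer than the 1 ms dead time collapse to the
larger-amplitude one (sequential scan, which keeps the detected count
monotone in the threshold); cutouts are 0.84 ms before and 2.16 ms after the
trough — at 12.5 kHz, 11 + 27 = 38 samples with the trough at sample 12,
the pre-window rounded up to whole samples. Cutouts overlapping a trace edge
are discarded. An electrode is *active* at ≥ 2 spikes/min (inclusive).

Degenerate inputs: an all-zero trace yields a zero RMS estimate and no
events; traces shorter than the filter's padding requirement raise an
explicit length error.

## Spike sorting

Sorting is strictly per electrode, on the pooled cutouts of a baseline plus
its treatment phases, so unit identity persists across phases. Cutouts are
projected onto the three leading principal axes of the electrode's waveform
set (sign fixed so the largest-magnitude loading is positive, making the
projection deterministic), then clustered with a mixture of multivariate
t-distributions with 10 degrees of freedom and 20 initial components,
initialized by seeded k-means.

The EM iterations are the standard ones for fixed degrees of freedom:
responsibilities and latent precision scales
`u = (dof + d)/(dof + Mahalanobis²)` in the E-step; weights, u-weighted
means, and u-weighted full 3×3 scatter matrices in the M-step. The
observed-data log likelihood is non-decreasing along a run. Model complexity
shrinks by two mechanisms *between* runs, each restarting the monotone
segment:

* **weight pruning** — components below weight 0.5/k_init are dropped;
* **consolidation** — the closest pair of components is merged
  (moment-matched) when their means lie within 4 Mahalanobis units on the
  average scatter, and EM re-runs to convergence.

Consolidation is what makes an over-specified start collapse to the true
number of units: plain EM gets stuck in local optima where fragments of one
cluster each retain substantial weight, and no weight threshold can remove
them. Fragments and nested outlier-catchers of one cluster lie a couple of
Mahalanobis units apart, while distinct units at the separations this
pipeline sorts (≥ 8× the within-cluster scale) lie far beyond the threshold,
so 4 is an uncritical midpoint; `merge_threshold = Inf` disables the
mechanism. Scatter matrices are regularized only if numerically singular,
and such iterations are flagged like restarts, keeping the ascent guarantee
exact elsewhere.

Spikes go to their maximum-responsibility component; clusters under 10
spikes dissolve into an outlier pool that is retained in outputs but
excluded from assay statistics. Electrodes with fewer than four waveforms
are kept as a single unsorted unit with a logged warning. Units with a
baseline rate ≥ 2 spikes/min (inclusive) enter the analysis.

## Well metrics

*Bursts* are maximal runs of ≥ 5 spikes with all inter-spike intervals
≤ 100 ms (greedy maximal-run semantics: a run ends at the first gap above
threshold). The implementation is run-length based and is tested for exact
agreement against a brute-force one-spike-at-a-time oracle.

The *weighted mean firing rate* (wMFR) is total spikes on active electrodes
divided by duration × number of active electrodes.

*Network bursts* use an envelope construction: all well spikes are binned at
25 ms, smoothed with a discrete Gaussian of σ = 1 bin, and thresholded at
1.25× the phase-mean envelope; contiguous supra-threshold intervals are
candidates. A candidate is kept when the electrodes *with an ISI burst
overlapping it* make up ≥ 35% of the well's electrodes (denominator: all
electrodes in the well). Kept candidates separated by < 100 ms merge;
boundaries tighten to the smallest interval holding 75% of the candidate's
spikes, trimmed equally from both tails; participation is re-checked on the
tightened interval. Intervals are half-open `[start, end)` during binning; a
network burst's reported boundaries are the first and last retained spike.

Two choices here deserve justification. First, participation counts
*bursting* electrodes rather than electrodes with any stray spike: a network
burst is an episode of simultaneous bursting, and at realistic firing rates
a mean-anchored envelope threshold sits well inside Poisson fluctuations, so
a spike-based participation rule would flag asynchronous activity
constantly, while the burst-based rule leaves homogeneous Poisson input
essentially empty and still scores every synchronous volley. Second,
participation is filtered *before* inter-burst-interval merging: merging
first could fuse two individually failing candidates into one passing one,
so the network-burst count would not be monotone in the merging interval.
Both the four headline parameters and every internal (bin width, smoothing,
threshold anchor, trimming) are exposed as parameters and written to run
manifests.

The *network burst percentage* is the share of the well's spikes that fall
inside network bursts; a well with zero spikes reports 0 with a flag.

## The hMNR assay

Fold change is the unit's phase rate over its reference-baseline rate.
Identification phases (neurotransmitter, antagonist) reference the first
baseline; test-compound phases reference the second baseline recorded after
washout — both bindings are configurable per phase. Units inactive in the
relevant baseline are excluded from that comparison. A unit *responds* when
its fold change is ≥ 1.25 or ≤ 0.75, both inclusive ("at least ±0.25").

Subtype rules are conjunctions of (agent, direction) clauses, fully
overridable: glutamatergic = increase under glutamate *and* decrease under
AP5/NBQX (both vs baseline 1); GABAergic = opposite-signed responses to GABA
and bicuculline, mature (GABA↓, bicuculline↑) vs immature (GABA↑,
bicuculline↓), reflecting the developmental GABA switch; dopaminergic /
serotonergic / cholinergic = responder in either direction under
haloperidol / buspirone / carbaryl. A unit may satisfy several rules and
then carries all labels. With the default rule set, rules whose agents are
absent from the plan are skipped; an explicitly supplied rule naming an
absent agent is a configuration error.

Concentration–response aggregation reports, per cumulative concentration and
per group (all analyzable units, plus one group per subtype), the unit
count, mean fold change ± SEM over units, responder counts per direction,
and percent responding. Percentages use baseline-active units as the
denominator; groups with no units are absent rather than zero.

## Group statistics

Well-level endpoints are compared with the branching scheme standard for MEA
data: the Brown–Forsythe test (Levene on absolute deviations from group
medians, via `car::leveneTest`) decides at α = 0.05 between one-way ANOVA
with Dunnett many-to-one contrasts (`multcomp::glht`, i.e. the exact
equicoordinate multivariate-t quantile) and Welch ANOVA with Games–Howell
all-pairs comparisons. Games–Howell is implemented directly: each pair's
mean difference over its Welch standard error, referred to the studentized
range with the pair's Welch–Satterthwaite degrees of freedom.

The test suite validates both post hoc procedures against seeded Monte-Carlo
null distributions (10⁶ draws): Dunnett's critical values agree with the
max-|t| null quantiles to a fraction of a percent for k = 3–6, n = 8. For
Games–Howell the natural check normalizes each pair's statistic by its own
adjusted critical value, whose max should have null 95% quantile 1; the
procedure meets a 2% band at k = 3–5 but is itself ≈ 2.1% anti-conservative
at k = 6, which the suite reports rather than hides. Note that in this
pipeline Games–Howell only ever runs on data the Brown–Forsythe gate has
flagged heteroscedastic.

## The simulator

The simulator is the package's ground truth, not a fixture: units carry a
subtype, a baseline rate, burstiness, a biphasic waveform template (narrow
Gaussian trough, broader positive overshoot, 3 ms support, trough normalized
to −1), and an amplitude in multiples of the noise RMS.

Firing is a two-state renewal process: tonic inter-spike intervals are a
2 ms refractory floor plus an exponential tail; each tonic spike starts,
with probability 0.1, a burst epoch of Poisson(5) extra spikes at 10–30 ms
intervals. The tonic mean is solved so the overall mean rate equals the
target, so empirical rates are unbiased at any burstiness; with bursts
disabled, counts are slightly under-dispersed relative to Poisson (the
refractory floor), so Poisson-tail bounds on counts hold. Pharmacology
enters as a (subtype, agent[, concentration]) → rate-multiplier table; an
agent missing from the table entirely is a configuration error, while a
known agent defaults to multiplier 1 for unlisted subtypes.

Default study conditions: 8 electrodes/well, 12.5 kHz, 900 s phases,
baseline rates log-uniform on 0.5–3 Hz (typical of hiPSC-derived cultures,
and comfortably above the 2 spikes/min activity floor), amplitudes uniform
on 8–12× noise RMS, and directionally correct multipliers (glutamate ×2 on
glutamatergic units, AP5/NBQX ×0.3, GABA ×0.5 / bicuculline ×2 on mature
GABAergic units and mirrored for immature ones, haloperidol ×2, buspirone
×0.5, carbaryl ×0.5, TMT ×2 on glutamatergic, emamectin ×0.4 on GABAergic).

Traces are the linear sum of templates placed at spike times plus
band-limited noise: white noise filtered to 200–3000 Hz and scaled so that
its RMS *after the detection-side filter* equals the requested value (a
second pass trims transition-band energy by a few percent, which the scaling
anticipates). Noise streams are keyed by (seed, well, electrode, phase), so
rendering a subset of units reproduces the identical noise realization and
superposition holds exactly. There is no electrode crosstalk, drift, line
noise, stimulation artifact, or LFP; spike shapes are stationary; spheres'
spatial geometry is not modeled — a well is a single source population.
Passing tests therefore demonstrate correctness of the analysis chain under
these idealized conditions, not robustness to every artifact of real
recordings.

## Problem sizes

The shipped suite exercises: the burst detector against the brute-force
oracle on 1,000 random trains of 10–10,000 spikes; detection on 8
electrodes × 900 s at 8–12× noise RMS plus a 900 s pure-noise electrode;
sorting on 50 simulated electrodes of 1–3 units (150–400 spikes each) at
waveform level, where detection has been validated separately; the hMNR
classification on 8 wells × 8 electrodes × 2 units over five 900 s phases
using ground-truth spike trains; and the Monte-Carlo statistics nulls at
10⁶ draws. The end-to-end rendered pipeline (`run_pipeline`) is smoke-tested
at reduced durations; `demo_config()` uses 120 s phases for the same reason.

## Known limitations

* The vendor's exact adaptive-threshold estimator, sorting initializer,
  outlier handling, and envelope internals are unpublished; the choices here
  are documented stand-ins exposed as parameters.
* No drift correction or overlap deconvolution: near-coincident spikes on
  one electrode within the dead time merge into one event.
* EC50/IC50 fitting is out of scope — the assay reports fold changes, as
  does the concentration–response table.
* The statistics module reports, but does not act on, groups with zero
  variance and n = 2; a nonparametric fallback is deliberately not
  attempted.
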