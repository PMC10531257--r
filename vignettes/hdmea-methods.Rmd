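---
title: "Methods: HD-MEA activity, connectivity and current-source-density analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HD-MEA activity, connectivity and current-source-density analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmea)
```

## Scope and data model

`hdmea` analyses extracellular recordings from high-density multielectrode
arrays (HD-MEAs): CMOS chips carrying a rectangular electrode grid — by
default 64 × 64 electrodes of 21 µm at 42 µm pitch (a 2.67 × 2.67 mm
active area) sampled at 9 kHz — under dissociated neuronal cultures or
acute/organotypic brain slices. The pipeline covers four analysis layers:

1. **Spike topology** — spike detection, number of spikes (NOS), mean
   firing rate (MFR), interspike intervals (ISI), single-electrode bursts
   and array-wide network bursts.
2. **Functional connectivity** — a directed graph inferred from
   millisecond spike timing, characterized by clustering coefficients
   (CC), shortest path lengths (PL), node degrees (ND) and
   sender/receiver/broker node roles.
3. **Local field potentials (LFP)** — low-pass filtering, double-threshold
   event detection, energy-based duration, refractory enforcement,
   area-coincidence cleaning and per-electrode/per-area feature tables.
4. **Current source density (CSD)** — saturation inpainting, spatial
   smoothing, a 9-point two-dimensional Laplacian, Hilbert-envelope
   selection of a region and time window of interest (ROI/TOI), and the
   average rectified CSD (rCSD) scalar.

The voltage carrier is an `mea_recording`: a µV-valued array indexed
`[row, col, sample]` plus sampling metadata, stored on disk in an HDF5
container (`write_recording()` / `read_recording()`). Everything derived
from it — spike trains, bursts, events, metrics — is a tibble, so results
compose with ordinary dplyr/ggplot2 workflows. Anatomical areas (e.g. DG,
CA1, CA3 of a hippocampal slice) enter as JSON masks mapping area names to
electrode lists; the package deliberately has no interactive
electrode-picking step.

Because proprietary acquisition systems dominate this instrument class,
every stage is validated against the package's own synthetic generator
rather than against any vendor software: the generator plants spikes,
LFP waves and dipole fields with known parameters, and the test suite
measures recovery.

## Synthetic recordings

`synthesize_spike_trains()` draws, per active electrode, an inhomogeneous
Poisson train whose rate switches between `base_rate` and
`base_rate × burst_rate_multiplier` under a two-state continuous-time
Markov modulator (`burst_on_rate`, `burst_off_rate`). This is the minimal
model that produces single-electrode bursts, and — because modulators are
independent — occasional chance alignment that exercises the network-burst
detector. Defaults: 2 spikes/s baseline, ×10 in bursts, on/off rates
0.05/0.5 s⁻¹, 80% of electrodes active.

`synthesize_recording()` renders three additive components:

* a biphasic ~1 ms spike waveform (one sine cycle, negative lobe first,
  default 60 µV peak) at every spike time;
* LFP waves: space–time separable deflections with Gaussian spatial
  envelope (`spatial_sigma` in pitches), double-exponential time course
  (default rise 5 ms, decay 20 ms) travelling radially from a center at
  `propagation_speed` (electrodes/ms). The analytic peak amplitude,
  arrival time and spatial footprint are recorded as ground truth; the
  planted ROI is the half-maximum footprint of the wave envelope;
* white Gaussian noise of SD `noise_sd`.

Signal-to-noise ratio (SNR) for recovery experiments is defined at the
generator level: planted wave peak amplitude divided by the additive
noise SD. All randomness flows from one seed per call; identical seeds
give identical output, bit for bit.

What the generator does **not** emulate: spatially correlated noise,
electrode-to-electrode gain drift, volume-conductor forward fields,
biophysical spike waveform diversity, or the non-stationarity of
developing cultures. Passing recovery tests therefore demonstrates the
correctness of the analysis chain, not detector performance on real
tissue.

`synthesize_cohort()` provides a two-condition contrast for
direction-of-effect testing: the `"hyper"` preset raises baseline rate
(1.5 → 3.5 spikes/s), burst onset rate (0.05 → 0.10 s⁻¹), planted LFP
event rate (0.10 → 0.30 events/s) and wave amplitude (150 → 300 µV)
relative to `"control"`, emulating a hyperexcitable culture/slice. The
factors are fixed documentation, not fits. Cohort recordings default to a
12 × 12 grid, 30 s at 3 kHz — desk-scale conditions under which the full
chain (spikes → LFP → CSD) runs in seconds per recording; the contrast is
qualitative (direction and significance), so grid size only affects
statistical power, which the tests demonstrate is ample.

## Spike analysis

The spike detector thresholds each electrode at
`sd_factor × median(|x|)/0.6745` — the median-absolute-deviation noise
estimate, insensitive to the spikes themselves — and registers a spike at
every negative-going local extremum beyond threshold (`polarity = "both"`
admits positive extrema too), with a 1 ms dead time (first-kept).
Defaults: `sd_factor = 5`. These choices are deliberately conventional:
where acquisition software hides its detector, a transparent standard one
is the only reproducible substitute, and all figures of merit are defined
against synthetic ground truth (recall and precision ≥ 0.95 at SNR 10 in
the suite).

Bursts use the max-ISI definition: maximal runs of ≥ `min_spikes` (5)
consecutive spikes with every gap ≤ `max_isi_ms` (100 ms). Network bursts
bin time at 10 ms and mark bins where ≥ 20% of active electrodes are
inside a burst; contiguous marked bins merge. An electrode is "active"
for spike metrics at ≥ 0.1 spikes/s. All four numbers are configurable;
the defaults are the package's documented convention, chosen from common
practice for cortical cultures on MEAs.

`spike_statistics()` reports NOS, MFR = NOS/duration and mean ISI per
electrode; ISI is undefined below two spikes and such electrodes are
excluded from pooled ISI summaries rather than imputed. `activity_map()`
lays MFR on the grid and conserves activity exactly
(`sum(map) × duration = total NOS`).

## Connectivity

`infer_connectivity()` bins the cross-correlogram of every ordered pair
of active electrodes over lags (0, 150] ms at 5 ms and compares its peak
with surrogates in which the target train is uniformly jittered within
±50 ms (20 surrogates). Jittering preserves rates and slow comodulation
while destroying fine timing, so exceedance of
`mean + z(α) × SD` (α = 0.001) is specific to millisecond coupling. Edge
weight is the standardized exceedance; edge lag the winning bin center.
This is a deliberately standard, fully disclosed method occupying the
place of undocumented vendor connectivity maps; its absolute edge counts
are not comparable to any particular vendor output, and the tests
therefore check construction (a +5 ms shifted train yields exactly the
A→B edge) and specificity (a binomial false-positive bound), not
replication.

Graph metrics run on the undirected simple view (igraph): local
clustering (0 where degree < 2), mean BFS path length over *reachable*
pairs — unreachable pairs are excluded rather than set to infinity, which
keeps pooled box plots finite on fragmented developing networks — and
degree. Electrodes in no edge are dropped from metrics. The pooled
summary includes the PL value at a cumulative node-count fraction
(default 0.70). Node roles use the directed degrees: sender if
out > 2 × in, receiver if in > 2 × out, broker otherwise.

## LFP analysis

The LFP chain applies, in order:

1. **Filtering** — causal single-pass Butterworth low-pass, 200 Hz,
   order 5. Butterworth is the natural reading of an unqualified "IIR
   low-pass" (maximally flat passband); single-pass keeps the effective
   order at 5, where a zero-phase double pass would square the magnitude
   response. The −3 dB point at 200 Hz and ≥ 30 dB at 1 kHz are asserted
   in the suite on pure tones.
2. **Detection** — hard double threshold at +40/−40 µV: every maximal
   excursion beyond either threshold seeds an event; the peak is the
   excursion's extremum, the amplitude the signed voltage there. Events
   closer than the 50 ms refractory period merge, first-kept (a
   `"largest"` policy is available; which of two close events should
   survive is a genuine convention choice).
3. **Duration** — a 50 ms energy window slides sample-by-sample forward
   and backward from the peak while its mean-square energy exceeds 1.5 ×
   the noise energy; the duration is the span between stopping points.
   The noise energy is the *median* windowed energy of the whole trace —
   robust so long as events occupy under half the windows, and requiring
   no separate noise epoch. If the energy is already at threshold at the
   peak the event receives the minimal one-window duration and a flag.
   Event energy is `Σ|V|·Δt` (µV·ms) over the duration span.
4. **Activity** — an electrode is active at ≥ 0.05 events/s.
5. **Cleaning** — an event is valid only if, within a ±150 ms half-window
   (300 ms total), at least 40% of its area's *total* electrodes (not
   only the active ones — "total" is read literally) host an event.
   Comparisons are inclusive ("at least"). Invalid events are retained
   with `valid = FALSE`; events outside every area are dropped with a
   logged count.
6. **Features** — per-electrode means of amplitude, duration and energy
   over valid events, rate in events/min, pooled per area.

The detector is verified event-for-event against an independent
brute-force scan (explicit sample enumeration plus explicit refractory
merge) on 1,000 random seeded traces, and the count is monotone
non-increasing in the threshold magnitude.

*Recovery semantics.* At zero noise a planted wave train is recovered
exactly. At SNR 5 (e.g. 300 µV peak over 60 µV generator noise) the fixed
±40 µV threshold sits ~3 in-band noise SDs above baseline, so occasional
noise excursions are mathematically unavoidable (Rice's crossing-rate
formula puts them near 1/s); recovery is therefore measured as *recall* —
the fraction of planted events matched by a detection on the same
electrode within ±100 ms — which the suite requires within 10%.
False-positive control is the separate job of the oracle-equivalence
check and the area-coincidence cleaning stage, whose 4-of-10 retain /
3-of-10 reject boundary behavior is asserted exactly.

## CSD analysis

Preprocessing: saturated samples (|V| ≥ 4000 µV by default; the level is
configurable since amplifier rails vary) are inpainted per frame by
discrete harmonic extension — iterated 4-neighbor averaging with the
valid electrodes as boundary data — which is the natural 2-D "linear
interpolation from surrounding regions": it reproduces planar gradients
exactly and reduces to the neighbor mean for isolated holes. Frames more
than half saturated raise an error instead of being invented, and the
before/after energy ratio of inpainted samples is reported for artifact
auditing. The potential is then smoothed per frame with a Gaussian kernel
of σ = 1 pitch, truncated at 3σ and renormalized at the grid boundary (a
constant field is a fixed point; the Gaussian semigroup property holds in
the interior to within the truncation error).

The CSD is the negated modified two-dimensional Laplacian on the 9-point
stencil,

$$\mathrm{CSD} = -\Big[\tfrac{2}{3}\big(\phi_E+\phi_W+\phi_N+\phi_S-4\phi\big)
 + \tfrac{1}{6}\big(\phi_{NE}+\phi_{NW}+\phi_{SE}+\phi_{SW}-4\phi\big)\Big],$$

computed at interior electrodes only; the one-electrode boundary ring is
flagged invalid rather than padded, since padding invents data. The
stencil carries no $1/\Delta^2$ factor, so values are reported in
arbitrary units of µV/pitch²; sinks are negative, sources positive. Three
analytic properties anchor the implementation: the delta response is
exactly $10/3$, separable sinusoids reproduce the $(k_x^2+k_y^2)\phi$ law
within 2% at $k = 0.2$ rad/pitch with error vanishing as $k \to 0$, and
the interior sum of a compactly supported field telescopes to zero.

ROI/TOI selection works on the Hilbert amplitude envelope
$A(x,y,t) = |\mathcal{H}[\phi](x,y,t)|$, computed per electrode after
mean-centering (a DC offset corrupts the envelope; the transform itself
is the standard FFT construction with doubled positive frequencies). The
amplitude variability is $\xi(x,y) = \mathrm{SD}_t[A]$, and the ROI is
selected by the strict inequality
$\xi > \mathrm{median}(\xi) + 2.326\,\mathrm{SD}(\xi)$ — the constant is
applied exactly as specified (it is the normal 99th percentile; no
further rationale is assumed), and an empty ROI is a flagged, legal
outcome. Note that $\xi$ responds to *event-like* envelope modulation: a
steady oscillation has constant envelope and $\xi \approx 0$, which is
why the test fixtures gate their planted dipoles on and off. TOI: with
$\mu_\text{noise}, \sigma_\text{noise}$ the mean and SD over non-ROI
electrodes of the time-averaged amplitude $\bar A$, each ROI electrode's
TOI is the sample set with
$A > \mu_\text{noise} + 2.326\sqrt{2}\,\sigma_\text{noise}$ (the
$\sqrt 2$ factor likewise applied literally). The ROI covering the whole
grid is an error (no noise complement). Finally
$\mathrm{rCSD} = \mathrm{mean}\,|\mathrm{CSD}|$ over all (ROI electrode,
TOI sample) pairs — NA, never a silent zero, when the mask is empty.
`sink_source_frames()` splits signed frames into sink (CSD < 0) and
source (CSD > 0) components that re-sum exactly.

A practical consequence of the printed TOI rule worth knowing: its
threshold keys on the *between-electrode* spread of mean amplitude. On
arrays whose non-ROI electrodes are statistically identical that spread
is small and the threshold sits close to the noise envelope mean, so
quiet samples leak into the TOI; with realistic electrode gain spread the
rule separates cleanly. The package applies the rule as printed and
leaves the interpretation to the analyst.

## Pipeline, configuration, statistics

`run_pipeline()` executes synthesis/ingest → spikes → network → LFP → CSD
as toggled from a YAML config (unknown keys are rejected so typos fail
loudly), writes CSV/JSON/GraphML artifacts plus a manifest echoing every
parameter, and derives per-stage seeds from the global seed by fixed
offsets so toggling one stage never reshuffles another's randomness.
Deterministic artifacts are bit-identical across re-runs, which the suite
asserts. Group comparison uses the unpaired two-tailed Welch t-test
(`welch_test()`, a thin wrapper over `stats::t.test` with
Welch–Satterthwaite degrees of freedom), checked against a closed-form
hand computation.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale:
1,000 random 2 s traces for the detector oracle, 1,000 random ≤ 12-node
graphs for the metric oracle, 32 × 32 grids for the analytic CSD checks,
and 10 + 10 cohort recordings (12 × 12, 30 s, 3 kHz) for the condition
contrast. These sizes were chosen so each property is exercised well past
its asymptotic regime while the whole suite remains a coffee-break run;
none of the algorithms depends on grid size except linearly in work.

Tolerances: exact equality is asserted wherever the algorithm is exact
(stencil responses, partition identities, boundary-inclusive rules);
floating-point identities use `1e-12` relative tolerance; stochastic
recoveries use 3-standard-error bands or the stated 10%/Jaccard-0.8
bounds under fixed seeds. Tie-breaks and boundary conventions are all
inclusive-≥ and first-kept unless documented otherwise.

## Known limitations

* The spike detector and connectivity method are transparent standards,
  not reconstructions of any vendor's pipeline; absolute spike counts,
  edge densities and derived metrics are not comparable across software.
* LFP energy is the rectified voltage–time integral in µV·ms; published
  "energy" figures from other pipelines may use different normalizations.
* CSD units are relative (no conductivity model, no 1/pitch² scaling);
  only within-study comparisons such as the control/hyper contrast are
  meaningful.
* Harmonic inpainting is trustworthy for sparse saturation; the 50%
  per-frame guard is a hard stop, not a quality guarantee.
* The synthetic cohort demonstrates the pipeline's ability to resolve a
  planted contrast; it says nothing about effect sizes in real tissue.
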