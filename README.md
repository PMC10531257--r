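# hdmea

Analysis of high-density multielectrode array (HD-MEA) extracellular
recordings in R: spike and burst topology, functional-connectivity graphs,
local field potential (LFP) event detection, and two-dimensional current
source density (CSD) — plus a ground-truthed synthetic recording generator
so the whole chain is testable without any acquisition hardware.

## Who this is for

Electrophysiologists working with CMOS HD-MEA chips (thousands of
electrodes on a rectangular grid, e.g. 64 × 64 at 42 µm pitch, 9 kHz
sampling) under dissociated neuronal cultures or hippocampal slices, who
need a transparent, scriptable alternative to vendor analysis software for:

- **Activity topology** — number of spikes (NOS), mean firing rate (MFR),
  interspike intervals (ISI), per-electrode bursts (max-ISI rule) and
  array-wide network bursts;
- **Functional connectivity** — directed graphs from cross-correlogram
  peaks tested against jitter surrogates, with clustering coefficient
  (CC), path length (PL), node degree (ND) and sender/receiver/broker
  roles per node;
- **LFP events** — order-5 Butterworth low-pass at 200 Hz, hard double
  threshold at ±40 µV, energy-walk duration (50 ms window, 1.5 × noise),
  50 ms refractory period, 0.05 events/s activity criterion, and
  area-coincidence cleaning ("at least 40% of an area's electrodes within
  300 ms");
- **CSD** — saturation inpainting, Gaussian smoothing (σ = 1 pitch), the
  9-point Laplacian

  `CSD = -[(2/3)(φE+φW+φN+φS-4φ) + (1/6)(φNE+φNW+φSE+φSW-4φ)]`,

  Hilbert-envelope ROI selection (`ξ > median(ξ) + 2.326·SD(ξ)`), TOI
  selection (`A > μ_noise + 2.326·√2·σ_noise`), and the rectified CSD
  scalar rCSD = mean |CSD| over the ROI/TOI.

Recordings travel in an HDF5 container; derived results are tibbles that
compose with dplyr and ggplot2 (`autoplot()` methods included).

## Worked example

```r
library(hdmea)

# one synthetic "hyperexcitable" recording with known ground truth
rec <- synthesize_cohort("hyper", 1, seed = 42,
                         grid = electrode_grid(12, 12),
                         duration = 30, sampling_rate = 3000)[[1]]$recording

spikes <- detect_spikes(rec)                    # robust-SD threshold, 5 x MAD
stats  <- spike_statistics(spikes)
glance(stats)[, c("n_electrodes", "total_nos", "mfr_median")]
#> # A tibble: 1 × 3
#>   n_electrodes total_nos mfr_median
#>          <int>     <int>      <dbl>
#> 1          128     31906       7.38

bursts <- detect_bursts(spikes)                 # max ISI 100 ms, >= 5 spikes
burst_statistics(bursts)[, c("n_bursts", "mean_duration_ms", "burst_rate_per_min")]
#> # A tibble: 1 × 3
#>   n_bursts mean_duration_ms burst_rate_per_min
#>      <int>            <dbl>              <dbl>
#> 1     1231             392.               19.5

lfp <- lowpass_filter(rec)                      # 200 Hz, order 5, causal
events <- detect_lfp_events(lfp)
attr(events, "electrodes") |> dplyr::filter(active) |> nrow()
#> [1] 32                                        # active sites (>= 0.05 events/s)

recording_summary(rec)                          # MFR + LFP rate + rCSD in one row
#> # A tibble: 1 × 3
#>     mfr lfp_rate_per_min  rcsd
#>   <dbl>            <dbl> <dbl>
#> 1  8.31               18  2.74
```

The `mfr` column is the pooled mean firing rate in spikes/s over firing
electrodes; `lfp_rate_per_min` is the mean LFP event rate over active
electrodes; `rcsd` is the mean rectified CSD inside the Hilbert-selected
ROI/TOI, in µV/pitch² (arbitrary units — sinks negative, sources positive
before rectification). Comparing conditions uses the Welch unpaired
two-tailed t-test; `synthesize_cohort_recording()` generates cohort
members one at a time so only the summaries stay in memory:

```r
mfr_c <- purrr::map_dbl(1:4, function(i)
  recording_summary(synthesize_cohort_recording("control", i, seed = 1)$recording)$mfr)
mfr_h <- purrr::map_dbl(1:4, function(i)
  recording_summary(synthesize_cohort_recording("hyper", i, seed = 1)$recording)$mfr)
welch_test(mfr_h, mfr_c, labels = c("hyper", "control"))
#> Welch two-sample t-test: hyper (n=4, mean=8.507) vs control (n=4, mean=2.439)
#>   t = 10.1163, df = 3.17, p = 0.001629
```

A full configured run (synthesis → spikes → network → LFP → CSD, with CSV/
JSON/GraphML artifacts and a parameter manifest) is one call:
`run_pipeline("config.yaml")`, or from a shell,
`Rscript scripts/hdmea.R run --config config.yaml`.

## What it deliberately does not do

Spike sorting; reading proprietary vendor file formats; conductivity-aware
(kernel/iCSD) current-source models; GUI-based electrode-to-area
assignment (area masks are plain JSON files). The spike detector and
connectivity inference are documented standard methods, not
reconstructions of any vendor's pipeline — see
`vignettes/hdmea-methods.Rmd` for the full model description, parameter
meanings and limitations.
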