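---
title: "Models and methods behind neuroburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neuroburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroburst)
```

# Scope

neuroburst analyses spontaneous activity of cultured neuronal networks
recorded on a planar 8 x 8 multielectrode array (64 electrodes, 150 um
pitch, 20 kHz per channel) and, in parallel, somatic calcium-reporter
fluorescence sampled at 4 Hz. Five stages are chained: spike detection,
network-burst segmentation from the total spiking rate, burst activation
patterns, delayed-synchrony functional-graph inference with hub
statistics, and calcium transient detection. Because raw culture
recordings of this kind are rarely shareable, the package ships a
synthetic-data generator that plants spikes, bursts, directed connections
and calcium events with known ground truth; every quantitative claim the
package makes about itself is a ground-truth-recovery statement that the
test suite recomputes.

# Spike detection

The per-channel detection threshold is

$$T = N_S\,\sigma, \qquad \sigma = \frac{\mathrm{median}(|x|)}{0.6745},$$

where $x$ is the band-passed signal (zero-phase Butterworth, 0.3-8 kHz,
order 2 applied forward and backward) and 0.6745 is the 0.75 quantile of
the standard normal, which rescales the median absolute value of a
Gaussian background to its standard deviation. The median is barely
inflated by the spikes themselves, so the threshold is nearly independent
of firing rate; the suite checks that contaminating 1% of samples with
large-amplitude spikes moves $\sigma$ by less than 2%. The default
$N_S = 4$ reliably separates spikes of 30 uV and above from a 5 uV noise
floor.

Detection takes maximal runs of $|x| > T$ (both polarities), times each
spike at the extremum of its run, and discards further crossings within
the 1 ms minimal interspike interval. One refinement matters in practice:
a run must stay above threshold for at least `minWidth` = 0.1 ms (2
samples at 20 kHz). Band-passed Gaussian noise crosses $4\sigma$ in
isolated single samples at roughly one event per second per channel
(Rice's upcrossing rate for a 0.3-8 kHz band predicts the same order),
whereas a biphasic extracellular spike of 30 uV stays above a 20 uV
threshold for about 0.25 ms. The width rule therefore removes
essentially all noise crossings while leaving sensitivity at 99%+;
without it no threshold detector at $N_S = 4$ can keep false detections
below 0.5/s/electrode on Gaussian noise.

# Network bursts from the total spiking rate

The total spiking rate TSR(t) counts spikes from all electrodes in 50-ms
half-open bins. The burst threshold is $T_{Burst} = 0.1 \times
\sigma_{TSR}$, the standard deviation taken over the full series
including silent bins. A burst is a maximal run of consecutive
suprathreshold bins containing at least one bin in which four or more
distinct electrodes fire ("over four electrodes" is read inclusively,
>= 4, configurable). Burst boundaries are refined from bin edges to the
first and last spike inside the run; without this refinement a 50-ms bin
grid could not resolve durations to within 10%. Runs separated by at
least one subthreshold bin are never merged.

The activation pattern maps, for each electrode, the median over bursts
of its first-spike latency from burst start -- the footprint of how
excitation propagates across the array. The median is used because
single-burst maps are noisy under propagation jitter.

## Burst generator

Planted bursts follow a stationary renewal process: burst duration, plus
a minimum silent gap of 100 ms (two TSR bins), plus an exponential
waiting time that absorbs the remainder of the requested mean interval.
The minimum gap encodes the observation that cultures bursting at
several hertz do so quasi-periodically; it also guarantees that two
bursts are always separated by at least one complete TSR bin, so they
remain resolvable at the 50-ms resolution. At 5 Hz with 100-ms bursts the
interval budget is fully consumed by burst + gap and the process is
nearly periodic. Within a burst, an origin electrode fires first and each
participating electrode (the origin's nearest neighbours) follows at
distance/velocity plus non-negative Gaussian jitter (sd 0.5 ms, truncated
at zero so the origin always leads); participants then fire Poisson
trains at 100 spikes/s until burst end, which at the default 8 electrodes
per burst yields a few hundred spikes per burst, the scale reported for
mature cultures. Background activity is homogeneous Poisson per
electrode.

Duration-recovery calibration (test suite and `scripts/acceptance.R`)
uses rates of 0.5, 1, 2 and 5 Hz with duration ranges compatible with
each rate (100-1000 ms down to 100 ms at 5 Hz), 0.2 Hz background, and
around 350 planted bursts in total; the median relative duration error is
3-5%, within the 10% bound claimed for this class of detector. The
false-burst null is calibrated at a 0.1 Hz/electrode Poisson background
(below one false burst per minute); at much higher background rates the
>= 4-electrode criterion alone cannot reject chance coincidences within a
single 50-ms bin.

# Delayed-synchrony graphs

For an ordered electrode pair $(i, j)$ the expected axonal delay is
$\tau_{ij} = d_{ij}/v$ with distance $d_{ij}$ from the array geometry and
conduction velocity $v$ (default 0.4 m/s, the unmyelinated cortical axon
scale; the proportionality constant is a free parameter of the method).
A spike of $j$ at $t$ is *delayed-synchronous* with $i$ when $i$ fired
inside $[t - \tau_{ij} - \delta/2,\; t - \tau_{ij} + \delta/2]$; the
tolerance $\delta$ defaults to 2 ms. Each postsynaptic spike is counted
at most once, and

$$C_{ij} = \frac{n_{synchr}}{n_j} \in [0, 1]$$

normalizes by the postsynaptic spike count. Entries are marked undefined
whenever either electrode is silent: a fraction with $n_j = 0$ is not
computable, and a silent presynaptic row carries no synchrony evidence
either, so neither contributes to the edge-selection quantile below. The
implementation is exactly equivalent to a brute-force all-pairs window
scan (the suite asserts identity over random rasters), just faster via
sorted-array interval counting.

Edges are the entries strictly above the empirical 95th percentile of all
defined off-diagonal values -- the largest 5% of coefficients. Entries
tied in value are kept or dropped together, making the selection
deterministic and order-independent; if all values are equal the graph is
degenerate and empty. Hubs are electrodes whose incident-edge degree
exceeds the 90th percentile of nonzero degrees (or an explicit degree
cutoff); each hub reports its degree and its *hub coefficient*, the
ratio of its connections to the total number of edges, so coefficients
sum to 2 over the array. Hub overlap between two sessions is the Jaccard
index of the hub sets in percent -- the natural reading of "percentage of
overlap" for two sets of electrodes.

## Connectivity generator

`generateConnectedRaster` plants directed edges: presynaptic electrodes
fire Poisson trains and each spike is copied to the target with the
edge's transmission probability at exactly the distance-proportional
delay (only intrinsic spikes are relayed, no multi-hop chains).
`plantedHubConnectivity` arranges 4 hub sources on the central 2 x 2
block, each projecting to 4 targets three grid steps away along the
array axes. This layout is chosen so that recovery is well-posed: the
targets of a hub are equidistant from it and pairwise more than
$v\,\delta/2 = 400$ um apart, so two copies of the same source spike can
never masquerade as a delayed-synchronous pair between two targets.
With transmission probability 0.9, 2 Hz sources, 150 s and no
background, the planted entries saturate near 1, chance coincidences sit
near 0.004, and the top-5% rule recovers the planted edge set with
Jaccard >= 0.8 and the four sources as the four best-connected
electrodes.

# Calcium transients

Traces (relative fluorescence, 0-255) are smoothed by averaging
neighbouring frames, differentiated by first differences, and
thresholded at `accuracyCoef` times the standard deviation of the
derivative (default 2; the coefficient is a free parameter of the
method). A pulse opens where the derivative exceeds $+T$ on two
consecutive frames and closes at the last frame below $-T$ before the
next pulse; unterminated pulses close at the trace end, and events
separated by less than two frames are merged. The two-frame opening rule
is a deliberate debounce: white noise exceeds $2\,\mathrm{sd}$ on about
2.3% of frames, which at 4 Hz would alone produce several spurious
events per minute, while two consecutive independent exceedances occur
about once per eight minutes. Real transients sampled at 4 Hz rise over
several frames, so the rule costs no sensitivity; pure-noise traces stay
below 0.5 false events/min in the calibration test.

## Calcium generator

Active cells (a configurable fraction; 97% in the sham preset) carry
events from a renewal process with the requested rate (6.9/min preset)
and Gaussian-distributed durations (mean 6.23 s preset). The pulse is a
linear rise over max(3 frames, 12% of duration), a plateau, and an
exponential terminal decay (tau = 0.5 s) that ends at the event
boundary; a 1.5 s minimum gap separates events (the refractory interval
between network-wide oscillations). These kinetics were fixed from two
physical constraints rather than tuned: the rise must span a few frames
at 4 Hz (sub-second onset, as for a high-affinity dye) yet be steep
enough that its per-frame derivative clears the threshold even at the
~70% duty cycle the sham presets imply, and the decay must be fast at
the event end so that the detected end tracks the true end (the residual
bias is about -10% of duration, within the 15% recovery band; note that
4 Hz sampling quantizes durations to 0.25 s). Under the sham presets
with noise sd 1 the detector recovers the active-cell count within +-2
cells, event frequency within 10% and mean duration within 15%.
Photobleaching, motion and focus drift are deliberately not modelled;
passing these tests demonstrates correctness of the algorithmic chain,
not robustness to imaging artefacts.

# Pipeline, reproducibility and summaries

`runPipeline` chains the stages from a nested-list or YAML
configuration, writes each stage's tables (raster, bursts, activation
map, synchrony matrix, edge list, hubs, GraphML, calcium events) plus a
JSON report and an md5 manifest, and is byte-identical when re-run with
the same seed -- a single master seed deterministically derives one
child seed per random stream. Output directories are named by the
caller; nothing time-dependent enters any output file. Replicate
recordings are summarized as mean +- SEM (SD/sqrt(n); a single replicate
reports SEM 0 flagged by n = 1). Formal between-group inference is out
of scope; the report exposes per-replicate values for external analysis.

Raw recordings travel as flat little-endian float32 binaries with a JSON
sidecar (rate, geometry, dimensions); rasters, traces and all result
tables are plain CSV with 0-based electrode/cell indices on disk
(1-based inside R, as everywhere in this ecosystem).

# Problem sizes and numerical choices

The shipped calibration runs use desk-scale problem sizes chosen to make
the statistics stable at interactive runtimes: ~350 planted bursts for
duration recovery, 20-second 4-channel recordings for spike detection
calibration, 150 s for connectivity recovery, 100 cells x 180 s for
calcium recovery, and 20 random rasters for the brute-force equivalence
check. Thresholds use strict inequalities throughout (immaterial for
continuous data, fixed for determinism); quantiles are R's default type
7; silent electrodes and empty inputs return empty, typed results rather
than errors wherever the operation is well-defined.

# Known limitations

* Spike detection assumes a stationary noise floor per channel; the
  sigma window is the whole recording (a sliding window would be needed
  for strongly nonstationary noise).
* Burst segmentation cannot resolve bursts separated by less than one
  50-ms bin; the generator's minimum gap encodes this resolution limit.
* The synchrony matrix tests pairwise delay consistency only; it does
  not distinguish direct connections from common-drive chains beyond
  what the delay geometry excludes, and no surrogate-based significance
  test is attached to edges.
* The calcium detector operates on given per-cell traces; ROI
  segmentation from images is out of scope.
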