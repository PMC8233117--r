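---
title: "Dynamic community inference for cortical fluorescence movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic community inference for cortical fluorescence movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commdynet)
```

## The problem and the model

Fast fluorescence imaging of the cortex (tens of frames per second,
thousands of pixels) shows functional associations between pixels that
reorganize within hundreds of milliseconds — far faster than the windows of
classical functional-connectivity mapping. `commdynet` treats each pixel as
an *individual* in a social system: at every point in time individuals
gather in *groups* (statistical clusters of a single snapshot), and a
*community* is the entity that persists across snapshots, linking groups and
individuals through time.

The pipeline is:

1. **dF/F** per pixel against a baseline window.
2. **Sliding-window correlation network.** For a window of `W` frames
   starting at `t0`, pixels `i, j` are joined iff their Pearson correlation
   over the window is at least `theta`; the correlation is the edge weight.
   Thresholding is one-sided: anticorrelated pairs carry no edge, because
   the window/threshold sweep that motivates the operating point considers
   positive couplings only. A pixel is *observed* in a snapshot iff it has
   at least one supra-threshold edge; a pixel whose series has zero variance
   inside the window is dropped from that snapshot rather than given NaN
   correlations.
3. **Static communities.** Louvain modularity optimization per snapshot on
   the weighted graph (weights used as-is; a `binary` mode is provided since
   the weighted/unweighted choice is a judgment call — weighted is the
   information-preserving reading).
4. **Dynamic communities.** Given the sequence of per-step partitions, a
   color per (group, time) and per (individual, time) is chosen to minimize
   the total *social cost*
   `c_sw * switches + c_vis * visits + c_abs * absences`.
5. **Node metrics** per pixel, activation summaries, and downstream
   experiments (group statistics, dose classifier, edge dropping).

## Social-cost semantics

For a coloring of groups and individuals:

* a **switch** is charged whenever an individual's color differs between two
  consecutive *defined* time points;
* a **visit** is charged for every (individual, step) where the individual is
  observed in a group whose color differs from its own;
* an **absence** is charged for every (individual, step) where the individual
  is unobserved while at least one group of its color gathers. A community
  that does not gather at a step charges nobody.

Conventions that the cost definition leaves open, fixed here:

* **Carry-forward.** An individual's color is undefined before its first
  observation, and is carried forward unchanged while unobserved; switches
  can therefore only happen at observed steps. This matches the metric
  normalizations, which divide by the number of observed steps.
* **Distinct colors per step.** Two groups at the same time step never share
  a color (the convention of the original dynamic-coloring formulation; the
  adaptation to imaging data does not state it). Both solvers enforce it.
* **Default costs** are `1, 1, 1`: equal costs are the published starting
  point, and no alternative values are reported, so unequal settings are
  exposed as configuration (`commdy_costs()`) but never used as defaults.

### Exact solver

`commdy_exact()` enumerates group colorings in canonical restricted-growth
order (quotienting out color permutations, with per-step injectivity), and
for each one assigns every individual its cost-minimal color sequence by
dynamic programming over the palette — the per-individual problems are
independent once group colors are fixed. The palette is the set of group
colors plus one *phantom* color that never gathers: any color unused by
groups is equivalent to it, so the search space is complete. The first
enumeration attaining the minimum is returned, which makes the reported
coloring the lexicographically smallest optimum up to renaming.

One caveat is inherited from the declared default color budget (groups at
the widest step, plus one): because fresh colors avoid absence charges, the
globally optimal coloring can need *more* colors than any single step shows.
When `commdy_exact()` serves as a reference optimum it should be given
`max_colors = sum(lengths(grouping$groups))`, which the oracle-comparison
tests do.

The exact solver refuses instances beyond ~8 individuals x 5 steps x 10
groups; enumeration grows like the Bell numbers.

### Heuristic solver

`commdy_infer()` is deterministic and three-phased, per start:

1. **Forward matching.** Each step's groups are matched to ongoing
   communities by maximum-weight bipartite matching on shared-member counts
   (exact assignment for <= 7 groups per step, greedy otherwise). A group
   whose best overlap is below `new_frac` of its size opens a new community.
2. **Individual assignment.** Given the group colors, each individual's
   color sequence is set by the same exact dynamic program the exact solver
   uses (a forward-backward pass, lexicographically smallest optimum).
3. **Repair passes.** Group colors are re-chosen per step to minimize
   visit + absence cost given the individual colors, then the individual DP
   is rerun; this alternation repeats until the total cost stops improving.

Three matching thresholds are tried as independent starts (0.5; 0 = any
overlap links; 2 = every group starts fresh and the repair passes do the
joining) and the cheapest result is kept. On random small instances the
heuristic attains the exact optimum roughly 80% of the time and is never
below it; no approximation factor is claimed — the published constant-factor
algorithm is a different construction, cited in the original line of work
and not re-derived here.

## The ten node metrics

Status per (individual, step) follows from the coloring: *member* (observed,
group color = own color), *visitor* (observed, colors differ), *absent*
(unobserved while own community gathers). Then, per individual:

| metric | definition |
|---|---|
| OBS | number of observed steps |
| SW | switches / OBS |
| VIS | visitor steps / OBS |
| ABS | absent steps / OBS |
| AS, MS | mean and max run length of consecutive observed steps with the same home color |
| HOM | mean fraction of current community comembers retained from the previous step |
| GS | mean size of the groups the individual was a member of (members + absents of the community, not visitors) |
| TS | mean time span (last minus first step of existence) of communities the individual was affiliated with as member or absent |
| CS | mean size (members + absents) of those communities over their gathering steps |

Edge-case conventions, fixed after inspecting what the definitions leave
open:

* **AS/MS** are raw run lengths, not per-observation rates; the scoping
  phrase "over the time steps the individual was observed" restricts the
  run domain to observed steps. The extra division by the number of
  activated pixels happens only at the activation-summary level, following
  the normalization used for cross-group bar plots.
* **HOM** averages over observed steps that have a defined previous
  affiliation and at least one current comember. Including first
  observations (as zeros) would make HOM < 1 for a perfectly static
  community, contradicting its meaning as a retention fraction; dividing by
  OBS outright has the same defect.
* **TS** takes a community to exist at any step where its color occurs on a
  group *or* as a carried individual color.
* **Per-activation aggregation** is the mean over pixels (not pixel-time
  pairs), recorded as such in the summary.
* A fully disconnected network has no observed pixels, hence no metrics:
  `analyze_stack()` reports a `NULL` summary, and the degradation analyses
  treat "no communities" as community size zero.

## The synthetic generator

`synth_spec()` plants `k` communities on the pixel grid (per epoch; planted
membership changes only at declared epoch boundaries, so switching metrics
can be scored against known switch times). Community `c` follows a latent
`z_c = standardize(shared waveform + sqrt(latent_noise) * white noise)`, and
a pixel with community `c` has series

```
baseline * (1 + amplitude * (sqrt(coupling) * z_c
                             + sqrt(1 - coupling) * private noise))
            + noise_sd * sensor noise
```

so `coupling` is both the fraction of structured variance carried by the
latent and the expected within-community correlation at `noise_sd = 0`.
Pixels labeled 0 are pure-noise background (an "off-slice" margin for
threshold-selection checks).

The shared waveform is either a paroxysmal transient — linear rise to a unit
peak at `peak_time_ms` (snapped to the frame grid; 150 ms at 71 fps puts the
peak 11 frames after onset) followed by exponential decay with
`decay_tau_s` — or a sinusoid at `osc_freq_hz` (default 3 Hz, the dominant
frequency of awake spontaneous activity). The rise shape is a modeling
choice: only the peak latency and the slow decline are constrained by the
phenomenon. Community phase offsets in the oscillatory mode are spread over
a quarter cycle: enough to keep between-community correlations under the
edge threshold, while the tone still survives in the spatial average (a
half-cycle spread would cancel it). Amplitudes are arbitrary units
throughout; the activations have no absolute fluorescence scale.

What the generator does *not* emulate: nonstationary or spatially correlated
noise (white Gaussian per pixel by default), photobleaching, motion,
hemodynamic contamination, or biophysical metabolic coupling. Passing the
recovery tests therefore shows the inference machinery is sound on its own
assumptions, not that real movies satisfy those assumptions.

## Numerically consequential defaults

| parameter | default | why |
|---|---|---|
| `W` | 50 frames | smallest window that keeps spurious off-slice correlations out at the default threshold (352 ms at 71 fps would be 25 frames; 50 is the operating point established by the window/threshold sweep) |
| `theta` | 0.7 | same sweep; one-sided |
| `stride` | 1 frame | maximal temporal resolution; coarser strides are legal input for the dynamic stage |
| dF/F baseline | first 10% of frames | both target preparations start quiescent; override per dataset |
| Louvain | resolution 1, weighted, stay-on-ties | ties broken toward the current community for stability |
| Louvain `restarts` | 5 | deterministic best-of-5 with sub-seeds derived from the seed; on graphs of <= 8 nodes this reaches the brute-force optimum in >= 95% of seeds |
| costs | 1, 1, 1 | published starting point |
| classifier | 50 trees, leave-one-out at activation level | subject-level holdout is available (`by_subject`) since the original validation unit is ambiguous |
| palette | 20 fixed colors | top-20 communities by occupancy, ties to the earlier-appearing community |
| SNR cap | 100 dB | a noiseless tone has only numerical residual power; values at/above the cap are reported as the cap |
| spectral estimator | Welch averaged periodogram, half-overlapping Hann segments, segment length = largest power of two <= n/2 | the estimator is unspecified upstream; any consistent PSD estimate serves |

Pixel coordinates are row-major, 0-based, origin top-left, in every exported
table. Degree maps offer both normalizations that appear in the source
material (by image maximum, and relative to response magnitude via the
`reference` argument of `summarize_activation()`), since the two are stated
in different places and the intent is not guessed.

## Scale of the shipped analyses

The test-suite and acceptance analyses run on deliberately small instances
chosen as the smallest sizes at which each property is meaningfully
exercised: planted movies of 54–90 pixels and 120–240 frames, strides of
10–25 (every stage also runs at stride 1, just on fewer frames), 30-seed
stability runs on a 90-pixel snapshot, and exact-solver oracles up to 6
individuals x 4 steps. The degradation analogue (coupling as an NMDA
blockade/aging stand-in) is evaluated at couplings 0.5/0.7/0.9: below ~0.5
the network at the default threshold is empty, the activation footprint
vanishes, and per-activated-pixel normalizations degenerate — the regime is
documented rather than extrapolated.

## Known limitations

* Louvain and the social-cost heuristic are greedy optimizers: both carry
  stability and near-optimality tests rather than guarantees.
* Sliding windows smear instantaneous events over `W` frames; a planted
  membership switch is localized to within ~2 snapshot steps, not frames.
* Lagged or partial correlations, frequency-resolved edges, and
  mixed-effects modeling of repeated activations per animal are out of
  scope; metric tables export cleanly to standard statistical tooling for
  the latter.
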