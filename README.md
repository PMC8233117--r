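# commdynet

Dynamic community analysis of cortical fluorescence imaging movies.

Functional associations between patches of cortex form and dissolve on the
timescale of hundreds of milliseconds. Long-window functional connectivity
averages this structure away. `commdynet` implements a pipeline designed for
fast, pixel-resolved fluorescence movies (e.g. flavoprotein autofluorescence
of paroxysmal depolarizations in disinhibited slices, or spontaneous ~3 Hz
oscillations in the awake cortex) that keeps the dynamics:

1. **Preprocess** — spatial binning, ROI selection, per-pixel dF/F.
2. **Temporal network** — a sliding correlation window (default 50 frames,
   stride 1) over pixel time series; pixel pairs with Pearson r >= 0.7 become
   weighted edges, one snapshot graph per window position.
3. **Static communities** — Louvain modularity optimization on each snapshot:
   greedy single-node moves followed by community aggregation, maximizing the
   weighted Newman–Girvan modularity
   Q = Σ_c [ w_in(c)/m − (d_c / 2m)² ].
4. **Dynamic communities** — the per-step groups are linked over time by
   social-cost minimization: a community label per (pixel, time) is chosen to
   minimize `c_sw · #switches + c_vis · #visits + c_abs · #absences`, where a
   *switch* changes a pixel's home community, a *visit* is an observation in a
   group of a foreign color, and an *absence* misses a gathering of one's own
   community (all unit cost by default). An exact branch-and-bound solver
   covers small instances; a deterministic matching + dynamic-programming
   heuristic with repair passes covers real ones.
5. **Metrics & experiments** — ten interpretable per-pixel metrics (OBS, SW,
   VIS, ABS, AS, MS, HOM, GS, TS, CS), degree maps, Mann–Whitney group
   comparisons with Holm–Bonferroni correction, a 50-tree random-forest dose
   classifier with leave-one-out validation and transfer scoring, and a
   random edge-dropping degradation experiment.

A synthetic movie generator with planted (possibly time-varying) pixel
communities and tunable coupling provides ground truth for every stage.

## Worked example

```r
library(commdynet)

spec <- synth_spec(height = 9, width = 9, n_frames = 200, n_communities = 3,
                   coupling = 0.9, noise_sd = 0.1, seed = 2)
movie <- generate_movie(spec)
stack <- dff(movie$stack)

net <- build_temporal_network(stack, W = 50, theta = 0.7, stride = 10)
#> temporal_network: 16 snapshots (W=50, theta=0.7, stride=10),
#>                   1082.25 edges/snapshot on average

parts    <- lapply(seq_along(net$snapshots),
                   function(k) louvain(net$snapshots[[k]], seed = k))
parts[[8]]
#> group_partition: t=71, 3 groups, Q=0.6667

grouping <- temporal_grouping(parts)
coloring <- commdy_infer(grouping)
#> dynamic_coloring: 16 steps, 81 individuals, 3 communities, cost 0

metrics <- node_metrics(coloring, grouping)
round(summarize_activation(metrics), 3)
#>   OBS SW VIS ABS AS MS HOM GS TS CS n_active norm_GS norm_CS norm_AS norm_MS
#> 1  16  0   0   0 16 16   1 27 15 27       81   0.333   0.333   0.198   0.198
```

Reading the output: all 81 pixels are observed in every snapshot (OBS = 16),
nobody switches, visits or goes absent (SW = VIS = ABS = 0, HOM = 1), every
pixel stays in its community for the whole timeline (AS = MS = OBS), and the
three recovered communities have 27 members each — exactly the planted
stripes (GS = CS = 27, normalized to 27/81 = 0.333). The zero social cost
says the per-step groups were perfectly consistent over time. Lowering
`coupling` (the stand-in for NMDA blockade or aging) fragments this picture:
mean degree and normalized community size fall, which is the directional
finding the degradation experiments in `compare_groups()`, `drop_edges()`
and `dose_classifier()` operate on.

The full pipeline, with file outputs and a reproducibility manifest, is one
call:

```r
out <- run_pipeline(run_config(
  simulate = list(height = 9, width = 9, n_frames = 200,
                  n_communities = 3, seed = 2),
  stride = 10, render = TRUE, out_dir = "run1"))
```

A thin command-line wrapper lives at `inst/cli/commdynet.R`
(`Rscript commdynet.R run-all --config cfg.json --out run1`).

## Vignette

`vignettes/dynamic-communities.Rmd` documents the model, the social-cost
semantics, the metric definitions and their edge-case conventions, the
synthetic generator's assumptions, and every numerically consequential
default.
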