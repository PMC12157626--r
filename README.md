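# strainsight

Quantification pipelines for live-cell fluorescence microscopy of
LIM-domain reporters on mechanically stressed ("strained") actin.

Tandem LIM domains from Zyxin-family and Prickle/Testin-family proteins
bind tension-bearing actin filaments directly. Two questions recur when
imaging such reporters in tissue (e.g. *Xenopus* dorsal mesoderm explants):

1. **How strongly is a GFP-tagged construct recruited to stressed-actin
   sites?** The sites are defined operationally by a co-expressed
   Zyxin-LCR reference reporter in the RFP channel. `strainsight` builds a
   reference mask from the RFP channel (background subtraction → Gaussian
   blur → Triangle auto-threshold → erosion → particle filter ≥ 30 px) and
   scores the construct channel with the enrichment statistic

   ```
   score = (GFP_i − GFP_o) / RFP_i
   ```

   where `GFP_i`/`GFP_o` are the mean construct intensities inside/outside
   the mask and `RFP_i` is the mean reference intensity inside it, all
   measured on the **original** (unprocessed) channels. Scores are
   normalized per trial to the mean of the wild-type reference group and
   compared across construct groups by one-way ANOVA.

2. **How fast are reporter structures lost after myosin inhibition
   (blebbistatin)?** `strainsight` counts bright construct-positive
   objects per frame of a single-channel time-lapse (background
   subtraction → Rényi-entropy auto-threshold → particle filter ≥ 10 px →
   connected-component count) and summarizes count-vs-time curves across
   replicates (mean ± SD per timepoint).

All image operators involved — sliding-paraboloid / rolling-ball
background subtraction, Gaussian blur, Triangle and Rényi-entropy
histogram thresholding, binary erosion, connected-component labeling with
size filtering — are implemented in the package and validated against
brute-force oracles. A seeded synthetic scene generator (`make_scene()`,
`make_timelapse()`) produces two-channel scenes and decaying time-lapses
with exact ground truth, so the full analysis chain is testable without
microscope data.

## Worked example

Score a synthetic cohort: a wild-type-like group whose construct is fully
recruited to strain sites (`enrichment_rho = 1`) against a group with
recruitment abolished (`enrichment_rho = 0`, e.g. a PET-domain-fused or
LIM-mutant construct):

```r
library(strainsight)

imgs <- list()
for (g in list(c("WT", 1), c("PET-fused", 0))) for (k in 1:4) {
  sc <- make_scene(scene_spec(width = 256, height = 256,
                              enrichment_rho = as.numeric(g[2]),
                              seed = 100 + k + 10 * (g[1] == "WT")))
  imgs[[length(imgs) + 1]] <- list(gfp = sc$gfp, rfp = sc$rfp,
                                   trial = 1, group = g[1],
                                   image = paste0(g[1], "_", k))
}
res <- run_enrichment_experiment(imgs, reference_group = "WT")
print(res)
#> enrichment experiment: 8 image(s), 2 group(s), 0 skipped
#>      group     mean_norm      sd_norm
#>  PET-fused -0.0001660263 0.0006894069
#>         WT  1.0000000000 0.0565770846
#> one-way ANOVA on score_norm: F(1, 6) = 1250, p = 3.41e-08
```

Reading the output: the reference (WT) group's mean normalized score is 1
by construction (per-trial normalization); the fully delocalized group
scores ≈ 0 — its construct signal is no higher inside the stressed-actin
mask than outside — and the ANOVA confirms the group difference. Raw
per-image scores, mask areas and chosen thresholds are in `res$scores`.

Counting structures in a decaying time-lapse (3-minute decay constant,
one frame per minute for 15 minutes):

```r
tl <- make_timelapse(timelapse_spec(base = scene_spec(n_puncta = 0, seed = 5),
                                    n_frames = 16, decay_tau = 3))
count_stack(tl$stack, condition = "blebbistatin")$count
#> [1] 12 12 12 12 12 12 12 12 31  0  0  0  0  0  0  0
```

Counts hold at the 12 true structures, spike once as the fading
filaments fragment into pieces while sinking through the detection
threshold, then fall to zero — the near-complete loss expected over a
15-minute myosin inhibition. The threshold is estimated on frame 0 and
held fixed for the series (see the methods vignette for why per-frame
re-estimation is offered only as an option).

A thin command-line wrapper with `simulate`, `count` and `enrich`
subcommands is installed at
`system.file("cli", "strainsight.R", package = "strainsight")`.

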