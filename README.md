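# nucleomap

Quantitative analyses for studies of bacterial DNA methyltransferases
(MTases) that span single-molecule microscopy, comparative genomics, and
in-vitro binding. The package grew out of the analysis needs of
live-cell tracking of an orphan adenine MTase in *Bacillus subtilis* —
an enzyme whose subcellular behaviour, genomic neighborhood, and
recognition-site statistics together decide whether it acts as part of a
restriction-modification (RM) defense system or as a lone epigenetic
regulator — and packages those analyses for reuse on any comparable
data set.

It provides, as composable, tested R functions:

- **Trajectory building** from per-frame single-molecule localizations
  by minimum-cost assignment (Hungarian algorithm) with a distance gate.
- **Diffusion analysis**: per-track mean-squared-displacement fits
  `MSD = 4Dτ + 2σ²`; track-length-weighted log₁₀D histograms with 1- or
  2-component Gaussian decomposition; and jump-length-distribution
  mixture fits `P(r ≤ R | mΔt) = Σᵢ fᵢ (1 − exp(−R²/4(DᵢmΔt + σ²)))`
  that report the bound (slow) weight fraction under per-state
  diffusion-coefficient constraints.
- **Normalized cell maps**: Feret-axis extraction from segmentation
  masks, projection of localizations to relative cell coordinates
  (u, v) ∈ [−1, 1]², symmetrization about both axes, probability
  density maps, and Pearson correlation between maps (e.g. MTase vs
  replisome marker).
- **Motif enrichment**: overlapping motif counts, maximal-order Markov
  (compositional-bias) expected counts
  `E(w) = N(w₁..k−1)·N(w₂..k)/N(w₂..k−1)`, O/E enrichment classes with
  0.72/1.30 thresholds and a ≥5-expected filter, cohort summaries, and
  chop/stagger sliding-window GC content.
- **Gene-neighborhood enrichment**: defense-family counting around
  anchor genes (±10 neighbors), a random contiguous-window null,
  mean ± SD summaries, and positional frequency of the top neighbor
  families.
- **EMSA quantitation**: background-subtracted fraction bound and
  four-parameter log-logistic (LL.4) EC50 fits, per replicate, with
  group mean ± SD.
- **Synthetic-data generators** for every input above (confined
  Brownian mixtures in spherocylindrical cells, genomes with planted
  motif bias, neighborhood tables with conserved families, noisy
  titrations) with known ground truth and explicit seeds.

## Worked example

Simulate a two-state tracking experiment at typical imaging conditions
(40-ms frames, 30-nm localization precision), rebuild trajectories from
the localization table, and decompose the population:

```r
library(nucleomap)

cfg <- tracking_sim_config(
  states = list(c(0.05, 0.5), c(1.0, 0.5)),  # (D um^2/s, fraction)
  sigma_loc = 0.03, frame_interval = 0.04, n_tracks = 1000, seed = 42)
sim    <- simulate_trajectories(cfg)
tracks <- link_localizations(sim$localizations, max_displacement = 0.8)
trajs  <- split_trajectories(tracks)
jm     <- fit_jump_mixture(trajs, n_states = 2, sigma = 0.03, seed = 42)
sprintf("D = (%.3f, %.2f) um^2/s, F_bound = %.3f", jm$D[1], jm$D[2], jm$F_bound)
#> "D = (0.047, 0.63) um^2/s, F_bound = 0.511"
```

The slow ("bound") fraction of 0.511 recovers the simulated 50/50 split;
the slow D recovers 0.05, while the fast-state D is compressed below the
simulated 1.0 by confinement in the 1-µm-wide cell — expected for
jump statistics collected inside bacteria.

Motif observed/expected on a toy sequence (two overlapping `GACGAG`
sites, expectation 2 from its own composition, hence neutral, but
excluded from cohort summaries by the ≥5-expected filter):

```r
classify_enrichment(motif_stats(c(toy = "GACGAGACGAG"), "GACGAG"))
#>   genome_id  motif observed expected oe_ratio enrichment_class passes_min_expected
#> 1       toy GACGAG        2        2        1          neutral               FALSE
```

EC50 from three simulated titration replicates (true EC50 40 nM, 5%
noise), fitted per replicate and averaged:

```r
tit <- simulate_titration(titration_sim_config(seed = 7))
tit$substrate <- "unmethylated"
ec50_summary(tit, group = "substrate")$summary
#>          group n ec50_mean  ec50_sd
#> 1 unmethylated 3  33.18778 7.346447
```

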