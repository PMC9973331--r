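---
title: "Models and methods behind nucleomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucleomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomap)
```

nucleomap implements the quantitative analyses used to characterize a
bacterial DNA methyltransferase across scales: how single molecules of the
enzyme diffuse and localize inside live rod-shaped cells, whether its
recognition motif is avoided in phage genomes, whether its gene sits in a
defense-island-like neighborhood, and how tightly it binds candidate DNA
substrates in vitro. This vignette explains each model, its assumptions,
the tunable parameters, and the numerical choices, in the order data flow
through the pipeline.

## Synthetic data as ground truth

Raw single-molecule microscopy and large genome cohorts are bulky and
rarely redistributable, so every input the pipeline consumes can be
generated synthetically with known ground truth. The generators are
first-class, tested code: all statistical guarantees quoted below are
verified against them.

**Trajectories.** A molecule lives in the 2D projection of a
spherocylindrical cell (rectangle with semicircular caps; defaults 3.0 um
pole-to-pole by 1.0 um wide, typical of exponentially growing *B.
subtilis*). Each track draws one diffusive state from the configured
weight fractions and keeps it for life — the downstream mixture fits are
static-state models, so simulating state interconversion would test a
model the pipeline does not fit. True positions take Gaussian steps with
per-axis variance $2D\Delta t$ and are reflected at the capsule boundary
by mirroring the radial overshoot; reported positions add independent
Gaussian localization error ($\sigma_{loc}$ per axis, default 0.03 um at
the default 40-ms frame interval). Track lengths are $2 +
\mathrm{Geom}(p)$ with mean 8 frames: photobleaching is memoryless, and
two localizations is the minimum that yields one displacement. The
configuration constructor rejects step scales comparable to the cell
(mirror reflection is a one-bounce approximation) and weight fractions
that do not sum to 1.

What the generator does *not* emulate: blinking and fluorophore
photophysics, 3D membrane geometry, motion blur within an exposure, and
detection dropouts. Passing tests therefore certify the estimators on
clean confined Brownian mixtures, not the full imperfection budget of
real microscopy.

**Genomes.** Order-0 sequences draw i.i.d. bases at the target GC
(defaults 43.5%, *B. subtilis*-like); order 1 uses a "sticky" kernel
$P(b\mid a) = (1-\rho)\pi_b + \rho\,[a=b]$ with $\rho = 0.2$, which has
the target composition as its exact stationary distribution while giving
genuine first-order dependence. Orders above 1 are rejected rather than
silently approximated. Motif planting counts spontaneous occurrences,
then mutates random occurrences (depletion) or overwrites the motif at
uniform positions (enrichment) and re-scans until the realized count
matches `round(factor * spontaneous)`; re-scanning is necessary because
single-base edits can create or destroy overlapping occurrences.

**Neighborhoods and titrations.** The neighborhood generator emits
anchor-centered tables (10 genes per side) in which conserved families
occupy fixed relative positions with a configured occupancy and
background genes carry a defense family with probability `defense_rate`.
The titration generator evaluates the four-parameter log-logistic curve
and adds Gaussian noise clipped to [0, 1].

## Trajectory linking

Localizations are linked frame-to-frame within each cell by minimum-cost
bipartite assignment on Euclidean distance — the Hungarian algorithm,
implemented in-package as an $O(n^3)$ shortest-augmenting-path solver and
unit-tested against brute-force permutation enumeration. The cost matrix
is augmented with birth/death diagonal entries equal to the gate
`max_displacement` (default 0.8 um/frame, about 5 camera pixels at 0.16
um/px), which makes the gate the exact indifference point: a candidate
link costing more than one death plus one birth is never taken. Links
beyond the gate are forbidden outright. There is no gap closing and no
merge/split handling; a track whose cell skips a frame terminates. Input
rows are sorted by (cell, frame, x, y) before linking, so results are
invariant to row order and equal-cost ties resolve deterministically.
Whether singleton tracks are kept is left to the caller (they are
emitted, flagged); the minimum length actually used downstream is a
parameter everywhere.

## Diffusion estimation

Per trajectory, the time-averaged mean squared displacement at lag $\tau
= m\Delta t$ is fitted by ordinary least squares to

$$\mathrm{MSD}(\tau) = 4D\tau + 2\sigma^2,$$

giving $D$ from the slope and the localization-precision term $\sigma$
from the intercept. Note the convention: with per-axis reported-position
noise $\sigma_{loc}$, the true 2D intercept is $4\sigma_{loc}^2$, so the
fitted $\sigma$ equals $\sqrt{2}\,\sigma_{loc}$; the fit deliberately
keeps the $2\sigma^2$ parameterization because that is the convention the
downstream comparisons use, and only relative changes in the intercept
matter to the pipeline. Fits use lags $1..\min(5, L-1)$ and require at
least 4 localizations: short-lag fits minimize the correlation bias of
time-averaged MSDs, and the choice is a parameter. A negative fitted
slope is clipped to a positivity floor of $10^{-4}$ um²/s (log-scale
histograms need positive support) and counted; a negative intercept
yields $\sigma = 0$.

The population histogram of $\log_{10} D$ weights each track by its
number of displacements ($L - 1$), normalizes to unit area, and uses
0.1-decade bins. One- or two-component Gaussian curves are fitted to the
bin heights — to the histogram, not by maximum likelihood on the raw
sample, because the histogram is the published object being decomposed —
with five seeded multi-starts for $k = 2$ and weights reported as
normalized Gaussian areas.

The jump-length decomposition fits the empirical cumulative distribution
of pooled displacements $r$ at lags $m = 1..5$, jointly, to the 2D
Rayleigh mixture

$$P(r \le R \mid m\Delta t) = \sum_i f_i\left(1 - e^{-R^2 / 4(D_i
m\Delta t + \sigma^2)}\right),$$

by bound-constrained least squares (L-BFGS-B, multi-start, stick-breaking
weights so $\sum f_i = 1$ holds exactly). Per-state constraint boxes on
$D_i$ are how a reference condition's confidence intervals are imposed
when only weight fractions should float across conditions; overlapping
boxes trigger an identifiability warning. The slow-state weight is
reported as $F_{bound}$. Deliberate simplifications relative to full
Spot-On-style analysis: no state-transition kinetics and no
defocalization (axial loss) correction — static fractions are the
quantity of interest, and the 2D synthetic data have no axial dimension
to lose molecules to. Verified performance under the study conditions
(50/50 mixture of 0.05 and 1.0 um²/s, $\sigma_{loc}$ = 0.03 um, 40-ms
frames, 2,000 tracks): the slow fraction is recovered with mean absolute
error below 0.05 across 20 seeds.

## Normalized cell maps

Cell axes come from Feret properties of the segmentation outline: the
long axis is the direction of the maximum Feret diameter (computed on the
convex hull; for rasterized masks the directions of all near-maximal
antipodal pairs are averaged, because the diameter is flat in angle near
its maximum and the single best pair is angularly noisy at pixel
resolution), and the short length is the maximal extent perpendicular to
it. Localizations map to relative coordinates $u, v \in [-1, 1]$ by
projection onto the axes and division by the half-lengths; points falling
just outside (segmentation vs localization jitter) are clipped and
counted. Assuming mirror symmetry about both axes, each point is
symmetrized to $(\pm u, \pm v)$, and maps are 2D histograms over
$[-1,1]^2$ normalized to total probability 1. The default grid is 41 × 21:
odd counts center a bin at the origin so the reflection symmetry of
symmetrized data is exact at bin level. Map similarity is the Pearson
correlation of flattened bin values, which is invariant to positive
rescaling (so the choice of normalization cannot change it); no smoothing
is applied before correlation — a blur would be cosmetic and would make
the statistic depend on an arbitrary bandwidth.

## Motif observed/expected statistics

Observed counts are overlapping occurrences; the default counts the
motif as written on the deposited strand, with a `both`-strands mode that
adds reverse-complement occurrences (counted only when the reverse
complement differs from the motif, so palindromes are not double
counted). The expected count is the maximal-order Markov (compositional
bias) estimator

$$E(w_{1..k}) = \frac{N(w_{1..k-1})\; N(w_{2..k})}{N(w_{2..k-1})},$$

with all $N$ computed on the same strand(s) as the observed counts — the
expectation under a Markov model of order $k - 2$ estimated from the
sequence itself, which absorbs compositional bias up to $(k-1)$-mers. A
zero denominator leaves the expectation undefined and the genome is
flagged and excluded. Enrichment classes use O/E thresholds 0.72 (under)
and 1.30 (over), and cohort summaries include only genomes with at least
5 expected motifs, because small expectations destabilize the ratio.
Ambiguity codes break both motif matches and $k$-mer counts
(conservative), and multi-record FASTA input is handled per record with
counts never spanning record boundaries. Sliding-window GC follows the
chop/stagger convention (1,000-bp windows every 10 bp, truncated at the
sequence end, BED-style half-open coordinates), excluding ambiguous bases
from numerator and denominator.

## Neighborhood enrichment

A neighbor gene counts as defense-associated if at least one of its
protein families is in the defense list — per gene, not per family, so a
single gene annotated with two defense domains contributes 1. The null
model samples uniformly random contiguous 20-gene windows: the phrase
"20 random neighborhoods in a sample of 50 genomes" admits two readings,
and the implementation takes 20 windows per genome (both knobs are
exposed) because 20 windows total would give an unusably small null.
Summaries report sample standard deviations ($n - 1$), matching the
usual mean ± SD notation. Positional frequency ranks families by total
occurrence; ties at the `top_n` boundary are all included, ordered
lexicographically, so ranking is deterministic.

## Binding curves

Fraction bound is background-subtracted bound intensity over the
background-subtracted lane total, with negatives clipped to zero (and
counted); rows where both corrected intensities vanish are undefined
rather than silently 0/0. Binding curves use the LL.4 four-parameter
log-logistic

$$f(x) = c + \frac{d - c}{1 + e^{\,b(\ln x - \ln e)}},$$

where $e$ is the EC50 reported directly and negative $b$ corresponds to
binding that rises with concentration; $x = 0$ is handled by the model's
limit instead of being dropped. Fitting is Levenberg-Marquardt least
squares with data-driven starts ($c, d$ from the response extremes, $e$
from the concentration nearest half-maximum, both slope signs tried) and
an orientation pass that returns $c \le d$ with a sign-consistent $b$.
The default workflow fits each replicate separately and averages the
per-replicate EC50s (mean ± sample SD), rather than pooling points —
replicate-level fits propagate between-replicate variability into the
reported SD. Verified calibration: with 5% measurement noise, 8
concentrations, and 3 replicates, the fitted EC50 falls within 25% of
truth in at least 90% of 100 seeds.

## Problem sizes and reproducibility

The verification suite uses 2,000 tracks × 20 seeds for the mixture
recovery, 100 simulated 50-kb genomes per enrichment cohort, 50 seeds for
the neighborhood null calibration, and 100 seeds for the EC50
calibration — sizes at which the binomial/Poisson sampling error of each
check is several times smaller than the tolerance it asserts. All
generators take explicit integer seeds and restore the caller's RNG
state, so identical configurations are byte-reproducible and independent
of surrounding code.

## Known limitations

- The MSD estimator ignores blur and lag-correlation corrections; its
  per-track $D$ is a few percent biased for short tracks (hence the
  median-over-long-tracks checks).
- The jump-length model assumes isotropic 2D diffusion with static
  states; confinement in narrow cells compresses the apparent fast-state
  $D$, though weight fractions are robust to this.
- The compositional-bias expectation is the maximal-order estimator;
  lower-order Markov expectations are not provided.
- The genome generator's order-1 dependence is a single-parameter sticky
  kernel, not a fitted transition matrix from any real genome.
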