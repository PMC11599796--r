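---
title: "Models and methods behind domsuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind domsuite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domsuite)
```

`domsuite` implements the analysis chain of a multi-assay mouse dominance
study: dyadic outcome scoring, pose-based behavioral-state discovery, and
cross-assay rank comparison. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not demonstrate.

## Dominance scoring

### Elo ratings with ties

Every animal starts at the baseline rating (default 1000). For a match
between A and B the expected score of A is

$$E_A = \frac{1}{1 + 10^{(R_B - R_A)/s}},$$

with scale $s = 400$ rating points (a 400-point advantage gives 10:1
expected odds), and the update is $R'_A = R_A + K\,(S_A - E_A)$ with
$K = 20$ and $S_A \in \{1, 0, 0.5\}$ for win, loss, tie. Because
$E_A + E_B = 1$, every update is exactly zero-sum, and the suite asserts
$\sum_i R_i = n \times \text{baseline}$ over arbitrary match streams. Elo
is the primary ranking here for three reasons: it accepts ties (scored as
half wins, pulling both animals toward their expectation), it respects
temporal order, and animals that never fight retain an interpretable
baseline. $K$ controls the memory of the rating: larger values track
recent form, smaller values average over history. The defaults are the
values conventional for small laboratory cohorts.

Final scores are simplified to dense ranks 1..n (1 = highest). Exact score
ties are broken deterministically by animal identifier; with continuous
ratings after any real match stream they essentially never occur, but the
tie-break keeps the rank vector a permutation of 1..n under all inputs.

### David's scores

With $\alpha_{ij}$ the number of wins of $i$ over $j$, the dyadic win
proportion is $P_{ij} = \alpha_{ij} / (\alpha_{ij} + \alpha_{ji})$ for
dyads that interacted and contributes 0 otherwise. Then
$w_i = \sum_j P_{ij}$, $w2_i = \sum_j P_{ij} w_j$, $l_i = \sum_j P_{ji}$,
$l2_i = \sum_j P_{ji} l_j$, and $DS_i = w_i + w2_i - l_i - l2_i$: a win
proportion weighted by the strength of the opponents it was earned
against. Ties carry no directional information and are excluded from
$\alpha$. Groups with no decisive interaction raise an explicit
"unmeasurable" error rather than returning zeros, since the score is
undefined there. The implementation is verified against a brute-force
loop-level oracle on exhaustive small win matrices, including the
$\sum_i DS_i = 0$ identity on fully interacting groups and invariance to
scaling all dyad counts by a common factor.

### Directional consistency, outcome rules, stability

The directional consistency index is $(H - L)/(H + L)$ with $H$ the total
interactions in each dyad's more frequent direction and $L$ the reverse;
it is 1 iff every dyad is unidirectional and 0 iff every dyad splits
evenly. It is computed from the same win matrix as David's scores (a
closed form small enough to implement directly).

Urine-marking matches tie when the spot counts differ by fewer than 5
spots *or* by less than 20% of the larger count; otherwise the larger
count wins. Because the rule is a disjunction, nearly equal large counts
always tie through the percentage branch; the absolute-spot branch is
binding only when the difference reaches 20% of the larger count. The
comparison is done in integer arithmetic (the 20% test as
$10^9 d < p\, m$ with integral $p$), so boundary cases are exact: a
(25, 20) pair is decisive, (26, 21) is a tie. The denominator of the
percentage rule (the larger count) is one of several defensible readings;
it is a configurable argument.

Reward-competition matches aggregate hand-labeled trial winners: tied
trials are excluded and the animal with more decisive trials wins; equal
decisive counts are assigned deterministically by identifier (mirroring
the practice of assigning a winner when totals tie), and a match with no
decisive trial at all is a tie.

Dyad stability is classified per assay with inclusive thresholds:
agonistic dyads need at least 3 interactions (else unmeasurable) and 75%
initiated by the same animal; urine dyads are stable only when every
trial is decisive with the same winner; tube dyads need 75% same winner;
reward dyads need 60% of decisive trials. Unmeasurable is a distinct
status, never silently dropped, so downstream reversal counts can report
it. The 75/60/5-spot boundaries are pinned by grid-probing tests and
recomputed by `scripts/acceptance.R`.

## Pose features

Input tracks are two animals $\times$ six nodes (nose, forehead, ears,
thorax, tail base) $\times$ frames, in pixels, with missing detections.
Preprocessing fills gaps by linear interpolation (edge gaps by nearest
value) and smooths each node track with a Savitzky–Golay filter, window
25 frames. The polynomial order is not dictated by the upstream tooling's
documentation; the default is 3, the common choice in pose-tracking
tutorials, and both are arguments. Since the filter fits local
least-squares polynomials, constant and polynomial tracks up to the
order pass through unchanged — the suite asserts this up to cubics. For
recordings shorter than the window, the window shrinks to the largest odd
length that fits, with a warning.

The seven per-frame features are sums and absolute differences across the
two animals of: thorax speed, port–nose distance, and the
port–thorax–nose orientation angle, plus the thorax–thorax distance.
Sum/absolute-difference pairs make every feature invariant to swapping
animal identities; folding the orientation angle to [0, 180]° makes
clockwise and counterclockwise configurations coincide. All features are
translation invariant; distances scale linearly under global rescaling
while angles do not change. These invariances are property-tested on
randomly generated recordings.

Numerical choices: speeds are computed *after* smoothing (displacements
of the smoothed thorax), in pixels/frame by default with an optional
conversion to pixels/second; the first frame's speed repeats the second's
so feature rows stay aligned with frames; degenerate angle geometry
(coincident points) yields a marker that is imputed from the nearest
valid frame.

Frames are subsampled (every third frame) and then z-scored over the pool
of all recordings, not per recording, because state discovery clusters
frames from all recordings together; per-recording normalization would
erase between-recording differences in state usage, which are the
quantity of interest downstream. Per-recording normalization is available
behind a flag. A zero-variance feature maps to a zero column with a
warning rather than NaNs.

## Behavioral-state discovery

States are found by k-means on the z-scored feature matrix, with
k-means++ seeding, 10 restarts, and the best-inertia solution kept; the
whole procedure is deterministic for a fixed seed. The restart count and
seeding are not dictated by the upstream analysis; they are ordinary
robustness choices. $k$ defaults to 8 but is a configuration value: the
reference workflow selects $k$ by human interpretability of per-cluster
review videos, and `sample_cluster_frames()` reproduces that workflow by
drawing up to 600 frames uniformly without replacement per cluster.
Cluster labels carry no meaning across runs, so every cross-run
comparison in the tests uses the adjusted Rand index.

The 2-D UMAP embedding (seed fixed at 42) is strictly for visualization:
cluster assignments are computed on the full seven-dimensional feature
space, and the tests assert that fitting states before or after embedding
yields identical labels.

Per-cluster enrichment by rank difference is
$n_{ij}/n_{i\cdot} - n_{\cdot j}/N$ — the share of stratum $i$'s frames
in cluster $j$ minus the cluster's overall share. Each stratum's row sums
to zero by construction (asserted to $10^{-12}$), entries lie in
$[-1, 1]$, frames from recordings without rank metadata are excluded
rather than guessed, and an explicitly requested stratum with no frames
is flagged NA rather than reported as zero enrichment.

## Cross-assay comparison

Score correlation matrices are Pearson correlations between assays'
per-animal scores, computed pairwise-complete within a stratification
group that must be passed explicitly (strain is never inferred from
identifiers). Entries with fewer than 3 complete pairs are NA and
flagged. P-values are Holm-adjusted over the off-diagonal comparisons by
default; the adjustment is a configuration field. Rank reversal analysis
considers only dyads classified stable in both assays of a pair:
identical dominant animals maintain relative rank, opposite ones reverse
it, and maintained + reversed always equals the stable-in-both count,
with other dyads reported as excluded. Fisher's exact comparisons of
reversal proportions between groups are thin wrappers over
`stats::fisher.test`.

## Synthetic data: what it emulates, and what passing tests show

### Match streams

`generate_matches()` draws dyadic outcomes from a Bradley–Terry-style
model: animal $i$ beats $j$ with probability
$\mathrm{logit}^{-1}(\beta (d_i - d_j))$ on distinct latent scores
$d$, with an independent tie probability and optional per-assay
inversion that flips every decisive outcome (emulating an assay that
measures the opposite of the latent order, as reported for the tube test
in some strains). Defaults — cages of 4, unit-spaced latent scores,
$\beta = 3$, 10% ties, 6 trials per dyad — describe a steep, stable
hierarchy of the kind group-housed male mice form. The validation suite
shows that at $\beta = 5$ and 50 trials per dyad the Elo ordering
recovers the latent order (Spearman $\ge 0.9$) in at least 95% of 100
seeds, and that inverting one of four assays drives its mean cross-assay
score correlation below $-0.5$ over 20 seeds.

### Arena trajectories

`generate_pose()` scripts a Markov dwell model over two-mouse states:
both at the reward port; one at the port with the other nearby but
averted; one at the port with the other along the far wall; and free
roaming. Skeletons are a rigid template (nose 25 px ahead of the thorax,
ears lateral of the forehead, tail 30 px behind) rotated to a per-frame
heading rule — toward or away from the port, evaluated at the animal's
current position. Gaussian pixel noise is added to every node and a
missing-completely-at-random fraction of whole detections is masked, so
interpolation and smoothing are genuinely exercised.

Locomotion is continuous: each episode has anchor positions, animals are
pulled toward them under a 5 px/frame speed cap and otherwise wander with
a correlated (Ornstein–Uhlenbeck) velocity process. This was a deliberate
design decision: placing animals afresh each frame, or teleporting them
between episodes, produces velocity artifacts — single-frame jumps that
the 25-frame smoothing window spreads into sustained high-velocity
bursts — that no real recording contains, and such bursts form a compact
outlier mode that k-means will always prefer to isolate. Mean dwell
defaults to 240 frames (8 s at 30 fps), matching the multi-second trial
epochs of a tone-cued competition; dwells must comfortably exceed
cross-arena travel time for per-frame labels to be meaningful.

A consequence worth stating plainly: in multi-state trajectories the
frames spent traveling between state configurations have no clean
discrete-state ground truth — the Markov driver has already switched
while the configuration is still en route. Locomotor transit is a real
behavioral mode of its own, which is one reason the reference workflow
chose its cluster count by human interpretability rather than by
recovery of predefined states. The scripted-state recovery check
therefore pools single-state recordings (one scripted state per
recording, three states across recordings — pooling across recordings is
exactly how the feature matrix is built) and shows the full pipeline
(dropout, interpolation, smoothing, features, pooled z-scoring, k-means
at $k = 3$) recovers the script with mean adjusted Rand index well above
0.8 at 5 px node noise and 5% dropout. The rank-difference manipulation
check uses full multi-state recordings, where the enrichment sign is
robust to transit: recordings of maximal-rank-gap dyads triple the
averted-state dwell, and the enrichment table reports a positive value
for that stratum in the cluster matched to the averted state, with the
rest of the row compensating to zero.

What passing these tests does *not* show: that real reward-competition
data contains three (or eight) discrete states, that real missingness is
completely at random (SLEAP dropout is occlusion-structured; a
gap-structured missingness flag exists for stress-testing
interpolation), or that real within-state movement resembles an
Ornstein–Uhlenbeck amble. The generator validates the machinery, not the
ethology.

## Problem sizes and determinism

The test suite and acceptance script run entirely on synthetic data
generated in code: cages of 4 animals with up to 50 trials per dyad (100
seeds for hierarchy recovery, 20 seeds of 8 cages for the inversion
check), and recordings of 600–1800 frames for the pose pipeline (10
replicates for state recovery). These sizes were chosen as the smallest
at which the targeted effects are unambiguous. Every stochastic function
takes an explicit seed, restores the caller's RNG state, and is asserted
bit-reproducible; the pipeline driver records seeds, configuration
digests, and per-stage output digests in its run manifest, and skips
stages whose outputs already match.

## Known limitations

Only dyadic (pairwise) analyses are implemented; hierarchy linearity
beyond the directional consistency index (Landau's h, triangle
transitivity) and temporal Elo variants are out of scope. Arena
recordings are strictly two-animal. The ethogram aggregation treats each
subject's behaviors independently, so simultaneous annotations for
different subjects never interact; overlapping same-behavior bouts are
unioned, a choice that treats double-scored overlap as an annotation
artifact and keeps percentages at or below 100%.
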