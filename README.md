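# domsuite

Social dominance in group-housed laboratory mice is measured with several
partially redundant assays — observation of agonistic behaviors (fights and
chases), territorial urine marking, the tube test, and trial-based reward
competitions — and the assays do not always agree, particularly across mouse
strains. `domsuite` is an R toolkit for the full analysis chain behind such
multi-assay studies: it scores dyadic contest streams into dominance
rankings, post-processes two-animal pose-estimation tracks into behavioral
features, discovers behavioral states by unsupervised clustering, and
compares rankings across assays. Synthetic generators with known ground
truth make every stage testable end to end.

## What it computes

**Dominance scores.** For a chronologically ordered stream of dyadic
outcomes within a cage:

* *Elo ratings with ties.* Each animal starts at a baseline
  R<sub>0</sub> = 1000. For a match between A and B, the expected score of A
  is E_A = 1 / (1 + 10^((R_B − R_A)/400)) and the update is
  R′_A = R_A + K (S_A − E_A) with K = 20 and S_A = 1, 0, or 0.5 for a win,
  loss, or tie. Updates are exactly zero-sum, and unmatched animals keep the
  baseline.
* *David's scores.* With α<sub>ij</sub> the wins of i over j and
  P<sub>ij</sub> = α<sub>ij</sub>/(α<sub>ij</sub>+α<sub>ji</sub>) for dyads
  that interacted, DS_i = w_i + w2_i − l_i − l2_i where w_i = Σ_j P_ij,
  w2_i = Σ_j P_ij w_j, l_i = Σ_j P_ji, l2_i = Σ_j P_ji l_j.
* *Directional consistency index.* (H − L)/(H + L), where H counts
  interactions in each dyad's predominant direction and L the reverse;
  1 = fully unidirectional, 0 = fully bidirectional.
* *Assay-specific outcome rules and dyad stability* — the urine tie rule
  (difference < 5 spots or < 20% of the larger count), majority rule over
  decisive reward trials, and stable/unstable/unmeasurable classification
  per dyad (≥ 75% same winner for tube and agonistic with at least three
  interactions; all-decisive-same-winner for urine; ≥ 60% of decisive
  trials for reward).

**Pose features and behavioral states.** Six-node two-animal tracks are
gap-filled by linear interpolation and smoothed with a 25-frame
Savitzky–Golay filter; seven per-frame features (sums and absolute
differences of thorax velocities, port–nose distances and port–thorax–nose
orientation angles, plus the thorax–thorax distance) are agent-invariant by
construction and rotation-invariant through angle folding. Every third
frame is pooled across recordings, z-scored, and clustered by k-means
(k-means++ seeding, 10 restarts); a seed-fixed UMAP embedding supports
plotting without influencing cluster assignments. Per-cluster enrichment by
dominance-rank difference is n<sub>ij</sub>/n<sub>i·</sub> −
n<sub>·j</sub>/N.

**Cross-assay comparison.** Pearson correlation matrices of per-animal
scores between assays (pairwise-complete, Holm-adjusted), and
maintained-versus-reversed relative ranks among dyads stable in two assays.

## Worked example

Simulate a cage of four with a steep latent hierarchy, one ordinary assay
and one inverted assay (as when a paradigm rewards the opposite of the
latent order), then score it:

```r
library(domsuite)
cfg <- hierarchy_config(n_animals = 4, beta = 3, tie_prob = 0.1,
                        trials_per_dyad = 8,
                        assays = c(urine = FALSE, tube = TRUE), seed = 42)
sim <- generate_matches(cfg)
urine <- subset(sim$matches, assay == "urine")
elo_ratings(urine)
#> Elo ratings (K = 20 , scale = 400 , baseline = 1000 )
#> assay: urine  cage: cage1
#>      final rank
#> m01 1130.7    1
#> m02 1080.6    2
#> m03  946.5    3
#> m04  842.2    4
david_scores(urine)
#> David's scores (44 decisive interactions)
#>       w   l   DS rank
#> m01 2.8 0.2  5.2    1
#> m02 2.2 0.8  2.8    2
#> m03 1.0 2.0 -2.0    3
#> m04 0.0 3.0 -6.0    4
dci(urine)
#> [1] 0.9545455
```

Both scoring systems recover the latent order (m01 highest), and the DCI of
0.95 says almost all interactions ran in each dyad's dominant direction.
Correlating final Elo scores across the two assays shows the inversion:

```r
tube <- subset(sim$matches, assay == "tube")
panel <- score_panel(data.frame(
  animal = rep(names(elo_ratings(urine)$final), 2),
  assay  = rep(c("urine", "tube"), each = 4),
  score  = c(elo_ratings(urine)$final, elo_ratings(tube)$final)))
score_correlation_matrix(panel, min_n = 4, p_adjust = "none")
#> Dominance score correlations, group: all (p adjust: none )
#>        urine   tube
#> urine  1.000 -0.981
#> tube  -0.981  1.000
```

The full chain — simulation, ranking, pose features, state discovery,
enrichment, cross-assay comparison — can be driven from one YAML file with
`run_pipeline("run.yaml")` (see `?run_pipeline`), or from the shell via the
wrapper in `inst/scripts/domsuite`.

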