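# dkoscreen

Monte-Carlo simulation and scoring of growth-based single- and
double-knockout CRISPR screens, with known ground-truth genetic
interactions.

## The problem

Combinatorial CRISPR screens knock out gene pairs to detect genetic
interactions (GIs) — deviations of double-knockout (DKO) fitness from the
additive expectation of the two single knockouts (SKO). GIs are rare,
screen data are noisy, and no gold-standard dataset of true interactions
exists, so GI-calling methods cannot be benchmarked on laboratory data
and library designs cannot be compared on the quantity that matters:
recovery of known truth. `dkoscreen` is for computational biologists and
screen designers who need synthetic DKO screen data in which every
phenotype and every interaction is set by construction.

## The model

Time is discrete in wild-type doubling cycles. A single-knockout cell
with phenotype *p* ∈ [−1, 1] divides *x* ~ Multinoulli(0, 1, 2; (−p)₊,
1 − |p|, (p)₊) times and leaves 𝟙(x ≠ 0)·2ˣ descendants. A
double-knockout combines the two independent division variables through
y = 𝟙(x₁x₂ ≠ 0)(x₁ + x₂ − 1) ∈ {0, 1, 2, 3}, giving a closed-form
division-probability vector **p**ᵧ. Interacting pairs have their
phenotypes resampled as pᵢᴵ ~ N₍₋₁,₁₎(pᵢ, σ²\_GI), and the true
interaction is

π = E(Cᵧ | p₁ᴵ, p₂ᴵ) − E(Cᵧ | p₁, p₂),  E(Cᵧ) = 2p₁ᵧ + 4p₂ᵧ + 8p₃ᵧ.

Libraries are initialized with per-gene log-normal frequency seeds split
over guides by Dirichlet draws; populations grow by exact multinomial
sampling and pass through multivariate-hypergeometric bottlenecks
retaining the Poisson single-infection fraction λe^(−λ) ≈ 22% at
MOI λ = 0.3. Screens are scored with delta log fold change,
dLFC = LFC_DKO − SMF₁ − SMF₂ (and its z-score, zdLFC), and evaluated by
Pearson r against π, precision/recall of the 80 most-negative dLFC pairs
against the 100 most-negative π pairs, AUC-PR, read concentration, and
replicate reproducibility.

## Worked example

```r
library(dkoscreen)
cfg <- simConfig(n = 20, coverage = 50, pctGI = 0.3, seed = 7)
se <- simulateScreen(cfg, nReplicates = 2)
se
#> ScreenExperiment: 1770 constructs x 2 replicate(s)
#>   genes: 20  guides/gene: 3  coverage: 50 x
#>   doublings per replicate: 3, 3
#>   assays: counts0, counts2, freq0, freq2, lfc

scores <- scoreInteractions(se)
head(scores[order(scores$dlfc), c("k1", "k2", "dlfc", "zdlfc", "pi", "I")])
#>     k1 k2      dlfc     zdlfc        pi I
#> 123  3 17 -4.536414 -2.776410 -3.333297 1
#> 8    2  5 -4.359117 -2.693370 -1.993287 1
#> 169 16 19 -3.877700 -2.467887 -1.687116 1
#> 137  1 18 -3.678227 -2.374459 -1.773017 1
#> 73   7 13 -3.497061 -2.289606 -1.884882 1
#> 113  8 16 -3.251936 -2.174796 -1.527653 1

unlist(screenMetrics(se, scores, kPred = 10, kTruth = 15))
#>      r_dlfc_pi precision_at_k    recall_at_k aucpr_negative  top5_fraction
#>      0.9170700      1.0000000      0.6666667      0.9663562      0.4600764
#>    replicate_r
#>      0.9853837
```

The six most-negative dLFC pairs are all flagged interactions (`I = 1`)
with strongly negative true π: at this toy scale the score recovers the
planted synthetic-lethal pairs essentially perfectly (precision 1 at
k = 10), while `replicate_r` shows two independently grown replicates of
the same library agree to r ≈ 0.99.

A full 120-gene baseline screen (64,620 constructs, coverage 100x)
simulates in about a second: `simulateScreen(simConfig(), seed = 1)`.
Configurations are serializable (`readSimConfig()`/`writeSimConfig()`),
published designs are available via `presetConfig()`, results are written
with `writeScreenResult()` (construct CSV, gene-pair CSV, metrics JSON,
run log with total doublings), and `sweepScreens()` drives parameter
grids for design profiling.

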