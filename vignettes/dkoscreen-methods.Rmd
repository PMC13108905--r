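---
title: "Simulating double-knockout CRISPR screens with known genetic-interaction truth"
author: "dkoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating double-knockout CRISPR screens with known genetic-interaction truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkoscreen)
```

## Why simulate a combinatorial knockout screen

Genetic interactions (GIs) — cases where the fitness cost of knocking out
a gene pair deviates from the expectation under independence of the two
single knockouts — are rare and cannot be validated in high throughput,
so there is no gold-standard dataset in which the true interactions are
known. Competing GI-calling methods therefore cannot be benchmarked on
laboratory data alone. `dkoscreen` generates growth-based single-
(SKO) and double-knockout (DKO) screen data in which every gene's fitness
phenotype and every pair's interaction value are set by construction, so
that scoring methods and *library designs* (coverage, guide efficacy,
guides per gene, initial-count dispersion, number of cell doublings,
interaction magnitude) can be profiled against a known truth.

## The cell-division model

Time advances in units of one wild-type doubling cycle. A cell carrying a
single knockout of a gene with theoretical phenotype $p \in [-1, 1]$
divides $x$ times in one cycle, with

$$x \sim \mathrm{Multinoulli}\big(0,1,2;\ (-p)_+,\ 1-|p|,\ (p)_+\big),$$

where $(a)_+ = \max(a, 0)$: negative phenotypes convert wild-type
divisions into death, positive phenotypes into double divisions, and
$p = 0$ leaves deterministic wild-type doubling. A cell dividing $x$
times leaves $\mathbb{1}(x \neq 0)\, 2^x$ descendants (death, 2, or 4).

For a double knockout the two division variables $x_1 \perp x_2$ combine
through

$$y = \mathbb{1}(x_1 x_2 \neq 0)\,(x_1 + x_2 - 1) \in \{0,1,2,3\},$$

so death of either knockout kills the cell and surviving division counts
add, minus the shared wild-type division. Pushing the independent joint
distribution of $(x_1, x_2)$ through $y$ gives the closed-form
division-probability vector implemented in `dkoDivisionProbs()`; when one
gene is a non-targeting control ($p = 0$) the DKO distribution collapses
exactly to the partner's SKO distribution, which is the property that
makes control-partnered constructs behave as single knockouts.

The expected number of descendants per cycle is
$E(C_y) = 2p_1 + 4p_2 + 8p_3 \in [0, 8]$ (`expectedDescendants()`).

### Ground-truth interactions

A fraction `pctGI` of the gene pairs containing no control gene is
flagged as interacting. For a flagged pair, the two phenotypes are
resampled ("jiggled") as $p_i^I \sim N_{[-1,1]}(p_i, \sigma_{GI}^2)$, and
the true interaction is defined on the growth-rate scale as

$$\pi = E(C_y \mid p_1^I, p_2^I) - E(C_y \mid p_1, p_2) \in [-8, 8],$$

computed from *gene-level* phenotypes only — guide efficacy never enters
the truth value (`trueGI()`). Non-flagged pairs have $p_i^I = p_i$ and
exactly $\pi = 0$. The jiggle is defined per pair: the same gene may
carry different jiggled phenotypes in different pairs, because an
interaction is a property of the pair, not of the gene.

## Library construction

`buildLibrary()` assembles the initial cell population:

1. **Gene panel.** Each of the $n$ genes is assigned to a class —
   negative, positive, wild-type, non-targeting control, and optionally
   an "unknown" class used to mimic unannotated panels. Counts are
   `round(fraction * n)` per class, remainder to wild-type, with a
   seeded shuffle deciding which gene index gets which class. Phenotypes
   are truncated-normal per class: negative on $[-1, -0.025]$, positive
   on $[0.025, 1]$, wild-type on $[-0.025, 0.025]$, unknown on
   $[-0.5, 0.5]$; controls are exactly 0.
2. **Frequency seeds.** $\log_{10} f'_k \sim N(0, \sigma_f^2)$ per gene;
   a pair's seed is the mean of its genes' seeds. The default
   $\sigma_f = 1/3.29$ puts a 10-fold gap between the 95th and 5th
   percentiles of the initial count distribution;
   `sigmaFFromConfidence()` maps any two-sided confidence level to the
   matching $\sigma_f$.
3. **Guides.** `round(pctHeg * n * nGuides)` guides are high-efficacy.
   In `CRISPRn` mode efficacies are truncated-normal on $[0.6, 1]$
   (high, default mean 0.9) and $[0, 0.6]$ (low, default mean 0.05), so
   the two categories never overlap; in `CRISPRn-100%Eff` mode every
   efficacy is exactly 1. A guide's effective phenotype is
   $p^{I\prime} = p^I \times \mathrm{Eff}$, attenuating the knockout
   when the guide is weak.
4. **Dirichlet allocation.** A gene's seed is split over its `nGuides`
   guides by a symmetric Dirichlet($\alpha = 100$) draw, and a pair's
   seed (times `nGuides`) over its `nGuides`$^2$ guide pairs, which
   makes the average frequency of a pair's dual constructs equal the
   average frequency of its genes' single constructs — an exact identity
   asserted in the tests. Relative frequencies are normalized globally,
   and integer initial counts are `round(f_rel * L0)` with
   $L_0 = C \times n_\mathrm{constructs}$ (coverage $C$ cells per
   construct). Counts may round to zero: dropout at low coverage is part
   of what the simulator is for, so there is no floor of one.

## Growth, bottlenecks and readout

`runScreen()` iterates while fewer than `nEncounters` bottlenecks have
occurred and fewer than `maxDoublings` (default 30) cycles have run:

* if the library size exceeds `nBottleneck` times the realized initial
  size (strict inequality), a bottleneck fires: transduction at Poisson
  multiplicity of infection $\lambda = 0.3$ retains the singly-infected
  fraction $\lambda e^{-\lambda} \approx 22\%$ of the current cells,
  drawn without replacement across constructs as a multivariate
  hypergeometric sample (sequential conditional `rhyper()` draws —
  exact and linear in constructs);
* every construct then grows one cycle by an exact multinomial draw over
  its division probabilities (vectorised as sequential binomials).

The bottleneck check precedes growth inside an iteration, so the final
bottleneck is still followed by one doubling; under the baseline
parameterization (`nBottleneck = 2`, `nEncounters = 1`) this yields
exactly three total doublings, which the tests assert. Every cycle is
logged (`t`, `ie`, library size, bottleneck, retained cells), and the
log is written to `run_log.txt` by `writeScreenResult()`.

Readout converts final counts to relative frequencies and per-construct
log2 fold change
$\mathrm{LFC} = \log_2\!\big((f^{rel}_2 + C_{pseudo}) / (f^{rel}_0 +
C_{pseudo})\big)$. The pseudocount defaults to $1/L_0$ — one cell on the
frequency scale — which keeps control-construct LFC centred at zero
while barely perturbing well-covered constructs; it is configurable
because published analyses rarely print their value. Replicates share
the initialized library (one `buildLibrary()` call) but grow under
independent RNG streams derived from the run seed, mirroring
independently transduced biological replicates of one library design;
replicate LFCs are aggregated by the elementwise mean.

## Scoring and evaluation

`scoreInteractions()` computes, per gene pair, the mean LFC of the
pair's dual constructs, each gene's single-mutant fitness (SMF, mean SKO
LFC over its guides), and

$$\mathrm{dLFC} = \mathrm{LFC}_{DKO} - \mathrm{SMF}_1 - \mathrm{SMF}_2,$$

plus its z-standardized version zdLFC (sample SD; mean 0 and SD 1 by
construction). Negative dLFC flags synthetic-sick/lethal pairs.
`screenMetrics()` assembles the evaluation panel: Pearson $r$ between
dLFC and $\pi$ over all pairs, precision/recall of the 80 most-negative
dLFC pairs against the 100 most-negative $\pi$ pairs, step-wise AUC-PR
with negative-$\pi$ pairs as positives, the fraction of final reads in
the top 5% of constructs, and the between-replicate LFC correlation.

Two tie-break/edge decisions worth knowing:

* top-$k$ selection breaks ties by stable pair order;
* the number of pairs with strictly negative $\pi$ is itself stochastic
  and fluctuates around 100 under the baseline design, so when fewer
  than `kTruth` strictly negative pairs exist the truth set is padded by
  stable order among the zero-interaction pairs with a warning
  (`requireNegatives = TRUE` turns this into an error). Pairs containing
  controls are scored — they are useful nulls — but can never enter the
  truth set by construction.

## Baseline parameterization and problem sizes

The `simConfig()` defaults are the systematic baseline: $n = 120$ genes
(15% negative with phenotype mean $-0.75$, 5% positive at $+0.75$, 75%
wild-type, 5% controls), 3 guides per gene, coverage 100x (64,620
constructs, $L_0 = 6{,}462{,}000$ cells), 3% interacting pairs with
$\sigma_{GI} = 1.5$, $\sigma_f = 1/3.29$, all guides fully efficient,
bottleneck at $2 L_0$ with one encounter. `presetConfig()` ships the
published library-design mimics (28-gene/5-guide, 120-gene, and a
246-gene panel with 64 negatives, 178 unknown-class genes, 4 controls at
coverage 1000x). The unit tests exercise reduced shapes (3–20 genes) for
exactness properties and run the full 120-gene baseline for the
reproduction checks, averaging stochastic statistics over five seeds;
the acceptance script uses twelve seeds per condition. These sizes are
the package's own choice of a replication level at which seed-to-seed
spread of the reported means is small relative to the effects measured.

## What the generator does and does not emulate

Emulated: per-construct count data with realistic dispersion,
selection-driven loss of diversity across doublings, dropout at low
coverage, transduction bottlenecks, guide-efficacy heterogeneity, and
replicate structure with shared library and independent growth noise.

Not emulated: off-target edits; sequencing-depth resampling (reads equal
cells); continuous-time or unequal-interval division (cells divide 0–3
times per discrete cycle); multiple infections per cell (MOI enters only
as the bottleneck retention fraction); and guide-sequence design (PAM
sites, cut positions). Passing tests therefore certify the sampling
machinery and scoring arithmetic, not that any particular laboratory
screen is distributed exactly like the simulation.

A further caveat on reproduction checks: published single-run sweep
values carry their own Monte-Carlo noise. In our replications the
statistics at the extreme parameter settings — precision at
$\sigma_{GI} = 1$ and the dLFC correlation at $\sigma_f = 1/1.05$ — come
out below the published single-run values even after seed averaging,
i.e. our tunability curves bend at slightly different knees, while the
baseline, coverage, guide-efficacy, read-concentration and
reproducibility statistics agree. One candidate explanation is the
treatment of the phenotype jiggle at the boundary: this package samples
the truncated normal exactly (inverse CDF on the truncated range),
whereas clipping draws to $[-1, 1]$ would place probability atoms at the
boundaries and inflate interaction magnitudes; the printed model is the
truncated distribution, which is what we implement.

## Numerical choices

* Rounding of counts and class sizes uses round-half-to-even (R's
  `round()`); the model description does not state a tie rule.
* Truncated normals are sampled by inverse CDF on the truncated range —
  exact, reproducible, and correct for intervals far in a tail (an error
  is raised below ~1e-300 of probability mass).
* Dirichlet draws are normalized `rgamma()` vectors.
* Phenotypes exactly at $\pm 1$ are legal boundary inputs; no epsilon
  clipping anywhere.
* One integer seed drives a root RNG; the initialization consumes it
  first and per-replicate growth seeds are drawn from it, so the same
  seed reproduces every output byte-for-byte (asserted in the tests).
* Degenerate inputs are defined rather than accidental: `nEncounters =
  0` returns the initial counts untouched; an extinct library is an
  explicit error; `sigma = 0` truncated normals return their mean.

## A worked session

```{r example}
cfg <- simConfig(n = 20, coverage = 50, pctGI = 0.3, seed = 7)
se <- simulateScreen(cfg, nReplicates = 2)
se
scores <- scoreInteractions(se)
head(scores[order(scores$dlfc), c("k1", "k2", "dlfc", "zdlfc", "pi", "I")])
unlist(screenMetrics(se, scores, kPred = 10, kTruth = 15))
```

Sweeps over designs use `sweepScreens()`:

```{r sweep, eval = FALSE}
sweepScreens(simConfig(), list(coverage = c(1, 5, 10, 50, 100, 200, 500)),
             seeds = 1:5, nReplicates = 2)
```

## Known limitations

Scalability: constructs grow as $n^2 n_g^2$; a 120-gene, 3-guide library
(64,620 constructs) simulates in seconds, but thousand-gene panels
produce millions of constructs and the per-construct bookkeeping
dominates. The model also treats every guide's efficacy as acting
multiplicatively on the phenotype, and treats replicates as sharing the
exact initialized counts rather than re-sampling transfection; both are
simplifications a user should keep in mind when transferring conclusions
to laboratory designs.
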