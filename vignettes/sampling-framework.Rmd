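---
title: "Ensemble sampling of binary realizations for quantitative AP-MS interaction scoring"
author: "apmsEnsemble authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble sampling for quantitative AP-MS scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsEnsemble)
```

## The problem

An AP-MS study purifies a set of tagged bait proteins and identifies the
prey proteins that come down with each bait, quantified by spectral counts.
The collated result is a prey × experiment matrix of non-negative integer
counts. Most matrix-model scoring methods for inferring protein–protein
interactions from such data operate on a *binary* presence/absence matrix,
so the count matrix is usually collapsed by replacing every positive count
with 1 ("direct binarization"). That collapse throws away the information
that a prey seen with 40 counts is a far more credible observation than a
prey seen once — and in real data sets roughly half of all positive counts
are 1 or 2, exactly the regime where contaminants concentrate.

`apmsEnsemble` implements a sampling framework that keeps binary scorers
unchanged while feeding them the quantitative information. A count `n`
becomes the probability

$$q_{ij} = 1 - (1 - p)^{n_{ij}}$$

that the observation is real, where `p` is the reliability of a single
spectral count (each of the `n` counts is viewed as an independent
observation, so the cell is "real" unless all `n` fail). An ensemble of
binary realizations is drawn by sampling each cell as an independent
Bernoulli variable with probability `q_ij`; every realization is scored
with the chosen binary scorer; and the per-pair scores are averaged over
the ensemble. Low-count observations thus participate in only a fraction
of realizations and are smoothly down-weighted, instead of being kept or
discarded wholesale.

## Scorers

All scorers consume per-experiment *presence sets*: the preys with a 1 in
the realization column plus, by default, the experiment's bait (a purified
sample physically contains its bait; this can be disabled). Control
columns are excluded by default, since none of these scorers model
controls. Replicate columns are treated as independent experiments.

**Null-model (Hart-style) scores.** With `s_e` proteins present in
experiment `e`, the co-purifying-pair bookkeeping is

- `X[A,B]` — number of experiments in which A and B co-purify,
- `N_A = Σ_{e ∋ A} (s_e − 1)` — co-purifying-pair incidences of A,
- `N = Σ_e C(s_e, 2)` — total co-purifying pairs,

and the null expectation is the rank-one factorization
`λ_AB = N_A N_B / N`. The Poisson score is
`−log(1 − PoissonCDF(X_AB; λ_AB))`, i.e. the strictly-greater-than upper
tail; the hypergeometric variant refers `X_AB` to a hypergeometric
distribution with population `N`, `N_A` marked items and `N_B` draws,
which the Poisson form approximates as the population grows. Because the
printed Poisson form fixes only the strict tail, both scorers expose a
`tail` flag (`"gt"` default, `"ge"` for the inclusive tail) applied
uniformly so that the two can be compared under the same convention.

**Socio-affinity index (SAI).** An observed/expected log-ratio score with
two directed spoke terms (how often each protein retrieves the other as
bait, relative to the partner's overall retrieval frequency) and a matrix
term (co-retrievals as preys relative to independence). This package uses
additive (+1) smoothing in both numerator and denominator, which keeps
every term finite on degenerate inputs while preserving sign: a pair never
seen together and never retrieving each other scores ≤ 0. Raw SAI scores
are unbounded below, so the ensemble aggregator floors each
per-realization SAI score at 0 before averaging (configurable;
no floor is applied for the other scorers).

**Purification enrichment (PE).** A likelihood-ratio score with two
parameters: `r`, the probability of detecting a true association in a
purification (default 0.3), and `n_pseudo`, the number of pseudocounts
added for each prey (default 10). Each bait experiment contributes
`log(r / f_j)` when the partner is retrieved and `log((1−r)/(1−f_j))`
when it is not; prey–prey evidence contributes analogous terms for
co-retrieval under independence (`f_i f_j`). The background frequency
`f_j` is the fraction of experiments retrieving prey `j`, regularized by
`n_pseudo` pseudocounts at the average prey frequency and clamped to
`[10^-6, 1 − 10^-6]`. The exact constants of the originally published
spoke/matrix weightings are not recoverable here, so these forms are this
package's own documented construction; both SAI and PE are verified
against independent straight-loop reference implementations in the test
suite.

**Baseline.** `spectralSumBaseline()` ranks each observed bait–prey pair
by the summed spectral counts of the prey over that bait's non-control
experiments — the natural quantitative comparator for all evaluations.
Summation (rather than the per-experiment maximum) was chosen so that
reproducible replicate observations rank above one-off large counts; when
two baits pull each other reciprocally, both contributions accumulate on
the one canonical pair.

## Ensemble mechanics and numerical choices

- **Candidate universe.** The mean is taken over a *fixed* pair universe
  determined by the direct binarization of the raw counts (all pairs that
  can ever co-occur, plus bait–prey retrieval pairs for the spoke-aware
  scorers). A pair absent from one realization's candidate set contributes
  0 for that trial — not the scorer's value at `X = 0` — so that "not
  observed in this realization" is neutral rather than weak evidence.
- **Degeneracy.** At `p = 1` every realization equals the direct
  binarization, and the ensemble score reduces exactly — in values and
  ranking — to the single-matrix score (for SAI, to the clamp-floored
  score under the default floor).
- **Reproducibility.** Each trial draws from its own substream seeded by a
  fixed function of `(seed, trial)`, with cells filled in a fixed
  column-major order. Any trial can therefore be regenerated in isolation
  and serial or trial-parallel execution gives identical results.
- **Defaults.** `p = 0.3` and 120 trials; both exposed. 120 trials keeps
  a full default-preset run to a few seconds while quadrupling the
  ensemble changes rankings only marginally (see below).
- **Guards.** Tail probabilities are floored at `1e-300` before `−log`, so
  scores are finite with a cap near 690.8 nats; `λ = 0` yields score 0.
  Scores are natural-log based throughout.
- **Ranking ties** are broken by `(a, b)` ascending lexicographic *byte*
  order, independent of the session locale, making every ranked output
  deterministic.

## The synthetic generator

There is no public ground truth at desk scale, so the package ships a
generative model used by all end-to-end tests. It emulates two qualitative
features of real AP-MS matrices: positive background counts concentrate at
1–2, and contamination is approximately rank-one (sticky proteins hit all
experiments in proportion to a protein-specific propensity).

Mechanics: disjoint complexes are planted in the protein universe; each
experiment purifies one bait (chosen round-robin from
`baits_per_complex` members per complex, so some baits have replicates);
each co-complex partner of the bait is detected with probability
`p_detect_true` and receives a count `1 + Poisson(mu_true − 1)`;
a `Poisson(contaminant_rate)` number of contaminant preys per experiment
is drawn with Dirichlet-distributed stickiness weights, each with a
geometric (support ≥ 1) count.

The default preset — 300 proteins, 40 complexes of size 5 (100 background
proteins), 150 experiments, 3 baits per complex, `p_detect_true = 0.7`,
`mu_true = 6`, `contaminant_rate = 8`, `contaminant_geom_p = 0.6`,
Dirichlet α = 0.5 — puts well over half of contaminant counts at 1–2 with
true-interactor counts stochastically larger, i.e. the regime in which
probabilistic down-weighting of single counts should help. The preset was
fixed once, before any end-to-end evaluation, and is not tuned per test.
What the generator does **not** emulate: peptide-level detectability,
protein length and abundance effects, MS1 intensities, overlapping or
sub-stoichiometric complexes, and bait-specific efficiency differences.
Passing the synthetic recovery tests therefore demonstrates internal
correctness of the machinery and the direction of the effect in the
intended regime — not performance on any particular real data set.

## Evaluation protocol

`evaluateTopK()` counts how many of the top-K ranked pairs appear in a
gold standard subset at a given evidence-support threshold; subsets at
higher thresholds are nested by construction, and counts are monotone in
K. `relativeToBaseline()` reports differences against the
spectral-count-ranking baseline, and `sweepP()` traces the improvement of
the ensemble over direct binarization as a function of `p`. For synthetic
scenarios the natural operating point K = (number of planted pairs) is
used. `averagePrecision()` summarizes a whole ranking when a single-number
comparison across replicates is needed.

## Problem sizes used in the shipped checks

End-to-end checks run the default preset (300 × 150) with 120-trial
ensembles: ten seeded replicates for the recovery comparison, a
four-values-of-`p` sweep per replicate, and one 120-vs-480-trial stability
comparison. These sizes keep the complete suite within a few minutes on a
single core while leaving the stochastic assertions well-powered.

## Known limitations

- Whole-universe rank stability at 120 trials is limited by the thousands
  of low-score contaminant pairs whose ensemble means rest on ~10 effective
  observations each; their mutual order remains noisy even though the top
  of the ranking is stable. Spearman correlation between independent
  120- and 480-trial runs on the default preset is ≈ 0.976, climbing
  monotonically with ensemble size (≈ 0.994 at 480 vs 1920).
- The identity-then-mean aggregation (with the SAI floor) is the only
  aggregation implemented; alternative transforms of per-realization
  scores are out of scope.
- Only the count → probability map `1 − (1−p)^n` is provided; saturating
  or abundance-normalized maps would slot into the same interface.
- SAI and PE follow this package's documented formulas (above), not a
  byte-level reproduction of the originally published implementations.

## A minimal session

```{r example}
sim <- simulateApms(syntheticParams(n_proteins = 60, n_complexes = 8,
                                    complex_size = 4, n_experiments = 40,
                                    seed = 7))
ens <- ensembleScore(sim$counts,
                     ensembleConfig(p = 0.3, trials = 60, seed = 1))
bin <- ensembleScore(sim$counts,
                     ensembleConfig(p = 1, trials = 1, seed = 1))
c(ensemble = averagePrecision(ens, goldSubset(sim$gold, 1)),
  binarization = averagePrecision(bin, goldSubset(sim$gold, 1)))
```
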