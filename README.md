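# apmsEnsemble

Ensemble sampling of binary realizations for quantitative AP-MS
protein–protein interaction scoring.

## The problem

Affinity-purification mass spectrometry (AP-MS) studies produce a
prey × experiment matrix of spectral counts: each purification of a tagged
bait protein yields, for every prey identified, a semi-quantitative count
of peptide-spectrum matches. Matrix-model interaction scorers — which
infer both bait–prey and prey–prey interactions from co-occurrence across
purifications — mostly operate on *binary* presence/absence data, so the
count matrix is usually collapsed by turning every positive count into a
1. That collapse discards the difference between a prey observed once
(quite possibly noise: in real data sets roughly half of all positive
counts are 1 or 2) and a prey observed with hundreds of counts.

`apmsEnsemble` keeps binary scorers unchanged while restoring the
quantitative information. Each count *n* is converted to the probability

    q = 1 − (1 − p)^n

that the observation is real, where *p* ∈ (0, 1] is the reliability of a
single spectral count (default 0.3). An ensemble of binary realizations
(default 120) is drawn by sampling every cell as an independent Bernoulli
variable with probability *q*; each realization is scored with an
unmodified binary scorer; and per-pair scores are averaged over the
ensemble. At *p* = 1 the procedure reduces exactly to the conventional
direct binarization.

Shipped binary scorers: the Hart-style co-occurrence null model with score
`−log(1 − PoissonCDF(X_AB; λ_AB))`, `λ_AB = N_A N_B / N` (and its exact
hypergeometric counterpart), the socio-affinity index (SAI), the
purification-enrichment (PE) likelihood-ratio score (`r` = 0.3,
`n_pseudo` = 10 by default), and a raw co-occurrence count. A
spectral-count-ranking baseline, a top-K gold-standard validation
protocol, a reliability-parameter sweep, and a synthetic AP-MS generator
with planted complexes and a sticky-contaminant background complete the
pipeline. See `vignettes/sampling-framework.Rmd` for the model details.

Intended users: proteomics / systems-biology analysts post-processing
AP-MS count matrices, and method developers who want a drop-in way to make
a binary PPI scorer count-aware.

## Worked example

```r
library(apmsEnsemble)

# synthetic study: 8 planted complexes of 4 proteins, 40 purifications,
# sticky contaminants with counts mostly 1-2
sim <- simulateApms(syntheticParams(n_proteins = 60, n_complexes = 8,
                                    complex_size = 4, n_experiments = 40,
                                    seed = 7))
sim$counts
#> SpectralCountMatrix: 60 preys x 40 experiments
#>   baits known for 40 experiment(s); 0 control column(s)
#>   418 positive cells; max count 12

ens <- ensembleScore(sim$counts,
                     ensembleConfig(p = 0.3, trials = 60, seed = 1))
ens
#> PairScoreTable: 971 pair(s), scorer 'ensemble_hart_poisson'
#>   top pairs:
#>     P52 -- P55  5.741
#>     P20 -- P49  5.406
#>     P09 -- P38  4.833

bin <- ensembleScore(sim$counts, ensembleConfig(p = 1, trials = 1, seed = 1))
c(ensemble     = averagePrecision(ens, goldSubset(sim$gold, 1)),
  binarization = averagePrecision(bin, goldSubset(sim$gold, 1)))
#>     ensemble binarization
#>    0.8561489    0.2932109
```

The two numbers are average precisions for recovering the planted
co-complex pairs from the full ranking: the 60-trial sampling ensemble at
*p* = 0.3 recovers the planted structure far better (0.86) than scoring a
single all-positive-counts-to-1 binarization with the same Poisson null
model (0.29), because contaminant cells with counts of 1–2 enter only a
minority of realizations.

A command-line front end covers the same pipeline:

```sh
exec/apmsensemble simulate --seed 7 --out-counts counts.tsv \
    --out-meta meta.tsv --out-gold gold.tsv
exec/apmsensemble ensemble --counts counts.tsv --meta meta.tsv \
    --scorer hart_poisson --p 0.3 --trials 120 --seed 17 --out ranked.tsv
exec/apmsensemble evaluate --ranked ranked.tsv --gold gold.tsv \
    --cutoffs 200,400 --thresholds 1 --out curves.tsv
```

Every output gets a `<out>.config.yaml` sidecar echoing the resolved
configuration, so any run can be reproduced exactly.

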