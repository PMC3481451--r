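# promsig

Promoter chromatin-signature discovery from paired RNA polymerase II and
H3K4me2 ChIP-seq coverage.

Active promoters have recognisable coverage *shapes*: Pol-II piles up at and
just downstream of the transcription start site (with a tail over the gene
body when the gene is elongating), while H3K4me2 flanks the TSS, often
bimodally. `promsig` is for genomicists who want to move beyond binary peak
calls: it learns the recurring promoter shapes from annotated TSSs, models
each one parametrically, and scans a genome for further loci matching any of
them — candidate novel promoters, alternative promoters inside gene bodies,
and promoter-like regulatory elements (enhancers, CpG islands, CTCF sites).

## The model

TSS-centered windows (101 bins of 100 bp; 5 kb each side, gene-oriented) of
both marks are smoothed, filtered (isolated TSSs only, minimum signal,
minimum variance) and clustered by k-means under correlation distance
1 − r, with the number of shapes chosen by the mean silhouette width. Each
cluster's mean profile per mark is then fitted with a finite mixture of two
double-exponential (Laplace) peaks and a uniform tail component,

f(t) = π₁ e^(−|t−μ₁|/β₁) / 2β₁ + π₂ e^(−|t−μ₂|/β₂) / 2β₂ + π₃ 1[a ≤ t ≤ b] / (b−a),

by minimizing the Kullback–Leibler divergence between the observed bin
distribution and the normalized model density, using a derivative-free
generalized pattern search (coordinate polling on an adaptive mesh, 16
restarts, stopping at 20,000 evaluations / 2,000 iterations / 10⁻⁶
tolerances). The fitted Pol-II and H3K4me2 densities are concatenated into
per-cluster templates; the genome is scanned with a sliding window whose
per-mark standardized segments are correlated with every template in both
orientations, and positions exceeding the 95th percentile of a
bin-permutation null are merged into called regions. Regions are finally
annotated hierarchically (RefSeq promoter > gene body > ncRNA > EST >
assembled transcript > ER > AR > CpG > CTCF), plus independent per-category
overlap counts.

## Worked example

Fit the mixture to a profile drawn from known parameters:

```r
library(promsig)
truth <- mixture_params(c(0.4, 0.4, 0.2), mu = c(-10, 10), beta = c(5, 5))
y   <- simulate_profile(truth, n_reads = 10000, seed = 7)
fit <- fit_mixture(y, seed = 3)
fit
#> Promoter-shape mixture fit (KL minimization by pattern search)
#> <mixture_params> pi=(0.402, 0.397, 0.202)  mu=(-10.01, 9.96)  beta=(5.05, 5.03)  U[-50.0, 50.0]
#> KL divergence: 0.00518275   (start 4, step_tol after 2784 evals)
round(coef(fit), 3)
#>     pi1     pi2     pi3     mu1     mu2   beta1   beta2       a       b
#>   0.402   0.397   0.202 -10.011   9.957   5.048   5.033 -50.000  50.000
```

All nine generating parameters come back within a few percent from a single
10,000-read profile. The fit is a classed model object with `coef`,
`predict`, `fitted`, `residuals`, `plot` and `simulate` methods.

Run the whole pipeline on a seeded synthetic genome (600 kb, 12 planted
signature regions over Poisson background; every stage writes plain-text
artifacts to the run directory):

```r
cfg <- pipeline_config(seed = 1, genome_length = 600000, n_plants = 12,
                       n_perm = 1000, k_range = 2)
run_stage("all", cfg, "run1")
#> regions.bed.tsv: 33 called regions; null.json: threshold_z = 0.159
#> annotation_counts.json (hierarchical):
#>   RefSeq_promoter EST CpG CTCF unmapped
#>                 7   2   2    1       21
```

All 12 planted regions are recovered within 500 bp of their true centers
(the remaining calls are background exceedances at the 5% threshold, as
expected without multiple-testing correction). The same stages are available
from a shell via the thin wrapper `inst/scripts/promsig`:

```sh
Rscript inst/scripts/promsig --stage all --run-dir run1 --seed 1 n_plants=12 genome_length=600000
```

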