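---
title: "Modeling promoter chromatin signatures with promsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling promoter chromatin signatures with promsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promsig)
```

## The problem

Active promoters leave a characteristic footprint in ChIP-seq coverage: RNA
polymerase II (Pol-II) accumulates at and just downstream of the
transcription start site (TSS), often with a tail of elongating polymerase
over the gene body, while H3K4me2 — a histone mark of active and poised
promoters — tends to flank the TSS bimodally. Promoters differ, though:
stalled polymerase gives a sharp peak without a tail, shifted peaks may mark
poised genes, and no single binary peak call captures these shapes. promsig
treats the *shape* of the paired Pol-II/H3K4me2 profile as the object of
inference: it learns the recurring shapes at known TSSs, fits each one with
a compact parametric model, and then searches a genome for further loci —
candidate novel or alternative promoters, and promoter-like regulatory
elements — whose coverage matches any learned shape.

## Data model and pre-processing

Coverage for both marks is summed into 100-bp bins. Around each annotated
TSS a window of 101 bins (positions $t \in \{-50,\dots,50\}$, i.e. 5 kb on
each side) is cut from both tracks; minus-strand windows are reversed so
that negative $t$ is always upstream in gene orientation. Without that
reversal the downstream Pol-II tail would cancel between strands and the
learned shapes would be artificially symmetric.

Pre-processing follows a fixed order:

1. **smoothing** — each bin is replaced by the mean of three consecutive
   bins. At the vector ends the window shrinks rather than padding, so no
   data is invented and length is preserved;
2. **isolation** — TSSs with another TSS within 10 kb are dropped entirely,
   on either strand, so neighbouring genes cannot write into each other's
   windows;
3. **low signal** — profile pairs whose maximum smoothed count across both
   marks is below 4 are dropped;
4. **low variance** — the variance of each concatenated pair is computed and
   pairs below the 10th percentile (linear interpolation, R's default
   quantile definition, used consistently for every percentile in the
   package) are dropped. Near-flat profiles otherwise dominate
   correlation-based clustering, which is scale-free.

The filter report reconciles exactly: input = retained + removals per stage,
including a separate count for TSSs whose window would leave the chromosome.

## Shape discovery: correlation k-means and silhouette

Profile pairs are clustered with k-means under correlation distance
$d(x, y) = 1 - r(x, y)$. Each half of the concatenated vector is
standardized separately (zero mean, unit norm per mark) so that both marks
contribute equally regardless of sequencing depth, and the whole row is then
unit-normalized. On such vectors the correlation distance is half the
squared Euclidean distance, so clustering is realized as spherical k-means:
Lloyd iterations with mean-and-renormalize centroid updates are then
guaranteed to decrease the within-cluster distance monotonically. Ten seeded
restarts are used by default and the best restart (smallest within-cluster
distance sum) is kept; an empty cluster arising mid-iteration is re-seeded
from the worst-fitting point of a cluster that can spare one.

The number of clusters is chosen by the mean silhouette width under the same
distance, computed via the `cluster` package; ties break toward fewer
clusters, and singleton clusters contribute zero width. Real promoter
collections of this kind typically resolve into a small handful of shapes —
on the order of four — but the package assumes nothing about that number
and simply maximizes the silhouette over a user-set range (default 2–8).

## The mixture model

Each cluster's mean Pol-II and mean H3K4me2 profiles are fitted
independently with a three-component mixture on the bin grid:

$$f(t) = \pi_1 \frac{e^{-|t-\mu_1|/\beta_1}}{2\beta_1}
       + \pi_2 \frac{e^{-|t-\mu_2|/\beta_2}}{2\beta_2}
       + \pi_3 \frac{\mathbf{1}[a \le t \le b]}{b-a},
\qquad \textstyle\sum_i \pi_i = 1 .$$

Two double-exponential (Laplace) components capture unimodal or bimodal
peaks — Pol-II is typically unimodal, H3K4me2 bimodal — and the uniform
component absorbs the flat tail that elongating polymerase leaves over the
gene body. Parameters and their defaults:

| parameter | meaning | units | constraint |
|---|---|---|---|
| $\pi_1,\pi_2,\pi_3$ | component weights | — | simplex |
| $\mu_1,\mu_2$ | peak locations | bins (100 bp) | $[-50, 50]$, $\mu_1\le\mu_2$ reported |
| $\beta_1,\beta_2$ | peak scales | bins | $\ge 0.1$ |
| $a, b$ | uniform support | bins | fixed at $[-50, 50]$ by default |

The uniform support is pinned to the full window by default: a narrower
uniform zeroes the model density at observed bins, which makes the fitting
objective infinite, and the full-window uniform is exactly the "flat tail
plus background" role the component plays. `estimate_uniform_support = TRUE`
frees $a$ and $b$ within bounds that keep all observed bins covered.

## Fitting: Kullback–Leibler divergence under pattern search

With $p$ the observed bin distribution and $q$ the model density normalized
over the grid, the fit minimizes $\mathrm{KL}(p\,\|\,q) = \sum_t p_t \log
(p_t/q_t)$. This normalized form has the same argmin as the raw
$\sum_t y_t \log(y_t / f(t))$ — rescaling $y$ multiplies the objective by a
constant and normalizing $f$ shifts it by a constant — while being
nonnegative and exactly zero at a perfect fit, which makes correctness
directly testable.

The optimizer is a generalized pattern search: from the incumbent, the $2n$
coordinate-direction points $x \pm \Delta e_i$ are polled; the first
improvement is accepted and the mesh doubles, otherwise the mesh halves. It
is derivative-free (the objective is only piecewise smooth in $\mu$) and
needs no constraint machinery because the search runs in a transformed box:
mixing proportions as two softmax logits (third logit fixed at zero), scales
on the log scale, locations boxed to the grid. Stopping follows four
criteria — 20,000 evaluations, 2,000 iterations, mesh below $10^{-6}$, or a
successful poll improving by less than $10^{-6}$. The last criterion only
applies once the mesh is itself below $10^{-6}$: a tiny gain on a coarse
mesh is routine mid-run and terminating on it leaves measurable error
(observed residuals around $10^{-2}$ on rotated quadratics), whereas the
coupled form preserves the optimizer's convergence guarantee. This is the
convention of the classic pattern-search toolboxes from which these four
criteria and their constants originate.

The search restarts 16 times: two data-informed starts placing $\mu_1,
\mu_2$ at the two highest smoothed local maxima of the profile (with
$\pi = (0.4, 0.4, 0.2)$, $\beta = 5$), plus 14 seeded Latin-hypercube draws
over the parameter box. The cluster *mean* profile is fitted rather than the
pooled member counts; under the normalized objective the two differ only by
scaling. $\mu_1 \le \mu_2$ is enforced by relabeling at output, never inside
the search.

```{r fit-example}
truth <- mixture_params(c(0.4, 0.4, 0.2), mu = c(-10, 10), beta = c(5, 5))
y <- simulate_profile(truth, n_reads = 10000, seed = 7)
fit <- fit_mixture(y, seed = 3)
fit
round(coef(fit), 3)
```

The fit is a classed model object with the usual accessors (`coef`,
`predict`, `fitted`, `residuals`, `plot`, `simulate`).

## Genome scanning and the permutation threshold

Each cluster yields a template: the fitted Pol-II density followed by the
fitted H3K4me2 density, each standardized. At every genome position the
101-bin windows of both tracks are standardized the same way and the
correlation with each template is the mean of the two per-mark correlations
— a region must match *both* marks to score highly. The per-position score
is the maximum over templates and over both template orientations (training
profiles were gene-oriented; the genome is not), and a window that is flat
in either mark scores zero.

Scanning runs on the **raw binned counts**, not the smoothed ones.
Smoothing is a clustering aid; the detection threshold comes from a
permutation null that destroys within-window bin order, and a permuted
window has no autocorrelation — comparing it against smoothed (hence
autocorrelated) windows miscalibrates the threshold badly in the direction
of false positives.

The null is built by repeatedly drawing one of the retained training
windows, permuting the bin order within each mark independently, and scoring
it exactly as the scan does; the threshold $z$ is the 95th percentile of
10,000 such draws. Positions above $z$ are grouped, groups closer than 5 kb
(half a window, so one locus yields one call) are merged, and each region is
reported centered on its correlation maximum with the full 10.1-kb window
footprint.

The default scan stride is one bin (100 bp) rather than 1 bp: counts exist
at bin resolution, so sub-bin strides cannot change which window a maximum
falls in; a 1-bp stride remains available when per-base coverage is
supplied.

## Hierarchical annotation

Called regions are labeled against an ordered catalog — RefSeq promoter >
gene body > ncRNA > EST > assembled transcript > ER > AR > CpG island >
CTCF — taking the first level hit, so a region inside both a promoter and a
CpG island counts as a promoter and the counts partition the region set.
Promoter windows are TSS ± 1 kb. Transcript-like categories are matched
through a 2-kb window around the region center; compact site categories by
direct span overlap; both rules are per-category configurable, since the
convention is only stated for transcripts in the source material.
Independent per-category counts (a region may hit several) are reported
alongside, and are by construction no smaller than the hierarchical ones.

## The synthetic-data generator

`simulate_genome()` produces the study conditions the method assumes and is
the basis of every end-to-end test: a 1-Mb genome, per-bin Poisson(1)
background in each track, and 20 planted regions, each adding a multinomial
draw of 5,000 reads per mark from a known mixture shape, reversed with
probability 1/2, at least 20 kb apart and 10 kb from chromosome ends.
Because plants are drawn from exactly the model family the fitter assumes,
recovery tests measure the pipeline's own correctness, not model
misspecification. What the generator deliberately does *not* emulate:
mappability gaps, copy-number variation, GC bias, fragment-length effects,
overdispersed background, or partial/composite peak shapes. Passing tests
therefore certify the algorithmic chain; they do not certify performance on
real ChIP-seq, where thresholds inherit whatever background structure the
permutation null is fed.

Problem sizes used by the test suite and the acceptance script: 100 oracle
draws for the divergence check, 10 random quadratics in 2–6 dimensions for
the optimizer, 20 parameter-recovery draws at 10,000 reads, planted sets of
60 and 120 profiles for cluster-number selection, one 1-Mb/20-plant genome
with a 10,000-draw null for the scan, and a 600-kb/12-plant configuration
for the byte-level determinism check (determinism is scale-independent, so
the smaller genome is used there).

## Numerical choices and degenerate inputs

- Percentiles (variance cutoff, null threshold) use linear interpolation,
  R's default `quantile` type 7, everywhere.
- Standardizing a zero-variance segment returns a flagged zero vector;
  window correlations involving one are 0, and a cluster whose mean profile
  is flat in either mark is excluded from scanning with a warning.
- K-means restarts keep the first of tied best solutions (smallest restart
  index); `select_k` breaks silhouette ties toward smaller k.
- All randomness flows from explicit integer seeds, fanned out per stage by
  fixed offsets; re-running any stage with the same seed and configuration
  reproduces its output files byte for byte.
- Coordinates are 0-based half-open everywhere inside the package (BED
  native); conversion to and from the 1-based conventions of wiggle, BAM
  and `GRanges` happens only in the I/O layer.

## Known limitations

- No input/control normalization or between-mark depth normalization is
  applied; the per-window standardization makes the scan scale-free, but
  systematically structured background will shift the permutation null.
- The permutation null treats bins within a window as exchangeable, which is
  correct for the raw-count scan here but would not be for autocorrelated
  (e.g. pre-smoothed) input coverage.
- The uniform component's support estimation is off by default; profiles
  whose tails genuinely end inside the window are then absorbed partly into
  the Laplace scales.
- Region calling reports one region per merged super-threshold group; two
  genuine promoters closer than the merge gap (5 kb) yield a single call.
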