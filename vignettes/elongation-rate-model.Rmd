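---
title: "Modeling nucleotide-specific transcription elongation rates from nascent RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nucleotide-specific transcription elongation rates from nascent RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elongrate)
```

## The model

Nascent RNA sequencing (NRS) protocols -- PRO-seq, NET-seq, GRO-seq -- record
the 3' ends of nascent transcripts, marking the active sites of engaged RNA
polymerase II at base-pair resolution. If polymerase occupancy along a gene
body is at steady state, the density at a nucleotide is inversely
proportional to how fast polymerase moves through it: slow sites accumulate
polymerase and reads, fast sites deplete them. `elongrate` turns that
observation into a generative model for gene-body read counts.

For gene $j$ with (trimmed) body length $N_j$, the read count at nucleotide
$i$ is modeled as

$$X_{i,j} \sim \mathrm{Pois}\!\left(\frac{\lambda\,\chi_j}{\zeta_{i,j}}\right),
\qquad \zeta_{i,j} = e^{\kappa \cdot Y_{i,j}},$$

where

* $\zeta_{i,j}$ is the **relative local elongation rate**, a dimensionless
  multiplier on the gene's average rate: $\zeta < 1$ marks a local slow-down,
  $\zeta > 1$ a speed-up. It is a log-linear function of the covariate vector
  $Y_{i,j}$ (k-mer indicators, smoothed epigenomic tracks) through a
  coefficient vector $\kappa$ **shared across all genes and sites**, which is
  what lets sparse per-site information be pooled genome-wide.
* $\chi_j$ is a free per-gene compound parameter, interpretable as the
  initiation-to-average-elongation-rate ratio. Only this ratio is
  identifiable from steady-state data; absolute rates are not.
* $\lambda$ is the read-depth scale, fixed at the average read depth over all
  analyzed sites.

Dropping data-only constants, the joint log likelihood over $M$ genes reduces
to sufficient statistics,

$$\ell = \sum_{j=1}^{M}\big[s_j\log\chi_j - \kappa\cdot T_j -
\lambda\,\chi_j U_j\big],$$

with $s_j = \sum_i X_{i,j}$, $T_j = \sum_i X_{i,j} Y_{i,j}$ (computed once)
and $U_j = \sum_i e^{-\kappa\cdot Y_{i,j}}$,
$V_j = \sum_i e^{-\kappa\cdot Y_{i,j}}\,Y_{i,j}$ (recomputed every
iteration). The fitter is plain gradient ascent on $\kappa$
($\partial\ell/\partial\kappa_n = \lambda\sum_j \chi_j V_{j,n} - T_{j,n}$)
with the per-gene maximizer $\hat\chi_j = s_j/(\lambda U_j)$ substituted
analytically on every iteration. For high-dimensional k-mer models the
objective gains an L1 penalty $-\nu\sum_n|\kappa_n|$ (ridge and elastic-net
variants are available behind the same interface but the lasso works best in
this setting), and $\nu$ is chosen by minimizing the Akaike Information
Criterion on a held-out 20% of genes.

A variant of the model absorbs a possible nucleotide bias at read 3' ends:
with bulk 3'-base frequencies $\pi_b$ (estimated read-count-weighted) each
Poisson mean is scaled by $\rho_b = 4\pi_b$, which adds a per-site offset
$-\log\rho_i$ to the linear predictor and leaves everything else unchanged;
with uniform composition the variant collapses exactly to the base model.

## Numerical choices

* **Learning rate.** Plain gradient ascent needs a step size matched to the
  objective's curvature. Because covariates are standardized, the diagonal
  Hessian elements are all close to the total analyzed read count, so the
  default step is its reciprocal (`learning_rate = "auto"`); at genome scale
  (thousands of genes) this reproduces the order of $10^{-7}$, and a fixed
  numeric rate can be supplied instead. Any step that lowers the objective is
  rejected and the rate halved, so the accepted objective trace is monotone.
* **Stopping.** Iteration ends when $\max_n|\Delta\kappa_n| <$ `tol`
  (default $10^{-8}$) or after `max_iter` (default 50 000) iterations.
* **L1 subgradient.** At $\kappa_n = 0$ the minimum-norm subgradient is used
  (the coefficient moves only when the unpenalized gradient exceeds $\nu$),
  and a step that would cross zero is clipped to exactly zero. Coefficients
  therefore sit at exact zeros, and the sparsity count uses a threshold of
  $10^{-6}$.
* **AIC parameter count.** $\hat k$ counts nonzero $\kappa$ entries only;
  held-out $\chi_j$ are re-optimized analytically on both arms of the split
  and would add a constant to every candidate, so they are excluded.
* **Default $\nu$ grid.** Log-spaced from $\nu_{\max}$ (the sup-norm of the
  gradient at $\kappa = 0$, above which every coefficient is zeroed, the
  convention of lasso path solvers) down by $10^{-2.5}$, in 10 steps.
* **Masked sites** (internal transcription-start windows, regulatory-element
  peaks) are excluded from all sums rather than zero-filled -- a zero count
  at an unmasked site is informative (it suggests fast elongation), so
  zero-filling masked sites would mimic infinitely fast regions.

## Covariates

**k-mer indicators** mark sites whose surrounding sequence matches a k-mer,
aligned so that the polymerase active site falls on the middle base for odd
k and on base $k/2$ (1-based) for even k -- slightly left of center, where
the catalytic site sits relative to the transcription bubble. A signed shift
moves the alignment up/downstream, allowing tests for sequence preferences
in the DNA--RNA hybrid or the unwound region ahead of the enzyme. Windows
running past the TU or containing N score 0. Internally all k-mers with
$k \le 5$ are functions of the 5-base window around a site, so sites are
grouped by window (at most $5^5$ groups including N-padding) and every
per-iteration quantity is computed from per-gene group counts.

**Standardization** rescales every covariate to mean 0, sd 1 (population
convention, dividing by $n$ -- the choice is arbitrary but fixed for
determinism) so coefficients are comparable across features. Features
defined only at a subset of sites (DNA methylation at CpGs) are standardized
over their defined sites and set to exactly 0 elsewhere, so undefined
positions exert no push in either direction -- this is also what separates a
methylation effect from a plain cytosine effect. Because standardization
turns mostly-zero indicator columns dense, the sufficient statistics are
computed from the raw sparse values and mapped through the linear transform
$\kappa\cdot Y^{std} = (\kappa/s)\cdot Y^{raw} - \sum_n \kappa_n m_n/s_n$;
`sufficient_stats_sparse()` exposes this path and the test suite checks it
against the dense computation to $10^{-10}$.

**Smoothing filters** spread a narrowly annotated feature's influence over
its neighborhood before regression: a Gaussian kernel for ChIP-seq-scale
features (defaults r = 400 nt, sigma = 100 nt; stem-loops r = 500 nt,
sigma = 200 nt) and a "generalized" kernel of empirical weights for splice
sites. Generalized weights are taken from a metaplot of relative read depth
around the feature: the profile median is subtracted as baseline and the
positive excursion becomes the kernel. The baseline-subtraction rule is this
package's choice; only "estimated from metaplots" is prescribed by the
underlying method. Filters are applied **before** standardization so the
GLM's scale invariants hold on the covariates it actually sees, and tracks
are zero-padded at TU boundaries (gene-body trimming makes the boundaries
data-poor regardless).

## The SimPol simulator

`simulate_occupancy()` tracks individual polymerases in each of many cells
in discrete time slices (default $10^{-4}$ min). Per slice, a polymerase at
site $i$ steps forward with probability
$\bar\zeta\,\zeta_i\,\Delta t$ unless blocked by the polymerase ahead
(within `footprint` nucleotides, default 1 -- collisions are rare in the
regimes simulated, so the footprint is second-order), and a new polymerase
initiates with probability $\alpha\,\Delta t$ when the gene start is free.
Units: $\bar\zeta$ is an absolute stepping rate in nt/min (default 2000,
the typical 2 kb/min mammalian elongation rate); $\zeta_i$ is the
dimensionless local multiplier; $\alpha$ is in events/min.

Two exact samplers are provided. The *slice* sampler iterates literally over
the $2\times10^5$ slices of a 20-minute simulation. The *event* sampler
exploits the memorylessness of per-slice Bernoulli trials: the departure
slice from site $i$ is
$\max(\text{entry}, \text{leader departure from } i+\text{footprint}) +
\mathrm{Geom}(p_i)$, one geometric draw per site visit, which reproduces the
slice process exactly under the same start-of-slice blocking convention and
is orders of magnitude faster. The suite checks the two agree statistically,
and that measured occupancy obeys the steady-state law (log-occupancy
regressed on log-rate has slope $-1$).

Occupancy is averaged over the second half of the simulated time; the first
half is discarded as equilibration (a full traversal of a 10-kb gene takes
about 5 min at 2 kb/min, so 10 min is comfortably past equilibrium). A
snapshot-at-end mode exists as an option. Read counts are then Poisson,
proportional to occupancy, with the proportionality constant set once per
dataset so that the mean expected depth matches a target -- using a single
constant across genes preserves the gene-to-gene depth differences induced
by their initiation rates, which is what the per-gene $\chi_j$ is for.

## Synthetic benchmarks: what they emulate, and what they do not

`generate_epigenomic_benchmark()` rebuilds the epigenomic validation: six
covariates (CTCF, four histone marks, RNA stem-loops) whose values are
constant within 1-kb blocks and drawn jointly from a latent Gaussian field,
emulating block-sampling of real tracks while preserving their correlation
structure. Correlation targets: 0.4 among histone marks, 0.2 marks vs
stem-loops, 0.1 marks vs CTCF. True coefficients default to estimates from
K562 nascent-RNA data (CTCF $-0.022$, H3K36me3 $-0.095$, H3K9me1 $-0.067$,
H4K20me1 $-0.041$, H3K79me2 $+0.030$, stem-loops $-0.051$). Local rates are
$\zeta_i = \exp(\kappa\cdot Y_i) + \delta_i$ with
$\delta_i \sim N(0, 0.1^2)$, floored at $10^{-3}$ since additive noise can
otherwise drive a rate non-positive. Per-gene initiation rates are
long-tailed lognormal (log-sd 1) rescaled to median 1 event/min. The full
study conditions are the defaults (10 replicates of 100 TUs of 10 kb in
5000 cells); the target read depth defaults to 0.5 reads per nucleotide, a
typical gene-body depth for a deeply sequenced PRO-seq library.

`generate_kmer_benchmark()` rebuilds the sequence validation: i.i.d.-uniform
random DNA, 100 randomly chosen 5-mers with coefficients uniform in
$[-0.3, 0.3]$ and all others zero, no rate noise. The true rates are built
on the raw indicator scale, $\zeta_i = \exp(\kappa_{w(i)})$ for the 5-mer at
site $i$: on the standardized scale a 1-in-1024 indicator takes values near
32 at matches, so coefficients of $\pm0.3$ would imply rates near $e^{9.6}$
-- physically meaningless and beyond any per-slice move probability. The two
parameterizations differ only by a linear reparameterization
($\kappa^{std}_n = \kappa^{raw}_n s_n$, intercept absorbed by $\chi_j$), so
predictions, correlations and sparsity patterns are unaffected.

These generators emulate the *statistical* structure the model cares about
-- block-correlated covariates, rate-dependent steady-state occupancy,
Poisson sampling, gene-level depth variation. They do not emulate promoter
pausing, termination, premature termination, mappability artifacts,
library-preparation bias (except through the explicit 3'-base bias variant),
or covariate measurement error; passing the benchmarks therefore shows the
inference machinery is correct and well-calibrated under the model's own
assumptions, not that those assumptions hold in any particular real dataset.

### Problem sizes used by the test suite

The shipped tests run reduced configurations chosen to keep the suite quick
while leaving the statistical behavior recognizable: the epigenomic
benchmark runs 2 replicates of 20 TUs in 500 cells (held-out rate prediction
lands near the full-scale value of $r^2 \approx 0.75$, and above 0.95
without rate noise), coefficient recovery uses 5 replicates of 20 TUs in 200
cells (medians within $\pm0.03$ of truth), and the 5-mer benchmark runs one
replicate of 50 TUs in 300 cells. Occupancy noise is negligible next to
Poisson read noise once a few hundred cells are time-averaged, so cell
counts are the cheapest dimension to reduce.

The 5-mer benchmark deserves a caveat: its information content scales with
(TUs $\times$ depth), and at 50 TUs and 0.5 reads/nt the per-feature
standard error (about 0.07 on the raw coefficient scale) approaches the
typical coefficient magnitude, so held-out AIC -- evaluated on only 8 test
genes, where even a strong feature's likelihood gain is comparable to the
AIC penalty of 2 -- selects very aggressive shrinkage, and both the
recovered support and the prediction accuracy degrade well below the
full-scale values. At 200 TUs (the full study's gene count, with reduced
cells) the same code recovers $r^2 \approx 0.86$ with $\approx 90$ nonzero
coefficients, 72% of them in the true set, matching the full-scale behavior.
This is a property of the scaled-down design, not of the estimator.

## Preprocessing

Real count tracks pass through three steps before fitting. Gene bodies are
trimmed to start 2250 bp downstream of the (refined) TSS -- past
promoter-proximal pause peaks -- and end 250 bp upstream of the TTS, with
bodies under 6 kb discarded. Windows of 2 kb around intragenic cap-site
peaks with more than 10 reads, and any predicted regulatory-element
intervals, are masked (their read density reflects initiation, not
elongation). Finally, the "U-shaped" average profile shared across gene
bodies is removed: genes are mapped to a common 1000-bin relative scale,
binned counts are median-normalized per gene, the cross-gene mean profile is
LOESS-smoothed (span 0.3, the package's choice; rescaled to mean height 1
and floored at 0.1 to avoid edge blow-ups), and raw counts are divided by
the curve at their relative position. Median normalization is done on binned
values because per-nucleotide medians are typically zero at realistic
depths; genes whose binned median is still zero are excluded with a warning.

## Known limitations

* Absolute rates, per-gene average rates and initiation rates are not
  separately identifiable from steady-state data; everything is relative.
* The model is log-linear and single-site: saturating or interacting
  covariate effects are absorbed into the linear fit.
* Batch standard errors ([fit_batches()]) capture gene-sampling variability
  only; no Fisher-information or bootstrap uncertainty is provided.
* TSS refinement and isoform selection are upstream concerns: gene bodies
  are taken as given intervals, and expression-level filtering (e.g. by
  TPM) is the caller's responsibility.
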