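---
title: "Scoring the quality and reproducibility of Hi-C contact matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the quality and reproducibility of Hi-C contact matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hic3dqc)
```

## The problem

A Hi-C experiment yields, per chromosome, a symmetric matrix of interaction
counts between genomic bins. Two dominant features shape these matrices:
the *genomic distance effect* (contact frequency decays roughly as a power
law of linear separation) and *domain structure* (TADs and A/B
compartments). Both conspire against naive quality control: two completely
unrelated experiments still correlate strongly because they share the
distance decay, while two excellent replicates at modest sequencing depth
can correlate poorly because the matrices are sparse. `hic3dqc` implements
four replicate-similarity scores that address this — each transforming the
matrix to suppress the distance-decay confounder and the sparsity noise
before comparing — plus a single-sample quality score, and the simulation
machinery (noise injection, downsampling, pseudo-replicates, synthetic
matrices) needed to benchmark them without any external data.

## The scores

**Stratum-adjusted correlation (`scc`).** Both matrices are smoothed with a
2D mean filter of half-width $h$ (each entry replaced by the mean of its
$(2h+1)^2$ window, clipped at the matrix edge — windows shrink rather than
invent counts). Entries are then stratified by bin offset $k$; within each
stratum the Pearson correlation $\rho_k$ of the two matrices is computed,
and the score is the weighted average
$\mathrm{SCC} = \sum_k w_k \rho_k / \sum_k w_k$ with
$w_k = N_k\,\mathrm{sd}(a_k)\,\mathrm{sd}(b_k)$. This weighting is the
variance weighting of a stratified covariance aggregate in the
Cochran–Mantel–Haenszel spirit; the exact published weight formula lives in
the method's own companion paper, so the choice is isolated in one internal
function and documented here as a design decision. Strata with fewer than
two pairs or zero variance are dropped. Defaults: $h$ = 20/5/1 at
10 kb/40 kb/500 kb (published trained values), strata up to 5 Mb
(125 bins at 40 kb) — most Hi-C signal sits well below that separation, and
far strata are almost empty and noisy.

**Random-walk concordance (`disco_score`).** The matrix is a weighted
graph: entries are normalized by $\sqrt{d_i d_j}$ (marginals $d$), rows are
normalized to a transition matrix $P$, and $P^t$ gives the $t$-step random
walk — a graph-native smoother that preserves sharp domain boundaries.
The distance between two maps is
$\|P_a^t - P_b^t\|_{L1} / \bar n_{\mathrm{nz}}$, where
$\bar n_{\mathrm{nz}}$ is the average number of non-empty bins in the two
original maps, and the score is $1 - d$. Each node can contribute an L1
difference of at most 2 (mutually exclusive contacts), so $d \in [0, 2]$
and the score lies in $[-1, 1]$. With several $t$ values the per-$t$
distances are combined by a trapezoidal AUC *normalized by the $t$-range*,
which keeps the per-$t$ scale and hence the $[0,2]$ range; with the default
$t = \{3\}$ (the published optimum) this degenerates to the single
distance. When coverages differ the deeper sample is first downsampled to
match — deeper maps are denser after smoothing, and unequal density leaks
into the L1 term.

**Spectral score (`spector_score`).** From each map restricted to
non-empty bins, the normalized graph Laplacian
$D^{-1/2}(D - W)D^{-1/2}$ is eigendecomposed; the $r$ eigenvectors with
smallest eigenvalues capture the map's large-scale organization, the rest
mostly noise. The distance is $S_d = \sum_{i<r} \|v_i^A - v_i^B\|$ and the
score $1 - S_d/(r\sqrt 2)$, clipped to $[0,1]$. Two numerical choices make
$S_d$ well defined: eigenvector signs are fixed (largest-magnitude
component positive) and each pair is additionally aligned by
$\min(\|v^A - v^B\|, \|v^A + v^B\|)$, bounding each term by $\sqrt 2$ for
unit vectors — which is what makes $r\sqrt 2$ the exact rescaling constant.
Both maps are decomposed on the intersection of their non-empty-bin
supports so the vectors are dimension-compatible. Near-degenerate
eigenvalues can swap eigenvector order between maps and perturb the score;
pairing is by ascending-eigenvalue index. Default $r = 20$: enough
eigenvectors to span compartments and large domains at 40 kb without
dipping into the noise tail.

**Enrichment-weighted correlation (`quasar_rep`, `quasar_qc`).** As the 3D
distance between two loci shrinks, the correlation between their matrix
rows approaches one. The transform: drop bins with no signal within 100
bins of the diagonal (iterated to a fixpoint); estimate the background as
the mean count per inter-bin distance over retained bins; form the
log-enrichment matrix (count / background); for every retained row pair
within 100 bins, correlate the two rows' log enrichments over columns
within 100 bins of both, excluding either row's diagonal cell and filtered
columns; weight each row pair by $\sqrt{\mathrm{enrichment} + 1}$. The
replicate score is the correlation, between two samples, of their
correlation matrices weighted this way (each divided by its sum of valid
weights); the quality score is the weighted mean correlation minus the
unweighted mean, pooled over chromosomes. In a structureless matrix,
enrichment and row correlation are uncoupled and the quality score sits
near zero; genuine 3D structure couples them and pushes it positive.

Two decisions the published description leaves open: the log enrichment of
a zero count is undefined, so zero-count cells are excluded from the
correlations (a pseudocount would instead have manufactured a signal from
the zeros' positions); and bin distances are measured in original bin
units — filtering keeps a mask rather than compacting indices, so removing
a bin does not shorten the genomic distance across the gap. The window is
100 *bins* at every resolution, as published. QC pooling across
chromosomes sums numerators and denominators before dividing
(`pooled = TRUE`); per-chromosome averaging is available, and the two
agree exactly for identical chromosomes. The quality score is *not*
invariant to globally rescaling counts: enrichments cancel, but the
weights $\sqrt{e+1}$ are computed from enrichments, while zero-cell
exclusion and the background change with depth — measured on the synthetic
defaults (200 bins, $10^6$ vs $10^7$ counts), a 10× depth change moved QC
from 0.0082 to 0.0085.

Per-experiment scores are the arithmetic mean over chromosomes
(`genome_score`); undefined chromosomes are excluded with a warning, never
silently counted as zero. Scores are computed for intrachromosomal
matrices only.

## The noise model

Two "pure noise" matrices are derived from a real matrix $M$ with $N$
total interactions:

* **Genomic-distance noise $G$** shuffles $M$'s entries within each bin
  offset $D$, preserving the distance decay exactly while destroying
  domains and compartments. To retain GC/mappability bias, the shuffle is
  stratified: at each offset, cells are ordered by the product of their two
  bin marginals and cut into consecutive strata of 100; values move only
  within their stratum. The shuffle is a permutation (sampling without
  replacement), so per-offset sums — and the total — are conserved exactly.
  The stratum *cut rule* (contiguous groups of a sorted order) is our
  reading of the published stratification, which fixes the stratum size but
  not the cut.
* **Random-ligation noise $R$** draws $N$ bin pairs, each endpoint
  independently with probability proportional to its marginal, emulating
  ligation of non-crosslinked fragments with per-bin bias.

A noisy matrix with $c$ total counts mixes interactions drawn uniformly
*without replacement* from $M$, $G$ and $R$ at proportions
$(1-f)$, $f\cdot g$, $f(1-g)$, with largest-remainder rounding so the
three contributions sum to $c$ exactly. The default ladder injects
$f \in \{5,10,15,20,30,40,50\}\%$ with $g \in \{1/3, 2/3\}$, the published
design; the noise-free reference for response curves is a pure resample
($f = 0$).

Downsampling (`downsample`) is the multivariate hypergeometric draw —
interactions are retained, not resampled. Pseudo-replicates pool two
replicates and draw two *independent* downsamples of the pooled matrix at
the average of the two coverages; whether the published procedure
partitions the pool instead is unstated, and independent draws keep the
two pseudo-replicates exchangeable.

## The synthetic generator

`simulate_cell_type()` builds a noise-free intensity surface as a product:
power-law distance decay $(|i-j|+1)^{\alpha}$, TAD blocks multiplying
within-domain intensity, an A/B compartment checkerboard multiplying
same-label cross-TAD pairs, and a lognormal per-bin bias. Defaults:
$\alpha = -1$ (the classic contact-probability scaling), 10 TADs at 3-fold
enrichment, 1.5-fold compartment enrichment, bias sdlog 0.3 — values a
40-kb-resolution map of a human chromosome arm would call unremarkable.
`sample_replicate()` is a multinomial draw of a stated number of
interactions from that surface. Biological replicates differ by resampling
noise plus a small per-replicate bias jitter (lognormal, sdlog 0.05), so
pseudo-replicates — whose variation is resampling only — are strictly
cleaner than biological replicates, and non-replicates (different ground
truths: different TADs, compartments, biases) are strictly farther.

What a green test on this generator establishes: that each score orders
*pseudo ≥ biological > non-replicate*, decreases monotonically under
injected noise, and respects its analytic extremes. What it does not
establish: behavior on real maps with restriction-fragment artifacts,
copy-number variation, translocations, or interchromosomal signal — none
of which the generator emulates.

## Numerical choices and degenerate inputs

* All stochastic operations take an explicit seed; one master seed is
  split into per-stage sub-seeds, and the caller's RNG state is restored.
* Undefined scores (everything filtered, empty maps, no retained strata)
  return `NA` with a warning — never a silent 0.
* The mean filter uses summed-area tables (exact, O(n²) for any $h$);
  matrix powers use repeated multiplication (t = 3 by default); the banded
  QuASAR correlations are the one compiled (Rcpp) loop in the package.
* Correlation entries with fewer than 3 shared columns or zero variance
  are invalid and excluded from both numerators and denominators.
* Largest-remainder rounding apportions mixture counts; ties break
  real > G > R.

## Worked example

```{r example, eval = FALSE}
gt <- simulate_cell_type(n_bins = 200, seed = 1)
a <- sample_replicate(gt, 1e6, seed = 2, bias_jitter = 0.05)
b <- sample_replicate(gt, 1e6, seed = 3, bias_jitter = 0.05)
scc(a, b, h = 5)             # 0.978 for this biological-replicate-like pair
disco_score(a, b, seed = 4)  # 0.964
spector_score(a, b)          # 0.840
quasar_rep(a, b)             # 0.868
quasar_qc(a)                 # 0.008, > 0 for structured maps

curve <- noise_response_curve(a, "genomedisco", seed = 5)
all(diff(curve$score) <= 0)  # TRUE: noise always lowers the score
```

## Known limitations

* Only intrachromosomal, single-chromosome matrices are modeled; no
  binary container formats.
* The SCC weight formula is a documented stand-in for the published CMH
  derivation (switchable in one place).
* Eigenvector pairing under near-degenerate eigenvalues is by index;
  strongly degenerate spectra can make the spectral score unstable.
* The generator does not model fragment-level artifacts, PCR duplication
  or interchromosomal contacts, so coverage-dependent effects driven by
  those processes are out of reach.
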