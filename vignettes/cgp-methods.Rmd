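---
title: "Separating the 1D and 3D components of Hi-C gene contacts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating the 1D and 3D components of Hi-C gene contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpmap)
```

## The model

A balanced Hi-C contact map gives, for every pair of genomic bins, a
corrected co-location frequency. Projected onto genes it yields the gene
proximity matrix $W$: $W_{ij}$ is the contact frequency between the bins
of genes $i$ and $j$ (when a gene spans several bins, the maximum over
spanned bin pairs, representing the minimum distance between the genes).
$W$ mixes two signals. Loci close on the DNA strand contact each other
frequently regardless of nuclear organization — the 1D component — while
cell-type-specific spatial arrangement contributes the 3D component that
carries regulatory information. We model the 1D component as

$$E_{ij} = k_i\,k_j\,f(d_{ij}),$$

where $f$ is the genome-wide mean contact frequency at genomic distance
$d$ (in bin units) for same-chromosome pairs and a constant for
different-chromosome pairs, and $k_i \ge 0$ is the *visibility* of gene
$i$ — a multiplicative propensity to produce ligation products,
reflecting gene length, accessibility and radial nuclear position. The
visibilities are not free: they are pinned by the row-sum constraints

$$\sum_j E_{ij} = \sum_j W_{ij} \quad \forall i,$$

so the null assigns each gene exactly its observed total contacts. The
corrected gene proximity (CGP) matrix is the residual

$$B = W - E.$$

Because of the constraints, every row of $B$ sums to zero: $B$ is a
generalized modularity matrix for the weighted gene-contact network, and
standard modularity machinery (quadratic forms in $\pm 1$ state vectors,
leading eigenvectors, block reductions) applies to the 3D genome.

Assumptions worth stating explicitly:

* *Separability.* The 1D component factorizes into per-gene visibilities
  times a distance kernel. Visibility is a single scalar per gene; any
  distance-dependent coverage bias not removed by balancing leaks into $f$.
* *Exchangeable inter-chromosomal background.* All gene pairs on
  different chromosomes share one expected rate (scaled by visibility).
  Chromosome-territory preferences therefore appear in $B$, which is what
  the chromosome-level analyses exploit.
* *Monotone decay.* $f^{\mathrm{intra}}(d)$ is non-increasing in $d$;
  the estimator enforces this.

## Fitting

`cgp_fit()` performs four steps.

**Decay estimation.** For each $d \ge 1$, the raw estimate of
$f^{\mathrm{intra}}(d)$ is the mean of all intra-chromosomal matrix
entries at offset $d$, pooled across chromosomes (all loci, not only
gene-occupied bins). Raw means are then smoothed with windows whose
half-width grows as $\lfloor 0.1\,d\rfloor$: short distances ($d<10$),
where each offset already averages thousands of pairs and the curve bends
fastest on the log scale, keep their raw means; long distances pool
proportionally wider windows, taming the noise of sparse far diagonals.
We deliberately use the floor rather than a ceiling: a forced $\pm1$-bin
window at $d = 1$ would pool the $d=0$ (self-bin) mean into $f(1)$ and
bias the normalized curve $f(d)/f(1)$ by roughly 20% for a power-law
decay with exponent 1. $d = 0$ — relevant only when two distinct genes
share a bin — is kept as its own point and never enters a $d \ge 1$
window, since self-bin counts sit in a different regime of the assay.
Finally a pool-adjacent-violators step (via `stats::isoreg`) clamps the
curve to be non-increasing, and unobserved distances inherit the nearest
smaller-distance value. $f^{\mathrm{inter}}$ is the plain mean over all
unordered inter-chromosomal bin pairs.

**Distance convention.** $d_{ij}$ is the absolute difference of the
genes' *representative bins* — the bin containing each gene's midpoint.
For single-bin genes this is exact; for multi-bin genes the midpoint is
the symmetric, deterministic choice.

**Normalization.** $E \propto k_i k_j f$ fixes $f$ only up to a
constant, so before iterating we rescale $f$ once such that, at the
initialization $k_i^{(0)} = \sqrt{\sum_j W_{ij}}$, total expected
contacts equal total observed contacts. After this single rescale only
$k$ is updated. (Consequently the reported $k$ is defined up to the
reciprocal scale of $f$; the products $k_ik_jf$, hence $E$ and $B$, are
invariant. We rescale genome-wide rather than per chromosome: the
constraints couple chromosomes through inter-chromosomal terms, and a
single kernel keeps $E$ comparable across the whole map.)

**Visibility solve.** The constraints form a coupled quadratic system.
We iterate
$k_i \leftarrow s_i \big/ \sum_j k_j f(d_{ij})$ with $s_i = \sum_j W_{ij}$,
damped geometrically, $k \leftarrow \sqrt{k_{\mathrm{new}} k_{\mathrm{old}}}$,
which suppresses the two-cycle oscillation the undamped update exhibits on
near-bipartite weight patterns. Convergence is declared when the largest
relative row residual
$\max_i |\sum_j E_{ij} - s_i| / \max(s_i, \varepsilon)$ drops below `tol`
(default $10^{-6}$; $\varepsilon = 10^{-12}$ guards zero rows), with a
hard cap of 1000 iterations — typical instances converge in 20–50.
Genes with zero total contacts get $k_i = 0$, zero rows in $E$ and $B$,
and are excluded from updates; they decouple exactly. Non-convergence
raises a condition carrying the residual trace rather than returning a
silently bad fit, and `compute_cgp()` independently rejects an $E$ whose
row sums disagree with $W$ beyond $10\times$`tol`.

On small instances the damped iteration agrees with a brute-force
nonlinear least-squares solve of the same system to $10^{-6}$ per
component (tested), and on synthetic maps generated from the model family
it recovers the true per-bin visibilities with Pearson $r > 0.99$ at 500
genes and realistic depth.

## Downstream statistics

**Q objective.** For ON/OFF states $x_i = \pm1$,
$Q = (\sum_{ij}W_{ij})^{-1}\sum_{ij}B_{ij}x_ix_j$, diagonal excluded,
both orders counted. Zero row sums make $Q$ exactly zero for constant
$x$, and $Q(x) = Q(-x)$. Significance uses permutation ensembles that
shuffle the *assignment of genes to matrix positions* (expression labels
fixed): globally; within A/B compartments; within TADs; or after first
permuting the TAD blocks along each chromosome — the permuted blocks are
random segments with the original size multiset, so this last ensemble
measures what mere 1D blockiness contributes. Genes outside any TAD
become singleton blocks (with a warning). Empirical p-values use the
$(r+1)/(n+1)$ convention so they are never zero. Under the global scheme,
shuffling positions is mathematically identical to shuffling the state
vector; under domain-preserving schemes the two differ, and we shuffle
positions. Degenerate inputs behave sensibly: a constant state vector
yields a null with zero variance, $z$ defined as 0 and $p = 1$.

**Monte Carlo maximization.** Hill climbing over ON↔OFF position swaps
(swapping like labels is a no-op, and the ON count is conserved): propose
a random ON/OFF pair, accept iff $Q$ strictly increases. The
$\Delta Q$ of a swap is computed incrementally from the cached gradient
$g = Bx$ in $O(G)$ per accepted step, and the incremental trajectory
agrees with direct recomputation to $10^{-10}$ (tested). The trajectory
is non-decreasing by construction. Plain greedy ascent can in principle
stall in local optima of $Q$; on the planted-module instances used here
it reliably exceeds the empirical $Q$, which is the scientific point —
the empirical expression layout is far from the spatial optimum.

**Tightness.** $b_p = \sum_{i,j\in p}B_{ij}$ over ordered pairs. The
null draws `n_rand` (default 5000) same-size gene sets uniformly without
replacement; $T_p = (b_p-\mu_p)/\sigma_p$. When $\sigma_p = 0$ (e.g. an
all-zero $B$) $T_p$ is defined as 0 and flagged. An `exhaustive` mode
enumerates all subsets (population SD) for oracle checks on small
instances. `tightness_change()` evaluates two conditions on their shared
gene universe with the *same* null sets, so identical conditions give
exactly $\Delta T = 0$ and swapping conditions exactly negates
$\Delta T$. Calibration on random sets of size 20 gives mean $\approx 0$,
SD $\approx 1$, as a z-score should.

**Chromosome reduction.** $\hat B_{\alpha\beta}$ sums $B$ over ordered
pairs $i\in\alpha, j\in\beta$ for $\alpha\neq\beta$, exactly as the
block sum is written; the diagonal is stored as zero while the
intra-chromosomal sums are kept separately so the decomposition
$\sum_{\alpha\neq\beta}\hat B_{\alpha\beta} + \sum_\alpha \mathrm{intra}_\alpha
= \sum_{ij}B_{ij} \approx 0$ can be verified. $\tilde B = \hat B /
\|\hat B\|_F$ makes maps comparable across cell types; an all-zero
$\hat B$ is returned as zero with a degenerate flag rather than dividing
by zero. The differential network keeps *all* edges in data; the display
threshold (default $|\Delta| \ge 0.05$) only flags which edges a drawing
would show. The chromosome universe is whatever the gene table provides —
the 23-chromosome human case is not hard-coded.

**Expression.** Co-expression is the outer product of log2 expression
values, with zero expression floored at a configurable negative value
(default $-4$, i.e. 1/16 of one unit): two silent genes then score
positive (same state), one active and one silent score negative. Log
base and floor are conventions, not science; both are parameters.
ON/OFF binarization fits a two-component Gaussian mixture to the log
values (`mclust`, unequal variances) and calls the higher-mean component
ON; degenerate fits fall back to a median split with a warning.

**Eigenvectors.** `leading_eigenvectors()` returns the top eigenpairs by
algebraic eigenvalue with a deterministic sign convention (largest-
magnitude component positive), suitable as classifier features; with all
vectors requested the spectral decomposition reconstructs $B$.

## The synthetic generator

`simulate_contact_map()` draws maps from the model family itself plus
planted 3D structure:
$\lambda_{ij} = \mathrm{depth}\cdot v_iv_j\cdot[g(|i-j|)\ \mathrm{intra};\ c_0\ \mathrm{inter}]\cdot m_{ij}$
with $g(d) = (d+1)^{-\gamma}$ plus an additive floor of $10^{-3}g(1)$
(so long-range expectations never vanish and $f$ stays estimable),
log-normal visibilities of mean 1, planted modules multiplying
within-module pairs by a boost $m$, and optional Poisson sampling. The
study conditions used throughout the tests are: $\gamma = 1$,
$c_0 = 0.01$, visibility spread 0.3 (log-SD), depth 300 (about 150
expected counts at $d=1$), boost $m = 3$, bin size 40 kb; the `small`
preset has 5 chromosomes × 200 bins with 500 single-bin genes, the
`tiny` preset 3 × 60 with 120 genes for repeated runs. These sizes keep
a full simulate–fit–test cycle interactive while leaving every estimate
comfortably identified.

`simulate_genes_and_expression()` places one gene per selected bin
(module bins always included), then draws the ON set by weighted
sampling: weight 10 inside planted modules, 5 elsewhere in the A
compartment, 1 in B (defaults of the study presets; both weights set to
1 give a uniform ON set). Log2 expression is a two-component Gaussian
(OFF mean 0, ON mean 5, SD 1) and 5% of OFF genes are zeroed to exercise
the floor. TADs are consecutive 10-bin blocks. Compartments deserve a
note: A segments are a *minority* (every fourth 25-bin segment, plus any
segment containing module bins), and ON genes are enriched in A. Both
choices mirror active chromatin — transcription concentrates in a
compartment that covers well under half the genome — and they matter for
the ensemble comparisons: if A covered half the genome and expression
ignored compartments, a within-compartment shuffle would retain no
co-localization signal at all (at ON density exactly ½ the expected
same-state excess within any module is zero), which is not how real
genomes behave. With the study conditions the compartment-preserving
null falls strictly between the global null and the empirical $Q$, and
the within-TAD null approaches the empirical $Q$ — here TADs coincide
with planted modules by construction, so preserving TAD membership
preserves nearly all planted signal; real TADs are not perfectly aligned
with co-regulated modules, so real data shows a larger gap.

Two matched conditions for differential analyses come from
`simulate_cgp_study(..., inter_boost = )`: every condition shares the
same intra modules and one common inter-chromosomal module (background
structure two related cell types share), while the *differential* inter
module (20 bins per side) is boosted only where requested. Gene
placement depends only on module bin positions, never on boosts, so the
two conditions have identical gene universes. The differential module is
sized to dominate its chromosome-pair block: a translocation-like signal
is a block-level event, and a module much smaller than the block is
mostly absorbed by the null's global renormalization of $f^{\mathrm{inter}}$
and the visibilities.

What the generator does *not* emulate: compartment-level plaid contact
structure (compartments here are annotation plus expression enrichment,
not a contact pattern of their own), TAD-level contact enrichment
blocks, unbalanced coverage (maps are generated balanced — balancing is
an input precondition, not a package responsibility), multi-bin genes
(exercised by dedicated unit fixtures instead), and karyotype
abnormalities beyond the planted modules. Passing tests on this
generator therefore demonstrate correctness of the estimators and
statistics under the model's own assumptions plus planted structure —
not robustness to every artefact of real Hi-C libraries.

## Numerical and design choices

* Coordinates are 0-based half-open throughout; GTF input (1-based
  inclusive) is converted on read. Strand is parsed and ignored.
* Genes on chromosomes absent from the contact map are dropped with a
  warning — there is no defensible imputation for them.
* $W$ has an identically zero diagonal (self-proximity excluded); the
  statistics enforce a zero diagonal on any user-supplied matrix.
* Dense text matrices are accepted up to 50,000 bins; beyond that, use
  COO input. Cooler containers are not read (no HDF5 reader in the
  package's dependency footprint); convert to COO text first.
* Overlapping genes keep the plain max-over-bin-pairs rule, which may
  pick a shared bin's near-diagonal value; no special casing.
* Ties in `top_inter_pairs()` break lexicographically by gene id, making
  output order deterministic.
* All stochastic operations take explicit seeds and are bit-reproducible
  given (seed, n).

## Limitations

* Visibility is a single multiplicative scalar per gene; assay biases
  that vary with distance or locally violate factorization are absorbed
  into $f$ or leak into $B$.
* The distance for multi-bin genes uses the midpoint representative bin;
  for very long genes at fine bin sizes this coarsens $d$ by up to half
  the gene length.
* The estimated $f$ at very long range rests on few pairs per distance;
  the widening smoothing windows and the monotone clamp stabilize it at
  the cost of local bias ~1–2% against a power law.
* Greedy Monte Carlo has no restarts or temperature; it certifies a
  lower bound on the maximal $Q$, not the global optimum, except on
  instances small enough to enumerate.
* Permutation and tightness nulls treat genes as exchangeable units
  (within the scheme's blocks); gene-length and GC composition effects
  present in real data are not matched by the null sets.
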