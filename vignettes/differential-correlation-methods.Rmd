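---
title: "Detecting differential correlation from network topology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential correlation from network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dctopo)
```

## The problem and the model

Differential expression asks whether a gene's *mean* changes between two
disease conditions; differential correlation (DC) asks whether its
*co-expression structure* changes. The motivating scenario is a regulatory
module — say, targets of one transcription factor — expressed coherently
where the regulator is functional and incoherently where it is not: means
may be identical while the correlation pattern collapses.

Testing each of the ~10^7 gene pairs separately drowns in multiple
testing, so both algorithms in this package work at the level of network
topology. For conditions $q \in \{A, B\}$ with $n$ samples each, the
Pearson correlation matrix $C^q$ is computed and Fisher-transformed,
$z^q_{ij} = \operatorname{atanh}(c^q_{ij})$. On this scale the sampling
fluctuation of a correlation is approximately $N(0, 1/(n-3))$ regardless
of its magnitude, which is what justifies an *equidistant* threshold grid
$t_m = m \cdot z_{\max}/k$, $m = 1, \dots, k$. At each $t_m$, a network
per condition connects genes with $z^q_{ij} > t_m$ (strict inequality;
negative correlations never form edges under the default signed rule).
Sweeping the grid instead of fixing one cutoff is the essential design
element: a strong correlation change of few genes occupies a long run of
high thresholds, a moderate change of many genes a run of middle
thresholds, and both kinds are caught by the same statistic.

### Global topology

At each threshold, genes in $\geq 3$-gene connected components of *both*
networks are removed, the networks are re-induced on the remaining genes,
and genes in a $\geq 3$-gene component of exactly one induced network are
*exclusive* at that threshold. The per-gene indicator profiles over the
grid are scanned for the longest contiguous run $[a, b]$; its length is
referred to the null scale of a difference of independent Fisher-z values
(Steiger's test),
$$Z = \frac{b - a}{\sqrt{1/(n_A - 3) + 1/(n_B - 3)}}, \qquad
p = \Pr(N(0,1) > Z),$$
one-sided because run lengths are nonnegative by construction (a
two-sided version would double every p-value and leave ranks unchanged).
The minimum component size of 3 is the smallest at which topology is
non-trivial — pairwise changes are better tested directly.

Two consequences of the set algebra are worth knowing. First, the induced
recomputation is deliberately conservative: a gene clustered in A only
through partners that are shared with B loses its component and is not
called. Second, one can show that a single gene can never hold exclusive
runs in A *and* in B at different thresholds: pre-removal component
membership only grows as the threshold falls, so joint membership (hence
removal) sets in exactly where the second condition's run would have to
live. The A-versus-B tie-break in `max_run()` is therefore reachable only
through directly supplied profiles; ties *within* one profile (two
equal-length runs separated by a removal window) do occur and are resolved
towards the run with the higher mean threshold — stronger correlations —
then towards A. `toy_fixture("tie_case")` realizes this end to end.

### Local topology

Per gene $i$ and threshold $t$, with open neighborhoods $V^{i,t}_A$,
$V^{i,t}_B$ (the gene itself excluded — including it would add a shared
member to every comparison and bias the statistic downward),
$$d_i^t = 1 - \frac{|V^{i,t}_A \cap V^{i,t}_B|}{|V^{i,t}_A \cup V^{i,t}_B|},
\qquad d_i^t := 0 \text{ if } |V^{i,t}_A \cup V^{i,t}_B| < 3,$$
averaged over the grid: $d_i = \frac1k \sum_m d_i^{t_m} \in [0, 1]$. The
guard mirrors the global algorithm's minimum cluster size. The method
itself defines no direction for a local change, but the neighborhood
counts do: we sum $d_i^t \cdot \operatorname{sign}(|V^{i,t}_A| -
|V^{i,t}_B|)$ over the grid and read the direction off the sign of that
signed sum — the condition in which the gene has the larger correlated
neighborhood. This reconstructs a signed/absolute pair of summaries;
users needing only a ranking can ignore the sign.

### False discovery rates

DC scores have no usable analytic null, so error control is by
subsampling: $B$ pairs of disjoint random groups of the original sizes
are drawn from the pooled cohort *ignoring labels*, scored, and
thresholded, giving null detection counts $n_0$ with mean $\bar n_0$ and
a 5–95% percentile band. For an observed count $n_{AB}$,
$$\mathrm{FDR} = \pi_0 \cdot \bar n_0 / n_{AB}, \qquad \pi_0 = 1,$$
the standard expected-false-positives-over-discoveries estimator;
$\pi_0 = 1$ slightly overestimates the FDR when signal exists. Null
groups are disjoint because overlapping groups would share sampling noise
and deflate apparent differential correlation. Counts above the observed
ones produce FDR estimates above 1; they are reported as-is and flagged
rather than clipped.

One subtlety the package handles for you: observed and null runs must be
scored on the *same* threshold grid, or their detection counts are not
comparable. `fdr_curve()` and `null_scores()` therefore fix the grid's
upper end from the pooled cohort (`pooled_z_max()`) unless an explicit
`z_max` or grid is supplied.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `k` (global) | 200 | thresholds | finer ranking; 100 gives nearly identical lists |
| `k` (local) | 100 | thresholds | grid of the local statistic |
| `z_max` | data max $|z|$ | Fisher z | grid end; fixed from the pooled cohort in FDR analyses |
| p cutoff (global) | 0.1 / 0.05 | — | detection thresholds used in reported tables |
| d cutoff (local) | 0.25 / 0.3 | — | likewise |
| `B` | 100 | subsamples | null-count precision; SE of $\bar n_0$ scales as $1/\sqrt{B}$ |
| `pi0` | 1 | — | conservative null-gene proportion |
| clip `eps` | 1e-6 | — | correlations mapped to $\pm(1 - 10^{-6})$ before atanh |

The grid convention: "$k$ equidistant values between 0 and $z_{\max}$"
excludes 0 (a zero threshold connects every positively correlated pair
into a near-complete graph and carries no information) and includes
$z_{\max}$, via $t_m = m \cdot z_{\max}/k$. Thresholds are compared
strictly ($z > t$), so a correlation exactly at a grid value is not an
edge.

## The synthetic-data generator

`synth_generate()` realizes a latent-factor model: module $m$ genes in
condition $q$ are $x_g = \sqrt{\rho_q} f_m + \sqrt{1-\rho_q}\,
\varepsilon_g$ with $f_m, \varepsilon_g$ i.i.d. standard normal across
samples, so the expected within-module correlation is exactly $\rho_q$; a
module with $\rho_A \neq \rho_B$ is differentially correlated and its
genes carry the ground-truth flag. Background genes are independent (or
equicorrelated at `background_rho` through one global factor), and
`de_shift` adds a mean offset in condition B for differential expression
without differential correlation. This construction was chosen over
sampling from a target covariance matrix because it gives the exact
expected correlation at $O(\text{genes} \times \text{samples})$ cost.

What it emulates: two equal-sized groups, condition-specific equicorrelated
modules, shared modules, and the near-duplicate tight correlations that
anchor $z_{\max}$ in real cohorts. What it does not: probe-level artifacts,
batch effects, heavy-tailed expression, inter-module (meta-module)
correlation, and gradual correlation structure. Tests passing on this
generator therefore certify the algorithmic machinery and its calibration
under the stated model, not robustness to microarray pathology.

One practical lesson from the null model is baked into the test suite: a
cohort consisting of *only* independent genes puts the adaptive
$z_{\max}$ inside the sampling-noise range, where neighborhoods are
essentially random and $d$ is large for every gene. Real cohorts (and
realistic simulations) contain strong correlations shared by both
conditions, which stretch the grid well past the noise scale and make
null detections rare. Simulations intended for FDR work should include a
tight shared module, or pass a fixed `z_max`.

Exact-correlation fixtures (`expression_from_correlation()`) map a target
correlation matrix through its Cholesky factor onto orthonormal
mean-zero Helmert rows, so sample correlations match the target to
machine precision; fixture edge values are placed at least 0.04 away from
grid points so strict comparisons cannot flip numerically.

## Numerical choices and degenerate inputs

* Correlations are clipped to $\pm(1 - 10^{-6})$ before the transform, so
  duplicated genes get a large finite $z$ rather than infinity.
* Constant genes are rejected by name (their correlation is undefined),
  as are matrices with missing or non-finite values — the intended
  upstream (normalized, probe-collapsed data) produces complete matrices.
* Unequal group sizes are rejected unless explicitly allowed: the larger
  group estimates correlations with less noise, which masquerades as
  differential correlation.
* Genes with no exclusive run at any threshold get $p = 1$, below a
  zero-length observed run ($p = 0.5$): "no evidence" ranks last.
* Score tables sort by the score with gene-id tie-breaks; all outputs are
  deterministic given inputs and seeds (subsample $b$ uses
  `base_seed + b`).
* Null-band percentiles use type-7 (linear interpolation) quantiles.
* Probe collapsing keeps the probe with the highest mean across all
  samples, ties to the lexicographically smallest probe id.
* TSV outputs carry a deterministic `#`-prefixed provenance header;
  SIF/GraphML network exports do not, to stay Cytoscape-parseable.

## Problem sizes used by the test suite

The suite checks oracle equivalence on instances of up to 30 genes
(literal per-threshold reimplementations with BFS components), parameter
recovery at 2020 genes with a planted 20-gene module ($\rho$ = 0.8 vs 0,
100 samples per group, 3 seeds), null-band calibration on a 120-gene
homogeneous cohort over 20 repetitions with $B = 20$, and random-score
cross-validation overlap over 200 repetitions. These sizes were chosen so
the full suite exercises every claim at desk scale; the algorithms
themselves run comfortably at $10^4$ genes (the per-threshold sweep is
$O(E_t)$ per network via sorted edge prefixes, and the local statistic is
computed from per-row threshold counts in $O(G^2 + Gk)$).

## Known limitations

* A gene participating in changes towards A and B at different threshold
  ranges is assigned only the winning direction.
* The local statistic has no per-gene p-value; significance statements
  come from the subsampling FDR, which is a property of a cutoff, not of
  a gene.
* Subsampling assumes the pooled cohort is a fair null mixture; strong
  batch structure aligned with the group labels would violate this.
* With two groups of very different biology, $\pi_0 = 1$ can be far too
  conservative.
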