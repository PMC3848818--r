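# dctopo

Untargeted detection of **differentially correlated (DC) genes** between two
sample groups — genes whose co-expression structure changes between
conditions (e.g. molecular subtypes of a tumor), even when their mean
expression does not. Intended for genes × samples expression matrices
(log2 scale, microarray or similar) split into two equal-sized groups, and
for the systems-biology audience that would otherwise reach for
differential-expression tests and miss regulatory rewiring.

## The method

Both algorithms start from the per-condition Pearson correlation matrices
`C^q` (q = A, B), Fisher-transformed entrywise:

    z_ij^q = atanh(c_ij^q) = 1/2 * log((1 + c_ij^q) / (1 - c_ij^q))

On the z scale the sampling noise of a correlation is ~ N(0, 1/(n-3)),
so an **equidistant grid of thresholds** t_1 < ... < t_k in (0, z_max]
treats weak and strong correlations comparably. At each threshold a
network per condition joins genes with z_ij > t; edge sets shrink as t
grows. Instead of committing to one cutoff, every analysis sweeps the
whole grid, which lets strong changes of a few genes and moderate changes
of many genes surface at the same level of significance.

**Global topology (`dcglob_scores`, k = 200 default).** At each threshold,
genes sitting in connected components (≥ 3 genes) of *both* networks are
removed; the networks are re-induced on the remaining genes, and genes in a
≥ 3-gene component of exactly one condition are *exclusive* at that
threshold. Per gene, the longest contiguous threshold run of exclusivity
[a, b] is converted to a one-sided p-value by Steiger's test for comparing
correlations:

    Z = (b - a) / sqrt(1/(n_A - 3) + 1/(n_B - 3)),   p = P(N(0,1) > Z)

**Local topology (`dcloc_scores`, k = 100 default).** Per gene i and
threshold t, the Jaccard-type dissimilarity of its neighbor sets
V_A, V_B in the two networks:

    d_i(t) = 1 - |V_A ∩ V_B| / |V_A ∪ V_B|     (0 if |V_A ∪ V_B| < 3)

averaged over the grid: d_i = (1/k) Σ_t d_i(t) ∈ [0, 1].

**Error control (`null_counts`, `estimate_fdr`, `fdr_curve`).** The null
distribution of detection counts comes from scoring B random disjoint
subsample pairs of the pooled cohort (group labels ignored). With n̄_0 the
mean null count and n_AB the observed count at a cutoff,

    FDR = π_0 · n̄_0 / n_AB,   with π_0 = 1 (slightly conservative)

## Worked example

Simulate a 500-gene cohort, 100 samples per group, with a 20-gene module
correlated only in condition A (ρ = 0.8 vs 0, the planted DC signal), a
30-gene module shared by both conditions (ρ = 0.7) and a 10-gene tight
module (ρ = 0.95, the near-duplicate correlations that anchor the
threshold grid in real cohorts):

```r
library(dctopo)
spec <- synth_spec(
  n_genes = 500, n_per_group = 100,
  modules = data.frame(size  = c(20, 30, 10),
                       rho_a = c(0.8, 0.7, 0.95),
                       rho_b = c(0.0, 0.7, 0.95)),
  seed = 1)
sim <- synth_generate(spec)

glob <- dcglob_scores(sim$pair)
head(glob, 3)
#>   gene_id direction run_start  run_end run_length            p
#> 1   g0006         A 0.2759703 1.188795  0.9128249 1.028058e-10
#> 2   g0019         A 0.2759703 1.188795  0.9128249 1.028058e-10
#> 3   g0020         A 0.2971988 1.199409  0.9022107 1.658687e-10

loc <- dcloc_scores(sim$pair)
head(loc, 3)
#>   gene_id         d signed_sum mean_neighbors_a mean_neighbors_b direction
#> 1   g0016 0.5469535   54.69535            18.25             8.95         A
#> 2   g0005 0.5395655   53.95655            17.98             7.48         A
#> 3   g0019 0.5383873   53.83873            17.28             6.74         A

pooled <- cbind(sim$pair$a, sim$pair$b)
fdr_curve(pooled, sim$pair, method = "dcloc", cutoffs = c(0.25, 0.3),
          B = 20, base_seed = 1)
#>   cutoff n_ab n0_mean     n0_se ci_5 ci_95   fdr
#> 1   0.25   20     1.1 0.3831998    0  5.05 0.055
#> 2   0.30   20     0.0 0.0000000    0  0.00 0.000
```

Reading the output: the top-ranked genes are planted module members in
both algorithms — `run_length ≈ 0.91` means gene g0006 was exclusively
clustered in condition A over almost the whole threshold range, giving
p ≈ 1e-10; `d ≈ 0.55` means about half of the threshold–neighborhood
comparisons differ for g0016. At cutoff d > 0.25 all 20 planted genes and
nothing else are detected, while random subsample pairs of the same cohort
yield 1.1 detections on average — an estimated FDR of 5.5%; at d > 0.3
the null mean drops to 0.

Expression and label files can also be read from delimited text
(`read_expression`), probe-level matrices collapsed per gene
(`collapse_probes`), and thresholded networks exported for Cytoscape
(`export_network`). A thin command-line wrapper with subcommands
`simulate`, `dcglob`, `dcloc`, `fdr`, `evaluate`, `export` is installed at
`exec/dctopo.R`.

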