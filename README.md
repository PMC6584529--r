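# gwasoverlap

Different populations studied for the same complex disease report largely
disjoint lists of significant GWAS tagSNPs. `gwasoverlap` asks whether that
disagreement is biological or merely positional, by measuring
between-population overlap at five increasingly coarse functional levels —
significant tagSNPs, LD-expanded loci, genes, enriched biological processes,
and functionally coherent subnetworks — and testing each against a
level-matched permutation null. It is aimed at statistical geneticists
comparing association results across cohorts or ancestries.

## The statistics

For per-population entity sets `E_1 … E_k` at a given level, the package
computes:

* the **overlap matrix**, `overlap(i, j) = |E_i ∩ E_j| / |E_i ∪ E_j|`
  (Jaccard); the LD level uses `Λ_ij = |L_ij ∪ L_ji| / |S_i ∪ S_j|`, where
  `L_ij` are population-i tagSNPs whose signal (the SNP itself or an LD
  partner at r² ≥ 0.5 within 500 kb) is significant in population j;
* the **cumulative overlap function**
  `f(l) = |{entities associated in ≥ l populations}| / |union|`, for
  `l = 1 … k`, which always satisfies `f(1) = 1`, `0 ≤ f(l) ≤ 1`, and is
  non-increasing;
* a **permutation null** per level — size-matched entity sets resampled from
  a level-appropriate pool and pushed through the same machinery (the
  function level re-runs enrichment per replicate; the network level re-runs
  the locus optimizer) — yielding per-`l` z-scores and add-one empirical
  p-values;
* **hierarchical clustering** of populations from each matrix
  (distance `1 − overlap`, average linkage), and optional disease-subtype
  stratification of the gene-level and network-level sets.

Genes are assigned by SNP containment in a region of interest (transcript
span extended 100 kb upstream / 10 kb downstream, strand-aware); enrichment
is hypergeometric over-representation at 5% BH-FDR; subnetworks are selected
by choosing one candidate gene per associated locus to maximize total
interaction-network edge weight (exhaustive for small instances, simulated
annealing otherwise). A synthetic-data module generates worlds (genome, LD
blocks, term catalog, term-coherent network) and multi-population studies
with separately tunable SNP-level and pathway-level sharing, plus ground
truth, so the whole pipeline runs and is testable without any downloads.

## Worked example

Simulate a five-population study at default scale (200 genes, 5000 SNPs,
100 significant tagSNPs per population, moderate pathway sharing) and run
all five levels:

```r
library(gwasoverlap)
run <- run_pipeline(list(simulate = list(), seed = 7,
                         perm = list(n_perm = 200, n_perm_network = 40)))
print(run)
#> overlap_run: 5 level(s) computed: snp, ld, gene, function, network
#>   snp: f(l) = 1 0.221 0.115 0.03 0
#>   ld: f(l) = 1 0.445 0.284 0.12 0.055
#>   gene: f(l) = 1 0.5 0.358 0.291 0.179
#>   function: f(l) = 1 0.375 0.375 0.25 0.25
#>   network: f(l) = 1 0.406 0.307 0.228 0.158
```

Each line is a cumulative overlap function: at the SNP level no tagSNP is
shared by all 5 populations (`f(5) = 0`), while after LD expansion 5.5% of
loci are, and 18% of genes harbor significant SNPs in all populations —
overlap the marker level cannot see. Pairwise structure lives in the
matrices:

```r
print(run$results$gene$matrix)
#> overlap_matrix (level: gene )
#>       P1    P2    P3    P4    P5
#> P1 1.000 0.451 0.402 0.393 0.452
#> P2 0.451 1.000 0.372 0.444 0.575
#> ...
print(run$results$`function`$significance)
#>   l observed       z sd_zero p_empirical    p_normal
#> 1 1    1.000 2.76716   FALSE 0.119402985 0.002827351
#> 2 2    0.375      NA    TRUE 0.004975124          NA
#> ...
```

At the function level the permutation null is degenerate beyond `l = 1`:
none of the 200 random gene sets enriches any term, so every observed value
is more extreme than every replicate (`p_empirical = 1/201`, z undefined).
Setting `out_dir` in the config additionally writes clustered heatmaps,
overlap-function plots with the null min/max band, all TSV tables and a JSON
manifest; `read_run_config()` loads the same settings from YAML (see
`inst/extdata/demo_config.yaml`).

Real data enter through standard formats: a SNP table TSV
(`population, snp_id, chrom, pos, pvalue`), gene models as BED6, gene sets
as GMT, the network as an edge-list TSV, and an LD table TSV
(`snp_a, snp_b, r2, dist_bp`).

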