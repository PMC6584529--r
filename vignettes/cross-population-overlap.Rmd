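---
title: "Quantifying cross-population overlap of disease-associated variation at five functional levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-population overlap of disease-associated variation at five functional levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasoverlap)
```

## The problem

Genome-wide association studies of the same complex disease run in different
populations tend to report strikingly different lists of significant tagSNPs.
That disagreement can mean two very different things: the populations may
truly differ in disease architecture, or they may share the underlying
biology while tagging it through different markers — different linkage
structure, different arrays, different allele frequencies. `gwasoverlap`
quantifies which of the two is happening by measuring between-population
overlap at five increasingly coarse functional levels:

1. **SNP** — shared significant tagSNPs.
2. **LD** — tagSNPs whose signal is shared once linkage disequilibrium
   partners count as equivalent.
3. **Gene** — shared genes harboring significant tagSNPs in their region of
   interest (ROI).
4. **Function** — shared biological-process terms enriched in those genes.
5. **Network** — shared genes in the most functionally coherent subnetwork
   spanning each population's associated loci.

If overlap grows as the level coarsens, populations agree on biology even
where they disagree on markers.

## Overlap statistics

For entity sets $E_1, \dots, E_k$ (one per population; tagSNPs, genes,
enriched terms or subnetwork genes) the package computes a $k \times k$
**overlap matrix** of Jaccard coefficients

$$\mathrm{overlap}(i,j) = \frac{|E_i \cap E_j|}{|E_i \cup E_j|},$$

and a **cumulative overlap function**

$$f(l) = \frac{|\{e : e \text{ associated in at least } l
\text{ populations}\}|}{|\bigcup_i E_i|}, \qquad l = 1, \dots, k .$$

For non-empty inputs $f(1) = 1$, $0 \le f(l) \le 1$, and $f$ is monotonically
non-increasing; the test suite asserts these identities on hundreds of random
instances.

The LD level differs slightly: population $j$ *supports* tagSNP $s$ when $s$
itself or any LD partner of $s$ (r² ≥ 0.5 within 500 kb, both thresholds
configurable) is significant in $j$. The matrix entry is
$|L_{ij} \cup L_{ji}| / |S_i \cup S_j|$, where $L_{ij}$ holds the population-i
tagSNPs supported in $j$, and $\lambda(l)$ counts union tagSNPs supported by
at least $l$ populations. A SNP counts as its own LD partner. The
identity-partner convention is deliberate: it makes a tagSNP shared verbatim
between two populations contribute to the LD-level overlap, so the LD matrix
dominates the SNP matrix pointwise and collapses to it exactly when the LD
table is empty — both properties are asserted in the tests. It also resolves
an ambiguity in the definition of $\lambda$: whether a tagSNP counts toward
its own support. With identity partnership $\lambda(1) = 1$ always holds.

## Pipeline stages and their parameters

| Stage | Parameter | Default | Meaning |
|---|---|---|---|
| LD expansion | `r2_min` | 0.5 | minimum squared dosage correlation |
| | `max_dist_bp` | 500 kb | maximum partner distance |
| ROI mapping | `upstream_bp` | 100 kb | extension upstream of transcription |
| | `downstream_bp` | 10 kb | extension downstream |
| Enrichment | `fdr_max` | 0.05 | Benjamini–Hochberg FDR threshold |
| Permutation | `n_perm` | 1000 | replicates at SNP/LD/gene/function levels |
| | `n_perm_network` | 200 | replicates at the network level |
| Subnetwork | `restarts` | 20 | annealing restarts |
| | `steps` | 2000 | moves per restart |

ROI extension is strand-aware: "upstream" is relative to the direction of
transcription, which is the standard reading for regulatory context;
`strand_aware = FALSE` reproduces naive left/right extension. Intervals
follow the BED convention (0-based, half-open) while SNP positions are
1-based, so position $p$ lies in $[s, e)$ iff $s \le p - 1 < e$. Duplicate
probes for one SNP are removed per population, keeping the smallest p-value
(the removal is required; the keep-min rule is this package's convention for
conflicting duplicates). Gene-level sets use significant tagSNPs only; the
locus/network stage uses LD-expanded loci (`ld_expand = FALSE` switches to
tag-only loci). Both choices are configurable because the boundary between
"significant" and "LD-equivalent" evidence is a modeling decision, not a
data property.

Enrichment is one-sided hypergeometric over-representation per term with BH
adjustment across terms — the standard ORA. The default universe is the set
of genes possessing a gene model (the mappable genome) rather than the
catalog union; a catalog-union universe is available via configuration.
Populations whose gene sets are enriched in no term carry no information at
the function level and are removed from the function and network analyses,
reducing $k$ there.

## Locus-constrained subnetwork selection

Loci are connected components of the graph on a population's significant
SNPs with edges between qualifying LD partners (LD is intra-chromosomal, so
components never span chromosomes). Each locus contributes the candidate
genes whose ROI contains a member SNP; loci with no candidates are dropped
with a warning. The selector then chooses exactly one candidate per locus to
maximize the total network edge weight among the chosen genes — the
prix-fixe constraint. The coherence score is plain summed edge weight; the
cited tool's genetic algorithm and its bespoke scoring are intentionally out
of scope, only the contract (one gene per course, maximal shared function)
is preserved.

Instances whose candidate-count product is at most $10^5$ are solved exactly
by enumeration; larger ones by simulated annealing over single-locus swap
moves (geometric cooling, $T_0 = 1$, factor 0.995, 2000 steps per restart,
best of 20 restarts), implemented in C++ with incremental score updates.
Ties are broken by the lexicographically smallest selected gene tuple, and a
seed makes results exactly reproducible. The test suite verifies that
annealing recovers the enumerated optimum on 50 randomized instances.

A population's subnetwork gene set $N_i$ is the set of *non-isolated*
vertices of the subgraph induced by the optimal selection. The selection
itself necessarily contains one gene for every locus, including loci whose
best candidate has no edge to anything else selected; such isolated picks
are artifacts of the constraint, not members of any coherent subnetwork, and
counting them would dilute $N_i$ with one arbitrary gene per uninformative
locus. `connected_only = FALSE` restores the literal every-locus reading.
Per-gene disease-association scores are reported as the fraction of
restart-best solutions containing the gene.

## Permutation significance

Null studies are built by resampling entity sets from a level-matched pool —
the array-SNP universe for SNP/LD levels, all modeled genes for gene and
function levels — without replacement within a population (observed sets are
duplicate-free) and independently across populations, so an entity may recur
between populations. Each replicate passes through the same machinery as the
observation: the LD level applies the same LD table to sampled sets, the
function level re-runs the full enrichment per replicate, and the network
level re-runs the locus pipeline and optimizer. That is what makes the test
*level-matched*: the null carries the same combinatorial structure as the
statistic it calibrates.

Observed values are scored per $l$ with $z = (f_{\mathrm{obs}} - \mu_0) /
\sigma_0$ against the null mean and standard deviation, an upper-tail normal
p-value, and the add-one empirical p-value
$(1 + \#\{f_{\mathrm{rep}} \ge f_{\mathrm{obs}}\}) / (n_{\mathrm{perm}} + 1)$.
Testing is one-sided (excess overlap). A degenerate null ($\sigma_0 = 0$)
yields a flagged undefined $z$ with the empirical p-value still reported; at
$l = 1$ this is always the case, since $f(1) = 1$ identically for the
observation and every replicate — calibration statements therefore concern
$l \ge 2$. The suite checks calibration directly: when the "observation" is
itself drawn from the null sampler, empirical p-values at $l = 2$ pass a
Kolmogorov–Smirnov uniformity check across 200 independent runs at
$n_{\mathrm{perm}} = 199$ and the mean z-score sits within $\pm 0.2$.

The network level re-optimizes every replicate, which is the expensive step;
its replicate count defaults to 200 rather than 1000. The full 1000 remains
one configuration key away.

## Population clustering

Each overlap matrix is turned into the dissimilarity $d(i,j) = 1 -
\mathrm{overlap}(i,j)$ and clustered agglomeratively with average linkage
(UPGMA). Neither a distance nor a linkage is canonical for this task;
$1 - \mathrm{Jaccard}$ is a metric and average linkage is the conventional
choice for similarity-derived distances. Populations enter in code order,
fixing tie-breaks deterministically. The dendrogram is checked against a
naive $O(k^3)$ agglomeration oracle via cophenetic distances.

## The synthetic world: what it emulates, what it does not

Because the analysis targets published summary statistics that cannot be
bundled, the package ships a generator that emulates the *structure* the
pipeline assumes, with ground truth attached:

* a multi-chromosome genome (3 × 10 Mb by default) with 200 non-overlapping
  genes on random strands and 5000 uniformly placed SNPs;
* haplotype-block LD: SNPs within 20 kb blocks receive Beta-distributed
  r² centered at 0.75, and no LD crosses a block boundary;
* a catalog of 25 terms of ~12 genes, and an interaction network enriched
  within terms (edge probability 0.25 for term-sharing pairs vs 0.02
  background) — a shared-function network in miniature;
* a subtype annotation splitting terms into two etiological groups
  (secretion-like vs resistance-like), labeling genes in both groups `both`.

Study generation plants sharing at two separable levels, because the
question the pipeline answers is precisely whether those levels decouple.
Each of $k = 5$ populations draws 3 causal terms — from a shared pool of 3
with probability `theta_func_share`, else from its private pool — and then
draws 100 significant tagSNPs: 80% from the causal terms' gene ROIs (copied
from a fixed shared SNP list with probability `theta_snp_share`, else drawn
fresh) and 20% uniform background noise. With `theta_func_share = 1` and
`theta_snp_share = 0`, populations agree perfectly on pathways while sharing
almost no markers — the regime in which coarser levels should reveal hidden
agreement. All randomness flows from a single seed, and every component can
be written to its standard on-disk format (TSV/BED/GMT), so synthetic and
real inputs are byte-compatible.

The generator deliberately does **not** emulate allele-frequency spectra,
population demography, imputation artifacts, or realistic LD decay — the
statistics under test resample entity identities, not genotypes, so none of
those features would change what a passing test demonstrates. Consequently,
passing tests show that the statistics, nulls and optimizer behave correctly
on data with the assumed sharing structure; they do not certify performance
on any particular real cohort.

Under the pathway-only sharing regime the suite measures, over 20 seeds, the
cumulative overlap at $l = k$ rising from effectively zero at the SNP level
to about 0.29 at the gene level and about 0.85 at the function level — the
escalation the method is designed to expose. The network level reaches about
0.26, between trivially low and function-level high but *below* the gene
level on these synthetic worlds: the one-gene-per-locus constraint makes
each population's subnetwork membership nearly an independent draw among the
covered causal genes, while the gene level counts every ROI-overlapping gene
deterministically, so the network level pays a combinatorial penalty at
$l = k$ that a richer coherence model (and the much larger real networks)
would not. For the same reason, the per-population subnetworks recover about
79% of planted causal genes under default sharing — close to, but below, the
~85% structural ceiling set by SNP coverage of causal ROIs and by planted
genes competing for the same locus. Both measurements are recomputed by the
test suite on every run; treat them as honest characterizations of this
selector on these worlds, not as bounds on the approach.

## Numerical and degenerate-input conventions

* Jaccard of two empty sets is defined as 0 with a warning (needed for
  permutation replicates that draw empty enrichment sets); the cumulative
  function of an all-empty collection is an error for observed data and a
  zero vector inside null replicates.
* Duplicate network edges keep the maximum weight; self-loops are dropped;
  missing weight columns default to 1.
* BED rows sharing a symbol are merged to the union span before ROI
  extension (mapping is at gene, not transcript, granularity).
* LD distance is the position difference between the two SNPs.
* Matrix symmetry is enforced within $10^{-9}$ before clustering.
* All tolerances on probability comparisons in the suite are $10^{-12}$.

## Problem sizes in the test suite

The suite runs on deliberately scaled instances chosen to exercise every
code path at interactive speed: oracle comparisons use $k \le 7$ and at most
a few hundred entities; calibration uses a 2000-SNP pool with two
populations of 500 over 200 runs of 199 permutations; the study-condition
measurements use the full default world (200 genes, 5000 SNPs, 5
populations) over 20 seeds. The bundled acceptance script runs the complete
pipeline at the same default scale with 300 permutation replicates (60 at
the network level).

## Known limitations

* The coherence score is summed edge weight; it has no notion of
  network-rewiring significance, and a hub gene can dominate selection.
* Function-level nulls re-run enrichment per replicate but hold the catalog
  fixed; term–term correlation is not modeled in the null.
* One LD table serves all populations in a run; population-specific panels
  must currently be handled by separate runs.
* Empirical p-values are bounded below by $1/(n_{\mathrm{perm}} + 1)$;
  headline z-scores are therefore the more informative statistic for
  extreme overlap.
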