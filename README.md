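# embryoevo

Stage-specific coexpression modules and evolutionary conservation in
human preimplantation embryos.

## What it does, and for whom

Human preimplantation development — oocyte, zygote, 2-cell, 4-cell,
8-cell, morula, late blastocyst — spans the degradation of the maternal
transcriptome and the activation of the embryo's own genome (ZGA).
`embryoevo` is for computational biologists who want to ask: *how does
evolutionary constraint move across these stages?* It takes a genes ×
samples RPKM matrix with per-sample stage labels plus five standard
per-gene annotation tables, and produces per-stage gene sets and four
conservation indices summarized into one ordered trend.

The analysis has two cores:

**1. Stage-specific module detection** (weighted gene coexpression).
From expression `x` (default log2(RPKM+1)):

- Pearson correlation `r_ij`, unsigned soft-threshold adjacency
  `a_ij = |r_ij|^β` (β = 12);
- topological overlap
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  `l_ij = Σ_u a_iu a_uj`, `k_i = Σ_u a_iu`;
- average-linkage clustering on `1 − TOM`, flat modules via a dynamic
  hybrid tree cut (deepSplit = 4, minimum size 30, with PAM-style
  attachment of stray genes within a module's radius);
- module eigengenes (first principal component over samples), greedy
  merging of modules with eigengene correlation > 0.9;
- assignment of each module to the developmental stage whose one-hot
  indicator its eigengene correlates with best (r > 0.7, p < 0.01 from
  `t = r√((n−2)/(1−r²))`), hub genes at r > 0.9.

**2. Per-stage conservation scoring.** For each stage gene set:

- median human–mouse dN/dS vs. medians of 10,000 random equally sized
  background sets (empirical p with +1 correction, two-sided by
  default, 95% resampling band);
- Fisher-exact enrichment of four phylostratigraphic age intervals
  (Opisthokonta-Bilateria … Mammalia-Eutheria);
- Fisher-exact enrichment of human–zebrafish ortholog classes (one2one /
  one2many / new_gene; many2many removed);
- upper-tail hypergeometric enrichment of transcription factors
  (GO:0006355) and of genes with a highly conserved noncoding element in
  the 500 bp upstream of the TSS;
- the trend: conservation score = −median dN/dS per stage, successive
  differences run-length encoded into a label such as `up-down-up`.

A seeded synthetic-data generator (`ped_preset()`, `simulate_fixture()`)
emulates the whole input bundle — replicate design 3,3,4,4,4,4,4, planted
50-gene stage modules, planted conservation signatures — so the entire
pipeline runs and is tested without downloads.

## Worked example

```r
library(embryoevo)

dir <- tempfile()
simulate_fixture(ped_preset(seed = 1), dir)
res <- run_pipeline(pipeline_config(dir, n_perm = 10000, seed = 1))

print(res$fit)
print(res$conservation)
```

```
stage_modules fit: 1191 genes, 7 modules (841 genes unassigned)
modules assigned to a stage: 7 of 7
stage set sizes:
         oocyte          zygote           2cell           4cell           8cell
             50              50              50              50              50
        morulae late_blastocyst
             50              50

stage_conservation over 7 stages
median dN/dS by stage:
            stage n_genes_with_dnds observed_median   p_value direction
1          oocyte                50          0.2967 0.0002000    higher
2          zygote                50          0.1936 0.4449555    higher
3           2cell                50          0.1917 0.5207479    higher
4           4cell                50          0.1166 0.0002000     lower
5           8cell                50          0.2342 0.0029997    higher
6         morulae                50          0.1643 0.1309869     lower
7 late_blastocyst                50          0.1422 0.0007999     lower
trend pattern: up-down-up
```

Reading the output: all 7 planted modules were recovered and each was
assigned to its true stage (the ~840 unassigned genes are the simulated
background). The 4-cell stage's median dN/dS (0.117) sits below the
resampling background (p = 2e-4, the floor of 10,000 permutations), the
8-cell stage swings back up (0.234, p = 0.003), and the late blastocyst
drops again — the `up-down-up` conservation trend. Result tables
(modules, eigengenes, stage sets, hubs, the four enrichment tables,
`trend.tsv`) and a `report.json` with every threshold, seed and input
checksum are written to the configured output directory.

In-memory, the same analysis is two fits:
`fit <- fit_stage_modules(es)` then
`stage_conservation(fit, annot, seed = 1)`, each returning a classed
object with `print`/`summary`/`plot` methods.

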