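# spanet

Seed-guided protein network reconstruction, centrality tuning and module
analysis — a pipeline for nominating phenotype-associated candidate genes
from protein–protein interaction (PPI) data.

## What it does

Starting from a short list of *core* proteins known to be involved in a
phenotype, `spanet` chains five analysis stages:

1. **Reconstruction** — the selective permissibility rule: pool the cores'
   GO annotations into a per-aspect table `T = (T_C, T_F, T_P)`; admit a
   protein `v` with annotation sets `(A_C, A_F, A_P)` iff
   `A_C ∩ T_C ≠ ∅  ∧  A_F ∩ T_F ≠ ∅  ∧  A_P ∩ T_P ≠ ∅`.
   Physical interactions among admitted proteins form the network; only the
   largest connected component is kept.
2. **Tuning** — per-node eigenvector centrality `x` with `Ax = λ₁x`
   (power iteration on `A + I`), tested against `R = 100` degree-preserving
   randomizations (double edge swaps): a one-sample two-tailed t-test of the
   R random scores against the observed score; nodes with `p < 10⁻⁴` are
   retained and the induced subgraph is the tuned network.
3. **Modules** — MCODE with the standard parameterization (degree threshold
   2, node score threshold 0.2, k-core 2, max depth 100, haircut on, fluff
   off): vertex weight = `k · density` of the highest k-core of the closed
   neighborhood; greedy seeded expansion; score = density × size.
4. **Enrichment & candidates** — per-module hypergeometric upper-tail tests
   `P(X ≥ k)`, `X ~ Hypergeom(N, K, n)`, of biological-process terms against
   the network's annotation universe, Benjamini–Hochberg within module,
   reported at `q < 10⁻⁴` for modules with ≥ 5 members; module members whose
   process annotation is empty or root-only are the unknown-function
   candidates.
5. **Reporter TFs** — gene p-values mapped to `z = Φ⁻¹(1 − p)`; a TF with n
   targets scores `raw_z = Σz/√n`, size-corrected against an empirical
   background of random gene sets, significant at `p < 0.05`.

A synthetic-benchmark generator (scale-free interactome, planted cliques,
planted permissible/unknown truth, planted active regulators) makes every
stage testable offline with known ground truth. Readers are included for
BioGRID TAB 2.0, GAF 2.x, SIF and plain edge-list/TSV formats.

Intended users: computational biologists prioritizing candidate genes from
interactome + annotation + expression data, and anyone needing a
reproducible, fully scriptable version of this network workflow.

## Worked example

```r
library(spanet)

bench <- synthetic_benchmark(generator_params(seed = 1))  # 500-protein benchmark
dir <- file.path(tempdir(), "bench")
write_benchmark(bench, dir)

res <- run_pipeline(pipeline_config(seed = 2),
                    ppi_path     = file.path(dir, "ppi.tsv"),
                    gaf_path     = file.path(dir, "annotations.gaf"),
                    cores_path   = file.path(dir, "cores.txt"),
                    out_dir      = file.path(dir, "report"),
                    regnet_path  = file.path(dir, "regnet.tsv"),
                    pvalues_path = file.path(dir, "pvalues.tsv"))
```

The run logs every stage with its thresholds:

```
[INFO] SPA admission: 160 candidate proteins (14 cores + 146 permissible)
[INFO] raw admitted network: 116 nodes, 192 edges, 13 components
[WARN] core protein(s) eliminated for lack of physical interactions: YP0218, YP0307, ...
[INFO] largest component retained: 73 nodes, 161 edges
[INFO] tuning: 72 of 73 nodes retained at alpha = 1e-04 with R = 100
[INFO] mcode: 3 modules in the tuned network
[INFO] enrichment: 3 significant term records; 3 unknown-function candidates
[INFO] reporter: 3 of 20 TFs significant at alpha = 0.05
```

The reconstruction admitted 160 of 500 proteins and kept the 73-node
largest component (cores without physical interactions drop out, as warned).
Tuning removed 1 of 73 nodes at the 99.99% confidence level. The three
detected modules are exactly the three planted complexes:

```r
modules_to_table(res$modules)
#>   rank score size seed_node                                  members
#> 1    1    10   10    YP0124 YP0124,YP0168,YP0233,...,YP0420,YP0449
#> 2    2     9    9    YP0208 YP0208,YP0303,YP0322,...,YP0413,YP0457
#> 3    3     8    8    YP0096 YP0096,YP0132,YP0231,...,YP0478,YP0487
```

Each module is significantly enriched for its planted process term — e.g.
module 1 carries term `GO:3000018` in 9 of its 10 members against 10
carriers among the 72 process-annotated network proteins, `q = 3.1e-08` —
and each contributes one unknown-function candidate (annotated only to the
process root):

```r
res$candidates
#>   protein module_rank    reason
#> 1  YP0449           1 root_only
#> 2  YP0383           2 root_only
#> 3  YP0478           3 root_only
```

The reporter stage ranks exactly the three planted active TFs first, far
above the 0.05 threshold (the fourth-ranked TF already misses it):

```r
head(res$reporters, 4)
#>     tf n_targets_scored     raw_z corrected_z      p_value significant
#> 1 TF01               30 21.223887   10.405058 1.175570e-25        TRUE
#> 2 TF03               30 21.067442   10.314912 3.016815e-25        TRUE
#> 3 TF02               30 19.764003    9.563859 5.672281e-22        TRUE
#> 4 TF13               30  5.597282    1.400864 8.062738e-02       FALSE
```

All report tables (`etn.tsv`, `tuning_table.tsv`, `modules.tsv`,
`enrichment.tsv`, `candidates.tsv`, `reporter_tfs.tsv`, topology summaries
and the pipeline log) are written to `out_dir`, byte-identically for a
fixed seed.

## Command line

The same stages are available as subcommands of the installed script:

```sh
SPANET=$(Rscript -e 'cat(system.file("exec", "spanet", package = "spanet"))')
Rscript $SPANET simulate --seed 3 --out-dir bench
Rscript $SPANET run-all --ppi bench/ppi.tsv --gaf bench/annotations.gaf \
    --cores bench/cores.txt --regnet bench/regnet.tsv \
    --pvalues bench/pvalues.tsv --seed 3 --out-dir report
Rscript $SPANET modules --network report/tetn.tsv --out-dir mods
```

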