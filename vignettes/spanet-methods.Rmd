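---
title: "Methods: seed-guided network reconstruction, centrality tuning and module analysis"
author: "spanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-guided network reconstruction, centrality tuning and module analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanet)
```

# The problem

Given a handful of proteins known to be involved in a phenotype (for example
ethanol tolerance in budding yeast), which other genes belong to the same
functional neighborhood, and which of them are uncharacterized and therefore
worth testing experimentally? `spanet` answers this with a chain of
network-analytic steps, each of which is an established technique; the value
is in the disciplined composition and in the statistical tuning between the
reconstruction and the module analysis:

1. **Reconstruction** (selective permissibility): grow a subnetwork of the
   physical interactome around the seed ("core") proteins, admitting only
   proteins whose Gene Ontology annotations resemble the cores'.
2. **Tuning**: remove nodes whose eigenvector centrality is explainable by
   degree alone, using an ensemble of degree-preserving random networks.
3. **Module detection**: decompose the tuned network into locally dense
   protein groups (MCODE).
4. **Enrichment and candidates**: test each module for over-represented
   biological-process terms and extract members with no informative process
   annotation — the candidate genes.
5. **Reporter transcription factors**: given a regulatory network and
   gene-level differential-expression p-values, rank TFs by how strongly the
   expression change concentrates on their targets.

# Reconstruction: the permissibility rule

The admission filter is a pooled *annotation collection table*: the union,
per GO aspect (cellular component, molecular function, biological process),
of the core proteins' annotation sets. A protein is *permissible* when its
own annotations intersect the table in **every** one of the three aspects.
"Match" is non-empty intersection, not containment: a table covering a few
percent of all annotations still admits on the order of a third of the
proteome, which containment semantics could not do. Terms are compared as
literal identifiers; no ontology-graph propagation is applied (a flag for it
was considered and rejected — the admission rule is already permissive, and
propagation would make the table's size meaningless). Proteins lacking all
annotation in some aspect can never satisfy that aspect and are
non-permissible; core proteins bypass the rule.

Edges are the physical interactions between admitted proteins. Self-loops
are removed, duplicate records collapsed, and only the largest connected
component is kept ("significantly small components" are, in every input we
have examined, singletons and handfuls of pairs; keep-largest is the
simplest reproducible reading). A consequence worth noting: an admitted
protein — even a core — with no surviving physical interaction is absent
from the result. The rule is applied in one non-iterative pass, so the
output is a pure function of the inputs.

# Tuning: centrality against a degree-preserving null

Eigenvector centrality (EVC) scores each node by the dominant eigenvector
of the adjacency matrix. We compute it by power iteration on `A + I`; the
unit diagonal shift leaves the eigenvector unchanged but guarantees
convergence on bipartite components, where the unshifted iteration
oscillates. Iteration stops when successive iterates differ by less than
`1e-10` in max norm (error after 100,000 iterations); scores are
nonnegative and L2-normalized. On disconnected graphs the global dominant
eigenvector is returned, so nodes outside the dominant component score
numerically zero — a legitimate sample value for the test below.

The null model is an ensemble of `n_random = 100` degree-preserving
randomizations (double edge swaps, ten attempted swaps per edge, swaps
creating loops or duplicate edges rejected). For every node we test its
`R = 100` random-network EVC values against the observed EVC as the
hypothesized mean: a one-sample two-tailed t-test with `R - 1` degrees of
freedom, retained when `p < 0.0001` (99.99% confidence). Degenerate
zero-variance samples follow the limit of the test: a constant sample equal
to the observed value is never significant; a constant sample different
from it always is. The tuned network is the subgraph induced on retained
nodes; it is *not* re-reduced to its largest component by default (a flag
adds that sweep), since the published workflow reports the induced
interaction set directly.

Two choices here were genuinely open. First, the test orientation: "nodes
significantly different from those in random networks" can be read as a
one-sample test of the random sample against the observed score (chosen
here) or a two-sample test against pooled randoms; the one-sample form
matches the description "average values of EVC corresponding to each node
were computed and a hypothesis testing was carried out". Second, whether
the random networks were required to stay connected: no repair is
performed, because the degree sequence is the stated invariant.

A numerical caveat that shaped the synthetic benchmark (below): when a
network contains two or more *equal* maximal cliques weakly coupled through
a sparse background, the top adjacency eigenvalues are nearly degenerate
and power iteration converges only at the rate of the eigenvalue splitting
— for symmetric planted cliques that is effectively never at `1e-10`. This
is not an implementation defect: the dominant eigenvector itself is
ill-conditioned at such symmetry. Realistic interactomes do not exhibit
exact clique symmetry; the generator therefore plants complexes of graded
sizes by default.

# Topology panel and hierarchical modularity

`summarize_topology()` reports node/edge counts, diameter, characteristic
(average shortest) path length, mean local clustering (zero for degree
below 2), the degree distribution and betweenness centralities normalized
by `(n-1)(n-2)/2`. It requires a connected input because the path metrics
are otherwise undefined.

Hierarchical modularity is quantified by the decay of mean clustering with
degree, `C(k) ~ k^-w`. `fit_clustering_power_law()` bins nodes by raw
integer degree (no logarithmic binning — the simplest reproducible
convention), drops bins with `k < 2` or `C(k) = 0` (log-undefined), and
fits ordinary least squares on log10–log10 axes; `w` is minus the slope. At
least 3 usable bins are required. A flat curve (`w ~ 0`) indicates no
hierarchy; hierarchical interactomes typically show `w` in the 0.5–1 range.
The deterministic clique-tree generator (`generate_hierarchical_ppi()`,
a 5-clique replicated fourfold per level with replica peripheries wired to
the root hub) has the analytic decay `C(k) ~ k^-1` and is used to validate
the fit: at 625 nodes the recovered exponent is within 0.15 of 1.

# Module detection (MCODE)

The vertex weight of `v` is `k * density` of the highest k-core of the
closed neighborhood of `v` (loops excluded), zero when `deg(v)` is below
the degree threshold. Detection expands greedily from the highest-weight
unvisited vertex: a breadth-first pass (at most `max_depth` layers) adds
unvisited neighbors whose weight strictly exceeds
`(1 - node_score_threshold)` times the *seed's* weight. Members are owned
by the first module that claims them, making module sets pairwise disjoint.
With haircut on, each module is trimmed to its 2-core; modules without a
k-core at the k-core threshold, or with fewer than two members, are
discarded. Score is subgraph density times size; ranking is by score, then
size, then lexicographically smallest member, and all ties in seed
selection and expansion order are broken by vertex id, so results are fully
deterministic. Defaults are the published setting: degree threshold 2, node
score threshold 0.2, k-core threshold 2, max depth 100, haircut on, fluff
off (the fluff flag parses but is not implemented).

Dialect notes, for comparison with other MCODE implementations: the
expansion gate uses the seed's weight (the original formulation), not the
complex's running score, and strict inequality at the boundary. One
behavior surprises people: two equal cliques joined by a *direct* bridge
edge merge into one module, because both bridge endpoints carry the full
clique weight and pass the expansion gate; the same cliques joined through
a low-degree bridge *vertex* are split cleanly, because the intermediate
vertex's weight falls below the gate. Both behaviors are asserted in the
test suite against hand enumeration.

# Enrichment and unknown-function candidates

Modules with at least `min_module_size = 5` members are tested, one
hypergeometric upper-tail test per biological-process term present in the
module. The reference universe is the whole annotation of the analyzed
network: every node of the tuned network carrying at least one process
term; `n` is the number of module members inside that universe, which keeps
the hypergeometric bounds valid when members lack process annotation.
Benjamini–Hochberg correction is applied within each module's term family
(the behavior of the standard module-enrichment tools), and records with
`q < 0.0001` are reported. The tail probability is computed in log space
via `phyper`, and is validated against exhaustive probability-mass
summation to relative error below `1e-10`.

A caution on the BH step-up transform: it is *not* idempotent on arbitrary
monotone inputs — re-adjusting `(0.5, 1)` yields `(1, 1)` because the
step-up factor `m/i` re-scales every entry. It is the identity on tied
adjusted families, and adjusted values never fall below the raw p-values;
those are the properties the suite asserts.

"Unknown biological function" is operationalized as a process annotation
that is empty or consists solely of the process root term `GO:0008150`
(annotation to the root is how curators mark uncharacterized gene
products). Candidates are reported with their module of origin and the
reason (`no_process_annotation` or `root_only`), in deterministic order.

# Reporter transcription factors

Gene p-values are mapped to z-scores by the inverse normal transform
`z = qnorm(1 - p)` after clipping p into `[1e-15, 1 - 1e-15]`. A TF with n
scored targets gets `raw_z = sum(z) / sqrt(n)`; because target sets overlap
and genes are dependent, `raw_z` is not standard normal under the null, so
it is size-corrected against an empirical background: for every distinct n,
10,000 random gene sets of size n are drawn from all scored genes, and
`corrected_z = (raw_z - mu_n) / sigma_n`. The reporter p-value is the
upper-tail normal probability of the corrected score; scoring is one-tailed
in significance (direction of change is not used), and no correction across
TFs is applied — the decision threshold is the raw `p < 0.05`, following
the published use of the reporter algorithm. Genes present in the
regulatory network but absent from the p-value table are excluded from both
target sets and the background; TFs left without scored targets are skipped
with a warning. If every gene carries the same z (no signal), the
background collapses and corrected scores are defined as zero.

# The synthetic benchmark

Because the original inputs (a 2013-era interactome release and an
unversioned annotation snapshot) are not recoverable, validation runs on a
generated benchmark with known truth at every stage. The default
parameters are the study conditions of the package:

| parameter | default | emulates |
|---|---|---|
| `n_proteins` | 500 | desk-scale interactome |
| `attachment_edges` | 2 | scale-free degree tail |
| `n_cores` | 14 | the literature-curated seed set size |
| `core_vocab_terms` | 10/40/80 (= 130) | the pooled 130-term collection table |
| `n_aspect_terms` | 60/120/220 | the surrounding vocabulary |
| `permissible_fraction` | 0.30 | about a third of the proteome admitted |
| `n_planted_modules`, `module_size`, `module_size_step` | 3, 8, 1 | dense complexes of sizes 8, 9, 10 |
| `unknown_fraction` | 0.01 | rate of uncharacterized proteins |
| `n_tfs`, `targets_per_tf`, `n_active_tfs` | 20, 30, 3 | regulome with planted signal |
| `active_tf_effect` | 4 | noncentrality of the expression signal |

Construction details that matter for interpreting test results:

* **Permissible truth is an exact-count sample** (`round(fraction *
  #non-cores)`), forced to contain every planted module member, rather than
  independent Bernoulli draws: the truth set has a deterministic size and
  the reconstruction stage can be checked for *exact* set equality.
* **Planted modules are cliques** (density 1, the strongest module signal)
  of graded sizes 8/9/10 with 1 to size/2 bridge edges to the background.
  Graded sizes are deliberate: equal-size cliques make the dominant
  eigenpair degenerate (see the tuning section). `module_size_step = 0`
  restores equal sizes for module-detection tests, which do not involve
  the eigensolver.
* **Modules are wired into the permissible backbone**: if a planted module
  would land outside the largest component of the permissible-induced
  subgraph, one of its bridge edges is re-pointed at that component
  (bridge counts unchanged). Without this, the reconstruction's
  largest-component sweep can discard a planted module and no downstream
  stage could recover it.
* **Functional coherence**: each planted module carries a distinctive
  process term shared by its (non-unknown) members, so module enrichment
  has planted positives.
* **Unknown-function proteins**: one per planted module, annotated to the
  process root only — root-annotated proteins are permissible (the root
  is part of the pooled core vocabulary, as seed lists realistically
  contain incompletely characterized proteins), so candidates flow through
  the full pipeline. Background unknowns have an empty process set and are
  non-permissible, exercising the other candidate reason.
* **Expression p-values**: targets of active TFs draw p from a two-sided
  normal test with noncentrality 4; everything else is Uniform(0, 1).

What the generator does **not** emulate: the GO term graph (terms are
flat identifiers), literature and study bias of interactome coverage,
correlated noise between annotation and interaction data, microarray
intensities (only gene-level p-values), and weighted or directed physical
interactions. Passing tests therefore demonstrate algorithmic correctness
and statistical calibration under the stated generative model — not
performance on any particular organism's data.

# Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline on the
500-protein benchmark with the published ensemble size (100
randomizations), the eigensolver cross-check on 200 random graphs of up to
50 nodes, the exhaustive hypergeometric sweep up to a reference of 200, and
the reporter null calibration with 200 TFs at 10,000 background samples.
All randomized stages derive sub-seeds from a single pipeline seed, and two
runs with the same seed produce byte-identical report directories (log
lines carry no timestamps for this reason).

# Known limitations

* The admission rule treats GO terms as opaque ids; annotation granularity
  differences between cores and candidates shift the admitted set.
* The t-test treats the R random EVC values of one node as an i.i.d.
  sample; rewiring correlations between replicates are ignored (they are
  small at ten swap attempts per edge, the default mixing).
* Retention near 100% is expected on small benchmark networks: almost every
  node's observed centrality differs measurably from its rewired
  expectation when the graph is small and structured. The informative
  output at desk scale is the per-node table, not the removal rate.
* MCODE's greedy single-pass vertex ownership makes module boundaries
  order-dependent in principle; determinism is restored by lexicographic
  tie-breaking, but other MCODE dialects will differ on ties.
* The reporter background resamples gene sets uniformly; if target sets
  are biased toward highly variable genes, the correction is conservative.
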