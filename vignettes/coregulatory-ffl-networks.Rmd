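---
title: "Discovering miRNA-TF co-regulatory feed-forward loops"
author: "coregFFL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering miRNA-TF co-regulatory feed-forward loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biological question and the model

MicroRNAs repress their target mRNAs post-transcriptionally while
transcription factors (TFs) activate or repress genes at the promoter.
The two regulator families recur together in small network motifs: a
**3-node feed-forward loop (FFL)** is a miRNA and a TF that share a target
gene, and a **4-node FFL** adds a second TF-bound gene whose protein
physically interacts with the miRNA's target (the *primary* target; the
TF-bound interactor is the *secondary* target). In a two-group design —
here the motivating case of high- versus low-proliferative osteosarcoma
cell lines, 4 versus 3 samples — enrichment of such motifs among
differentially expressed (DE) genes points to miRNA-TF pairs that
co-regulate the phenotype.

`coregFFL` implements the complete inference chain:

1. **Differential expression.** For each feature, log2FC = mean(high) −
   mean(low). The per-feature variance is shrunk toward a common prior by
   empirical Bayes: with pooled within-group variance $s^2$ on $d$
   residual degrees of freedom, the moderated variance is
   $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated
   $t = \mathrm{log2FC}/(\tilde s\sqrt{1/n_1 + 1/n_2})$ is referred to a
   $t_{d_0+d}$ distribution. The hyperparameters $(d_0, s_0^2)$ are
   estimated from the marginal distribution of $s^2$ across features by
   moment matching on $\log s^2$ (digamma/trigamma identities for the
   scaled-F marginal, with a Newton inversion of the trigamma function).
   If the moment estimate of $d_0$ is infinite, $\tilde s^2 = s_0^2$; a
   single-feature matrix falls back to the ordinary pooled $t$
   ($d_0 = 0$); a flat feature with equal group means reports $p = 1$
   rather than NaN. miRNA probes are pre-filtered to the 75% most
   variable across all samples (ties at the cut broken by feature id so
   the result is deterministic); mRNAs are not variance-filtered.
   Thresholds follow the printed criteria: miRNAs at BH-FDR < 0.05 and
   |log2FC| ≥ 1, mRNAs deliberately looser at raw p < 0.05 and
   |log2FC| ≥ 0.7 because miRNA-driven changes in mRNA abundance are
   subtle. The p-threshold is strict (<), the fold-change threshold
   inclusive (≥), matching the printed operators.

2. **Functional targets and enrichment.** Predicted miRNA targets (a
   TargetScan-like table) are kept at context score ≤ −0.1 (more negative
   = stronger predicted repression; duplicate (miRNA, gene) rows keep the
   minimum score, the most-repressive-site reading) and restricted to
   genes on the mRNA platform. A *functional* target is a predicted
   target that is DE **in the direction opposite** to its miRNA
   (inverse-regulation assumption). Each miRNA is tested for enrichment
   of its targets among DE genes with an upper-tail hypergeometric test
   ($N$ = platform genes, $K$ = DE genes, $n$ = predicted targets, $k$ =
   functional targets), BH-corrected across miRNAs; miRNAs at FDR < 0.05
   are retained. A permutation procedure recomputes the enrichment score
   ES = −log10 p for `n_permutations` uniform draws of the DE-gene count
   from the platform; the permutation p-value is
   $(1 + \#\{ES_b \ge ES_{obs}\})/(B+1)$ — ties count as exceeding, and
   the +1 pseudo-count keeps p bounded away from zero. The permutation
   p is reported alongside the parametric FDR, not used as a second
   filter.

3. **GO functional clustering.** Retained miRNAs' functional targets are
   clustered by Gene Ontology biological-process semantic similarity.
   Term information content is $IC(t) = -\ln p(t)$ with $p(t)$ the
   fraction of annotated genes carrying $t$ or a descendant; term-pair
   similarity is the IC of the maximum-IC common ancestor (Resnik);
   gene-pair similarity aggregates term scores by best-match average
   (symmetrized), with a max-over-pairs variant available. The
   dissimilarity handed to clustering is max(sim) − sim with a zero
   diagonal. FANNY fuzzy clustering minimizes
   $\sum_v \frac{\sum_{i,j} u_{iv}^r u_{jv}^r d_{ij}}{2\sum_j u_{jv}^r}$
   directly on the dissimilarity matrix. Model selection: the fuzziness
   $r^\*$ is the smallest grid value whose *normalized* Dunn partition
   coefficient $F_c' = (kF_c - 1)/(k - 1)$ exceeds 0.5 for every
   candidate $k$ (the raw $F_c$ has floor $1/k$, which would make a
   fixed 0.5 rule depend on $k$ — that is why the normalized form is
   compared); the cluster number $k^\*$ maximizes the Dunn separation
   index (minimum between-cluster distance over maximum within-cluster
   diameter; values > 1 indicate well-separated clusters) at $r^\*$.
   Genes with no biological-process annotation are excluded before
   clustering, with a logged count. Each cluster is profiled by
   hypergeometric gene-set over-representation.

4. **FFL motif testing.** TF targets are genes (and miRNAs) with at least
   one binding site **completely contained** in the promoter, the
   symmetric window of ±2000 nt around the TSS; a site straddling the
   window boundary does not count. Internally all coordinates are 0-based
   half-open, so a site $[s, e)$ hits the promoter of a TSS at position
   $\tau$ iff $\tau - w \le s$ and $e \le \tau + w$; 1-based closed input
   intervals $[a, b]$ are converted to $[a-1, b)$ at the file boundary.
   Only TFs expressed at mean log2 intensity ≥ 8 in at least one group
   are considered. Per functional cluster and miRNA-TF pair:
   * the **3-node test** asks whether the pair shares more DE common
     targets than expected among the miRNA's predicted targets
     ($N$ = predicted, $K$ = predicted ∧ TF-bound, $n$ = functional,
     $k$ = functional ∧ TF-bound);
   * the **4-node test** asks the same within the miRNA's first-neighbor
     PPI network — the functional targets plus their direct interaction
     partners ($N$ = neighbors, $K$ = TF-bound neighbors, $n$ = DE
     neighbors, $k$ = DE ∧ TF-bound neighbors).
   Degenerate configurations ($K = 0$ or $N = 0$) return p = 1 rather
   than an error. BH adjustment runs **within each (cluster ×
   motif-type) family**, mirroring the separate reporting of 3-node and
   4-node motifs per cluster, and pairs at FDR < 0.2 are materialized as
   motif records. Co-regulated gene pairs of significant miRNA-TF pairs
   are then checked for elevated coexpression: their Pearson
   correlations are compared with `n_permutations` equally sized draws
   of random gene pairs by a one-sided two-sample KS test (alternative:
   the observed correlation distribution is stochastically greater);
   zero-variance genes are skipped with a log entry.

5. **Networks.** Significant motifs are merged per cluster into a typed
   undirected graph (node types mirna/tf/primary/secondary — a gene that
   is primary anywhere stays primary; edge kinds miRNA-target, TF-target
   including TF→miRNA promoter binding, PPI; parallel edges collapse
   with regulatory kinds taking precedence). Degree and exact betweenness
   are computed on the undirected view; hubs are the top ceil(25%) of
   miRNAs and of TFs and the top ceil(5%) of targets by degree (ties
   broken by betweenness, then id — the ceiling guarantees at least one
   hub per type). Communities come from the walktrap algorithm
   (Pons-Latapy random-walk agglomeration, walk length 4, the
   algorithm's published default), cut at maximum modularity; each
   module is annotated with its top over-represented gene set, or "-"
   when nothing passes FDR < 0.05.

# The synthetic-data generator

No expression data are bundled; `simulateBundle()` creates a complete
input bundle with planted ground truth so that every stage is testable
offline. What it emulates:

* a 4-vs-3 two-group design (log2-scale Gaussian noise, default SD 0.5 —
  microarray intensities are approximately Gaussian on the log2 scale
  after normalization, and the pipeline consumes normalized matrices);
* 9 down- and 8 up-regulated miRNAs with |log2FC| drawn around 2
  (SD 0.25), matching the scale of the printed DE table;
* two planted DE gene pools (up and down, 12% of genes each); each
  planted miRNA draws half of its 30 predicted targets from the
  opposite-direction pool (inverse regulation), the rest from null
  genes; a few weak-scored predictions per miRNA exercise the
  context-score filter;
* planted 3-node FFLs (a TF binding ~85% of one miRNA's functional
  targets, sites placed fully inside promoters) and 4-node FFLs (DE
  secondaries with a PPI edge to a primary and a TFBS in their
  promoter), alternating between up- and down-miRNAs so both functional
  branches receive motifs; background TF binding at 2% of promoters and
  decoy sites straddling promoter boundaries exercise the
  complete-containment rule; one TF is left unexpressed to exercise the
  expression filter;
* an Erdős–Rényi background PPI (edge probability 0.01);
* a toy GO DAG with one root and two branches (binary trees of depth 3):
  up-pool genes are annotated into branch A ("metabolic-like"),
  down-pool genes into branch B ("signaling-like"), each with 2-3 branch
  terms, flipped with 5% noise; a third of null genes get coherent
  single-branch annotations so the IC corpus is realistic.

Because functional targets are drawn from shared pools, TFs planted for
one miRNA genuinely bind targets of other same-direction miRNAs; the
discovery stage therefore legitimately reports more significant pairs
than were explicitly planted. Recovery is assessed on the planted pairs;
structural validity is re-verified for *every* emitted record.

What the generator does **not** emulate: array-level artifacts (dye
bias, batch, background), probe-to-gene summarization, realistic GO
depth and annotation sparsity, degree-heterogeneous (scale-free) PPI
topology, and correlated noise between samples. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to raw-array preprocessing issues.

`nullBundle()` regenerates the same structure with every effect size set
to zero, giving exact nulls for calibration: DE p-values are uniform,
permutation enrichment p-values centre on 0.5, and FFL discoveries at
FDR < 0.2 are controlled (under the global null, BH's expected
false-discovery proportion equals the probability of any discovery,
which is at most the nominal level).

# Numerical choices and edge cases

* **FANNY.** Memberships update from the stationarity condition of the
  objective, computed in log space so small fuzziness exponents stay
  finite; a coordinate with non-positive attractiveness is assigned
  crisply to its best cluster. The first start is deterministic
  (farthest-point seeding on the dissimilarity matrix); four further
  random restarts (seeded) are run and the best objective kept. The
  objective is non-increasing by construction — a safeguard stops the
  iteration if an update would increase it — and iteration ends at a
  relative change below 1e-9 or 500 iterations. Note that for
  degenerate inputs (all dissimilarities equal) the uniform membership
  is a fixed point but a saddle of the objective; the optimizer may
  legitimately return an asymmetric solution with a lower objective.
* **Dunn index degeneracies.** All-singleton clusterings have zero
  diameters: the index is +Inf when clusters are separated and an error
  when identical items are split. Grid cells with $k \ge n$ are reported
  as NA and excluded from selection. If no fuzziness value satisfies the
  0.5 rule, the largest grid value is used with a warning; if no $k$
  reaches a Dunn index above 1, a weak-structure warning is raised.
* **Hypergeometric conventions.** All tests are upper-tail $P(X \ge k)$;
  $k = 0$ gives p = 1 identically, so empty overlaps can never reject.
* **Promoters.** The window is symmetric around the TSS regardless of
  strand — with a symmetric ±2000 nt window, strand does not change
  membership; strand is retained in the data for provenance. Genes
  listed with several TSSs keep the first (logged).
* **Determinism.** One seed in the configuration drives every stochastic
  stage through independent derived sub-seeds; the same seed reproduces
  every stage table bit-for-bit, and the generator writes byte-identical
  files for equal seeds.

# Design decisions that were genuinely open

* **Gene-level similarity aggregation**: best-match average was chosen
  as the common default among Resnik-based gene similarities; a
  max-over-term-pairs variant is available via `aggregate = "max"`.
* **Similarity → dissimilarity**: max(sim) − sim, the simplest monotone
  transform onto a proper dissimilarity with zero self-distance.
* **Enrichment direction**: the enrichment count $k$ uses
  inverse-direction DE targets, consistent with the functional-target
  definition; `direction_aware = FALSE` switches to direction-free
  counting.
* **3-node null universe**: the miRNA's own predicted targets (the
  pair-specific null); a global-universe variant is available in
  `ffl3Test(universe = ...)` for sensitivity analysis.
* **First-neighbor network**: includes the primary targets themselves
  as well as their interaction partners; secondary-target candidates
  are DE genes with direction unconstrained.
* **Hub rounding**: ceiling, guaranteeing at least one hub per type.
* **Centralities and communities** use the undirected view; the GraphML
  export retains all attributes for directed re-interpretation.

# Problem sizes

The test suite and the acceptance script run entirely on generated data:
the standard bundle uses 60 miRNAs, 250 genes plus 12 TFs on the mRNA
platform, 7 samples, 30 predicted targets per miRNA, 6 + 5 planted FFL
pairs; permutation stages use 100-1000 draws depending on context; the
permutation-null calibration uses a 2000-gene universe with 400-gene
target sets so the discrete tie mass of the (1+x)/(B+1) estimator stays
small; walktrap accuracy uses twenty 80-node planted-partition graphs.
These sizes were chosen as the smallest at which each statistical
property is cleanly measurable.

# Limitations

The package consumes normalized expression matrices and externally
produced target predictions, binding sites, TSS annotations, PPIs and GO
structures; it does not normalize arrays, predict targets, or resolve
multi-transcript genes. Numerical equality with limma's `eBayes` is not
targeted (the variance-prior estimator differs in detail, though the
agreement is close; the test suite uses limma as a cross-check). The FFL
null models are pair-specific hypergeometric tests; alternative nulls
(for example degree-preserving rewiring) are out of scope.

# A minimal session

```{r example, eval = FALSE}
library(coregFFL)

sim <- simulateBundle(simulationParams(seed = 1))
cfg <- pipelineConfig(seed = 1)
res <- runPipeline(sim$bundle, cfg, outdir = "results")

head(res$de_mirna_sig)          # DE miRNAs passing FDR<0.05, |lfc|>=1
res$enrichment                  # per-miRNA target enrichment + permutation p
res$clustering$k_star           # selected cluster number
subset(res$ffl$pairs, significant)
res$networks$C1$network         # typed co-regulatory network, cluster C1
res$networks$C1$module_annotation
```
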