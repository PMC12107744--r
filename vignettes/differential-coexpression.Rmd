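---
title: "Differential co-expression inference with dcnet: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression inference with dcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

## The problem

Bulk or single-cell transcriptomics experiments often contrast two sample
groups — tumor vs. normal, treated vs. control, late vs. early time point.
Differential expression analysis asks which genes change in *level*;
differential co-expression (DC) analysis asks which gene *pairs* change in
their **association**. A regulatory interaction can rewire — weaken, vanish,
or invert — without either gene changing its mean, and conversely a strong
expression shift in a regulator typically perturbs its association with its
targets. `dcnet` scores such changes edge by edge and attaches empirical
significance to them.

Two modes are supported. In **mode 1** every unordered gene pair is tested
and the result is an undirected differential co-expression network. In
**mode 2** a user-supplied regulator→target (TF→TG) edge list restricts
testing to a biological prior, and the result is a directed differential
gene regulatory network. Mode 2 is the intended use for pathway-level
questions: the statistical burden drops from $G(G-1)/2$ tests to the size
of the prior.

## The model

For a candidate pair $(g_1, g_2)$ three association values are computed
under one common metric: $r_a$ on the samples of condition $A$, $r_b$ on
condition $B$, and $r_{ab}$ on all samples pooled. Two differential metrics
summarize them:

* **absolute difference in co-expression**
  $\Delta r = |r_a - r_b|$ — the magnitude of rewiring between conditions;
* **degree of association shift**
  $s = r_{ab} - 2\,(r_a + r_b)$ — a combination of the pooled and
  per-condition associations. A condition-specific shift in expression level
  distorts $r_{ab}$ (the pooled cloud becomes a two-cluster mixture) while
  leaving $r_a$ and $r_b$ untouched, so $s$ responds to
  differential-expression-driven rewiring that $\Delta r$ cannot see.

Three association metrics are available: Pearson correlation (linear
association), Spearman correlation (monotone association), and an
entropy-based measure. The entropy measure bins each vector into $B$
equal-frequency bins via average-tie ranks ($B = \lfloor\sqrt{n}\rfloor$ by
default, at least 2), computes the mutual information and marginal entropies
of the binned variables in nats, and returns

$$\mathrm{sign}\big(\rho_{\mathrm{Spearman}}\big)\cdot
  \frac{I(X;Y)}{\sqrt{H(X)\,H(Y)}} \in [-1, 1].$$

It quantifies how far the joint expression distribution departs from
independence, is sensitive to non-monotone dependence, and — because the
binning is rank-based — is invariant under strictly increasing transforms of
either gene. The signed construction keeps it compatible with the
correlation metrics inside $\Delta r$ and $s$. Zero-variance vectors get
association 0 with a `degenerate` flag that propagates to the output table
instead of producing `NaN`.

## The pooled permutation null

Classical permutation tests for DC build one null distribution per edge,
which is prohibitively expensive for genome-scale candidate sets. `dcnet`
builds a **single pooled background model** shared by all tested edges: for
each of $N_p$ draws (default 10000) one candidate edge is picked uniformly
at random with replacement, each gene's values are shuffled *within each
condition* (preserving the per-condition marginals while destroying the
gene–gene coupling) to obtain null $\tilde r_a, \tilde r_b$, and both
pooled vectors are shuffled across all samples for null $\tilde r_{ab}$.
The null metrics $\tilde\Delta r$ and $\tilde s$ are formed exactly as for
observed edges. Sampling edges with replacement makes the null reflect the
marginal distributions of the genes actually tested.

Empirical p-values use a $+1$ pseudocount in numerator and denominator, so
$p \in (0, 1]$ and the estimate is conservative. The $\Delta r$ test is
right-tailed ($\Delta r$ is non-negative by construction); the $s$ test is
two-tailed, implemented as twice the smaller tail probability capped at 1.
Each metric family is then corrected for multiple testing across all tested
edges, by default with Benjamini–Hochberg, and significance means
*adjusted* $p < \alpha$ with $\alpha = 0.01$ strictly.

A practical resolution consequence worth knowing: the smallest achievable
raw p-value is $1/(N_p + 1)$, so after BH the smallest achievable adjusted
p-value over $E$ edges is about $E/(N_p+1)$. Detecting anything at
$\alpha = 0.01$ therefore requires $N_p \gtrsim 100\,E$ when only a handful
of edges are truly differential. Choose `n_perm` with the candidate set
size in mind, not as a fixed constant.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `metric` | `"pearson"` | association measure; `"entropy"` for non-monotone dependence, `"spearman"` for robustness to outliers |
| `n_perm` | 10000 | pooled null size $N_p$; see the resolution note above |
| `alpha` | 0.01 | threshold on BH-adjusted p-values, applied strictly (<) |
| `correction` | `"fdr_bh"` | any of BH, BY, Holm, Hochberg, Hommel, Bonferroni, none |
| `rule` | `"either"` | which metric family admits an edge into the final network (`deltar`, `s`, `either`, `both`); both families are always computed, the rule only filters |
| `s_form` | `"standard"` | the shift formula; see the next section |
| `bins` | `"auto"` | entropy bin count, $\lfloor\sqrt n\rfloor$ with a floor of 2 |
| `seed` | 42 | single RNG seed; the entire run is reproducible |

At least about 10 samples per condition are recommended (the package warns
below that); below 2 per condition it refuses to run.

## The two forms of the shift metric

The default (`s_form = "standard"`) computes $s = r_{ab} - 2(r_a + r_b)$.
This form has a structural property the user must be aware of: it is
dominated by the term $-2(r_a + r_b)$, so *any strongly co-expressed edge*
sits far in the left tail of the pooled null — whether or not its
association changed between conditions. On data where most candidate edges
are strongly co-expressed (e.g. a curated regulon at high base correlation),
the standard $s$ does not separate differential from merely co-expressed
edges; on sparser priors, where typical candidate associations are weak, it
behaves as a joint test of "co-expressed at all, or shifted".

The alternative (`s_form = "centered"`) computes
$s = r_{ab} - (r_a + r_b)/2$: the pooled association minus the *mean* of
the per-condition associations. This is exactly zero for an edge whose
pooled cloud is consistent with its within-condition behavior, however
strong the co-expression, and becomes negative when a condition-specific
mean shift splits the pooled cloud. In the package's own benchmarks
(`scripts/acceptance.R`) the centered form with Pearson association detects
knockdown perturbations well while the standard form detects none; we keep
the standard form as the default because it is the published definition,
and expose the centered form as an explicit choice. Both the observed and
the null $s$ always use the same form.

## The simulator

`simulate_benchmark()` generates benchmark data with known ground truth:

1. a random tree over `n_tf` TFs and `n_tg` TGs, grown by attaching each new
   node to a uniformly chosen existing TF (TGs are always leaves; edges are
   directed regulator→target);
2. a correlation matrix $\Sigma_{ij} = \rho^{d(i,j)}$ with $d$ the tree
   path distance — the canonical graph-to-covariance construction, positive
   definite for trees with $\rho \in (0,1)$;
3. control samples drawn from $\mathcal N(\mu \mathbf 1, \sigma^2 \Sigma)$;
4. a perturbed-gene set (TFs sampled before TGs, so perturbations sit
   upstream and propagate) and case samples drawn from a modified model:
   * **knockdown** — case mean multiplied by `knockdown_factor` (default
     0.1);
   * **diff_expr** — `de_shift` (default $2\sigma$) added to the case mean;
   * **inversion** — every edge incident to a perturbed gene flips its
     correlation sign; the flip propagates as a path-product of edge signs,
     which for a tree equals $z_i z_j \rho^{d(i,j)}$ with $z = \pm 1$
     cumulative root-path signs, hence remains positive definite;
   * **loss_of_coexpr** — incident edges are cut; pairs separated by a cut
     become uncorrelated (block-diagonal, again positive definite);
   * **mixed** — each perturbed gene gets one of the four types uniformly;

   a nearest-positive-definite repair (eigenvalue clipping at $10^{-8}$,
   unit-diagonal rescaling) guards the constructions, and is a no-op for
   trees;
5. i.i.d. Gaussian noise $\mathcal N(0, \texttt{noise\_sd}^2)$ added to
   every entry of both groups;
6. ground truth: every network edge incident to at least one perturbed gene
   is truly differential. This includes the mean-only perturbations
   (knockdown, DE), on the position that differential expression of a
   regulator rewires its interactions — which is precisely what the pooled
   association and the $s$ metric are meant to register.

Defaults: 20 TFs, 80 TGs, 100 samples split 50/50, $\rho = 0.8$,
$\mu = 6$, $\sigma = 1$, `noise_sd` 0.1, 10% of genes perturbed. These
emulate a small, strongly coupled regulon measured on a normalized
microarray-like scale with modest technical noise and a well-powered
balanced design.

What the simulator deliberately does **not** emulate: count noise and
mean–variance coupling of RNA-seq, within-condition substructure
(heterogeneous subgroups), feedback loops or non-tree topology, indirect
effects propagating through unmodeled regulators, and batch effects.
Passing benchmarks here shows that the statistics recover planted
covariance/mean changes under Gaussian assumptions — not that any real
dataset satisfies those assumptions.

`simulate_null_dataset()` generates the matching null experiment — i.i.d.
genes, exchangeable conditions — used to verify type-I error control of the
pooled background.

`benchmark_sweep()` reproduces the benchmarking design: a grid over the
case-to-total sample ratio and the perturbed-gene fraction (the canonical
grid is 0.1–0.9 in steps of 0.1), with several independent simulations and
several algorithm runs per scenario, every run scored by the Matthews
correlation coefficient over the network's candidate edges (zero-denominator
convention: MCC = 0).

## Numerical and design choices

* **Equal-frequency binning, average-tie ranks** for the entropy metric:
  deterministic, rank-invariant, no empty-bin pathologies. The flip side is
  insensitivity of the *pooled* entropy association to pure mean shifts —
  the rank binning absorbs a location shift of one gene almost entirely, so
  the entropy metric relies on $\Delta r$-type signal rather than
  $s$-type signal for mean perturbations.
* **Natural logarithms** in the entropy; normalization cancels the base.
* **Degenerate vectors** (zero variance) yield association 0 plus a flag;
  degenerate edges are reported with $p = 1$, never dropped, so output rows
  always align with the candidate set.
* **Tie handling in empirical p-values**: counting uses weak inequalities
  on both sides, consistent with the pseudocount convention.
* **Canonical pair order** in mode 1 (lexicographic min, max) and full
  seeding of every random step make runs byte-reproducible; two runs with
  the same seed write identical output files.
* **Problem sizes in the shipped tests**: the test-suite benchmarks use the
  default 100-gene network with 2000 permutations and 3–5 seeds per
  scenario, and the null checks use 30 genes × 100 samples with 1000
  permutations — sizes chosen so the whole suite documents the method's
  behavior in minutes while keeping Monte-Carlo error well inside the
  asserted margins.

## Known limitations

* The standard $s$ form conflates baseline co-expression with shift (see
  above); use `rule = "deltar"` or `s_form = "centered"` when the candidate
  prior is densely co-expressed.
* The pooled null assumes candidate edges are reasonably homogeneous; a
  candidate set mixing wildly different marginal distributions makes the
  shared null conservative for some edges and liberal for others.
* Heavy class imbalance shrinks the within-condition permutation space of
  the smaller group, coarsening the null; the package warns below 10
  samples per condition.
* Empirical p-value resolution bounds BH discoveries by
  $E/(N_p + 1) < \alpha$; budget `n_perm` accordingly.
* No handling of missing values, normalization, or batch correction — the
  input is expected to be a clean, already-normalized matrix.
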