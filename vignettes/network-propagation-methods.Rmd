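---
title: "Ranking disease miRNAs by network propagation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking disease miRNAs by network propagation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnarank)
```

## The model

`mirnarank` scores how close each miRNA sits, in a diffusion sense, to the
known miRNAs of a disease. The substrate is the bipartite miRNA–target
gene graph: nodes are miRNAs and genes, edges are targeting interactions
treated as mutual (undirected, unweighted). A random walker starts from a
seed distribution $p_0$ and at each step either moves to a uniformly
chosen neighbour (probability $1-\gamma$) or restarts at $p_0$
(probability $\gamma$):

$$p_{t+1} = (1-\gamma)\,W' p_t + \gamma\, p_0,$$

with $W'$ the column-stochastic transition matrix
$W'_{ij} = A_{ij}/\deg(v_j)$. Iteration stops when
$\lVert p_{t+1}-p_t\rVert_1 < 10^{-6}$; the stationary vector $p_\infty$
ranks the candidates.

The working assumption is modularity: the miRNAs of one disease tend to
co-target an overlapping set of genes, so a walker released on the known
miRNAs *and on their targets* accumulates on the other miRNAs wired into
the same module. That motivates the two-part seed set
$S = S_m \cup S_g$ — known disease miRNAs plus the union of their target
genes — weighted by $\alpha$:

$$p_0(v) = \begin{cases}
\alpha/|S_m| & v \in S_m\\
(1-\alpha)/|S_g| & v \in S_g\\
0 & \text{otherwise.}
\end{cases}$$

At $\alpha = 1$ this degenerates to the classical miRNA-only seeding. We
accept $\alpha = 1$ (closed interval) precisely so that the degenerate
case is reachable: the continuity of the LOOCV AUC as
$\alpha \to 1^-$ is one of the package's invariant tests.

The comparison method (`method = "rwrmda"`) runs the same walk with
miRNA-only seeding on a *homogeneous* miRNA network whose edge weight is
the number of shared target genes (optionally their Jaccard index —
`shared_count` is the default because it is the plainer reading of
"shared targets"; both are offered since the literature varies). Its
weighted adjacency is column-normalized the same way.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `gamma` | restart probability per step (dimensionless, (0, 1]) | 0.5 | midpoint of the conventional sweep range [0.1, 0.9]; balances local vs global diffusion |
| `alpha` | initial mass on seed miRNAs vs their targets ((0, 1]) | 0.5 | equal split; performance is empirically flat in `alpha` on modular data |
| `tol` | L1 convergence threshold | 1e-6 | the method's standard stopping rule |
| `max_iter` | iteration cap | 1000 | the contraction bound guarantees convergence in $\lceil\log(tol/2)/\log(1-\gamma)\rceil$ steps — under 160 even at `gamma = 0.1` |

`gamma = 1` is permitted as the degenerate full-restart walk
($p_\infty = p_0$), useful for testing, though sweeps conventionally stop
at 0.9. `gamma = 0` is rejected: the linear system can be singular and a
restart-free walk no longer measures proximity to the seeds.

## Numerical choices

* **Normalization.** Column-stochastic degree normalization of the
  symmetric adjacency. Row-normalized variants exist in the propagation
  literature and yield different rankings on degree-heterogeneous
  networks; column normalization is the standard walker semantics (mass
  leaves each node along its edges) and pairs with exact mass
  conservation, $\sum_i (p_t)_i = 1$ at every step, which the tests
  assert to $10^{-10}$.
* **Convergence norm.** The stopping rule's norm is taken as L1, the
  natural partner of mass conservation; the residual then provably
  contracts by $1-\gamma$ per step, which the tests check along the
  recorded residual trace.
* **Ties.** Ranking ties are broken lexicographically by miRNA id, making
  every output deterministic; LOOCV percentiles give half credit to ties,
  so a constant scorer has AUC exactly 0.5.
* **Oracle.** The iterative solver is cross-checked against the dense
  closed form $\gamma (I-(1-\gamma)W')^{-1} p_0$ (`stationary_direct`,
  test-only, feasible to a few thousand nodes) to $10^{-8}$ sup-norm on
  random networks.
* **Degenerate inputs.** Nodes exist only via edges, so zero-degree
  columns cannot arise in loaded networks. In the similarity baseline
  they can (miRNAs sharing no target with anyone): the walk runs on the
  non-isolated subgraph, isolated miRNAs score exactly 0 and rank last,
  and seeding fails only when *every* seed is isolated. Isolated miRNAs
  are kept in the ranking (score 0) rather than dropped so both methods
  rank the same candidate set.
* **Identifier matching** is case-insensitive after whitespace trimming
  (mixed conventions like `hsa-miR-506`/`hsa-mir-506` coexist across
  public datasets); ids are stored in canonical lower case. The input
  dialect (tab or comma) is auto-detected from the first line, and a
  first row whose leading field carries no digit while the next row's
  does is treated as a header — identifiers in every common miRNA/OMIM
  naming scheme contain digits, column labels do not.

## Evaluation

LOOCV holds out each known disease miRNA in turn; the remaining known
miRNAs seed the walk and the held-out one competes against **all**
non-seed network miRNAs (not a sampled control set, and including miRNAs
associated with other diseases — the stricter and simpler convention).
The AUC is the mean held-out rank percentile, which equals the
trapezoidal area under the pooled ROC built by sweeping a rank threshold
(`roc_points()`), up to tie effects bounded by `1/min(n_candidates)`. The
transition matrix is built once per network and reused across folds —
seeding changes, topology does not, so results are bit-identical to
rebuilding.

`parameter_sweep()` computes one LOOCV AUC per cell of the
$5 \times 9$ grid $\alpha \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$,
$\gamma \in \{0.1, \dots, 0.9\}$; each cell is exactly the standalone
`loocv()` value.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` plants a module: `n_module_mirna = 12` miRNAs and
`n_module_gene = 40` genes connected at `p_in = 0.35`, all other pairs at
`p_bg = 0.02`, in a 60 × 200 network; 8 module miRNAs become the known
miRNAs of disease `SYN1`. These sizes put the module signal
(about 14 within-module targets per module miRNA against about 4
background edges) in the regime where propagation should, and does,
recover held-out members with median LOOCV AUC above 0.85, while the
`p_in = p_bg` null stays near 0.5 — the two calibration checks run in the
acceptance suite. A Bernoulli edge model is used rather than a
configuration model: it is the simplest mechanism with the modular
structure the method exploits, and degree correction adds nothing at this
scale. Any degree-0 node is repaired with one uniform (module-respecting)
edge so the edge list defines every node. True module membership is
returned so tests can also score rankings against ground truth directly.

What it does **not** emulate: the heavy-tailed target-count distributions
of real miRNAs, predicted-target false positives, multi-disease
association tables, or expression-derived candidate lists. Passing the
recovery checks therefore shows the machinery is correct and the method
behaves as designed on modular signal — not that any particular AUC will
be attained on real miRWalk/TargetScan-scale data.

Test and acceptance problem sizes (60 × 200 networks, 10 generator
replicates, the full 45-cell sweep on one replicate) were chosen so the
whole suite completes in seconds while keeping every fold a genuine
propagation on a few hundred nodes.

## Interface design

The four-step workflow (load → rank → evidence → export) is exposed three
ways: exported functions, a CLI (`rank`, `loocv`, `sweep`, `diseases`,
`evidence`, `export`, `simulate`) and a stateful in-process service
facade mirroring the four REST-style automation calls (diseaseList,
filtered diseaseList, rank — stored server-side in a single
most-recent-ranking slot — and getRank/limit, all JSON-capable). The
facade is transport-free by design: it gives workflow engines the exact
POST-then-GET semantics without binding the package to an HTTP server,
and the test suite asserts its rankings are identical to the CLI's.

Evidence search is PubMed co-occurrence only — one query per miRNA of the
form `("<mirna>"[All Fields]) AND ("<disease>"[All Fields])` — with the
fetcher injected as a function, so the default suite runs fully offline
on stubs and live NCBI E-utilities access (`pubmed_fetcher()`, rate
limited) is opt-in. Graph export writes rank and score as plain numeric
node attributes and distinguishes known from candidate association edges
by an `edge_class` attribute; visual styling (colour ramps, solid vs
dashed) is deliberately left to the consumer (Cytoscape, igraph, etc.).

## Known limitations

* Edges are unweighted; interaction confidence scores are ignored.
* One network at a time; no multi-network or disease-similarity
  integration, and no teleport-vector variants beyond the two seedings.
* miRBase version reconciliation is out of scope — ids are matched
  verbatim (case-insensitively), so mixed-version inputs silently drop
  the unmatched ids (they are reported in `dropped`).
* The LOOCV AUC estimator is the mean rank percentile; papers using
  sampled control sets or fixed top-k cutoffs will report different
  numbers on the same data.
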