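---
title: "Extracting key pathways from networks and multi-omics indicator matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting key pathways from networks and multi-omics indicator matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given an undirected molecular interaction network (typically protein-protein
interactions) and one or more binary gene-by-case **indicator matrices** — a 1
meaning that a gene is significantly altered in that case for that omics
study — we look for **key pathways**: maximal connected sub-networks in which
all nodes but at most *K* are *active*, where a gene counts as active when
its omics measurements are aberrant in all but a bounded number of cases.
Such sub-networks point at condition-specific network modules (e.g. a
signaling component deregulated across most tumors of a cohort) rather than
at isolated gene hits.

`keypathways` implements the full pipeline: file formats, the activity
model, an exact enumerator, two scalable heuristics, prior-knowledge lists,
a (K, L) parameter sweep with node scoring for visualization, and a
synthetic-fixture generator used throughout the test suite.

## The activity model

Each indicator matrix $M_i$ carries its own **case-exception threshold**
$L_i$: gene $g$ is active *for matrix* $M_i$ when its row contains at most
$L_i$ zero entries. Thresholds may be given as absolute counts or as a
percentage of the matrix's cases. Percentages resolve by **ceiling**:
$L = \lceil p/100 \cdot n_\text{cases} \rceil$. Both printed reference
values that motivated this rule (25% of 155 cases → 39; 25% of 291 cases →
73) are consistent with ceiling and with round-half-up but not with floor;
ceiling is the more permissive reading of an "at most $L$ non-active cases"
threshold and is what the package commits to.

Per-matrix activity literals are combined through a boolean **formula**
over the matrix names with binary `AND`, `OR`, `XOR` — e.g.
`(up AND hypo) OR (down AND hyper)` to couple expression direction with
methylation state. Chains without parentheses associate left with no
operator precedence; `XOR` over more than two operands is therefore the
left fold, never an n-ary "exactly one". For cohorts measured on the *same*
cases an alternative route exists: combine two matrices cell-wise
(`kp_cellwise_combine`) and threshold the result. The two routes agree
exactly for `AND` at $L=0$; for `OR` the formula route implies the
cell-wise route but not conversely, so they are distinct modeling choices,
not interchangeable implementations.

Two conventions matter for real data:

* **Genes absent from a matrix** count every case as non-active, so they
  are inactive under any $L < n_\text{cases}$. This is deliberately
  conservative — an unmeasured gene is never promoted to active.
* The **universe** of the activity profile is the network's node set;
  matrices may cover more or fewer genes, and coverage statistics are
  reported by `kp_validate()`.

Activity is computed once, up front, for every network node
(`kp_activity_profile`); the search algorithms consume only the resulting
active/exception states and never re-touch the matrices.

## Prior knowledge

A **positive list** forces its nodes to behave as active regardless of the
data (they bypass the thresholds and never consume the exception budget); a
**negative list** forces its nodes to always count as exceptions. Negative
nodes are *not* forbidden — they can still enter a pathway, but only by
spending budget — so the lists bias rather than constrain the search. The
two lists must be disjoint.

## Search

All solvers optimize the same objective: maximal connected node sets with
at most $K$ exception-state nodes (each exception node counts once against
the budget, however many cases it fails in). A pathway must additionally
contain at least one active-state node: an all-exception set carries no
signal, and admitting such sets would make every isolated inactive node a
"pathway" at $K \ge 1$.

**Exact enumeration** (`kp_enumerate_pathways`) walks every connected
induced subgraph exactly once via anchor-based enumeration with exclusive
extension sets, pruning any branch whose exception count already exceeds
$K$ (supersets can only add exceptions). A set is reported when no neighbor
can be added — no active neighbor exists and the budget is exhausted for
exception neighbors. Single-node maximality coincides with set-inclusion
maximality here: any valid connected superset can be reached by adding one
node at a time through valid intermediates, because connectivity permits an
incremental ordering and the exception count is monotone under addition.
The test suite verifies this equivalence on random instances rather than
assuming it. Enumeration is exponential in the worst case; the default size
cap is 25 nodes (override with `force = TRUE`), and its intended roles are
small instances and serving as the correctness oracle for the heuristics.

**Greedy expansion** (`kp_greedy_expand`, `kp_greedy_search`) grows a set
from each active node, repeatedly adding the best frontier node with
preference (1) active over exception, (2) more active neighbors outside the
set, (3) lexicographically smaller ID — a deterministic tie-break that also
makes the whole multi-start search reproducible without any seed.

**Ant colony optimization** (`kp_aco_search`) keeps one pheromone value
$\tau_v$ per vertex, initialized at $\tau_\max$. Each ant picks a start
among active nodes with probability $\propto \tau_v^\alpha$ and grows its
set choosing frontier node $u$ with probability
$\propto \tau_u^\alpha \eta_u^\beta$, where $\eta_u = 1$ for active nodes
and $\eta_u = \epsilon$ for exception nodes, always within the budget.
After each iteration all pheromones evaporate,
$\tau \leftarrow (1-\rho)\tau$, and the iteration-best solution $S$
deposits $|S|/|V|$ on its members, clamped to $[\tau_\min, \tau_\max]$.
Defaults: 20 ants, 100 iterations, $\alpha = 1$, $\beta = 2$,
$\rho = 0.1$, $\epsilon = 0.1$, $\tau \in [0.01, 1]$. The pheromone bounds
are this package's choice (MMAS-style clamping keeps exploration alive);
the remaining defaults are moderate values that let the colony reliably
reach the exact optimum on the small benchmark fixtures used in the tests.
One RNG stream per run, seeded from `seed`, drives both start selection and
growth; the caller's RNG state is saved and restored.

Every heuristic output is valid by construction (sets only grow through
budget-respecting additions) and single-node maximal (growth stops only
when no addition is possible).

## Parameter sweep and node scoring

Choosing $K$ and $L$ is the hardest practical step. `kp_run_sweep` solves
every cell of a $K \times L_1 \times \dots \times L_n$ grid — recomputing
the activity profile per cell, since $L$ changes activity — and aggregates
a per-node **appearance score**: the raw score of node $v$ is
$\sum_{\text{cells}} \sum_{P \ni v} |P|$, normalized by the maximum so the
top node scores exactly 1. The score grows with both the number and the
size of the pathways containing a node, which is the property the
color-intensity visualization needs; the particular weighting (sum of
sizes, max-normalized) is this package's concrete choice and is not
configurable. Score tables are written per cell and as a global aggregate
(`kp_write_sweep`), loadable as Cytoscape node attributes for a continuous
color mapping. Heuristic cells derive independent seeds from
`hash(base_seed, cell_index)`, so cells neither share state nor change when
the grid is reordered or extended.

## Synthetic fixtures

`kp_generate_fixture` builds a connected random network (uniform random
spanning tree plus extra distinct edges) and plants a connected module by
seeded BFS growth from a random root, then draws indicator-matrix cells
i.i.d. Bernoulli: planted genes active with probability 0.9, background
genes with 0.05, over 50 cases, 100 nodes / 200 edges (mean degree 4,
comparable to a sparse interactome), module size 15. These defaults are the
package's standard recovery scenario; 200 edges was fixed a priori as a
realistic sparsity, since only the network's density — not its exact edge
count — matters for recovery.

What the generator does *not* emulate: case-case correlation (cells are
independent given the gene; the method only consumes per-row counts, so
correlation would not change any computed quantity), degree heterogeneity
of real interactomes (the spanning-tree construction yields near-Poisson
degrees, not scale-free tails), and realistic marginals of expression or
methylation calls. Passing the recovery tests therefore demonstrates
correctness of the machinery under a clean planted-signal model, not
performance on real cohorts.

## Numerical and design choices

* Percent thresholds: ceiling, with a $10^{-9}$ guard against
  floating-point excess just above exact integers.
* Absolute thresholds larger than the case count clamp with a warning.
* All ID ordering (pathway members, tie-breaks, output files) uses
  byte-wise (C-locale) sorting, so outputs are identical across locales.
* Pathway lists sort by descending size, ties lexicographically by the
  sorted node IDs; identical node sets are deduplicated exactly (no
  overlap-based filtering).
* Fixed seeds yield byte-identical output files for every algorithm,
  sweeps included.
* Degenerate inputs: an empty active set yields an empty result (exit
  status 0 from the CLI); isolated active nodes form singleton pathways;
  self-loops and duplicate edges are dropped at parse time with a logged
  count.

## Validation scale

The test suite validates the exact enumerator against an exhaustive
all-subsets oracle on 100 random instances of up to 12 nodes, the
heuristics against the enumerator on fixtures of up to 25 nodes (100 seeded
ACO runs at the default budget on a 12-node fixture), parser behavior on a
synthetic network of 9,427 nodes and 36,812 edges, and module recovery on
50 replicates of the 100-node scenario. These sizes keep the full suite in
the low minutes on a single core while still exercising every code path;
the solvers themselves handle interactome-scale networks (the heuristics
are linear per growth step in the frontier size).

## Limitations

* Statistical discretization of raw omics data into indicator matrices is
  out of scope; the package starts from 0/1 calls.
* Only the individual-node-exception budget is implemented; a global
  case-exception budget summed over nodes is a different search strategy
  and is not provided.
* The exact enumerator is exponential; beyond a few dozen nodes only the
  heuristics are practical, and they carry no optimality guarantee.
* Equivalence with any particular GUI implementation of the same problem
  is not claimed; the contracts are validity, maximality, determinism, and
  oracle agreement as described above.
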