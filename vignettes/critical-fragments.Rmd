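---
title: "Critical fragments: graph-theoretic screening for instabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical fragments: graph-theoretic screening for instabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critfrag)
```

## The model and the question

A biochemical mechanism with $n$ species $A_i$ and $m$ elementary reactions

$$B_j:\ \sum_i \alpha_{ji} A_i \xrightarrow{\;k_j\;} \sum_i \beta_{ji} A_i$$

under mass-action kinetics is the ODE system $\dot u = S\,w(u)$ with
stoichiometric matrix $S_{ij} = \beta_{ji}-\alpha_{ji}$ and rates
$w_j = k_j \prod_i u_i^{\alpha_{ji}}$. Whether such a model *can* display
multistability, sustained oscillations or Turing-driven patterning is
usually probed by bifurcation analysis, which becomes impractical for
models with many species and parameters. The screening implemented here
asks a weaker but parameter-free question: does the *network structure*
admit these instabilities at all, for any parameter values?

The object of study is the Jacobian parametrized by the equilibrium
concentrations $u$ and equilibrium rate values $w$ (both treated as free
positive parameters):

$$J_{ik}(u,w) = \sum_j S_{ij}\,\alpha_{jk}\,\frac{w_j}{u_k},$$

whose characteristic-polynomial coefficients $a_k(u,w)$ (here defined as the
sums of $k \times k$ principal minors of $-J$) decide stability. A
saddle-node bifurcation — the generic route to multistability — requires
$a_r(u,w) = 0$ for some positive parameters, where $r = \operatorname{rank}
S$ is the order of the last non-vanishing coefficient. Since every $a_k$ is
a sum of monomials $w_{j_1}\cdots w_{j_k} / (u_{i_1}\cdots u_{i_k})$ with
integer coefficients, $a_r$ can only vanish if at least one coefficient is
negative.

## Fragments and their weights

The combinatorics of those signs live on the bipartite digraph of the
mechanism: species nodes, reaction nodes, arcs $A_k \to B_j$ when
$\alpha_{jk} > 0$ and $B_j \to A_i$ when $\beta_{ji} > 0$. Its weighted
elements are

* **edges** $[A_k, B_j]$ with weight $K_E = -\alpha_{jk}^2$,
* **positive paths** $[A_k, B_j, A_i]$ (production of $A_i$ from $A_k$)
  with weight $\alpha_{jk}\beta_{ji}$,
* **negative paths** $[A_k, B_j, \bar A_i]$ ($A_k, A_i$ co-reacting,
  $k \neq i$; the two orientations are distinct paths) with weight
  $-\alpha_{jk}\alpha_{ji}$,
* **cycles**: chains of paths with pairwise-distinct start species, closed
  cyclically; weight = product of path weights,
* **subgraphs** $g$: species-disjoint collections of cycles and edges, with
  $K_g = (-1)^c \prod_{C} K_C \prod_E (-K_E)$ ($c$ = number of cycles),
* **fragments** $S_k$: all subgraphs sharing one species set of size $k$
  and one reaction multiset of size $k$, with weight
  $K_{S_k} = \sum_{g \in S_k} K_g$.

The central identity states

$$a_k(u,w)\;=\;\sum_{S_k} K_{S_k}\,
  \frac{w_{j_1}\cdots w_{j_k}}{u_{i_1}\cdots u_{i_k}},$$

with a one-to-one correspondence between fragments and monomials. A
fragment with $K_{S_k} < 0$ is **critical**; one of order $r$ is necessary
for multistability, one of order $k < n$ for Turing instability, and one of
order $k < r$ flags possible Hopf oscillations. `verify_identity()` checks
the identity symbolically, order by order, and is the master self-test of
the package: every enumeration layer (fragments, cycles, subgraphs,
weights) must be simultaneously correct for it to hold.

```{r identity}
mech <- load_fixture("reversible_substrate_inhibition")
verify_identity(mech)
```

## The enumeration algorithm

A naive enumeration pairs each of the $\binom{N}{k}$ species subsets with
all $R^k$ reaction tuples and filters; this blows up quickly. Instead the
package uses the fact that every fragment contains at least one subgraph
made of edges only: it suffices to pick, for each species of a subset, one
reaction that species is a reactant of. Distinct picks can induce the same
(species set, reaction multiset) pair, and the pair — not the pairing — is
the fragment's identity, so keys are deduplicated. Without that merge each
fragment would be counted once per edges-only assignment and the
coefficient identity above would fail; the identity test enforces the
merge. `count_generated()` reports both raw candidate counts (the
correspondence count is the $k$-th elementary symmetric function of the
species out-degrees), which for the double-layer MAPK cascade differ by
orders of magnitude.

Per fragment, subgraphs are enumerated assignment-wise. Every subgraph
induces the edges-only assignment that maps each species to the reaction of
the component it starts, so the subgraph sets of distinct assignments are
disjoint and their union is exhaustive. For one assignment:

1. **Path graph.** Nodes are the positive paths and the two expanded
   traversals of each negative path of the fragment (each species running
   through its paired reaction); an arc joins paths chained end-to-start;
   self-loops are allowed (autocatalysis).
2. **Cycle detection.** Elementary circuits of the path graph are
   enumerated by an anchored depth-first search in the style of Johnson's
   algorithm, amended so that a branch is abandoned the moment a start
   species would repeat — invalid closed walks are pruned *during* the
   search rather than filtered afterwards, which keeps memory flat. The
   tests cross-check against an unpruned circuit enumerator with post-hoc
   filtering.
3. **Cycle graph and cliques.** Cycles become nodes of an undirected graph
   with an edge between species-disjoint cycles; every clique (enumerated
   with igraph, including the empty clique, which the worked examples
   require for the pure-edge subgraph) plus the paired edges of the
   uncovered species is a subgraph. Because each species consumes exactly
   its paired reaction, the reaction multiset is conserved by construction.

Weighting then follows the formulas above; results are deduplicated by
rotation-invariant canonical forms (cycles are rotated so the smallest
species index leads).

One design point deserves emphasis: the lookup table of subgraph components
is built per assignment (species paired with one reaction), not per
reaction multiset. On the worked substrate-inhibition fragment the
multiset-wide table would admit a third cycle that belongs to no subgraph;
the pair-based construction yields exactly the two cycles that occur in
subgraphs, and the assignment-wise union provably loses nothing (see
above). The brute-force oracle in the test suite works multiset-wide and
agrees on the final subgraph sets.

## Sign conventions and numerical choices

* $a_k$ is defined as the sum of principal $k$-minors of $-J$, the
  convention under which the worked coefficient of the substrate-inhibition
  model comes out verbatim and critical fragments are exactly the negative
  monomials.
* The edge weight is $K_E = -\alpha_{jk}^2$ (squared). For unit
  coefficients the square is invisible; the two conventions part ways on
  mechanisms with a coefficient-2 reactant, where only the squared form
  satisfies the coefficient identity (the diagonal Jacobian entry of
  $q A \to \dots$ carries $\alpha^2 = q^2$, and the edges-only subgraph
  must supply it). The randomized identity tests cover `max_stoich = 2`
  mechanisms precisely to pin this down.
* The stoichiometric rank gates the multistability criterion, so it is
  computed exactly (fraction-free Bareiss elimination over the integers),
  never with a floating tolerance. Intermediate values are bounded by
  Hadamard's inequality and stay far below the exact-integer range of
  doubles for any realistic mechanism.
* All symbolic work uses a bespoke sparse ring of terms
  $c\,\cdot\,w\text{-multiset}/u\text{-set}$ with integer coefficients;
  equality is exact term-by-term comparison, never numerical sampling.
* Degenerate inputs: a fragment key in which some species admits no
  component has zero subgraphs and weight 0 (not an error); a reaction with
  identical sides contributes a zero stoichiometric column and null
  Jacobian entries but still induces arcs, edges and self-loop paths, and
  the identity holds because its fragment weights cancel exactly.

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `order` | `run_analysis()` | $\mathrm{rank}(S)$ | fragment order; the rank order is the multistability-relevant one |
| `workers` | `run_analysis()` | 1 | forked workers over the fragment queue; output is worker-count invariant |
| `cap` | `combinatorial_fragments()` | $10^6$ | guard on the brute-force baseline |
| `n_guard` | `verify_identity()` | 9 | refuse symbolic expansion beyond this many species |
| `max_stoich` | `random_mechanism()` | 2 | stoichiometric coefficients of generated mechanisms ("small integers") |
| `p_io` | `random_mechanism()` | 0.15 | chance a generated reaction is a pure inflow/outflow |

The parallel architecture follows the work-queue design: fragments are
independent work units, a coordinator merges results, and reports are
sorted so that output is byte-identical for any worker count (the tests
compare 1 vs 4 workers).

## What the generated mechanisms emulate — and what they do not

`random_mechanism()` mirrors the structural assumptions of the theory:
elementary reactions with up to two reactant and two product species,
coefficients 1–2 (mass-action "small integers"), occasional pure inflows
and outflows, and every species used somewhere. It does **not** emulate
thermodynamic consistency, detailed balance, conservation-law structure
typical of signalling networks, or realistic degree distributions; passing
the randomized suites therefore certifies the combinatorics and algebra of
the implementation on small dense networks, not biological plausibility of
any particular random draw. Results on real mechanisms rest on the packaged
curated examples.

## Problem sizes

The default test and verification runs use: full symbolic verification up
to $n = 7$ species (the glycolysis switch, seconds), whole-mechanism
screens up to 12 species / 18 reactions at sub-maximal orders, and complete
rank-order screens for the 8-species Cdc42 network (1961 fragments) and the
9-species single-layer MAPK cascade (2352 fragments), each a few seconds.
The full order-9 screen of the double-layer MAPK cascade (tens of
thousands of fragments) is feasible with `run_analysis(m, order = 9,
workers = ...)` but is intentionally not part of the default suites; its
correctness is covered by the enumeration-cost inequalities, the
sub-maximal-order spot checks and the randomized oracle equivalences.

## Known limitations

* Mass-action kinetics only; Hill/Michaelis–Menten rate laws would need a
  multigraph generalization of the weights.
* The screen yields *necessary* conditions: a critical fragment proves the
  sign structure admits the instability, not that parameters realizing it
  exist; no bifurcation continuation or reaction–diffusion simulation is
  attempted, and no $(u, w)$ values are suggested.
* SBML import is out of scope; the plain-text dialect is the only input
  format.
* Symbolic verification is limited to $n \le 9$ by design (the principal
  minor expansion is exponential); the graph enumeration itself has no such
  guard.

## Published listings with typographic defects

Two packaged mechanisms are shipped in corrected form because the printed
listings contradict their own published analysis results; the headers of
the fixture files carry the details. The Cdc42 network additionally ships
verbatim (`cdc42_as_printed`) so both readings can be compared:
`validate_mechanism()` flags the orphaned species in the verbatim listing,
and the corrected variant (`cdc42_corrected_b12`) is the one reproducing
the published rank (5) and critical-fragment count (35).
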