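# critfrag

Parameter-free screening of mass-action biochemical mechanisms for their
capacity for **multistability**, **oscillations** and **Turing
instability**, via critical-fragment enumeration on the bipartite
species–reaction digraph.

## Who this is for

Modelers deciding between candidate reaction mechanisms before fitting any
rate constants. Bifurcation analysis of a large ODE model is expensive;
this screen answers a prior, purely structural question: *can* the network
exhibit the instability for **any** positive parameter values? Mechanisms
failing the necessary condition can be discarded early.

## The method

A mechanism with species $A_i$ and elementary reactions
$B_j: \sum_i \alpha_{ji} A_i \to \sum_i \beta_{ji} A_i$ under mass action
is $\dot u = S\,w(u)$, with $S_{ij} = \beta_{ji} - \alpha_{ji}$. The
Jacobian parametrized by equilibrium concentrations $u$ and rate values
$w$,

$$J_{ik}(u,w) = \sum_j S_{ij}\,\alpha_{jk}\, w_j / u_k,$$

has characteristic-polynomial coefficients $a_k(u,w)$ (sums of principal
$k$-minors of $-J$) that decompose **exactly** over the bipartite digraph:

$$a_k(u,w) = \sum_{S_k} K_{S_k}\; \frac{w_{j_1}\cdots w_{j_k}}
{u_{i_1}\cdots u_{i_k}},$$

one monomial per *fragment* $S_k$ (a set of $k$ species with a multiset of
$k$ reactions). The fragment weight $K_{S_k}$ sums the signed weights of
the fragment's *subgraphs* — species-disjoint covers by cycles and edges,
with $K_g = (-1)^c \prod_C K_C \prod_E (-K_E)$, edge weight
$K_E = -\alpha_{jk}^2$, positive-path weight $\alpha_{jk}\beta_{ji}$ and
negative-path weight $-\alpha_{jk}\alpha_{ji}$. A fragment with
$K_{S_k} < 0$ is **critical**:

* order $r = \operatorname{rank} S$ critical fragment — necessary for
  multistability (saddle-node);
* order $k < n$ — necessary for Turing instability, and a route to Hopf
  oscillations when $k < r$.

Fragments are enumerated through their edges-only subgraphs (orders of
magnitude fewer candidates than the combinatorial baseline); per fragment,
cycles are found as pruned elementary circuits of a *path graph* and
combined into subgraphs via cliques of a *cycle graph*. The whole pipeline
is verified symbolically against principal-minor expansions by
`verify_identity()`.

## Worked example

```r
library(critfrag)
mech <- load_fixture("reversible_substrate_inhibition")
mech
#> Mass-action mechanism: 4 species, 6 reactions
#>   A1 -> ; k1
#>   -> A1 ; k2
#>   A1 + A2 -> A3 ; k3
#>   A3 -> A2 ; k4
#>   A1 + A3 -> A4 ; k5
#>   A4 -> A1 + A3 ; k6

run_analysis(mech, all_orders = TRUE)
#> mechanism: 4 species, 6 reactions, rank(S) = 3
#> orders analyzed: 1, 2, 3
#> fragments: order 1: 7; order 2: 17; order 3: 17
#> critical fragments: 1
#> order 3 | species 1,2,3 | reactions 3,4,5 | K=-1
#> multistability necessary condition (critical fragment of order rank(S) = 3): MET
#> Turing instability / oscillation potential (critical fragment of order k < n = 4): YES (present)
```

One conservation relation ($u_2+u_3+u_4$ constant) gives rank 3, so
multistability requires an order-3 critical fragment; the screen finds
exactly one — species $\{A_1,A_2,A_3\}$ with reactions $\{B_3,B_4,B_5\}$,
weight $-1$ from its three subgraphs ($-1-1+1$). Its monomial is the single
negative term of $a_3$:

```r
format_sympoly(charpoly_coefficient(symbolic_jacobian(mech), 3))
#> w1*w3*w5/(u1*u2*u3) + w1*w3*w6/(u1*u2*u4) + w1*w4*w6/(u1*u3*u4)
#>   - w3*w4*w5/(u1*u2*u3) + w3*w4*w6/(u1*u3*u4)
```

so the model can undergo a saddle-node bifurcation only where
$w_4 > w_1$ — structure alone narrows the parameter hunt.

From a shell, the same screen is

```sh
Rscript inst/scripts/critfrag mechanism.txt --order 3 --workers 4 --format tsv
```

(after installation, `system.file("scripts", "critfrag", package =
"critfrag")` locates the script). Mechanism files are one reaction per
line: `A1 + A2 -> A3 ; k3`, with `-> A1 ; k2` for inflows, `A1 -> ; k1`
for outflows, integer coefficients as in `2 A1 -> A2 ; k4`, and `#`
comments.

Packaged mechanisms (`load_fixture()`): a reversible substrate-inhibition
scheme, a glycolysis–gluconeogenesis switch, the yeast Cdc42 polarity
network (verbatim and corrected variants), and single- and double-layer
MAPK cascades.

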