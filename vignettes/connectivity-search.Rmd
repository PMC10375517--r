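---
title: "Methods: degree-weighted path counts and their null distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degree-weighted path counts and their null distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetpaths)
```

## The model

A hetnet assigns every node a metanode (type) and every edge a metaedge.
`hetpaths` represents the network as one 0/1 adjacency matrix per metaedge,
rows and columns bound positionally to per-metanode node orderings, stored
on disk as a directory (`metagraph.json`, `nodes/*.tsv`, `edges/*`) and
loaded lazily. Two modelling assumptions are baked into the data structures:

* **no self-edges** — adjacency diagonals are zero for self-typed
  metaedges. The duplicate-node corrections below rely on this.
* **binary edges** — path metrics are defined on unweighted adjacency;
  edge weights and trail counting (repeated nodes, distinct edges) are out
  of scope.

The connectivity measure is the degree-weighted path count. For damping
exponent $w \ge 0$, a duplicate-free path contributes its path degree
product $\prod_{\text{edges}} (d_\text{tail} d_\text{head})^{-w}$, degrees
taken per metaedge; the DWPC between a source and target node is the sum of
PDPs over all such paths of one metapath. $w$ trades off specificity
(paths through hubs carry little specific signal) against sensitivity; the
package default is $w = 0.5$, i.e. square-root degree damping, and $w = 0$
recovers the path count exactly. A node with degree zero receives weight 0,
not an error: it lies on no path, so its contribution is vacuously zero.

## Exact path counting by matrix multiplication

The product of degree-weighted adjacency matrices counts *walks*. Walks
revisiting a node must be removed, and only nodes of the same metanode can
collide. The dispatcher (`dwpc()`) first finds the metanodes that occur
more than once in the metapath's type sequence, merges their occurrence
spans into *repeat groups*, and multiplies per-segment results together —
exact because distinct groups share no repeated metanode. Within a group:

* a single metanode repeated 2–3 times is solved by chaining the spans
  between consecutive occurrences and subtracting the product diagonal at
  each closure (`dwpc_short_repeat()`); nonrepeated metanodes inserted
  between occurrences ride along inside the chains and need no special
  treatment;
* when the group's outermost metanode occurs exactly twice — at the group
  boundaries — the interior is solved recursively as its own metapath, the
  boundary edges are multiplied on, and the diagonal is subtracted. This
  *repeat-around* rule covers nested (BAAB) patterns and hierarchies such
  as C(BABA)C in one stroke, and is exact because the outer metanode cannot
  occur inside the interior;
* two metanodes interleaved as X..Y..X..Y are solved by
  inclusion–exclusion (`dwpc_baba()`): subtract walks repeating X, subtract
  walks repeating Y, and add back the doubly-repeating walks, which are an
  elementwise product $D_1 \odot D_2^\top \odot D_3$;
* anything else — a metanode occurring four or more times, or three or
  more interleaved repeated metanodes (ABCABC and the like) — is solved by
  explicit duplicate-free path enumeration (`dwpc_general()`).

The routing is deliberately conservative: a pattern goes to a matrix
formula only when the formula is provably exact for it, and to enumeration
otherwise, so the dispatcher is exact for *every* metapath, at worst
slower. One consequence worth noting: four occurrences of one metanode in
nested arrangement (e.g. `DrDaGaDrD`) are *labelled* `nested` by
`categorize_metapath()`, but routed to enumeration — wrapping the inner
pair and outer pair separately would miss the cross-pair collisions
(first-with-third node, second-with-fourth), which we verified against the
enumeration oracle while selecting the routing table. The category labels
describe the repeat pattern; the routing table decides solvability.

`dwpc_approx()` (exact only on disjoint simple patterns, first repeat
corrected otherwise) and `dwpc_mayers()` (diagonal subtraction at every
occurrence of the first repeated metanode) are provided as labelled
alternatives for comparison; the dispatcher never uses them.

Segment results are cached in the store keyed by (segment abbreviation,
damping), and full matrices written under `path-counts/dwpc-<w>/` are
reused on disk-backed stores. Cache hits return the stored matrix, so
results are bit-identical regardless of cache state.

## Canonical orientation

A metapath and its reverse carry the same information
(`dwpc(reverse(mp)) = t(dwpc(mp))`), so global enumeration and
`precompute()` keep one representative per reversal class — the
orientation with the lexicographically smaller abbreviation — and queries
reverse stored results transparently. Directed metaedges are abbreviated
with `>`/`<` markers (`Gr>G` forward, `G<rG` reverse); undirected kinds use
bare lowercase letters. The marker convention makes tokenization of
abbreviations unambiguous where plain letters would collide; the parser
nevertheless tries all readings and reports an explicit ambiguity error
listing candidates should a metagraph create one.

## The null model

XSwap randomizes each metaedge independently: `round(10 × edges)` swap
attempts by default, each drawing two distinct edges and exchanging
endpoints, rejecting (without retry) proposals that create a self-edge or
duplicate. Degrees are preserved exactly — this is the property everything
downstream leans on. Undirected self-metaedge edges are swapped as
unordered pairs, which keeps the matrix symmetric and the degrees honest.
Each metaedge's sub-seed is a stable hash of (seed, metaedge abbreviation),
so permutations do not depend on iteration order.

Because permutation preserves degree, null DWPCs are pooled across all
node pairs with the same (source degree, target degree), where the degrees
are those of the metapath's first and last metaedge. Per degree group only
running totals are kept — $N$, $n$ nonzero, $\sum x$, $\sum x^2$, number of
permutations — which are additive across permutations (`merge_stats()` is a
commutative monoid), keep storage proportional to distinct degree pairs
rather than node pairs, and suffice for everything below.

**Gamma-hurdle fit.** Null DWPCs are frequently zero, and the nonzero part
is well approximated by a gamma. We fit
$\Gamma_H(\lambda, \alpha, \beta)$ by the method of moments:
$\hat\lambda = n/N$; with nonzero mean $m$ and Bessel-corrected variance
$v$, $\hat\alpha = m^2/v$ (shape) and $\hat\beta = m/v$ (rate), the
moment estimators consistent with the density
$x^{\alpha-1} e^{-\beta x}$. Parameter recovery on $10^5$ draws across a
$3^3$ grid ($\lambda \in \{0.2, 0.5, 0.9\}$, $\alpha \in \{0.5, 2, 8\}$,
$\beta \in \{0.5, 1, 4\}$) confirms the convention: $\lambda$ within
±0.01, $\alpha$ and $\beta$ within ±5%.

**P-values.** For an observed DWPC $t > 0$ the p-value is
$\lambda \cdot P(\Gamma(\alpha, \beta) \ge t)$, the gamma tail evaluated by
the regularized upper incomplete gamma function (`stats::pgamma`),
numerically stable for large shape. The $\lambda$ weight makes the two
mixture components sum to a coherent tail probability —
$P(X \ge t) \to \lambda$ as $t \to 0^+$, and simulated calibration (nulls
and observations from one gamma-hurdle) holds the 5% level to within ±0.01
at $10^4$ replicates; a `conditional = TRUE` option drops the weight for
users who want the tail conditional on a nonzero draw. The fit is declared
unavailable when $n < 2$ or the nonzero values have zero spread — the
minimal workable rule, since the Bessel correction needs $n \ge 2$ — and
the empirical rules take over: $t = 0 \Rightarrow p = 1$; all-zero nulls
with $t > 0 \Rightarrow p = 0$; zero-spread nonzero nulls with common value
$v$: $p = 0$ if $t > v$, else $n/N$.

**Multiple testing.** P-values are Bonferroni-multiplied by the number of
metapaths sharing the source metanode, target metanode and length, counted
in query orientation (the count is symmetric under reversal). The family
size is computed from powers of the metanode-level orientation-count
matrix. No false-discovery-rate procedure is offered: FDR needs all
p-values at once and a uniform null, neither of which holds here.

**Storage rule.** `precompute()` retains every nonzero DWPC for length-1
metapaths (direct edges are always of interest) and, for length ≥ 2, rows
with adjusted p below $5 (n_\text{source} n_\text{target})^{-0.3}$ —
penalizing metapaths with large DWPC matrices so plentiful metanodes do not
monopolize storage.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `w` | 0.5 | damping exponent (dimensionless); 0 = path counts |
| `multiplier` | 10 | XSwap attempts per edge |
| `n_permutations` | 25 (function default) | permuted hetnets per null; 200 is the scale used for a production knowledge-graph run |
| `dense_threshold` | 0.7 | matrix density at/above which files are written dense (TSV) rather than sparse (MatrixMarket) |
| `per_metapath_limit` | 100 | paths kept per metapath in `path_table()` |

Path-count matrices hold exact integers in doubles (exact to $2^{53}$,
far beyond any fixture here); DWPC matrices are 64-bit floats.

## The synthetic generator, and what passing tests show

`generate_hetnet()` draws each metaedge's edges by sampling
`round(density × admissible cells)` cells without replacement (so realized
density matches the request up to rounding, reproducibly per seed), with
self-edges excluded and undirected self-metaedges symmetrized.
`demo_fixture_spec()` — five metanodes, seven metaedges including
undirected self, directed self and bipartite kinds — is chosen so that
metapaths up to length 4 exercise every repeat category, including the
enumeration fallbacks. `toy_fixtures()` are two hand-built stores whose
DWPC values are single-path arithmetic one can verify by hand (0.5 for
`GiGiG` on the 3-gene chain; 0.25 for `CtDtCtD` on the 2×2 compound–disease
net).

The generator emulates typed sparsity and mild degree heterogeneity; it
does **not** emulate heavy-tailed degree distributions, correlated edge
placement, or knowledge-graph scale. Passing tests therefore demonstrate
algorithmic correctness — exactness of the matrix corrections against
enumeration, degree preservation, estimator consistency, calibration under
the model — not that the gamma-hurdle is a good fit to any particular real
network's nulls, which must be judged per application (the running totals
retained per group are exactly what such a diagnostic needs).

## Numerical choices

* Matrix corrections agree with enumeration to machine precision; tests
  compare with relative tolerance $10^{-8}$ floored at magnitude 1, since
  exact-zero entries carry cancellation residue near $10^{-16}$.
* Nonzero-part variances computed from running totals can come out
  infinitesimally negative for zero-spread groups; they are clipped at 0
  before taking square roots, and the fit falls back to the empirical rules
  in exactly those cases.
* Table orderings are deterministic: metapath tables sort by adjusted p
  with lexicographic abbreviation tie-break; path tables by descending path
  score, then abbreviation, then path string.
* Degenerate inputs: zero-degree nodes weight to 0; empty edge sets
  permute to empty; a degree group absent from the null statistics (only
  possible when results and store mismatch, since permutation preserves
  degrees) reports `NA` rather than extrapolating.

## Problem sizes used by the tests

The suite runs on stores of 8–30 nodes per metanode at densities 0.1–0.3,
10–50 permutations, and oracle sweeps over all metapaths of length ≤ 4 on
ten seeded fixtures; the calibration and recovery simulations use $10^4$
replicates and $10^5$ draws. These sizes keep the full suite in the
low minutes on one core while covering every code path, and are stated here
as the package's chosen operating points for its own verification.

## Limitations

* Permuted stores are generated in memory during `precompute()`; for
  networks beyond fixture scale, generate permutations to disk (the CLI
  `permute` subcommand writes `permutations/NNN.hetmat/`) and accumulate
  statistics per permutation with `merge_stats()`.
* The DWPC transformation sometimes applied before downstream modelling
  (compacting the DWPC distribution) is exposed only as a post-processing
  hook by the caller; p-values here are always computed on raw DWPCs.
* No trail counting, no weighted edges, no FDR adjustment.
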