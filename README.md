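# hetpaths

Connectivity search in heterogeneous networks: degree-weighted path counts
with permutation-based significance.

## The problem

Hetnets (heterogeneous information networks) type their nodes (*metanodes*:
genes, compounds, diseases, ...) and edges (*metaedges*: binds, treats,
interacts, ...). A *metapath* is a type-level path such as `CbGpPWpG`
(Compound–binds–Gene–participates–Pathway–participates–Gene), and counting
the paths of a metapath between two nodes measures one mode of their
connectivity. Raw path counts are dominated by node degree: hub nodes
accumulate paths regardless of any specific relationship. `hetpaths` is for
researchers who want to ask, for any two nodes of a knowledge graph,
"along which metapaths are these two nodes *more* connected than expected
from degree alone, and through which specific paths?" — without training
labels.

## The method

**DWPC.** For a metapath and damping exponent *w*, each duplicate-free path
contributes its *path degree product*: the product over its edges of
(d_tail · d_head)^(−w), where degrees are specific to each edge's metaedge.
The degree-weighted path count is the sum of PDPs over all paths between a
source and target node; at *w* = 0 it is the plain path count. The default
*w* = 0.5 halves the degree exponents (square-root damping).

DWPC matrices for all node pairs at once are computed by chained
multiplication of degree-weighted adjacency matrices, with exact corrections
that remove walks revisiting a node. Writing D(·) for a DWPC matrix and
diag(·) for the matrix of a product's diagonal:

* short repeats — D(XaXbX) = D(XaX) D(XbX) − diag(D(XaX) D(XbX))
* nested repeats — D(XaYbYcX) = D(XaY) D(YbY) D(YcX) − diag(·)
* overlapping repeats — D(XaYbXcY) = D1 D2 D3 − diag(D1 D2) D3 −
  D1 diag(D2 D3) + D1 ⊙ D2ᵀ ⊙ D3

Metapaths are segmented by their repeat pattern and solved recursively from
these building blocks; long (≥ 4) repeats and other complex patterns fall
back to explicit path enumeration (`dwpc_general()`), which also serves as
the correctness oracle in the test suite.

**Null model.** Each metaedge of the network is independently randomized by
XSwap (degree-preserving edge swaps, 10 attempts per edge). DWPCs computed
on the permuted networks are pooled across all node pairs sharing the same
(source degree, target degree) — permutation preserves degree, so such
pairs are exchangeable — and only running totals are kept per degree group:
N, n (nonzero), Σx, Σx², and the number of permutations. A *gamma-hurdle*
distribution Γ_H(λ, α, β) — probability 1 − λ at zero, a gamma with shape α
and rate β above zero — is fit to each group by the method of moments
(λ̂ = n/N, α̂ = m²/v, β̂ = m/v with Bessel-corrected v), and the p-value of
an observed DWPC *t* > 0 is λ · P(Γ(α, β) ≥ t), with empirical fallbacks
for degenerate groups. P-values are Bonferroni-adjusted by the number of
metapaths sharing the source metanode, target metanode and length.

## Worked example

```r
library(hetpaths)

store <- generate_hetnet(demo_fixture_spec(n_nodes = 30, density = 0.1, seed = 0))
results <- precompute(store, max_length = 2, w = 0.5, n_permutations = 50, seed = 0)

metapath_table(results, store, "c0", "d1")
#>   metapath path_count   dwpc p_value p_adjusted n_dwpcs n_nonzero_dwpcs precomputed
#> 1      CtD          1 0.2041   0.132      0.132     400             106        TRUE
#> 2    CbGaD          1 0.0456   0.573      0.573     750             559        TRUE

path_table(results, store, "c0", "d1")
#>   metapath      path percent_of_dwpc path_score
#> 1      CtD     c0-d1             100      0.878
#> 2    CbGaD c0-g19-d1             100      0.242
```

Reading the first row: compound `c0` and disease `d1` are joined by one
direct *treats* edge (path count 1, DWPC 0.204 after degree weighting).
Across 50 permuted networks, the 400 null DWPCs pooled for this degree
group were nonzero 106 times, and the fitted gamma-hurdle puts probability
0.132 on a null DWPC this large — suggestive but not significant
connectivity; no other same-length metapath competes, so the adjusted
p-value is unchanged. The path table ranks the individual paths behind all
metapaths by path score, percent-of-DWPC × (−log₁₀ p).

A thin CLI wrapping these functions ships at `inst/cli/hetpath.R`
(subcommands `fixtures`, `convert`, `permute`, `dwpc`, `precompute`,
`search`).

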