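Package: hetpaths
Title: Connectivity Search in Heterogeneous Networks via Degree-Weighted Path Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether two nodes of a typed heterogeneous
    network (hetnet) are more connected than expected from node degree alone.
    Computes path counts and degree-weighted path counts (DWPCs) for arbitrary
    metapaths by adjacency-matrix multiplication with exact corrections that
    exclude walks revisiting a node, generates degree-preserving permuted
    networks with the XSwap algorithm, pools permuted-network DWPCs into
    degree-grouped summary statistics, fits a gamma-hurdle null distribution by
    the method of moments, and reports per-metapath and per-path significance
    tables. Hetnets are stored in an on-disk matrix directory format with lazy
    loading, and deterministic generators for synthetic hetnets are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
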