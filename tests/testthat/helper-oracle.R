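# Independent brute-force DWPC oracle: iterative breadth-first expansion of
# all walks as a table of node-index sequences, then filtering walks that
# revisit a node (same metanode, same index) and summing path degree
# products. Deliberately a different mechanism from the package's recursive
# enumeration.
oracle_dwpc <- function(store, mp, w = 0.5) {
  steps <- mp$steps
  L <- nrow(steps)
  types <- c(steps$from[1], steps$to)
  A <- lapply(seq_len(L), function(k) {
    metaedge_adjacency(store, steps$key[k], steps$reversed[k])
  })
  res <- matrix(0, nrow(A[[1]]), ncol(A[[L]]),
                dimnames = list(rownames(A[[1]]), colnames(A[[L]])))
  walks <- matrix(seq_len(nrow(A[[1]])), ncol = 1)
  pdp <- rep(1, nrow(walks))
  for (k in seq_len(L)) {
    Ak <- A[[k]]
    deg_s <- rowSums(Ak)
    deg_t <- colSums(Ak)
    el <- which(Ak > 0, arr.ind = TRUE)
    if (nrow(el) == 0) return(res)
    hits <- lapply(walks[, k], function(node) which(el[, 1] == node))
    reps <- lengths(hits)
    edge_rows <- unlist(hits)
    walks <- cbind(walks[rep(seq_len(nrow(walks)), reps), , drop = FALSE],
                   el[edge_rows, 2])
    pdp <- pdp[rep(seq_along(reps), reps)] *
      (deg_s[el[edge_rows, 1]] * deg_t[el[edge_rows, 2]])^(-w)
    if (nrow(walks) == 0) return(res)
  }
  ok <- apply(walks, 1, function(r) !anyDuplicated(paste(types, r)))
  if (!any(ok)) return(res)
  lin <- walks[ok, 1] + (walks[ok, L + 1] - 1) * nrow(res)
  agg <- rowsum(pdp[ok], group = lin)
  res[as.integer(rownames(agg))] <- agg
  res
}

# independent metapath-class counter: explicit cartesian expansion of
# oriented metaedge sequences, chain-compatibility filter, then
# reversal-class deduplication on abbreviation strings built by paste()
oracle_count_metapaths <- function(mg, len) {
  ors <- hetpaths:::mg_orientations(mg)
  n <- nrow(ors)
  grids <- do.call(expand.grid, rep(list(seq_len(n)), len))
  ok <- rep(TRUE, nrow(grids))
  if (len > 1) {
    for (k in seq_len(len - 1)) {
      ok <- ok & ors$to[grids[, k]] == ors$from[grids[, k + 1]]
    }
  }
  grids <- grids[ok, , drop = FALSE]
  fwd <- ors$from[grids[, 1]]
  rev_ab <- ors$to[grids[, len]]
  for (k in seq_len(len)) {
    fwd <- paste0(fwd, ors$token[grids[, k]], ors$to[grids[, k]])
    kk <- len - k + 1
    rev_ab <- paste0(rev_ab, ors$rev_token[grids[, kk]], ors$from[grids[, kk]])
  }
  length(unique(pmin(fwd, rev_ab)))
}

# two-metanode metagraph rich in repeat patterns (BAAB, BABA, short repeats)
cd_rich_metagraph <- function() {
  metagraph(
    metanodes = data.frame(identifier = c("Compound", "Disease"),
                           abbreviation = c("C", "D")),
    metaedges = data.frame(
      source = c("Compound", "Compound", "Disease", "Compound"),
      target = c("Disease", "Disease", "Disease", "Compound"),
      kind = c("treats", "palliates", "resembles", "resembles"),
      abbreviation = c("t", "p", "r", "r"),
      directed = FALSE
    )
  )
}
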