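# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable sub-seed from a base seed and a metaedge abbreviation, so the
# permutation of one metaedge does not depend on iteration order
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (cd in codes) h <- (h * 131 + cd) %% 1048573
  as.integer((as.numeric(seed) * 1048583 + h) %% 2147483629)
}

#' Degree-preserving edge permutation (XSwap)
#'
#' Randomizes an edge list while preserving every node's degree exactly.
#' Each attempt draws two distinct edges (a,b) and (c,d) and proposes the
#' swap (a,d), (c,b); for undirected edges the endpoint roles of the second
#' edge are flipped uniformly at random first. Proposals creating a
#' self-edge or a duplicate edge are rejected (and not retried). The number
#' of attempts is `round(multiplier * number of edges)`.
#'
#' @param edges two-column matrix or data.frame of edges. For undirected
#'   edges within one node set, each unordered pair appears once.
#' @param directed treat endpoint roles as fixed (directed edges); `FALSE`
#'   allows the uniform endpoint-role flip for undirected edges within one
#'   node set.
#' @param bipartite the two columns index different node sets (different
#'   metanodes), so a self-edge is impossible and endpoint roles are always
#'   fixed.
#' @param multiplier attempts per edge (default 10).
#' @param seed integer seed; output is reproducible per seed.
#' @return List with `edges` (permuted, same class and degree sequence) and
#'   `report` (attempts, completed swaps, fraction of original edges no
#'   longer present, seed).
#' @export
xswap <- function(edges, directed = FALSE, bipartite = FALSE, multiplier = 10,
                  seed = 0) {
  if (multiplier <= 0) stop("validation error: multiplier must be positive")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("validation error: edges must have two columns")
  src <- edges[, 1]
  tgt <- edges[, 2]
  same_ns <- !bipartite
  if (bipartite) directed <- TRUE   # roles are typed, never interchangeable
  key <- function(a, b) {
    if (directed) paste0(a, "\r", b)
    else paste0(pmin(a, b), "\r", pmax(a, b))
  }
  if (same_ns && any(src == tgt)) stop("validation error: self-edge in input")
  keys0 <- key(src, tgt)
  if (anyDuplicated(keys0)) stop("validation error: duplicate edge in input")

  m <- length(src)
  attempts <- as.integer(round(multiplier * m))
  completed <- 0L
  if (m >= 2 && attempts > 0) {
    present <- new.env(parent = emptyenv(), size = 2L * m)
    for (k in keys0) assign(k, TRUE, envir = present)
    with_seed(seed, {
      ii <- sample.int(m, attempts, replace = TRUE)
      jj <- sample.int(m - 1L, attempts, replace = TRUE)
      jj <- ifelse(jj >= ii, jj + 1L, jj)   # two distinct edges
      flips <- stats::runif(attempts) < 0.5
    })
    for (s in seq_len(attempts)) {
      i <- ii[s]; j <- jj[s]
      a <- src[i]; b <- tgt[i]
      cc <- src[j]; dd <- tgt[j]
      if (!directed && flips[s]) { tmp <- cc; cc <- dd; dd <- tmp }
      if (same_ns && (a == dd || cc == b)) next    # self-edge
      k1 <- key(a, dd); k2 <- key(cc, b)
      if (k1 == k2) next
      if (exists(k1, envir = present, inherits = FALSE)) next
      if (exists(k2, envir = present, inherits = FALSE)) next
      rm(list = c(key(a, b), key(src[j], tgt[j])), envir = present)
      assign(k1, TRUE, envir = present)
      assign(k2, TRUE, envir = present)
      src[i] <- a; tgt[i] <- dd
      src[j] <- cc; tgt[j] <- b
      completed <- completed + 1L
    }
  }
  out <- edges
  out[, 1] <- src
  out[, 2] <- tgt
  changed <- if (m == 0) 0 else 1 - length(intersect(keys0, key(src, tgt))) / m
  list(
    edges = out,
    report = list(attempts = attempts, completed_swaps = completed,
                  fraction_edges_changed = changed, seed = seed)
  )
}

#' Permute a hetnet with XSwap
#'
#' Applies [xswap()] independently to each metaedge's edge set, with a
#' sub-seed derived deterministically from `seed` and the metaedge
#' abbreviation (so results do not depend on metaedge order). Node tables
#' and the metagraph are unchanged; every per-metaedge degree vector is
#' preserved exactly. Undirected self-metaedges are swapped as unordered
#' pairs and remain symmetric.
#'
#' @param store a [hetnet] store.
#' @param multiplier swap attempts per edge (default 10).
#' @param seed integer seed.
#' @return A new in-memory [hetnet] store; per-metaedge
#'   [xswap()] reports are attached as attribute `"reports"`.
#' @export
permute_hetnet <- function(store, multiplier = 10, seed = 0) {
  mg <- store$metagraph
  edges <- list()
  reports <- list()
  for (i in seq_len(nrow(mg$metaedges))) {
    e <- mg$metaedges[i, ]
    m <- metaedge_adjacency(store, e$key)
    self_undirected <- !e$directed && e$source_abbrev == e$target_abbrev
    idx <- which(if (self_undirected) upper.tri(m) & m > 0 else m > 0,
                 arr.ind = TRUE)
    bipartite <- e$source_abbrev != e$target_abbrev
    perm <- xswap(idx, directed = e$directed, bipartite = bipartite,
                  multiplier = multiplier, seed = derive_seed(seed, e$key))
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    out[perm$edges] <- 1
    if (self_undirected) out <- pmax(out, t(out))
    edges[[e$key]] <- out
    reports[[e$key]] <- perm$report
  }
  permuted <- hetnet(mg, store$nodes, edges)
  attr(permuted, "reports") <- reports
  permuted
}
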