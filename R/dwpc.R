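#' Degree-weight an adjacency matrix
#'
#' Entry (i, j) of the result is `adjacency(i,j) * d_i^(-w) * d_j^(-w)`,
#' where the degrees are those of the matrix's own metaedge. This is the
#' building block of the degree-weighted path count: paths through
#' high-degree nodes are downweighted. Nodes of degree zero lie on no path;
#' their rows/columns are zero rather than an error.
#'
#' @param adjacency 0/1 (bi)adjacency matrix.
#' @param source_degrees,target_degrees nonnegative degree vectors for the
#'   rows and columns; defaults are the row and column sums of `adjacency`.
#' @param w damping exponent, >= 0. At `w = 0` the adjacency is returned
#'   unchanged.
#' @return Weighted matrix of the same shape.
#' @export
degree_weight <- function(adjacency, source_degrees = rowSums(adjacency),
                          target_degrees = colSums(adjacency), w = 0.5) {
  if (w < 0) stop("parameter error: damping exponent w must be nonnegative")
  stopifnot(length(source_degrees) == nrow(adjacency),
            length(target_degrees) == ncol(adjacency))
  ds <- ifelse(source_degrees > 0, source_degrees^(-w), 0)
  dt <- ifelse(target_degrees > 0, target_degrees^(-w), 0)
  adjacency * outer(ds, dt)
}

# oriented adjacency matrices for each step of a metapath
mp_step_adjacency <- function(store, mp) {
  lapply(seq_len(nrow(mp$steps)), function(k) {
    metaedge_adjacency(store, mp$steps$key[k], mp$steps$reversed[k])
  })
}

mp_step_weighted <- function(store, mp, w) {
  lapply(mp_step_adjacency(store, mp), degree_weight, w = w)
}

zero_diag <- function(m) {
  diag(m) <- 0
  m
}

#' Short-repeat DWPC correction
#'
#' For a metanode repeated at both ends of one or two walk segments
#' (patterns `XaX`, `XaXbX`), the walks revisiting the endpoint node are
#' exactly the diagonal of the product, which is subtracted:
#' `D(XaXbX) = D(XaX) D(XbX) - diag(D(XaX) D(XbX))`.
#'
#' @param d1,d2 square degree-weighted matrices over the same metanode
#'   ordering; `d2` may be omitted for a single segment.
#' @return Matrix with zero diagonal.
#' @export
dwpc_short_repeat <- function(d1, d2 = NULL) {
  if (nrow(d1) != ncol(d1)) stop("shape error: short-repeat input must be square")
  m <- if (is.null(d2)) d1 else d1 %*% d2
  if (nrow(m) != ncol(m)) stop("shape error: short-repeat product must be square")
  zero_diag(m)
}

#' Nested-repeat (BAAB) DWPC correction
#'
#' For `XaYbYcX` the inner `Y` repeat is resolved first (as a short repeat),
#' then the outer `X` repeat is corrected by subtracting the diagonal:
#' `D(XaYbYcX) = D(XaY) D(YbY) D(YcX) - diag(...)`.
#'
#' @param left,inner,right conformable matrices for the X-to-Y, corrected
#'   Y-to-Y, and Y-to-X pieces.
#' @return Matrix with zero diagonal.
#' @export
dwpc_nested <- function(left, inner, right) {
  m <- left %*% inner %*% right
  if (nrow(m) != ncol(m)) stop("shape error: nested-repeat product must be square")
  zero_diag(m)
}

#' Overlapping-repeat (BABA) DWPC correction
#'
#' For `XaYbXcY` three corrections remove walks repeating either X or Y
#' (inclusion-exclusion; the final Hadamard term restores walks repeating
#' both, which were subtracted twice):
#' `D = D1 D2 D3 - diag(D1 D2) D3 - D1 diag(D2 D3) + D1 * t(D2) * D3`.
#'
#' @param d1,d2,d3 conformable matrices for the X-to-Y, Y-to-X and X-to-Y
#'   chain pieces.
#' @return Corrected matrix.
#' @export
dwpc_baba <- function(d1, d2, d3) {
  if (ncol(d1) != nrow(d2) || ncol(d2) != nrow(d3)) {
    stop("shape error: overlapping-repeat chain does not conform")
  }
  d12 <- d1 %*% d2
  d23 <- d2 %*% d3
  d12 %*% d3 -
    diag(diag(d12), nrow = nrow(d12)) %*% d3 -
    d1 %*% diag(diag(d23), nrow = nrow(d23)) +
    d1 * t(d2) * d3
}

# metapath repeat-pattern analysis -------------------------------------------

# merged occurrence spans of repeated metanodes; returns list of c(a, b)
# slot intervals (1-based over the type sequence)
repeat_groups <- function(types) {
  counts <- table(types)
  repeated <- names(counts)[counts > 1]
  if (length(repeated) == 0) return(list())
  spans <- t(vapply(repeated, function(tp) range(which(types == tp)),
                    numeric(2)))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  merged <- list(spans[1, ])
  for (i in seq_len(nrow(spans))[-1]) {
    last <- merged[[length(merged)]]
    if (spans[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], spans[i, 2]))
    } else {
      merged[[length(merged) + 1]] <- spans[i, ]
    }
  }
  merged
}

# classify the repeat pattern of one group (slots a..b of `types`)
classify_group <- function(types, a, b) {
  sub <- types[a:b]
  counts <- table(sub)
  reps <- names(counts)[counts > 1]
  if (length(reps) == 1) {
    pos <- which(sub == reps)
    k <- length(pos)
    contiguous <- all(diff(pos) == 1)
    if (k <= 3) return(if (contiguous) "short_repeat" else "interleaved_nonrepeat")
    if (k == 4 && !contiguous) return("nested")
    return("long_repeat")
  }
  if (length(reps) == 2 && all(counts[reps] == 2)) {
    p1 <- which(sub == reps[1])
    p2 <- which(sub == reps[2])
    if (p1[1] > p2[1]) { tmp <- p1; p1 <- p2; p2 <- tmp }
    if (p2[2] < p1[2]) return("nested")        # X Y Y X
    return("overlapping")                      # X Y X Y
  }
  # hierarchical patterns such as C(BABA)C still expose an outermost pair
  if (sub[1] == sub[length(sub)] && counts[sub[1]] == 2) return("nested")
  "other_complex"
}

#' Segment a metapath by its repeat pattern
#'
#' Slot spans of repeated metanodes are merged into repeat groups; edges
#' outside any group form plain chain segments. Concatenating the segments
#' reproduces the metapath. Each repeat-group segment carries the category
#' its DWPC routine is chosen by.
#'
#' @param mp a metapath.
#' @return List of segments, each a list with `edges` (step indices),
#'   `slots`, `category` and `abbrev`.
#' @export
segment_metapath <- function(mp) {
  types <- metapath_types(mp)
  L <- length(mp)
  groups <- repeat_groups(types)
  in_group <- rep(FALSE, L)
  segs <- list()
  for (g in groups) {
    edges <- seq(g[1], g[2] - 1)
    in_group[edges] <- TRUE
    segs[[length(segs) + 1]] <- list(
      edges = edges, slots = g[1]:g[2],
      category = classify_group(types, g[1], g[2])
    )
  }
  free <- which(!in_group)
  if (length(free) > 0) {
    runs <- split(free, cumsum(c(1, diff(free) != 1)))
    for (r in runs) {
      segs[[length(segs) + 1]] <- list(
        edges = as.integer(r), slots = r[1]:(r[length(r)] + 1),
        category = "no_repeats"
      )
    }
  }
  segs <- segs[order(vapply(segs, function(s) s$edges[1], numeric(1)))]
  for (i in seq_along(segs)) {
    segs[[i]]$abbrev <- metapath_abbrev(sub_metapath(mp, segs[[i]]$edges))
  }
  segs
}

sub_metapath <- function(mp, edges) {
  new_metapath(`rownames<-`(mp$steps[edges, , drop = FALSE], NULL))
}

#' Categorize a metapath by its repeated metanodes
#'
#' Deterministic labels: `no_repeats` (no metanode occurs twice),
#' `disjoint` (several non-overlapping repeat groups, e.g. `DrDtCrC`),
#' `short_repeat` (one metanode repeated up to 3 times in a row, e.g.
#' `GiGiG`), `interleaved_nonrepeat` (a short repeat with nonrepeated
#' metanodes inserted between occurrences), `nested` (BAAB-style, e.g.
#' `CtDrDtC`, or nested occurrence pairs as in `DrDaGaDrD`), `overlapping`
#' (BABA-style, e.g. `DtCtDpC`), `long_repeat` (a metanode repeated 4+
#' times in a row), and `other_complex` (e.g. ABCABC).
#'
#' @param mp a metapath.
#' @return List of class `metapath_category` with `label` and `segments`
#'   (the [segment_metapath()] decomposition).
#' @export
categorize_metapath <- function(mp) {
  segs <- segment_metapath(mp)
  cats <- vapply(segs, function(s) s$category, character(1))
  repeat_segs <- cats[cats != "no_repeats"]
  label <- if (length(repeat_segs) == 0) {
    "no_repeats"
  } else if (length(repeat_segs) >= 2) {
    "disjoint"
  } else {
    repeat_segs
  }
  structure(list(label = label, segments = segs), class = "metapath_category")
}

#' @export
print.metapath_category <- function(x, ...) {
  parts <- vapply(x$segments, function(s) s$abbrev, character(1))
  cat(sprintf("%s: [%s]\n", x$label, paste(parts, collapse = "][")))
  invisible(x)
}

# dispatcher -----------------------------------------------------------------

chain_product <- function(W, edges) {
  Reduce(`%*%`, W[edges])
}

# exact DWPC over slots a..b of the metapath, applying segmentation
solve_range <- function(store, mp, W, a, b, w) {
  types <- metapath_types(mp)
  sub_types <- types[a:b]
  counts <- table(sub_types)
  if (all(counts == 1)) return(chain_product(W, seq(a, b - 1)))
  groups <- repeat_groups(sub_types)
  pieces <- list()
  cursor <- a
  for (g in groups) {
    ga <- a + g[1] - 1
    gb <- a + g[2] - 1
    if (ga > cursor) pieces[[length(pieces) + 1]] <- chain_product(W, seq(cursor, ga - 1))
    pieces[[length(pieces) + 1]] <- solve_group(store, mp, W, ga, gb, w)
    cursor <- gb
  }
  if (cursor < b) pieces[[length(pieces) + 1]] <- chain_product(W, seq(cursor, b - 1))
  Reduce(`%*%`, pieces)
}

# exact DWPC for one repeat group (slots a..b; types[a..b] contains all
# occurrences of every metanode repeated within it)
solve_group <- function(store, mp, W, a, b, w) {
  types <- metapath_types(mp)
  sub <- types[a:b]
  counts <- table(sub)
  reps <- names(counts)[counts > 1]

  if (length(reps) == 1 && counts[reps] <= 3) {
    pos <- a - 1 + which(sub == reps)
    if (length(pos) == 2) {
      return(solve_group_pair(store, mp, W, pos[1], pos[2], w))
    }
    left <- solve_group_pair(store, mp, W, pos[1], pos[2], w)
    right <- solve_group_pair(store, mp, W, pos[2], pos[3], w)
    return(dwpc_short_repeat(left, right))
  }

  # repeat-around: the outermost metanode occurs exactly twice, at the group
  # boundaries; solve the interior exactly, wrap, and subtract the diagonal
  if (sub[1] == sub[length(sub)] && counts[sub[1]] == 2) {
    return(solve_group_pair(store, mp, W, a, b, w))
  }

  # overlapping X..Y..X..Y with nonrepeated inserts inside the chains
  if (length(reps) == 2 && all(counts[reps] == 2)) {
    px <- a - 1 + which(sub == sub[1])
    py <- a - 1 + which(sub == types[b])
    if (px[1] < py[1] && py[1] < px[2] && px[2] < py[2]) {
      d1 <- chain_product(W, seq(px[1], py[1] - 1))
      d2 <- chain_product(W, seq(py[1], px[2] - 1))
      d3 <- chain_product(W, seq(px[2], py[2] - 1))
      return(dwpc_baba(d1, d2, d3))
    }
  }

  dwpc_enumerate_range(store, mp, W, a, b)
}

# X..X span whose endpoint metanode occurs only at the span boundaries:
# wrap the exactly-solved interior and remove the diagonal
solve_group_pair <- function(store, mp, W, p1, p2, w) {
  if (p2 == p1 + 1) return(zero_diag(W[[p1]]))
  if (p2 == p1 + 2) return(zero_diag(W[[p1]] %*% W[[p1 + 1]]))
  inner <- solve_range(store, mp, W, p1 + 1, p2 - 1, w)
  zero_diag(W[[p1]] %*% inner %*% W[[p2 - 1]])
}

# enumeration over a slot range: exact for any pattern (used as the
# fallback for long repeats and complex patterns)
dwpc_enumerate_range <- function(store, mp, W, a, b) {
  sub <- sub_metapath(mp, seq(a, b - 1))
  walk_paths_matrix(store, sub, W[seq(a, b - 1)])
}

#' General (enumeration-based) DWPC
#'
#' Computes the exact DWPC for any metapath by enumerating duplicate-free
#' paths and summing path degree products (PDPs). The PDP of a path is the
#' product over its edges of `(deg_tail * deg_head)^(-w)`, with degrees
#' specific to each edge's metaedge. Slower than the matrix routines, but
#' valid for every repeat pattern; it serves as the correctness oracle for
#' the specialized routines in [dwpc()].
#'
#' @param store a [hetnet] store.
#' @param mp a metapath.
#' @param w damping exponent (default 0.5; `w = 0` yields path counts).
#' @return A `dwpc_matrix` object.
#' @export
dwpc_general <- function(store, mp, w = 0.5) {
  W <- mp_step_weighted(store, mp, w)
  values <- walk_paths_matrix(store, mp, W)
  new_dwpc_matrix(mp, w, values, algorithm = "general")
}

# DFS enumeration of duplicate-free paths, accumulating PDPs into a matrix
walk_paths_matrix <- function(store, mp, W) {
  A <- mp_step_adjacency(store, mp)
  L <- length(mp)
  types <- metapath_types(mp)
  nbrs <- lapply(seq_len(L), function(k) {
    lapply(seq_len(nrow(A[[k]])), function(i) which(A[[k]][i, ] > 0))
  })
  # earlier slots holding the same metanode (only these can collide)
  prev_same <- lapply(seq_len(L + 1), function(j) {
    which(types[seq_len(j - 1)] == types[j])
  })
  n_src <- nrow(A[[1]])
  n_tgt <- ncol(A[[L]])
  res <- matrix(0, n_src, n_tgt,
                dimnames = list(rownames(A[[1]]), colnames(A[[L]])))
  visited <- integer(L + 1)
  src <- 0L
  descend <- function(slot, node, pdp) {
    if (slot == L + 1L) {
      res[src, node] <<- res[src, node] + pdp
      return(invisible())
    }
    for (nxt in nbrs[[slot]][[node]]) {
      ps <- prev_same[[slot + 1L]]
      if (length(ps) > 0 && any(visited[ps] == nxt)) next
      visited[slot + 1L] <<- nxt
      descend(slot + 1L, nxt, pdp * W[[slot]][node, nxt])
    }
    invisible()
  }
  for (i in seq_len(n_src)) {
    src <- i
    visited[1L] <- i
    descend(1L, i, 1)
  }
  res
}

# dwpc_matrix container -------------------------------------------------------

new_dwpc_matrix <- function(mp, w, values, algorithm,
                            kind = if (w == 0) "path_count" else "dwpc") {
  if (kind == "path_count") values <- round(values)
  structure(
    list(metapath = mp, w = w, values = values, kind = kind,
         algorithm = algorithm),
    class = "dwpc_matrix"
  )
}

#' @export
print.dwpc_matrix <- function(x, ...) {
  cat(sprintf("%s matrix for %s (w = %g, %dx%d, algorithm: %s)\n",
              x$kind, metapath_abbrev(x$metapath), x$w,
              nrow(x$values), ncol(x$values), x$algorithm))
  invisible(x)
}

#' Degree-weighted path counts by matrix multiplication
#'
#' The dispatcher: the metapath is categorized and segmented by its repeat
#' pattern ([categorize_metapath()]); chain segments are plain matrix
#' products, repeat groups are routed to the specialized exact corrections
#' ([dwpc_short_repeat()], [dwpc_nested()], [dwpc_baba()], and a recursive
#' repeat-around rule for hierarchies like C(BABA)C), and long (4+) repeats
#' or other complex patterns fall back to path enumeration. The result is
#' exact — identical to [dwpc_general()] — and deterministic regardless of
#' cache state.
#'
#' Results are cached in memory keyed by (metapath abbreviation, w). For
#' directory-backed stores, matrices previously written under
#' `path-counts/dwpc-<w>/` (e.g. by [precompute()]) are reused.
#'
#' @inheritParams dwpc_general
#' @param w damping exponent; `w = 0` gives the duplicate-free path count.
#' @param dense_threshold density at or above which cached matrices are
#'   written dense.
#' @param cache use (and populate) the in-memory and on-disk caches.
#' @return A `dwpc_matrix` with fields `metapath`, `w`, `values`, `kind`
#'   (`path_count` when `w = 0`, else `dwpc`) and `algorithm`.
#' @examples
#' store <- toy_fixtures()$toy_gig
#' mp <- parse_metapath("GiGiG", store$metagraph)
#' dwpc(store, mp, w = 0.5)$values["g0", "g2"]  # 0.5
#' @export
dwpc <- function(store, mp, w = 0.5, dense_threshold = 0.7, cache = TRUE) {
  ab <- metapath_abbrev(mp)
  cache_key <- paste0(ab, "|w=", w)
  if (cache) {
    if (exists(cache_key, envir = store$cache, inherits = FALSE)) {
      return(get(cache_key, envir = store$cache))
    }
    if (!is.null(store$dir)) {
      stem <- file.path(store$dir, "path-counts", paste0("dwpc-", w), ab)
      values <- read_matrix_file(stem)
      if (!is.null(values)) {
        dimnames(values) <- list(store$nodes[[mp$steps$from[1]]],
                                 store$nodes[[mp$steps$to[nrow(mp$steps)]]])
        out <- new_dwpc_matrix(mp, w, values, algorithm = "cached")
        assign(cache_key, out, envir = store$cache)
        return(out)
      }
    }
  }
  W <- mp_step_weighted(store, mp, w)
  values <- solve_range(store, mp, W, 1, length(mp) + 1, w)
  out <- new_dwpc_matrix(mp, w, values,
                         algorithm = categorize_metapath(mp)$label)
  if (cache) assign(cache_key, out, envir = store$cache)
  out
}

#' Path counts for a metapath
#'
#' Duplicate-free path counts: [dwpc()] at damping `w = 0`.
#'
#' @inheritParams dwpc
#' @return A `dwpc_matrix` of kind `path_count` (integer-valued).
#' @export
path_count <- function(store, mp, cache = TRUE) {
  dwpc(store, mp, w = 0, cache = cache)
}

#' Approximate DWPC
#'
#' Corrects repeats exactly in disjoint simple patterns, but within a
#' complex repeat group only the first repeated metanode's first repeat is
#' corrected (by diagonal subtraction); remaining steps are multiplied
#' through uncorrected. Equals the exact DWPC whenever the metapath
#' contains only disjoint simple repeat patterns.
#'
#' @inheritParams dwpc_general
#' @return A `dwpc_matrix` of kind `dwpc_approx`.
#' @export
dwpc_approx <- function(store, mp, w = 0.5) {
  types <- metapath_types(mp)
  W <- mp_step_weighted(store, mp, w)
  L <- length(mp)
  counts <- table(types)
  exact_cats <- c("no_repeats", "short_repeat", "interleaved_nonrepeat",
                  "nested", "overlapping")
  segs <- segment_metapath(mp)
  pieces <- lapply(segs, function(s) {
    a <- s$slots[1]; b <- s$slots[length(s$slots)]
    simple <- s$category %in% exact_cats &&
      !(s$category == "nested" &&
          length(unique(types[s$slots][duplicated(types[s$slots])])) == 1)
    if (simple) {
      solve_group_or_chain(store, mp, W, a, b, w, s$category)
    } else {
      # first-repeat-only correction
      t0 <- types[a]
      p2 <- a - 1 + which(types[a:b] == t0)[2]
      m1 <- chain_product(W, seq(a, p2 - 1))
      if (nrow(m1) == ncol(m1)) m1 <- zero_diag(m1)
      if (p2 < b) m1 %*% chain_product(W, seq(p2, b - 1)) else m1
    }
  })
  values <- Reduce(`%*%`, pieces)
  new_dwpc_matrix(mp, w, values, algorithm = "approx", kind = "dwpc_approx")
}

solve_group_or_chain <- function(store, mp, W, a, b, w, category) {
  if (category == "no_repeats") chain_product(W, seq(a, b - 1))
  else solve_group(store, mp, W, a, b, w)
}

#' Mayers diagonal-subtraction approximation
#'
#' An alternative approximate DWPC, provided for comparison only (never used
#' by [dwpc()]): the running matrix product is accumulated from the first
#' occurrence of the first repeated metanode, and the main diagonal is
#' subtracted at every later occurrence of that metanode.
#'
#' @inheritParams dwpc_general
#' @return A `dwpc_matrix` of kind `dwpc_approx`.
#' @export
dwpc_mayers <- function(store, mp, w = 0.5) {
  types <- metapath_types(mp)
  W <- mp_step_weighted(store, mp, w)
  L <- length(mp)
  counts <- table(types)
  reps <- names(counts)[counts > 1]
  if (length(reps) == 0) {
    return(new_dwpc_matrix(mp, w, chain_product(W, seq_len(L)),
                           algorithm = "mayers", kind = "dwpc_approx"))
  }
  first_rep <- types[min(which(types %in% reps))]
  pos <- which(types == first_rep)
  prefix <- if (pos[1] > 1) chain_product(W, seq_len(pos[1] - 1)) else NULL
  m <- NULL
  for (e in seq(pos[1], L)) {
    m <- if (is.null(m)) W[[e]] else m %*% W[[e]]
    if ((e + 1) %in% pos[-1]) m <- zero_diag(m)
  }
  values <- if (is.null(prefix)) m else prefix %*% m
  new_dwpc_matrix(mp, w, values, algorithm = "mayers", kind = "dwpc_approx")
}

#' Enumerate the paths behind a DWPC
#'
#' Lists the duplicate-free paths of a metapath between two nodes, with each
#' path's degree product (PDP) and its percentage contribution to the DWPC
#' (the DWPC is the sum of the PDPs).
#'
#' @inheritParams dwpc_general
#' @param source_id,target_id node identifiers with the metapath's endpoint
#'   types.
#' @param limit optional maximum number of paths, kept in descending PDP
#'   order.
#' @return data.frame with columns `nodes` (list column of node identifier
#'   vectors), `path` (readable string), `path_degree_product` and
#'   `percent_of_dwpc`; zero rows when no path exists.
#' @export
enumerate_paths <- function(store, mp, source_id, target_id, w = 0.5,
                            limit = NULL) {
  src_type <- mp$steps$from[1]
  tgt_type <- mp$steps$to[nrow(mp$steps)]
  si <- match(source_id, store$nodes[[src_type]])
  ti <- match(target_id, store$nodes[[tgt_type]])
  if (is.na(si)) {
    stop("type error: node '", source_id, "' is not a ", src_type,
         " node (metapath source type)")
  }
  if (is.na(ti)) {
    stop("type error: node '", target_id, "' is not a ", tgt_type,
         " node (metapath target type)")
  }
  A <- mp_step_adjacency(store, mp)
  W <- mp_step_weighted(store, mp, w)
  L <- length(mp)
  types <- metapath_types(mp)
  nbrs <- lapply(seq_len(L), function(k) {
    lapply(seq_len(nrow(A[[k]])), function(i) which(A[[k]][i, ] > 0))
  })
  prev_same <- lapply(seq_len(L + 1), function(j) {
    which(types[seq_len(j - 1)] == types[j])
  })
  paths <- list()
  pdps <- numeric(0)
  visited <- integer(L + 1)
  descend <- function(slot, node, pdp) {
    if (slot == L + 1L) {
      if (node == ti) {
        paths[[length(paths) + 1L]] <<- visited
        pdps[[length(pdps) + 1L]] <<- pdp
      }
      return(invisible())
    }
    for (nxt in nbrs[[slot]][[node]]) {
      ps <- prev_same[[slot + 1L]]
      if (length(ps) > 0 && any(visited[ps] == nxt)) next
      visited[slot + 1L] <<- nxt
      descend(slot + 1L, nxt, pdp * W[[slot]][node, nxt])
    }
    invisible()
  }
  visited[1L] <- si
  descend(1L, si, 1)

  if (length(paths) == 0) {
    return(data.frame(nodes = I(list()), path = character(0),
                      path_degree_product = numeric(0),
                      percent_of_dwpc = numeric(0)))
  }
  total <- sum(pdps)
  ord <- order(-pdps)
  if (!is.null(limit)) ord <- ord[seq_len(min(limit, length(ord)))]
  node_ids <- lapply(paths[ord], function(idx) {
    vapply(seq_along(idx), function(j) store$nodes[[types[j]]][idx[j]],
           character(1))
  })
  data.frame(
    nodes = I(node_ids),
    path = vapply(node_ids, paste, character(1), collapse = "-"),
    path_degree_product = pdps[ord],
    percent_of_dwpc = 100 * pdps[ord] / total
  )
}
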