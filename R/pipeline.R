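# metanode-level count matrix: entry (s, t) is the number of oriented
# metaedge traversals from type s to type t; its L-th power counts oriented
# metapaths, giving the Bonferroni family size for (s, t, L)
type_count_matrix <- function(mg) {
  ab <- mg$metanodes$abbreviation
  M <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
  ors <- mg_orientations(mg)
  for (i in seq_len(nrow(ors))) {
    M[ors$from[i], ors$to[i]] <- M[ors$from[i], ors$to[i]] + 1
  }
  M
}

#' Number of metapaths with the same endpoints and length
#'
#' The size of the Bonferroni family used by [adjust_pvalue()]: the count
#' of metapaths oriented from `source` to `target` with exactly the given
#' length.
#'
#' @param mg a [metagraph].
#' @param source,target metanode abbreviations or identifiers.
#' @param length metapath length.
#' @return Integer count.
#' @export
metapath_family_size <- function(mg, source, target, length) {
  source <- mg_resolve_metanode(mg, source)
  target <- mg_resolve_metanode(mg, target)
  M <- type_count_matrix(mg)
  P <- Reduce(`%*%`, rep(list(M), length))
  P[source, target]
}

# total values computed per metapath at precompute time: one path-count
# matrix and one DWPC matrix on the real network plus one DWPC matrix per
# permuted network
computation_accounting <- function(n_cells, n_permutations) {
  n_cells * (n_permutations + 2)
}

find_node_type <- function(store, node_id) {
  for (ab in names(store$nodes)) {
    if (node_id %in% store$nodes[[ab]]) return(ab)
  }
  stop("lookup error: unknown node '", node_id, "'")
}

# endpoint degree vectors of a metapath: degrees of the first metaedge on
# the source side and the last metaedge on the target side
mp_endpoint_degrees <- function(store, mp) {
  L <- nrow(mp$steps)
  first <- metaedge_adjacency(store, mp$steps$key[1], mp$steps$reversed[1])
  last <- metaedge_adjacency(store, mp$steps$key[L], mp$steps$reversed[L])
  list(source = as.integer(round(rowSums(first))),
       target = as.integer(round(colSums(last))))
}

# vectorized p-values for a matrix of observed DWPCs against one stats table
pvalues_for_matrix <- function(values, stats, sdeg, tdeg, conditional = FALSE) {
  p <- matrix(NA_real_, nrow(values), ncol(values))
  method <- matrix(NA_character_, nrow(values), ncol(values))
  key <- paste(rep(sdeg, times = ncol(values)),
               rep(tdeg, each = nrow(values)), sep = "\r")
  skey <- paste(stats$source_degree, stats$target_degree, sep = "\r")
  for (g in unique(key)) {
    cells <- which(key == g)
    row <- stats[match(g, skey), ]
    if (is.na(row$N)) next   # degree group unseen in permutations
    t_g <- values[cells]
    fit <- fit_gamma_hurdle(row)
    p_g <- numeric(length(t_g))
    m_g <- character(length(t_g))
    zero <- t_g <= 0
    p_g[zero] <- 1
    m_g[zero] <- "empirical"
    if (any(!zero)) {
      if (is.null(fit)) {
        if (row$n == 0) {
          p_g[!zero] <- 0
        } else {
          v <- row$sum / row$n
          p_g[!zero] <- ifelse(t_g[!zero] > v, 0, row$n / row$N)
        }
        m_g[!zero] <- "empirical"
      } else {
        p_g[!zero] <- gamma_hurdle_pvalue(fit, t_g[!zero],
                                          conditional = conditional)
        m_g[!zero] <- "gamma_hurdle"
      }
    }
    p[cells] <- p_g
    method[cells] <- m_g
  }
  list(p = p, method = method)
}

#' Precompute DWPCs, null statistics and prioritized rows
#'
#' For every metapath up to `max_length` (canonical orientation only — a
#' metapath and its reverse are never both stored), computes the full
#' path-count and DWPC matrices on the real network, accumulates
#' degree-grouped null summary statistics over `n_permutations` XSwap
#' permuted networks, computes per-pair p-values and Bonferroni-adjusted
#' p-values, and retains rows passing the [storage_threshold()] rule.
#'
#' For directory-backed output the per-metapath artifacts (DWPC and
#' path-count matrices under `path-counts/`, statistics under
#' `null-stats/`, retained rows under `rows/`) are written as they
#' complete; a rerun skips finished metapaths and reproduces identical
#' results (the permuted networks are regenerated deterministically from
#' `seed`).
#'
#' @param store a [hetnet] store.
#' @param max_length maximum metapath length.
#' @param w damping exponent (default 0.5).
#' @param n_permutations number of permuted hetnets for the null (the
#'   study-scale default is 200; choose smaller values for interactive
#'   use).
#' @param seed integer seed for the permutations.
#' @param multiplier XSwap attempts per edge.
#' @param dir output directory; defaults to the store's own directory, or
#'   in-memory only when the store has none.
#' @param dense_threshold density rule for the matrix containers.
#' @return An object of class `hetpath_results`: list with `rows` (retained
#'   rows, all `precomputed = TRUE`), `stats` (named list of statistics
#'   tables per canonical metapath), `metapaths`, and the run parameters.
#' @export
precompute <- function(store, max_length, w = 0.5, n_permutations = 25,
                       seed = 0, multiplier = 10, dir = store$dir,
                       dense_threshold = 0.7) {
  mg <- store$metagraph
  mps <- enumerate_metapaths(mg, max_length)
  node_counts <- vapply(store$nodes, length, integer(1))
  perms <- lapply(seq_len(n_permutations), function(p) {
    permute_hetnet(store, multiplier = multiplier,
                   seed = derive_seed(seed, paste0("permutation:", p)))
  })

  use_disk <- !is.null(dir)
  if (use_disk) {
    for (d in c(file.path("path-counts", paste0("dwpc-", w)),
                file.path("path-counts", "path-count"),
                "null-stats", "rows")) {
      dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
    }
  }

  fam_cache <- list()
  family_size <- function(s, t, L) {
    kk <- paste(s, t, L)
    if (is.null(fam_cache[[kk]])) {
      fam_cache[[kk]] <<- metapath_family_size(mg, s, t, L)
    }
    fam_cache[[kk]]
  }

  all_rows <- list()
  all_stats <- list()
  for (mp in mps) {
    ab <- metapath_abbrev(mp)
    rows_path <- if (use_disk) file.path(dir, "rows", paste0(ab, ".tsv"))
    stats_path <- if (use_disk) file.path(dir, "null-stats", paste0(ab, ".tsv.gz"))
    if (use_disk && file.exists(rows_path) && file.exists(stats_path)) {
      rows <- utils::read.delim(rows_path, stringsAsFactors = FALSE)
      all_rows[[ab]] <- rows
      all_stats[[ab]] <- read_null_stats(stats_path)
      next
    }

    dm <- dwpc(store, mp, w = w, dense_threshold = dense_threshold)
    pm <- path_count(store, mp)
    deg <- mp_endpoint_degrees(store, mp)
    stats <- Reduce(merge_stats, lapply(perms, function(ps) {
      degree_group_stats(dwpc(ps, mp, w = w), deg$source, deg$target,
                         metapath = ab)
    }))

    sig <- pvalues_for_matrix(dm$values, stats, deg$source, deg$target)
    L <- length(mp)
    fam <- family_size(mp$steps$from[1], mp$steps$to[L], L)
    p_adj <- matrix(adjust_pvalue(as.vector(sig$p), fam), nrow(sig$p))

    rule <- storage_threshold(node_counts[[mp$steps$from[1]]],
                              node_counts[[mp$steps$to[L]]], L)
    keep <- if (rule$keep_all_nonzero) dm$values > 0
            else p_adj < rule$p_threshold
    idx <- which(keep, arr.ind = TRUE)
    skey <- paste(stats$source_degree, stats$target_degree, sep = "\r")
    gi <- match(paste(deg$source[idx[, 1]], deg$target[idx[, 2]], sep = "\r"),
                skey)
    nz_mean <- ifelse(stats$n[gi] > 0, stats$sum[gi] / stats$n[gi], NA_real_)
    nz_var <- ifelse(stats$n[gi] > 1,
                     (stats$sum_sq[gi] - stats$n[gi] * (stats$sum[gi] / stats$n[gi])^2) /
                       (stats$n[gi] - 1), NA_real_)
    rows <- data.frame(
      metapath = ab,
      source_id = store$nodes[[mp$steps$from[1]]][idx[, 1]],
      target_id = store$nodes[[mp$steps$to[L]]][idx[, 2]],
      path_count = pm$values[idx],
      dwpc = dm$values[idx],
      p_value = sig$p[idx],
      p_adjusted = p_adj[idx],
      method = sig$method[idx],
      source_degree = deg$source[idx[, 1]],
      target_degree = deg$target[idx[, 2]],
      n_dwpcs = stats$N[gi],
      n_nonzero_dwpcs = stats$n[gi],
      nonzero_mean = nz_mean,
      nonzero_sd = sqrt(pmax(nz_var, 0)),  # clip cancellation noise
      precomputed = TRUE,
      stringsAsFactors = FALSE
    )
    rows <- rows[order(rows$p_adjusted, rows$source_id, rows$target_id), ]
    rownames(rows) <- NULL

    if (use_disk) {
      write_matrix_file(dm$values,
                        file.path(dir, "path-counts", paste0("dwpc-", w), ab),
                        dense_threshold)
      write_matrix_file(pm$values,
                        file.path(dir, "path-counts", "path-count", ab),
                        dense_threshold)
      write_null_stats(stats, stats_path)
      utils::write.table(rows, rows_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      # re-read so resumed and fresh runs agree byte-for-byte
      rows <- utils::read.delim(rows_path, stringsAsFactors = FALSE)
      stats <- read_null_stats(stats_path)
    }
    all_rows[[ab]] <- rows
    all_stats[[ab]] <- stats
  }

  rows <- do.call(rbind, c(all_rows, list(make.row.names = FALSE)))
  if (is.null(rows)) rows <- data.frame()
  structure(
    list(rows = rows, stats = all_stats,
         metapaths = vapply(mps, metapath_abbrev, character(1)),
         w = w, max_length = max_length, n_permutations = n_permutations,
         multiplier = multiplier, seed = seed, node_counts = node_counts),
    class = "hetpath_results"
  )
}

#' @export
print.hetpath_results <- function(x, ...) {
  cat(sprintf(paste0("precomputed connectivity search results: %d metapaths ",
                     "(length <= %d), %d retained rows, %d permutations, w = %g\n"),
              length(x$metapaths), x$max_length, nrow(x$rows),
              x$n_permutations, x$w))
  invisible(x)
}

#' Ranked metapaths between two nodes
#'
#' Returns one row per metapath oriented from the source node's type to the
#' target node's type (up to `max_length`), reversing stored canonical
#' orientations transparently — querying (target, source) yields the same
#' table with every metapath reversed. Rows retained by [precompute()] are
#' flagged `precomputed`; the rest are computed on the fly by exactly the
#' same code path, unless `precomputed_only = TRUE` drops them. Rows are
#' sorted by adjusted p-value, ties broken by abbreviation.
#'
#' @param results a `hetpath_results` object from [precompute()].
#' @param store the [hetnet] store the results were computed on.
#' @param source_id,target_id node identifiers.
#' @param max_length maximum metapath length (default: the precompute cap).
#' @param precomputed_only only return rows stored at precompute time.
#' @return data.frame with the metapath, path count, DWPC, p-values, the
#'   endpoint degrees, and the null-distribution summary columns.
#' @export
metapath_table <- function(results, store, source_id, target_id,
                           max_length = results$max_length,
                           precomputed_only = FALSE) {
  stype <- find_node_type(store, source_id)
  ttype <- find_node_type(store, target_id)
  mg <- store$metagraph
  mps <- enumerate_metapaths(mg, max_length, source = stype, target = ttype)
  out <- list()
  for (mp in mps) {
    ab <- metapath_abbrev(mp)
    rab <- metapath_rev_abbrev(mp)
    flipped <- rab < ab
    canon_ab <- if (flipped) rab else ab
    canon_mp <- if (flipped) reverse_metapath(mp) else mp
    cs_id <- if (flipped) target_id else source_id
    ct_id <- if (flipped) source_id else target_id

    hit <- results$rows[results$rows$metapath == canon_ab &
                          results$rows$source_id == cs_id &
                          results$rows$target_id == ct_id, , drop = FALSE]
    if (nrow(hit) == 1) {
      row <- hit
    } else if (precomputed_only) {
      next
    } else {
      row <- compute_metapath_row(results, store, canon_mp, cs_id, ct_id)
      if (is.null(row)) next
    }
    # report in query orientation
    out[[length(out) + 1]] <- data.frame(
      metapath = ab,
      source_id = source_id, target_id = target_id,
      path_count = row$path_count, dwpc = row$dwpc,
      p_value = row$p_value, p_adjusted = row$p_adjusted,
      method = row$method,
      source_degree = if (flipped) row$target_degree else row$source_degree,
      target_degree = if (flipped) row$source_degree else row$target_degree,
      n_dwpcs = row$n_dwpcs, n_nonzero_dwpcs = row$n_nonzero_dwpcs,
      nonzero_mean = row$nonzero_mean, nonzero_sd = row$nonzero_sd,
      precomputed = nrow(hit) == 1,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(data.frame())
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$p_adjusted, tab$metapath), ]
  rownames(tab) <- NULL
  tab
}

# one table row computed on the fly, identically to precompute()
compute_metapath_row <- function(results, store, canon_mp, cs_id, ct_id) {
  ab <- metapath_abbrev(canon_mp)
  w <- results$w
  stats <- results$stats[[ab]]
  if (is.null(stats)) {
    stop("lookup error: no null statistics for metapath ", ab,
         "; rerun precompute() with a larger max_length")
  }
  i <- match(cs_id, store$nodes[[canon_mp$steps$from[1]]])
  j <- match(ct_id, store$nodes[[canon_mp$steps$to[nrow(canon_mp$steps)]]])
  dm <- dwpc(store, canon_mp, w = w)
  pm <- path_count(store, canon_mp)
  deg <- mp_endpoint_degrees(store, canon_mp)
  srow <- stats[stats$source_degree == deg$source[i] &
                  stats$target_degree == deg$target[j], , drop = FALSE]
  if (nrow(srow) == 0) {
    # degree group unseen in permutations: permutations preserve degrees,
    # so this indicates a store/results mismatch; report p as missing
    srow <- stats_from_values(numeric(0), metapath = ab)
    srow$N <- NA_real_
  }
  t <- dm$values[i, j]
  if (is.na(srow$N)) {
    p <- NA_real_
    method <- NA_character_
  } else {
    sig <- dwpc_pvalue(srow, t)
    p <- sig$p_value
    method <- sig$method
  }
  L <- nrow(canon_mp$steps)
  fam <- metapath_family_size(store$metagraph, canon_mp$steps$from[1],
                              canon_mp$steps$to[L], L)
  nz_mean <- if (isTRUE(srow$n > 0)) srow$sum / srow$n else NA_real_
  nz_sd <- if (isTRUE(srow$n > 1)) {
    sqrt(max(0, (srow$sum_sq - srow$n * nz_mean^2) / (srow$n - 1)))
  } else NA_real_
  data.frame(
    metapath = ab, source_id = cs_id, target_id = ct_id,
    path_count = pm$values[i, j], dwpc = t,
    p_value = p, p_adjusted = if (is.na(p)) NA_real_ else adjust_pvalue(p, fam),
    method = method,
    source_degree = deg$source[i], target_degree = deg$target[j],
    n_dwpcs = srow$N, n_nonzero_dwpcs = srow$n,
    nonzero_mean = nz_mean, nonzero_sd = nz_sd,
    precomputed = FALSE, stringsAsFactors = FALSE
  )
}

#' Ranked paths across metapaths
#'
#' Lists the individual paths behind selected metapaths between two nodes,
#' scored so paths are comparable across metapaths: the path score is the
#' proportion of the metapath's DWPC contributed by the path times the
#' magnitude of the metapath's p-value, `(percent/100) * (-log10 p)`.
#'
#' @param results a `hetpath_results` object.
#' @param store the [hetnet] store.
#' @param source_id,target_id node identifiers.
#' @param metapaths character vector of metapath abbreviations (in query
#'   orientation, as returned by [metapath_table()]); default: all
#'   metapaths in the metapath table.
#' @param per_metapath_limit paths kept per metapath (default 100).
#' @param adjusted score with the Bonferroni-adjusted p-value instead of
#'   the unadjusted one.
#' @return data.frame of paths sorted by descending path score.
#' @export
path_table <- function(results, store, source_id, target_id,
                       metapaths = NULL, per_metapath_limit = 100,
                       adjusted = FALSE) {
  tab <- metapath_table(results, store, source_id, target_id)
  if (!is.null(metapaths)) {
    tab <- tab[tab$metapath %in% metapaths, , drop = FALSE]
  }
  out <- list()
  for (r in seq_len(nrow(tab))) {
    mp <- parse_metapath(tab$metapath[r], store$metagraph)
    p <- if (adjusted) tab$p_adjusted[r] else tab$p_value[r]
    if (is.na(p) || tab$dwpc[r] <= 0) next
    paths <- enumerate_paths(store, mp, source_id, target_id, w = results$w,
                             limit = per_metapath_limit)
    if (nrow(paths) == 0) next
    out[[length(out) + 1]] <- data.frame(
      metapath = tab$metapath[r],
      path = paths$path,
      path_degree_product = paths$path_degree_product,
      percent_of_dwpc = paths$percent_of_dwpc,
      p_value = p,
      path_score = paths$percent_of_dwpc / 100 * (-log10(p)),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  res <- res[order(-res$path_score, res$metapath, res$path), ]
  rownames(res) <- NULL
  res
}
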