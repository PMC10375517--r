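#' Degree-grouped null DWPC summary statistics
#'
#' Null DWPCs from permuted networks are pooled across all node pairs
#' sharing the same (source degree, target degree), where the degrees are
#' those of the metapath's first and last metaedge. Since permutation
#' preserves degree, node pairs in one degree group are exchangeable, which
#' multiplies the effective number of permutations. Only running totals are
#' kept per group: total count `N`, nonzero count `n`, `sum`, `sum_sq` and
#' the number of permuted hetnets `n_perms` — sufficient to fit the
#' gamma-hurdle null or compute an empirical p-value, and additive across
#' permutations.
#'
#' @param null_matrix matrix of null DWPC values (all source x target node
#'   pairs), or a `dwpc_matrix`.
#' @param source_degrees,target_degrees integer degree vectors for the rows
#'   and columns (degrees of the metapath's first/last metaedge).
#' @param metapath metapath abbreviation label for the rows.
#' @return data.frame with one row per observed degree pair and columns
#'   `metapath`, `source_degree`, `target_degree`, `N`, `n`, `sum`,
#'   `sum_sq`, `n_perms` (= 1).
#' @export
degree_group_stats <- function(null_matrix, source_degrees, target_degrees,
                               metapath = "") {
  if (inherits(null_matrix, "dwpc_matrix")) {
    if (metapath == "") metapath <- metapath_abbrev(null_matrix$metapath)
    null_matrix <- null_matrix$values
  }
  if (length(source_degrees) != nrow(null_matrix) ||
      length(target_degrees) != ncol(null_matrix)) {
    stop("shape error: degree vectors do not match the null matrix")
  }
  v <- as.vector(null_matrix)
  sd <- rep(as.integer(source_degrees), times = ncol(null_matrix))
  td <- rep(as.integer(target_degrees), each = nrow(null_matrix))
  key <- paste(sd, td, sep = "\r")
  agg <- rowsum(cbind(N = 1, n = as.numeric(v > 0), sum = v, sum_sq = v^2),
                group = key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    metapath = metapath,
    source_degree = as.integer(vapply(parts, `[`, character(1), 1)),
    target_degree = as.integer(vapply(parts, `[`, character(1), 2)),
    N = as.numeric(agg[, "N"]),
    n = as.numeric(agg[, "n"]),
    sum = as.numeric(agg[, "sum"]),
    sum_sq = as.numeric(agg[, "sum_sq"]),
    n_perms = 1
  )
  out <- out[order(out$source_degree, out$target_degree), ]
  rownames(out) <- NULL
  out
}

# zero-row stats table: the identity element for merge_stats
empty_stats <- function() {
  data.frame(metapath = character(0), source_degree = integer(0),
             target_degree = integer(0), N = numeric(0), n = numeric(0),
             sum = numeric(0), sum_sq = numeric(0), n_perms = numeric(0))
}

#' Merge degree-grouped summary statistics
#'
#' Fieldwise addition of running totals, matched on (metapath,
#' source_degree, target_degree). Associative and commutative, with the
#' empty (or all-zero) statistics table as identity — so statistics can be
#' accumulated permutation-by-permutation in any order. Merging two
#' single-group records with different keys is a key error.
#'
#' @param a,b statistics tables as returned by [degree_group_stats()].
#' @return Merged statistics table.
#' @export
merge_stats <- function(a, b) {
  if (nrow(a) == 0) return(b)
  if (nrow(b) == 0) return(a)
  if (nrow(a) == 1 && nrow(b) == 1) {
    same <- a$metapath == b$metapath &&
      a$source_degree == b$source_degree && a$target_degree == b$target_degree
    if (!same) {
      stop("key error: cannot merge statistics for different ",
           "(metapath, source degree, target degree) groups")
    }
  }
  both <- rbind(a, b)
  key <- paste(both$metapath, both$source_degree, both$target_degree,
               sep = "\r")
  agg <- rowsum(as.matrix(both[c("N", "n", "sum", "sum_sq", "n_perms")]),
                group = key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(
    metapath = both$metapath[first],
    source_degree = both$source_degree[first],
    target_degree = both$target_degree[first],
    agg[match(key[first], rownames(agg)), , drop = FALSE]
  )
  out <- out[order(out$metapath, out$source_degree, out$target_degree), ]
  rownames(out) <- NULL
  out
}

#' Fit a gamma-hurdle distribution from summary statistics
#'
#' The gamma-hurdle distribution places probability `1 - lambda` at zero
#' and `lambda` on a gamma distribution with shape `alpha` and rate `beta`
#' (density proportional to `x^(alpha-1) exp(-beta x)`). All three
#' parameters are estimated by the method of moments from the running
#' totals alone: `lambda = n/N`; with nonzero-part mean `m = sum/n` and
#' Bessel-corrected variance `v = (sum_sq - n m^2)/(n - 1)`, the shape is
#' `alpha = m^2/v` and the rate `beta = m/v`.
#'
#' @param stats a single-group statistics row ([degree_group_stats()]).
#' @return List of class `gamma_hurdle` with `lambda`, `alpha`, `beta`, or
#'   `NULL` when the fit is unavailable (fewer than 2 nonzero values, or
#'   zero sample variance) and the caller should fall back to
#'   [empirical_pvalue()].
#' @export
fit_gamma_hurdle <- function(stats) {
  stopifnot(nrow(stats) == 1)
  n <- stats$n
  N <- stats$N
  if (n < 2) return(NULL)
  m <- stats$sum / n
  v <- (stats$sum_sq - n * m^2) / (n - 1)
  if (!is.finite(v) || v <= 0) return(NULL)
  structure(list(lambda = n / N, alpha = m^2 / v, beta = m / v),
            class = "gamma_hurdle")
}

#' @export
print.gamma_hurdle <- function(x, ...) {
  cat(sprintf("gamma-hurdle(lambda = %.4g, alpha = %.4g, beta = %.4g)\n",
              x$lambda, x$alpha, x$beta))
  invisible(x)
}

#' Gamma-hurdle tail probability of a DWPC
#'
#' The probability that a gamma-hurdle draw is at least `t > 0`:
#' `lambda` times the upper tail of the gamma component at `t` (evaluated
#' with the regularized upper incomplete gamma function via
#' [stats::pgamma()]). Strictly decreasing in `t`, with values in
#' `(0, lambda]`. `conditional = TRUE` drops the `lambda` weight, giving
#' the tail probability conditional on a nonzero draw.
#'
#' @param params a `gamma_hurdle` fit.
#' @param t observed DWPC, strictly positive (`t = 0` is handled by
#'   [empirical_pvalue()], never here).
#' @param conditional omit the hurdle weight `lambda`.
#' @return The p-value.
#' @export
gamma_hurdle_pvalue <- function(params, t, conditional = FALSE) {
  if (any(t <= 0)) stop("t must be positive; zero DWPCs use the empirical rules")
  weight <- if (conditional) 1 else params$lambda
  weight * stats::pgamma(t, shape = params$alpha, rate = params$beta,
                         lower.tail = FALSE)
}

#' Empirical p-value from summary statistics
#'
#' Fallback for the cases where the gamma fit is unavailable, computing the
#' proportion of null DWPCs at least as large as the observed value from
#' the running totals: `t = 0` gives 1; a positive `t` against all-zero
#' nulls gives 0; when all nonzero nulls share one value `v = sum/n`,
#' `t > v` gives 0 and otherwise `n/N`.
#'
#' @param stats a single-group statistics row.
#' @param t observed DWPC.
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(stats, t) {
  stopifnot(nrow(stats) == 1)
  if (t <= 0) return(1)
  if (stats$n == 0) return(0)
  v <- stats$sum / stats$n
  if (t > v) return(0)
  stats$n / stats$N
}

#' Significance of a DWPC against its degree-grouped null
#'
#' Routes to the gamma-hurdle tail probability when the fit is available
#' (at least two nonzero nulls with positive spread and `t > 0`), and to
#' the empirical rules otherwise.
#'
#' @param stats a single-group statistics row ([degree_group_stats()]),
#'   accumulated over at least one permutation.
#' @param t observed DWPC.
#' @param conditional passed to [gamma_hurdle_pvalue()].
#' @return List of class `significance_result` with `dwpc`, `p_value`,
#'   `method` (`"gamma_hurdle"` or `"empirical"`) and `stats_used`.
#' @export
dwpc_pvalue <- function(stats, t, conditional = FALSE) {
  stopifnot(nrow(stats) == 1)
  params <- if (t > 0) fit_gamma_hurdle(stats) else NULL
  if (is.null(params)) {
    p <- empirical_pvalue(stats, t)
    method <- "empirical"
  } else {
    p <- gamma_hurdle_pvalue(params, t, conditional = conditional)
    method <- "gamma_hurdle"
  }
  structure(list(dwpc = t, p_value = p, method = method, stats_used = stats),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("DWPC %.6g: p = %.4g (%s)\n", x$dwpc, x$p_value, x$method))
  invisible(x)
}

#' Bonferroni-adjust a DWPC p-value
#'
#' The family is the set of metapaths sharing the observed metapath's
#' source metanode, target metanode and length; the adjusted p-value is
#' `min(1, p * family size)`.
#'
#' @param p p-value in `[0, 1]`.
#' @param metapath_family_size number of metapaths in the family (>= 1).
#' @return Adjusted p-value.
#' @export
adjust_pvalue <- function(p, metapath_family_size) {
  if (metapath_family_size < 1) {
    stop("parameter error: family size must be at least 1")
  }
  stopifnot(p >= 0, p <= 1)
  pmin(1, p * metapath_family_size)
}

#' Storage rule for precomputed DWPC rows
#'
#' Metapaths of length 1 keep every nonzero DWPC (direct edges are always
#' reported, regardless of significance). Metapaths of length >= 2 keep
#' rows with adjusted p-value below `5 * (n_source * n_target)^(-0.3)`,
#' penalizing metapaths with large DWPC matrices.
#'
#' @param n_source,n_target node counts of the source and target metanodes.
#' @param length metapath length.
#' @return List with `keep_all_nonzero` (logical) and `p_threshold`
#'   (numeric; `NA` for length 1).
#' @export
storage_threshold <- function(n_source, n_target, length) {
  stopifnot(n_source >= 1, n_target >= 1, length >= 1)
  if (length == 1) {
    list(keep_all_nonzero = TRUE, p_threshold = NA_real_)
  } else {
    list(keep_all_nonzero = FALSE,
         p_threshold = 5 * (n_source * n_target)^(-0.3))
  }
}

#' Ordered pair counts
#'
#' `node_pair_count(n)` is the number of ordered node pairs (`n^2`) — the
#' cells of a square DWPC matrix; `degree_pair_count(d)` is the number of
#' ordered degree pairs (`d^2`) — the summary-statistic rows after degree
#' grouping. Their ratio is the storage reduction degree grouping buys.
#'
#' @param n_nodes,distinct_degrees nonnegative counts.
#' @return Integer-valued count.
#' @export
node_pair_count <- function(n_nodes) {
  stopifnot(n_nodes >= 0)
  as.numeric(n_nodes)^2
}

#' @rdname node_pair_count
#' @export
degree_pair_count <- function(distinct_degrees) {
  stopifnot(distinct_degrees >= 0)
  as.numeric(distinct_degrees)^2
}

#' Draw from a gamma-hurdle distribution
#'
#' @param n number of draws.
#' @param lambda probability of a nonzero draw.
#' @param alpha,beta shape and rate of the gamma component.
#' @return Numeric vector of draws.
#' @export
rgamma_hurdle <- function(n, lambda, alpha, beta) {
  nonzero <- stats::runif(n) < lambda
  out <- numeric(n)
  out[nonzero] <- stats::rgamma(sum(nonzero), shape = alpha, rate = beta)
  out
}

# build a one-row stats record from raw null values (tests, simulations)
stats_from_values <- function(values, metapath = "", source_degree = 0L,
                              target_degree = 0L, n_perms = 1) {
  data.frame(metapath = metapath, source_degree = source_degree,
             target_degree = target_degree,
             N = length(values), n = sum(values > 0),
             sum = sum(values), sum_sq = sum(values^2), n_perms = n_perms)
}

#' Read and write null summary statistics
#'
#' Statistics tables are serialized as gzipped TSV, one row per (metapath,
#' source degree, target degree) with the running-total columns.
#'
#' @param stats a statistics table.
#' @param path file path (conventionally `.tsv.gz`).
#' @return `read_null_stats` returns the statistics table.
#' @export
write_null_stats <- function(stats, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(stats, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_null_stats
#' @export
read_null_stats <- function(path) {
  utils::read.delim(gzfile(path), stringsAsFactors = FALSE)
}
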