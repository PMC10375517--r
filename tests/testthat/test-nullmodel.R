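test_that("null DWPCs are grouped by endpoint degree with correct totals", {
  gig <- toy_fixtures()$toy_gig
  mp <- parse_metapath("GiGiG", gig$metagraph)
  null_m <- dwpc(gig, mp, 0.5)$values
  deg <- metaedge_degrees(gig, "GiG")
  stats <- degree_group_stats(null_m, deg$source, deg$target, metapath = "GiGiG")
  # degrees (1,2,1): four (1,1) cells, two (1,2), two (2,1), one (2,2)
  expect_equal(stats$N[stats$source_degree == 1 & stats$target_degree == 1], 4)
  expect_equal(stats$N[stats$source_degree == 1 & stats$target_degree == 2], 2)
  expect_equal(stats$N[stats$source_degree == 2 & stats$target_degree == 1], 2)
  expect_equal(stats$N[stats$source_degree == 2 & stats$target_degree == 2], 1)
  expect_equal(sum(stats$N), length(null_m))
  expect_true(all(stats$n_perms == 1))
  # Cauchy-Schwarz on running totals
  nz <- stats[stats$n > 0, ]
  expect_true(all(nz$sum^2 <= nz$n * nz$sum_sq + 1e-12))

  zero <- degree_group_stats(matrix(0, 3, 3), deg$source, deg$target)
  expect_true(all(zero$n == 0) && all(zero$sum == 0))
  expect_error(degree_group_stats(null_m, 1:2, deg$target), "shape error")
})

test_that("summary statistics match raw-value statistics on small fixtures", {
  set.seed(1)
  values <- rgamma_hurdle(500, 0.6, 3, 2)
  stats <- hetpaths:::stats_from_values(values)
  expect_equal(stats$N, 500)
  expect_equal(stats$n, sum(values > 0))
  expect_equal(stats$sum, sum(values))
  expect_equal(stats$sum_sq, sum(values^2))
  nz <- values[values > 0]
  fit <- fit_gamma_hurdle(stats)
  expect_equal(fit$lambda, mean(values > 0), tolerance = 1e-10)
  expect_equal(fit$alpha, mean(nz)^2 / var(nz), tolerance = 1e-10)
  expect_equal(fit$beta, mean(nz) / var(nz), tolerance = 1e-10)
})

test_that("merge_stats is a commutative monoid over running totals", {
  set.seed(2)
  tabs <- lapply(1:20, function(i) {
    m <- matrix(rgamma_hurdle(12, 0.5, 2, 1), 3, 4)
    degree_group_stats(m, c(1, 2, 2), c(1, 1, 3, 3), metapath = "XaYbX")
  })
  fwd <- Reduce(merge_stats, tabs)
  bwd <- Reduce(merge_stats, rev(tabs))
  expect_equal(fwd, bwd)
  expect_true(all(fwd$n_perms == 20))
  # identity element
  expect_equal(merge_stats(fwd, hetpaths:::empty_stats()), fwd)
  zero <- fwd[1, ]
  zero[c("N", "n", "sum", "sum_sq", "n_perms")] <- 0
  merged <- merge_stats(fwd[1, ], zero)
  rownames(merged) <- NULL
  expect_equal(merged, `rownames<-`(fwd[1, ], NULL))
  expect_error(
    merge_stats(fwd[1, ], `[<-`(fwd[2, ], "metapath", value = "other")),
    "key error")
})

test_that("merged statistics equal one-pass statistics over pooled matrices", {
  store <- generate_hetnet(demo_fixture_spec(n_nodes = 10, density = 0.2,
                                             seed = 3))
  mp <- parse_metapath("CbGiG", store$metagraph)
  deg <- hetpaths:::mp_endpoint_degrees(store, mp)
  perms <- lapply(1:5, function(p) permute_hetnet(store, seed = p))
  mats <- lapply(perms, function(ps) dwpc(ps, mp, 0.5)$values)
  incremental <- Reduce(merge_stats, lapply(mats, degree_group_stats,
                                            deg$source, deg$target))
  pooled <- degree_group_stats(do.call(rbind, mats),
                               rep(deg$source, 5), deg$target)
  expect_equal(incremental[c("source_degree", "target_degree", "N", "n")],
               pooled[c("source_degree", "target_degree", "N", "n")])
  expect_equal(incremental$sum, pooled$sum, tolerance = 1e-12)
  expect_equal(incremental$sum_sq, pooled$sum_sq, tolerance = 1e-12)
})

test_that("method-of-moments gamma-hurdle fit matches hand-computed values", {
  # N = 6 with nonzero values {1, 2, 3}
  stats <- hetpaths:::stats_from_values(c(0, 0, 0, 1, 2, 3))
  fit <- fit_gamma_hurdle(stats)
  expect_equal(fit$lambda, 0.5)
  expect_equal(fit$alpha, 4)   # m = 2, Bessel-corrected v = 1
  expect_equal(fit$beta, 2)
  # unavailable fits
  expect_null(fit_gamma_hurdle(hetpaths:::stats_from_values(c(0, 0, 5))))
  expect_null(fit_gamma_hurdle(hetpaths:::stats_from_values(c(2, 2, 2))))
})

test_that("the moments fit recovers generating parameters from large samples", {
  set.seed(7)
  for (lambda in c(0.2, 0.9)) {
    for (alpha in c(0.5, 8)) {
      beta <- 1
      draws <- rgamma_hurdle(1e5, lambda, alpha, beta)
      fit <- fit_gamma_hurdle(hetpaths:::stats_from_values(draws))
      expect_lt(abs(fit$lambda - lambda), 0.01)
      expect_lt(abs(fit$alpha - alpha) / alpha, 0.05)
      expect_lt(abs(fit$beta - beta) / beta, 0.05)
    }
  }
})

test_that("gamma-hurdle p-values match closed forms and quadrature", {
  exp_fit <- structure(list(lambda = 0.5, alpha = 1, beta = 1),
                       class = "gamma_hurdle")
  expect_equal(gamma_hurdle_pvalue(exp_fit, log(2)), 0.25)
  # limit t -> 0+ approaches lambda (1 when lambda = 1)
  one <- structure(list(lambda = 1, alpha = 3, beta = 2),
                   class = "gamma_hurdle")
  expect_equal(gamma_hurdle_pvalue(one, 1e-12), 1, tolerance = 1e-8)
  # quadrature oracle for the normalized gamma tail
  fit <- structure(list(lambda = 0.5, alpha = 4, beta = 2),
                   class = "gamma_hurdle")
  tail <- integrate(function(x) x^3 * exp(-2 * x), 2, Inf)$value *
    2^4 / gamma(4)
  expect_equal(gamma_hurdle_pvalue(fit, 2), 0.5 * tail, tolerance = 1e-8)
  expect_equal(gamma_hurdle_pvalue(fit, 2, conditional = TRUE), tail,
               tolerance = 1e-8)
  # strictly decreasing in t, bounded by lambda
  ts <- seq(0.1, 5, by = 0.1)
  ps <- gamma_hurdle_pvalue(fit, ts)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= fit$lambda))
  expect_error(gamma_hurdle_pvalue(fit, 0), "positive")
})

test_that("empirical p-value rules cover the degenerate cases", {
  all_zero <- hetpaths:::stats_from_values(rep(0, 10))
  expect_equal(empirical_pvalue(all_zero, 0), 1)
  expect_equal(empirical_pvalue(all_zero, 0.8), 0)
  # N = 100, 30 nonzero nulls all equal to 2.0
  spread0 <- hetpaths:::stats_from_values(c(rep(0, 70), rep(2, 30)))
  expect_equal(empirical_pvalue(spread0, 1.5), 0.3)
  expect_equal(empirical_pvalue(spread0, 2.5), 0)
  expect_equal(empirical_pvalue(spread0, 0), 1)
})

test_that("dwpc_pvalue routes between the gamma fit and empirical rules", {
  stats <- hetpaths:::stats_from_values(c(0, 0, 0, 1, 2, 3))
  zero <- dwpc_pvalue(stats, 0)
  expect_equal(zero$p_value, 1)
  expect_equal(zero$method, "empirical")
  pos <- dwpc_pvalue(stats, 2)
  expect_equal(pos$method, "gamma_hurdle")
  expect_equal(pos$p_value,
               0.5 * pgamma(2, 4, rate = 2, lower.tail = FALSE))
  degenerate <- dwpc_pvalue(hetpaths:::stats_from_values(c(0, 2, 2)), 1)
  expect_equal(degenerate$method, "empirical")
  # p-values always in [0, 1]
  set.seed(11)
  for (i in 1:50) {
    s <- hetpaths:::stats_from_values(rgamma_hurdle(50, 0.4, 2, 2))
    p <- dwpc_pvalue(s, rexp(1))$p_value
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("p-values are calibrated when nulls and observations share a distribution", {
  set.seed(13)
  n_rep <- 2000
  hits <- 0
  for (i in seq_len(n_rep)) {
    nulls <- rgamma_hurdle(400, 0.7, 3, 2)
    t <- rgamma_hurdle(1, 0.7, 3, 2)
    p <- dwpc_pvalue(hetpaths:::stats_from_values(nulls), t)$p_value
    hits <- hits + (p <= 0.05)
  }
  expect_equal(hits / n_rep, 0.05, tolerance = 0.25)  # +- ~0.0125
})

test_that("Bonferroni adjustment multiplies by the family size, capped at 1", {
  # printed worked example: p = 5.9% over 3 Disease...Pathway metapaths
  expect_equal(adjust_pvalue(0.059, 3), 0.177)
  expect_equal(adjust_pvalue(0.6, 3), 1)
  expect_equal(adjust_pvalue(0.2, 1), 0.2)
  expect_error(adjust_pvalue(0.2, 0), "parameter error")
})

test_that("storage rules keep all direct edges and threshold longer metapaths", {
  r1 <- storage_threshold(137, 1822, 1)
  expect_true(r1$keep_all_nonzero)
  r2 <- storage_threshold(137, 1822, 2)
  expect_false(r2$keep_all_nonzero)
  expect_equal(r2$p_threshold, 5 * (137 * 1822)^(-0.3))
  expect_equal(r2$p_threshold, 0.1202, tolerance = 1e-3)
  r3 <- storage_threshold(20945, 20945, 3)
  expect_equal(r3$p_threshold, 0.0128, tolerance = 1e-2)
})

test_that("pair counts square the node and degree counts", {
  expect_equal(node_pair_count(20945), 438693025)
  expect_equal(degree_pair_count(302), 91204)
  expect_equal(node_pair_count(0), 0)
})

test_that("null statistics round-trip through gzipped TSV", {
  dir <- withr::local_tempdir()
  stats <- hetpaths:::stats_from_values(c(0, 1, 2), metapath = "GiGiG",
                                        source_degree = 2L, target_degree = 1L)
  path <- file.path(dir, "GiGiG.tsv.gz")
  write_null_stats(stats, path)
  back <- read_null_stats(path)
  expect_equal(back$sum, stats$sum)
  expect_equal(back$metapath, "GiGiG")
})
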