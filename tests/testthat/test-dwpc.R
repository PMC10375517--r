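toys <- toy_fixtures()
hmg <- hetionet_metagraph()

test_that("degree weighting downweights by endpoint degrees", {
  adj <- unname(metaedge_adjacency(toys$toy_gig, "GiG"))
  w05 <- degree_weight(adj, w = 0.5)
  expect_equal(w05,
               matrix(c(0, 0.70711, 0,
                        0.70711, 0, 0.70711,
                        0, 0.70711, 0), 3, 3, byrow = TRUE),
               tolerance = 1e-5)
  expect_equal(degree_weight(adj, w = 0), adj)
  # isolated node: its row and column stay zero, no error
  iso <- rbind(cbind(adj, 0), 0)
  wi <- degree_weight(iso, w = 0.5)
  expect_equal(wi[4, ], rep(0, 4))
  expect_equal(wi[, 4], rep(0, 4))
  expect_error(degree_weight(adj, w = -1), "parameter error")
})

test_that("metapaths are categorized by their repeat pattern", {
  expect_equal(categorize_metapath(parse_metapath("CbGpPW", hmg))$label,
               "no_repeats")
  expect_equal(categorize_metapath(parse_metapath("DrDtCrC", hmg))$label,
               "disjoint")
  expect_equal(categorize_metapath(parse_metapath("DtCtDpC", hmg))$label,
               "overlapping")
  expect_equal(categorize_metapath(parse_metapath("DrDaGaDrD", hmg))$label,
               "nested")
  expect_equal(categorize_metapath(parse_metapath("CtDrDtC", hmg))$label,
               "nested")
  expect_equal(categorize_metapath(parse_metapath("GiGiG", hmg))$label,
               "short_repeat")
  expect_equal(categorize_metapath(parse_metapath("DaGaD", hmg))$label,
               "interleaved_nonrepeat")
  expect_equal(categorize_metapath(parse_metapath("GiGiGiGiG", hmg))$label,
               "long_repeat")
})

test_that("no_repeats label holds exactly when no metanode recurs", {
  for (mp in enumerate_metapaths(demo_fixture_spec()$metagraph, 3)) {
    types <- metapath_types(mp)
    expect_equal(categorize_metapath(mp)$label == "no_repeats",
                 !anyDuplicated(types) > 0, info = metapath_abbrev(mp))
  }
})

test_that("segmentation covers the metapath exactly once", {
  segs <- segment_metapath(parse_metapath("DrDtCrC", hmg))
  expect_equal(vapply(segs, function(s) s$abbrev, character(1)),
               c("DrD", "DtC", "CrC"))
  expect_equal(vapply(segs, function(s) s$category, character(1)),
               c("short_repeat", "no_repeats", "short_repeat"))

  single <- segment_metapath(parse_metapath("GiGiG", hmg))
  expect_length(single, 1)
  expect_equal(single[[1]]$category, "short_repeat")

  expect_length(segment_metapath(parse_metapath("CbGpPW", hmg)), 1)

  # edges of the segments partition the steps, in order
  for (ab in c("DrDtCrC", "CbGiGaD", "CtDrDtCbG", "DaGiGpPWpGaD")) {
    mp <- parse_metapath(ab, hmg)
    segs <- segment_metapath(mp)
    edges <- unlist(lapply(segs, function(s) s$edges))
    expect_equal(sort(edges), seq_len(length(mp)))
  }
})

test_that("short-repeat correction zeroes the diagonal and matches worked values", {
  gig <- toys$toy_gig
  mp <- parse_metapath("GiGiG", gig$metagraph)
  pc <- path_count(gig, mp)$values
  expect_equal(unname(pc), matrix(c(0, 0, 1,
                                    0, 0, 0,
                                    1, 0, 0), 3, 3, byrow = TRUE))
  dm <- dwpc(gig, mp, w = 0.5)$values
  expect_equal(dm["g0", "g2"], 0.5)  # single path, PDP (1*2)^-.5 * (2*1)^-.5
  expect_equal(unname(diag(dm)), rep(0, 3))

  d1 <- degree_weight(unname(metaedge_adjacency(gig, "GiG")), w = 0.5)
  prod <- dwpc_short_repeat(d1, d1)
  expect_equal(unname(diag(prod)), rep(0, 3))
  expect_equal(prod, unname(dm))
  expect_error(dwpc_short_repeat(matrix(0, 2, 3)), "shape error")
})

test_that("overlapping (BABA) corrections remove node-revisiting walks", {
  cd <- toys$toy_cd
  mp <- parse_metapath("CtDtCtD", cd$metagraph)
  d <- degree_weight(unname(metaedge_adjacency(cd, "CtD")), w = 0.5)
  baba <- dwpc_baba(d, t(d), d)
  # only duplicate-free path: c1-d0-c0-d1 with PDP 0.25
  expect_equal(baba[2, 2], 0.25)
  expect_equal(baba[1, 1], 0, tolerance = 1e-12)
  # ... although uncorrected walks give a nonzero c0 -> d0 value
  expect_equal((d %*% t(d) %*% d)[1, 1], 0.625)
  expect_equal(dwpc(cd, mp, w = 0.5)$values, dwpc_general(cd, mp, 0.5)$values)
  expect_equal(path_count(cd, mp)$values["c1", "d1"], 1)
  expect_equal(path_count(cd, mp)$values["c0", "d0"], 0)
  # annihilation by an all-zero middle matrix
  expect_equal(dwpc_baba(d, matrix(0, 2, 2), d), matrix(0, 2, 2))
  expect_error(dwpc_baba(d, matrix(0, 3, 3), d), "shape error")
})

test_that("nested (BAAB) metapaths match the enumeration oracle", {
  mg <- cd_rich_metagraph()
  store <- generate_hetnet(fixture_spec(mg, n_nodes = c(C = 4, D = 4),
                                        density = 0.4, seed = 7))
  mp <- parse_metapath("CtDrDtC", mg)
  expect_equal(categorize_metapath(mp)$label, "nested")
  expect_equal(dwpc(store, mp, 0.5)$values, oracle_dwpc(store, mp, 0.5),
               tolerance = 1e-10)
  pc <- dwpc(store, mp, 0)$values
  expect_equal(pc, oracle_dwpc(store, mp, 0))
  expect_true(all(pc == round(pc)))
  expect_equal(unname(diag(dwpc(store, mp, 0.5)$values)), rep(0, 4))
})

test_that("the dispatcher equals the enumeration routine on every metapath up to length 4", {
  for (seed in 0:1) {
    store <- generate_hetnet(demo_fixture_spec(n_nodes = 10, density = 0.2,
                                               seed = seed))
    for (mp in enumerate_metapaths(store$metagraph, 4)) {
      a <- dwpc(store, mp, 0.5)$values
      b <- dwpc_general(store, mp, 0.5)$values
      expect_lt(max(abs(a - b)) / max(1, max(abs(b))), 1e-8)
      pc <- dwpc(store, mp, 0)$values
      expect_identical(pc, round(pc))
      expect_lt(max(abs(pc - dwpc_general(store, mp, 0)$values)), 1e-9)
    }
  }
})

test_that("the dispatcher and both enumerators agree with the independent oracle", {
  store <- generate_hetnet(demo_fixture_spec(n_nodes = 8, density = 0.25,
                                             seed = 4))
  for (ab in c("GiGiG", "CbGiGbC", "CtDaGbC", "GbCtDaG", "Gr>GiG<rG",
               "CbGr>GpPW", "DaGiGaD")) {
    mp <- parse_metapath(ab, store$metagraph)
    expect_equal(dwpc(store, mp, 0.5)$values, oracle_dwpc(store, mp, 0.5),
                 tolerance = 1e-10, info = ab)
    expect_equal(dwpc_general(store, mp, 0.5)$values,
                 oracle_dwpc(store, mp, 0.5), tolerance = 1e-10, info = ab)
  }
})

test_that("transpose law: dwpc of the reverse is the transpose", {
  store <- generate_hetnet(demo_fixture_spec(n_nodes = 12, density = 0.15,
                                             seed = 6))
  for (ab in c("CbGiG", "CtDaG", "GiGiG", "CbGpPWpG", "DaGr>G")) {
    mp <- parse_metapath(ab, store$metagraph)
    expect_equal(dwpc(store, reverse_metapath(mp), 0.5)$values,
                 t(dwpc(store, mp, 0.5)$values), tolerance = 1e-12, info = ab)
  }
})

test_that("DWPC entries do not increase with the damping exponent", {
  store <- generate_hetnet(demo_fixture_spec(n_nodes = 12, density = 0.2,
                                             seed = 8))
  mp <- parse_metapath("CbGiGaD", store$metagraph)
  prev <- dwpc(store, mp, 0)$values
  for (w in c(0.25, 0.5, 0.75, 1)) {
    cur <- dwpc(store, mp, w)$values
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("DWPC decomposes into the path degree products of its paths", {
  store <- generate_hetnet(demo_fixture_spec(n_nodes = 10, density = 0.25,
                                             seed = 9))
  mp <- parse_metapath("CbGiGaD", store$metagraph)
  dm <- dwpc(store, mp, 0.5)$values
  for (i in c(1, 4, 7)) {
    for (j in c(2, 5, 9)) {
      paths <- enumerate_paths(store, mp, store$nodes$C[i], store$nodes$D[j],
                               w = 0.5)
      expect_equal(sum(paths$path_degree_product), dm[i, j],
                   tolerance = 1e-8)
      if (nrow(paths) > 0) {
        expect_equal(sum(paths$percent_of_dwpc), 100, tolerance = 1e-6)
        # sorted by descending contribution
        expect_true(!is.unsorted(rev(paths$path_degree_product)))
      }
    }
  }
})

test_that("enumerate_paths lists the worked toy-CD paths", {
  cd <- toys$toy_cd
  mp <- parse_metapath("CtDtCtD", cd$metagraph)
  paths <- enumerate_paths(cd, mp, "c1", "d1", w = 0.5)
  expect_equal(nrow(paths), 1)
  expect_equal(paths$nodes[[1]], c("c1", "d0", "c0", "d1"))
  expect_equal(paths$path_degree_product, 0.25)
  expect_equal(paths$percent_of_dwpc, 100)
  # every c0 -> d0 walk repeats a node
  expect_equal(nrow(enumerate_paths(cd, mp, "c0", "d0", w = 0.5)), 0)
  expect_error(enumerate_paths(cd, mp, "d0", "d1", w = 0.5), "type error")
})

test_that("the approximation is exact on disjoint and simple patterns", {
  mg <- cd_rich_metagraph()
  store <- generate_hetnet(fixture_spec(mg, n_nodes = c(C = 8, D = 8),
                                        density = 0.25, seed = 11))
  for (ab in c("DrDtCrC", "CrCrC", "CtDrDtC", "CtDtC")) {
    mp <- parse_metapath(ab, mg)
    expect_equal(dwpc_approx(store, mp, 0.5)$values,
                 dwpc(store, mp, 0.5)$values, tolerance = 1e-10, info = ab)
  }
  # on a complex overlapping pattern the approximation differs but stays finite
  mp <- parse_metapath("CtDtCtDtC", mg)
  approx <- dwpc_approx(store, mp, 0.5)
  expect_equal(approx$kind, "dwpc_approx")
  expect_true(all(is.finite(approx$values)))
  mayers <- dwpc_mayers(store, mp, 0.5)
  expect_equal(mayers$kind, "dwpc_approx")
  expect_true(all(is.finite(mayers$values)))
})

test_that("caches return identical values in memory and from disk", {
  dir <- withr::local_tempdir()
  store <- generate_hetnet(demo_fixture_spec(n_nodes = 10, density = 0.2,
                                             seed = 12))
  mp <- parse_metapath("CbGiGaD", store$metagraph)
  cold <- dwpc(store, mp, 0.5)$values
  warm <- dwpc(store, mp, 0.5)$values
  expect_identical(cold, warm)

  hetmat_write(store, dir)
  disk <- hetmat_read(dir)
  first <- dwpc(disk, mp, 0.5)
  dir.create(file.path(dir, "path-counts", "dwpc-0.5"), recursive = TRUE)
  hetpaths:::write_matrix_file(first$values,
                               file.path(dir, "path-counts", "dwpc-0.5",
                                         "CbGiGaD"))
  fresh <- hetmat_read(dir)
  cached <- dwpc(fresh, mp, 0.5)
  expect_equal(cached$algorithm, "cached")
  expect_equal(cached$values, first$values, tolerance = 1e-12)
})
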