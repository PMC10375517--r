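#' Specify a synthetic hetnet
#'
#' A fixture spec bundles a metagraph, node counts per metanode, an edge
#' density per metaedge and a seed, from which [generate_hetnet()] builds a
#' reproducible random hetnet.
#'
#' @param mg a [metagraph].
#' @param n_nodes named integer vector (by metanode abbreviation) of node
#'   counts; a single unnamed value is recycled for all metanodes.
#' @param density named numeric vector (by metaedge forward abbreviation) of
#'   edge densities in `[0, 1]`; a single unnamed value is recycled.
#' @param seed integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(mg, n_nodes, density, seed = 0) {
  stopifnot(inherits(mg, "metagraph"))
  mn <- mg$metanodes$abbreviation
  me <- mg$metaedges$key
  if (is.null(names(n_nodes))) n_nodes <- stats::setNames(rep(n_nodes, length(mn)), mn)
  if (is.null(names(density))) density <- stats::setNames(rep(density, length(me)), me)
  if (any(density > 1) || any(density < 0)) {
    stop("parameter error: density must lie in [0, 1]")
  }
  structure(list(metagraph = mg, n_nodes = n_nodes, density = density,
                 seed = seed),
            class = "fixture_spec")
}

#' Generate a random hetnet from a spec
#'
#' Each metaedge's edges are drawn by sampling `round(density * cells)`
#' admissible cells without replacement, so the realized density matches the
#' request up to rounding. Self-edges are never produced; undirected
#' self-metaedge matrices are symmetric. The same spec and seed always
#' produce the identical store.
#'
#' @param spec a [fixture_spec].
#' @return A [hetnet] store.
#' @export
generate_hetnet <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mg <- spec$metagraph
  nodes <- lapply(
    stats::setNames(nm = mg$metanodes$abbreviation),
    function(ab) sprintf("%s%d", tolower(ab), seq_len(spec$n_nodes[[ab]]) - 1L)
  )
  edges <- list()
  for (i in seq_len(nrow(mg$metaedges))) {
    e <- mg$metaedges[i, ]
    ns <- spec$n_nodes[[e$source_abbrev]]
    nt <- spec$n_nodes[[e$target_abbrev]]
    m <- matrix(0, ns, nt)
    self_typed <- e$source_abbrev == e$target_abbrev
    self_undirected <- self_typed && !e$directed
    cells <- if (self_undirected) which(upper.tri(m))
             else if (self_typed) which(row(m) != col(m))
             else seq_len(ns * nt)
    n_draw <- round(spec$density[[e$key]] * length(cells))
    if (n_draw > 0) {
      picked <- with_seed(derive_seed(spec$seed, paste0("gen:", e$key)),
                          sample(cells, n_draw))
      m[picked] <- 1
    }
    if (self_undirected) m <- pmax(m, t(m))
    dimnames(m) <- list(nodes[[e$source_abbrev]], nodes[[e$target_abbrev]])
    edges[[e$key]] <- m
  }
  hetnet(mg, nodes, edges)
}

#' Hand-constructed toy hetnets
#'
#' Two tiny stores with worked-out DWPC values, used throughout the
#' documentation and tests:
#' * `toy_gig` — 3 Gene nodes `g0, g1, g2` with *interacts* edges
#'   `g0–g1`, `g1–g2`. Degrees are (1, 2, 1); the only `GiGiG` path from
#'   `g0` to `g2` has PDP `(1*2)^(-1/2) * (2*1)^(-1/2) = 0.5` at `w = 0.5`.
#' * `toy_cd` — 2 Compound and 2 Disease nodes with *treats* edges
#'   `c0–d0`, `c0–d1`, `c1–d0`. The only duplicate-free `CtDtCtD` path,
#'   `c1–d0–c0–d1`, has PDP 0.25 at `w = 0.5`; every `c0`-to-`d0` walk
#'   repeats a node, so DWPC(c0, d0) = 0.
#'
#' @return Named list of [hetnet] stores `toy_gig` and `toy_cd`.
#' @export
toy_fixtures <- function() {
  gig_mg <- metagraph(
    metanodes = data.frame(identifier = "Gene", abbreviation = "G"),
    metaedges = data.frame(source = "Gene", target = "Gene",
                           kind = "interacts", abbreviation = "i",
                           directed = FALSE)
  )
  gig_adj <- matrix(c(0, 1, 0,
                      1, 0, 1,
                      0, 1, 0), 3, 3, byrow = TRUE,
                    dimnames = list(c("g0", "g1", "g2"), c("g0", "g1", "g2")))
  toy_gig <- hetnet(gig_mg, list(G = c("g0", "g1", "g2")), list(GiG = gig_adj))

  cd_mg <- metagraph(
    metanodes = data.frame(identifier = c("Compound", "Disease"),
                           abbreviation = c("C", "D")),
    metaedges = data.frame(source = "Compound", target = "Disease",
                           kind = "treats", abbreviation = "t",
                           directed = FALSE)
  )
  cd_adj <- matrix(c(1, 1,
                     1, 0), 2, 2, byrow = TRUE,
                   dimnames = list(c("c0", "c1"), c("d0", "d1")))
  toy_cd <- hetnet(cd_mg, list(C = c("c0", "c1"), D = c("d0", "d1")),
                   list(CtD = cd_adj))

  list(toy_gig = toy_gig, toy_cd = toy_cd)
}

#' A small multi-metanode demonstration spec
#'
#' Five metanodes and seven metaedges (including undirected self, directed
#' self and bipartite kinds), 30 nodes per metanode and density 0.1 —
#' large enough to exercise every repeat pattern of metapaths up to length
#' 4, small enough that enumeration-based checks run in seconds.
#'
#' @param n_nodes nodes per metanode (default 30).
#' @param density edge density (default 0.1).
#' @param seed integer seed.
#' @return A [fixture_spec].
#' @export
demo_fixture_spec <- function(n_nodes = 30, density = 0.1, seed = 0) {
  mg <- metagraph(
    metanodes = data.frame(
      identifier = c("Gene", "Compound", "Disease", "Pathway", "Anatomy"),
      abbreviation = c("G", "C", "D", "PW", "A")
    ),
    metaedges = data.frame(
      source = c("Gene", "Compound", "Compound", "Disease", "Disease",
                 "Gene", "Gene"),
      target = c("Gene", "Gene", "Disease", "Gene", "Anatomy",
                 "Pathway", "Gene"),
      kind = c("interacts", "binds", "treats", "associates", "localizes",
               "participates", "regulates"),
      abbreviation = c("i", "b", "t", "a", "l", "p", "r"),
      directed = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
    )
  )
  fixture_spec(mg, n_nodes = n_nodes, density = density, seed = seed)
}
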