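#' Construct an in-memory hetnet store
#'
#' A hetnet store holds a metagraph, an ordered node list per metanode, and
#' one 0/1 adjacency matrix per metaedge (rows ordered by the source
#' metanode's node list, columns by the target's). Stores are backed by an
#' environment so adjacency matrices can be loaded lazily from disk (see
#' [hetmat_read()]) and derived results cached.
#'
#' @param mg a [metagraph].
#' @param nodes named list (by metanode abbreviation) of character vectors of
#'   node identifiers.
#' @param edges named list (by metaedge forward abbreviation, e.g. `"CbG"`)
#'   of adjacency matrices. Matrices for undirected self-metaedges must be
#'   symmetric; self-typed matrices must have zero diagonals (self-edges are
#'   disallowed).
#' @return An object of class `hetnet`.
#' @export
hetnet <- function(mg, nodes, edges) {
  stopifnot(inherits(mg, "metagraph"))
  missing_nodes <- setdiff(mg$metanodes$abbreviation, names(nodes))
  if (length(missing_nodes) > 0) {
    stop("missing node lists for metanodes: ", paste(missing_nodes, collapse = ", "))
  }
  store <- new.env(parent = emptyenv())
  store$metagraph <- mg
  store$nodes <- lapply(nodes, as.character)
  store$edges <- new.env(parent = emptyenv())
  store$dir <- NULL
  store$cache <- new.env(parent = emptyenv())
  class(store) <- "hetnet"
  for (key in names(edges)) {
    m <- as.matrix(edges[[key]])
    storage.mode(m) <- "double"
    validate_adjacency(store, key, m)
    assign(key, m, envir = store$edges)
  }
  store
}

#' @export
print.hetnet <- function(x, ...) {
  n_nodes <- sum(vapply(x$nodes, length, integer(1)))
  cat(sprintf("hetnet: %d metanodes (%d nodes), %d metaedges%s\n",
              nrow(x$metagraph$metanodes), n_nodes,
              nrow(x$metagraph$metaedges),
              if (is.null(x$dir)) "" else paste0(" @ ", x$dir)))
  invisible(x)
}

validate_adjacency <- function(store, key, m) {
  e <- mg_metaedge(store$metagraph, key)
  ns <- length(store$nodes[[e$source_abbrev]])
  nt <- length(store$nodes[[e$target_abbrev]])
  if (nrow(m) != ns || ncol(m) != nt) {
    stop("consistency error: adjacency for ", key, " is ",
         nrow(m), "x", ncol(m), " but node tables imply ", ns, "x", nt)
  }
  if (any(m != 0 & m != 1)) {
    stop("consistency error: adjacency for ", key, " must be 0/1")
  }
  if (e$source_abbrev == e$target_abbrev) {
    if (any(diag(m) != 0)) {
      stop("consistency error: self-edges are disallowed (nonzero diagonal in ", key, ")")
    }
    if (!e$directed && !isTRUE(all.equal(m, t(m)))) {
      stop("consistency error: undirected self-metaedge ", key, " must be symmetric")
    }
  }
  invisible(TRUE)
}

#' Retrieve a metaedge adjacency matrix
#'
#' Matrices are loaded from disk on first access for directory-backed stores
#' (lazy loading), then cached in memory.
#'
#' @param store a [hetnet] store.
#' @param metaedge metaedge forward abbreviation (e.g. `"CbG"`), or a
#'   metapath step.
#' @param oriented_reverse return the transposed view (target-to-source).
#' @return A base 0/1 matrix with node identifiers as dimnames.
#' @export
metaedge_adjacency <- function(store, metaedge, oriented_reverse = FALSE) {
  key <- metaedge
  e <- mg_metaedge(store$metagraph, key)
  if (exists(key, envir = store$edges, inherits = FALSE)) {
    m <- get(key, envir = store$edges)
  } else {
    if (is.null(store$dir)) {
      stop("I/O error: no adjacency loaded for metaedge ", key)
    }
    m <- read_adjacency_file(store, key)
    assign(key, m, envir = store$edges)
  }
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(store$nodes[[e$source_abbrev]],
                        store$nodes[[e$target_abbrev]])
  }
  if (oriented_reverse) t(m) else m
}

#' Per-metaedge node degrees
#'
#' Degrees are specific to the metaedge: the source degree of a node is its
#' number of edges of this type (row sums of the adjacency matrix), and the
#' target degree the column sums. Both sides sum to the metaedge's edge
#' count.
#'
#' @inheritParams metaedge_adjacency
#' @return List with integer vectors `source` and `target`.
#' @export
metaedge_degrees <- function(store, metaedge) {
  m <- metaedge_adjacency(store, metaedge)
  list(source = as.integer(round(rowSums(m))),
       target = as.integer(round(colSums(m))))
}

# disk format ----------------------------------------------------------------
# <dir>/
#   metagraph.json
#   nodes/<MetanodeAbbrev>.tsv[.gz|.bz2|.xz|.zip]   columns: identifier, name
#   edges/<key>.sparse.mtx    (MatrixMarket; density < dense threshold)
#   edges/<key>.dense.tsv     (tab-separated values; density >= threshold)
#   path-counts/, permutations/  (generated data)

#' Write a hetnet store to a HetMat-style directory
#'
#' @param store a [hetnet] store.
#' @param dir directory to create.
#' @param dense_threshold adjacency matrices with density at or above this
#'   value are written dense (TSV); below it, sparse (MatrixMarket).
#'   Default 0.7.
#' @param compress_nodes write node tables gzip-compressed.
#' @return `dir`, invisibly.
#' @export
hetmat_write <- function(store, dir, dense_threshold = 0.7,
                         compress_nodes = FALSE) {
  dir.create(file.path(dir, "nodes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "edges"), showWarnings = FALSE)
  write_metagraph(store$metagraph, file.path(dir, "metagraph.json"))
  for (ab in store$metagraph$metanodes$abbreviation) {
    ids <- store$nodes[[ab]]
    tab <- data.frame(identifier = ids, name = ids, stringsAsFactors = FALSE)
    path <- file.path(dir, "nodes", paste0(ab, ".tsv"))
    if (compress_nodes) {
      con <- gzfile(paste0(path, ".gz"), "w")
      on.exit(close(con), add = TRUE)
      utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (key in store$metagraph$metaedges$key) {
    m <- metaedge_adjacency(store, key)
    write_matrix_file(m, file.path(dir, "edges", key), dense_threshold)
  }
  invisible(dir)
}

#' Read a hetnet store from a HetMat-style directory
#'
#' The metagraph and node tables are read eagerly; adjacency matrices are
#' loaded lazily, on first access through [metaedge_adjacency()], so a store
#' with a missing matrix file reads fine until that metaedge is used.
#' Compressed node tables (`.gz`, `.bz2`, `.xz`, `.zip`) are read
#' transparently.
#'
#' @param dir a directory written by [hetmat_write()].
#' @return A [hetnet] store bound to `dir`.
#' @export
hetmat_read <- function(dir) {
  mg_path <- file.path(dir, "metagraph.json")
  if (!file.exists(mg_path)) {
    stop("format error: ", dir, " has no metagraph.json")
  }
  mg <- parse_metagraph(mg_path)
  store <- new.env(parent = emptyenv())
  store$metagraph <- mg
  store$nodes <- lapply(
    stats::setNames(nm = mg$metanodes$abbreviation),
    function(ab) read_node_table(dir, ab)$identifier
  )
  store$edges <- new.env(parent = emptyenv())
  store$dir <- normalizePath(dir)
  store$cache <- new.env(parent = emptyenv())
  class(store) <- "hetnet"
  store
}

read_node_table <- function(dir, abbrev) {
  base <- file.path(dir, "nodes", paste0(abbrev, ".tsv"))
  for (ext in c("", ".gz", ".bz2", ".xz", ".zip")) {
    path <- paste0(base, ext)
    if (!file.exists(path)) next
    con <- switch(ext,
      ".gz" = gzfile(path), ".bz2" = bzfile(path), ".xz" = xzfile(path),
      ".zip" = unz(path, sub("\\.zip$", "", basename(path))),
      path)
    tab <- utils::read.delim(con, stringsAsFactors = FALSE,
                             colClasses = "character")
    return(tab)
  }
  stop("format error: no node table for metanode ", abbrev, " under ", dir)
}

read_adjacency_file <- function(store, key) {
  stem <- file.path(store$dir, "edges", key)
  m <- read_matrix_file(stem)
  if (is.null(m)) {
    stop("I/O error: missing adjacency matrix file ", stem,
         ".sparse.mtx (or .dense.tsv)")
  }
  validate_adjacency(store, key, m)
  e <- mg_metaedge(store$metagraph, key)
  dimnames(m) <- list(store$nodes[[e$source_abbrev]],
                      store$nodes[[e$target_abbrev]])
  m
}

# shared matrix containers for adjacency and cached DWPC matrices
write_matrix_file <- function(m, stem, dense_threshold = 0.7) {
  density <- mean(m != 0)
  if (density >= dense_threshold) {
    utils::write.table(m, paste0(stem, ".dense.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    paste0(stem, ".sparse.mtx"))
  }
  invisible(stem)
}

read_matrix_file <- function(stem) {
  sparse_path <- paste0(stem, ".sparse.mtx")
  dense_path <- paste0(stem, ".dense.tsv")
  if (file.exists(sparse_path)) {
    m <- as.matrix(Matrix::readMM(sparse_path))
    storage.mode(m) <- "double"
    return(m)
  }
  if (file.exists(dense_path)) {
    m <- as.matrix(utils::read.table(dense_path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    return(m)
  }
  NULL
}

#' Build a hetnet store from edge lists
#'
#' Convenience converter for plain-text graphs: a directory containing
#' `metagraph.json`, `nodes/<Abbrev>.tsv` node tables and
#' `edgelists/<key>.tsv` two-column (`source`, `target`) node-identifier
#' edge lists is assembled into an in-memory [hetnet] store.
#'
#' @param dir directory with `metagraph.json`, `nodes/` and `edgelists/`.
#' @return A [hetnet] store.
#' @export
hetnet_from_edgelists <- function(dir) {
  mg <- parse_metagraph(file.path(dir, "metagraph.json"))
  nodes <- lapply(
    stats::setNames(nm = mg$metanodes$abbreviation),
    function(ab) read_node_table(dir, ab)$identifier
  )
  edges <- list()
  for (i in seq_len(nrow(mg$metaedges))) {
    e <- mg$metaedges[i, ]
    src <- nodes[[e$source_abbrev]]
    tgt <- nodes[[e$target_abbrev]]
    m <- matrix(0, length(src), length(tgt), dimnames = list(src, tgt))
    path <- file.path(dir, "edgelists", paste0(e$key, ".tsv"))
    if (file.exists(path)) {
      el <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character")
      m[cbind(match(el$source, src), match(el$target, tgt))] <- 1
      if (!e$directed && e$source_abbrev == e$target_abbrev) {
        m <- pmax(m, t(m))
      }
    }
    edges[[e$key]] <- m
  }
  hetnet(mg, nodes, edges)
}
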