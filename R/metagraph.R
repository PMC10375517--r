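#' Construct a metagraph
#'
#' A metagraph is the schema of a hetnet: its metanodes (node types) and
#' metaedges (edge types). Metanode abbreviations are uppercase-leading
#' (e.g. `"G"`, `"PW"`); metaedge kind abbreviations are lowercase
#' (e.g. `"i"` for *interacts*, `"p"` for *participates*).
#'
#' @param metanodes data.frame with columns `identifier` and `abbreviation`.
#' @param metaedges data.frame with columns `source`, `target` (metanode
#'   identifiers), `kind`, `abbreviation` (kind abbreviation) and `directed`
#'   (logical).
#' @return An object of class `metagraph`.
#' @examples
#' mg <- metagraph(
#'   metanodes = data.frame(identifier = "Gene", abbreviation = "G"),
#'   metaedges = data.frame(source = "Gene", target = "Gene",
#'                          kind = "interacts", abbreviation = "i",
#'                          directed = FALSE)
#' )
#' @export
metagraph <- function(metanodes, metaedges) {
  metanodes <- as.data.frame(metanodes, stringsAsFactors = FALSE)
  metaedges <- as.data.frame(metaedges, stringsAsFactors = FALSE)
  required_mn <- c("identifier", "abbreviation")
  required_me <- c("source", "target", "kind", "abbreviation", "directed")
  if (!all(required_mn %in% names(metanodes))) {
    stop("metanodes must have columns: ", paste(required_mn, collapse = ", "))
  }
  if (!all(required_me %in% names(metaedges))) {
    stop("metaedges must have columns: ", paste(required_me, collapse = ", "))
  }
  metanodes <- metanodes[required_mn]
  metaedges <- metaedges[required_me]
  metaedges$directed <- as.logical(metaedges$directed)

  if (any(!nzchar(metanodes$identifier))) {
    stop("schema error: metanode identifiers must be nonempty")
  }
  if (anyDuplicated(metanodes$identifier)) {
    stop("schema error: duplicate metanode identifier")
  }
  if (anyDuplicated(metanodes$abbreviation)) {
    stop("schema error: duplicate metanode abbreviation")
  }
  if (any(!grepl("^[A-Z][A-Za-z0-9]?$", metanodes$abbreviation))) {
    stop("schema error: metanode abbreviations must be 1-2 characters, uppercase-leading")
  }
  if (any(!grepl("^[a-z][a-z0-9]?$", metaedges$abbreviation))) {
    stop("schema error: metaedge kind abbreviations must be 1-2 characters, lowercase")
  }
  dangling <- setdiff(c(metaedges$source, metaedges$target), metanodes$identifier)
  if (length(dangling) > 0) {
    stop("schema error: metaedge endpoint not declared as metanode: ",
         paste(dangling, collapse = ", "))
  }

  abbrev_of <- stats::setNames(metanodes$abbreviation, metanodes$identifier)
  metaedges$source_abbrev <- unname(abbrev_of[metaedges$source])
  metaedges$target_abbrev <- unname(abbrev_of[metaedges$target])
  metaedges$key <- metaedge_key(metaedges$source_abbrev, metaedges$abbreviation,
                                metaedges$target_abbrev, metaedges$directed)
  # treat undirected metaedges as unordered for uniqueness
  canon <- ifelse(
    !metaedges$directed & metaedges$target_abbrev < metaedges$source_abbrev,
    paste(metaedges$target_abbrev, metaedges$abbreviation, metaedges$source_abbrev),
    paste(metaedges$source_abbrev, metaedges$abbreviation, metaedges$target_abbrev)
  )
  if (anyDuplicated(canon)) {
    stop("schema error: duplicate metaedge (source, kind, target) triple")
  }

  mg <- list(metanodes = metanodes, metaedges = metaedges)
  class(mg) <- "metagraph"
  mg
}

# forward abbreviation of a metaedge, e.g. "CbG" or "Gr>G"
metaedge_key <- function(source_abbrev, kind_abbrev, target_abbrev, directed) {
  paste0(source_abbrev, kind_abbrev, ifelse(directed, ">", ""), target_abbrev)
}

#' @export
print.metagraph <- function(x, ...) {
  cat(sprintf("metagraph: %d metanodes, %d metaedges\n",
              nrow(x$metanodes), nrow(x$metaedges)))
  cat("metanodes:", paste(x$metanodes$abbreviation, collapse = " "), "\n")
  cat("metaedges:", paste(x$metaedges$key, collapse = " "), "\n")
  invisible(x)
}

#' Parse a metagraph from its JSON serialization
#'
#' The schema document lists metanodes (with identifiers and abbreviations)
#' and metaedges (with endpoints, kind, kind abbreviation and direction).
#'
#' @param text JSON text, or the path of a `metagraph.json` file.
#' @return A [metagraph] object.
#' @seealso [write_metagraph()]
#' @export
parse_metagraph <- function(text) {
  if (length(text) == 1 && !grepl("[{\n]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(text, simplifyDataFrame = TRUE)
  if (is.null(doc$metanodes) || is.null(doc$metaedges)) {
    stop("schema error: document must contain 'metanodes' and 'metaedges'")
  }
  metagraph(doc$metanodes, doc$metaedges)
}

#' Serialize a metagraph to JSON
#'
#' Serialization round-trips: `parse_metagraph(write_metagraph(mg))` is
#' semantically identical to `mg`.
#'
#' @param mg a [metagraph].
#' @param path optional file path; when given, JSON is written there.
#' @return JSON text (invisibly when `path` is given).
#' @export
write_metagraph <- function(mg, path = NULL) {
  stopifnot(inherits(mg, "metagraph"))
  doc <- list(
    metanodes = mg$metanodes,
    metaedges = mg$metaedges[c("source", "target", "kind", "abbreviation", "directed")]
  )
  json <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' The Hetionet v1.0 metagraph
#'
#' Returns the schema of Hetionet v1.0, a knowledge graph of human biology,
#' disease, and medicine with 11 metanodes and 24 metaedges (of which only
#' Gene-regulates-Gene is directed). The schema ships with the package as
#' `extdata/hetionet-v1.0-metagraph.json`.
#'
#' @return A [metagraph] with 11 metanodes and 24 metaedges.
#' @examples
#' mg <- hetionet_metagraph()
#' nrow(mg$metanodes)  # 11
#' nrow(mg$metaedges)  # 24
#' @export
hetionet_metagraph <- function() {
  path <- system.file("extdata", "hetionet-v1.0-metagraph.json",
                      package = "hetpaths", mustWork = TRUE)
  parse_metagraph(path)
}

# lookup helpers -------------------------------------------------------------

# metaedge row by forward key; errors if absent
mg_metaedge <- function(mg, key) {
  i <- match(key, mg$metaedges$key)
  if (is.na(i)) stop("lookup error: no metaedge with abbreviation '", key, "'")
  mg$metaedges[i, ]
}

mg_metanode_abbrevs <- function(mg) mg$metanodes$abbreviation

# resolve a metanode given an abbreviation or identifier; returns abbreviation
mg_resolve_metanode <- function(mg, x) {
  if (x %in% mg$metanodes$abbreviation) return(x)
  i <- match(x, mg$metanodes$identifier)
  if (is.na(i)) stop("lookup error: unknown metanode '", x, "'")
  mg$metanodes$abbreviation[i]
}

# Oriented metaedge table: one row per traversable orientation of each
# metaedge. Undirected self-metaedges (e.g. GiG) contribute one orientation;
# all others contribute two. `token` is the mid-path abbreviation fragment
# ("b", "r>", "<r"); `rev_token` is the fragment used when the step is read
# in the reverse direction.
mg_orientations <- function(mg) {
  me <- mg$metaedges
  rows <- vector("list", nrow(me) * 2L)
  k <- 0L
  for (i in seq_len(nrow(me))) {
    e <- me[i, ]
    fwd_token <- if (e$directed) paste0(e$abbreviation, ">") else e$abbreviation
    rev_token <- if (e$directed) paste0("<", e$abbreviation) else e$abbreviation
    k <- k + 1L
    rows[[k]] <- data.frame(
      key = e$key, from = e$source_abbrev, to = e$target_abbrev,
      kind = e$abbreviation, directed = e$directed, reversed = FALSE,
      token = fwd_token, rev_token = rev_token, stringsAsFactors = FALSE
    )
    self_undirected <- !e$directed && e$source_abbrev == e$target_abbrev
    if (!self_undirected) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        key = e$key, from = e$target_abbrev, to = e$source_abbrev,
        kind = e$abbreviation, directed = e$directed, reversed = TRUE,
        token = rev_token, rev_token = fwd_token, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows[seq_len(k)])
}
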