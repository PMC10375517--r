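#' @title Metapaths
#' @description A metapath is an ordered, orientation-aware sequence of
#'   metaedges, e.g. `CbGpPWpG` = Compound-binds-Gene-participates-Pathway-
#'   participates-Gene (the final *participates* step is traversed in
#'   reverse). Metapaths are created by [parse_metapath()] or
#'   [enumerate_metapaths()].
#' @name metapath
NULL

# steps: data.frame(key, from, to, kind, directed, reversed, token, rev_token)
new_metapath <- function(steps) {
  stopifnot(nrow(steps) >= 1)
  if (nrow(steps) > 1 && any(steps$to[-nrow(steps)] != steps$from[-1])) {
    stop("invalid metapath: adjacent steps do not chain")
  }
  mp <- list(steps = steps)
  class(mp) <- "metapath"
  mp
}

#' Metapath abbreviation
#'
#' @param mp a metapath.
#' @return The abbreviation string, e.g. `"CbGpPWpG"`. Directed metaedges
#'   carry `>` / `<` markers (`"Gr>G"` forward, `"G<rG"` reversed).
#' @export
metapath_abbrev <- function(mp) {
  s <- mp$steps
  paste0(s$from[1], paste0(s$token, s$to, collapse = ""))
}

# abbreviation of the reversed metapath, without constructing it
metapath_rev_abbrev <- function(mp) {
  s <- mp$steps
  n <- nrow(s)
  paste0(s$to[n], paste0(s$rev_token[n:1], s$from[n:1], collapse = ""))
}

#' Metanode type sequence of a metapath
#'
#' @param mp a metapath.
#' @return Character vector of metanode abbreviations, length `length(mp) + 1`.
#' @export
metapath_types <- function(mp) c(mp$steps$from[1], mp$steps$to)

#' @export
length.metapath <- function(x) nrow(x$steps)

#' @export
print.metapath <- function(x, ...) {
  cat(sprintf("metapath %s (length %d)\n", metapath_abbrev(x), length(x)))
  invisible(x)
}

#' @export
`==.metapath` <- function(e1, e2) {
  metapath_abbrev(e1) == metapath_abbrev(e2)
}

#' Reverse a metapath
#'
#' Steps are reversed and their orientations flipped, so that
#' `reverse_metapath(reverse_metapath(mp))` equals `mp`. The reverse of
#' `DaGpPWpG` is `GpPWpGaD`.
#'
#' @param mp a metapath.
#' @return The reversed metapath.
#' @export
reverse_metapath <- function(mp) {
  s <- mp$steps[rev(seq_len(nrow(mp$steps))), ]
  out <- data.frame(
    key = s$key, from = s$to, to = s$from, kind = s$kind,
    directed = s$directed, reversed = !s$reversed,
    token = s$rev_token, rev_token = s$token, stringsAsFactors = FALSE
  )
  # undirected self-metaedges have a single canonical orientation
  self_und <- !out$directed & out$from == out$to
  out$reversed[self_und] <- FALSE
  rownames(out) <- NULL
  new_metapath(out)
}

# canonical representative of the reversal-equivalence class:
# the orientation with the lexicographically smaller abbreviation
canonical_metapath <- function(mp) {
  if (metapath_rev_abbrev(mp) < metapath_abbrev(mp)) reverse_metapath(mp) else mp
}

#' Parse a metapath abbreviation
#'
#' Tokenizes an abbreviation such as `"CbGpPWpG"` against a metagraph.
#' Abbreviations alternate metanode abbreviations (uppercase-leading) and
#' metaedge kind abbreviations (lowercase, with `<` / `>` markers for
#' directed kinds). Tokenization tries all consistent readings: zero valid
#' readings is a parse error, more than one is an ambiguity error listing
#' the candidates.
#'
#' @param abbreviation metapath abbreviation string.
#' @param mg a [metagraph].
#' @return A metapath whose [metapath_abbrev()] reproduces the input.
#' @examples
#' mg <- hetionet_metagraph()
#' mp <- parse_metapath("CbGpPWpG", mg)
#' mp$steps$reversed  # FALSE FALSE TRUE
#' @export
parse_metapath <- function(abbreviation, mg) {
  ors <- mg_orientations(mg)
  metanode_abbrevs <- mg_metanode_abbrevs(mg)
  parses <- list()

  # DFS over the remaining string; `at_type` is the metanode the next step
  # must leave from (NA at the very start).
  descend <- function(rest, at_type, steps_idx) {
    if (is.na(at_type)) {
      for (a in metanode_abbrevs) {
        if (startsWith(rest, a)) {
          descend(substring(rest, nchar(a) + 1L), a, steps_idx)
        }
      }
      return(invisible())
    }
    if (!nzchar(rest)) {
      if (length(steps_idx) >= 1) parses[[length(parses) + 1L]] <<- steps_idx
      return(invisible())
    }
    cand <- which(ors$from == at_type)
    for (i in cand) {
      tok <- paste0(ors$token[i], ors$to[i])
      if (startsWith(rest, tok)) {
        descend(substring(rest, nchar(tok) + 1L), ors$to[i], c(steps_idx, i))
      }
    }
    invisible()
  }
  descend(abbreviation, NA_character_, integer(0))

  if (length(parses) == 0) {
    stop("parse error: '", abbreviation, "' is not a metapath of this metagraph")
  }
  if (length(parses) > 1) {
    cands <- vapply(parses, function(idx) {
      paste(ors$key[idx], collapse = ",")
    }, character(1))
    stop("parse error: ambiguous metapath abbreviation '", abbreviation,
         "'; candidate readings: ", paste(cands, collapse = " | "))
  }
  steps <- ors[parses[[1]], , drop = FALSE]
  rownames(steps) <- NULL
  new_metapath(steps)
}

#' Enumerate metapaths of a metagraph
#'
#' Enumerates all metapaths of length 1 to `max_length`. When `source` and
#' `target` are unspecified, each reversal-equivalence class
#' \{mp, reverse(mp)\} is counted once, represented by the orientation with
#' the lexicographically smaller abbreviation; on the Hetionet v1.0
#' metagraph this yields 24, 242 and 1,939 metapaths of lengths 1, 2 and 3
#' (2,205 in total up to length 3). When `source` and `target` are given,
#' all metapaths oriented source-to-target are returned without
#' deduplication.
#'
#' @param mg a [metagraph].
#' @param max_length maximum metapath length (>= 1).
#' @param source,target optional metanode abbreviations or identifiers
#'   restricting endpoints.
#' @param lengths optional integer vector of lengths to keep (subset of
#'   `1:max_length`), e.g. `lengths = 2` for length exactly 2.
#' @return List of metapaths ordered by length then abbreviation.
#' @examples
#' mg <- hetionet_metagraph()
#' length(enumerate_metapaths(mg, 2))  # 24 + 242
#' @export
enumerate_metapaths <- function(mg, max_length, source = NULL, target = NULL,
                                lengths = NULL) {
  stopifnot(max_length >= 1)
  if (is.null(lengths)) lengths <- seq_len(max_length)
  if (!is.null(source)) source <- mg_resolve_metanode(mg, source)
  if (!is.null(target)) target <- mg_resolve_metanode(mg, target)
  ors <- mg_orientations(mg)
  by_from <- split(seq_len(nrow(ors)), ors$from)

  # any endpoint constraint fixes the orientation; reversal-class
  # deduplication only applies to the fully unconstrained enumeration
  oriented <- !is.null(source) || !is.null(target)
  out <- list()
  seen <- new.env(parent = emptyenv())

  # walks as integer vectors of orientation-row indices, extended per level
  frontier <- if (is.null(source)) seq_len(nrow(ors)) else
    which(ors$from == source)
  walks <- lapply(frontier, function(i) i)

  for (L in seq_len(max_length)) {
    if (L %in% lengths) {
      for (wk in walks) {
        if (!is.null(target) && ors$to[wk[length(wk)]] != target) next
        mp <- new_metapath(`rownames<-`(ors[wk, , drop = FALSE], NULL))
        if (oriented) {
          out[[length(out) + 1L]] <- mp
        } else {
          ab <- metapath_abbrev(mp)
          rab <- metapath_rev_abbrev(mp)
          canon <- if (rab < ab) rab else ab
          if (is.null(seen[[canon]])) {
            seen[[canon]] <- TRUE
            out[[length(out) + 1L]] <-
              if (rab < ab) reverse_metapath(mp) else mp
          }
        }
      }
    }
    if (L == max_length) break
    walks <- unlist(lapply(walks, function(wk) {
      nxt <- by_from[[ors$to[wk[length(wk)]]]]
      lapply(nxt, function(i) c(wk, i))
    }), recursive = FALSE)
    if (length(walks) == 0) break
  }

  abbrevs <- vapply(out, metapath_abbrev, character(1))
  lens <- vapply(out, length, integer(1))
  out[order(lens, abbrevs)]
}
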