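#' Dense bit-vector encoding of a splice-graph path
#'
#' In the dense layout the first `n` bits (0 to n-1) correspond to the graph's
#' nodes and an edge between nodes `i` and `j` (`i < j`, 0-based) maps to bit
#' `n*i + j`. As literally written that edge formula collides with the node
#' bits (e.g. edge (0, j) maps to bit `j`), so by default the edge region is
#' offset by `n`: edge bit `n + n*i + j`. Set `offset = FALSE` for the
#' un-offset formula.
#'
#' @param n Number of nodes in the graph.
#' @param node_set Integer vector of 0-based node indices.
#' @param edge_set Two-column matrix of 0-based edges `(i, j)`, `i < j`.
#' @param offset Offset edge bits by `n` (default `TRUE`).
#' @return Sorted integer vector of set bit indices.
#' @export
encode_path_dense <- function(n, node_set = integer(),
                              edge_set = matrix(0L, 0, 2), offset = TRUE) {
  node_set <- as.integer(node_set)
  if (length(node_set) && any(node_set < 0L | node_set >= n)) {
    abort("node index out of range")
  }
  if (nrow(edge_set)) {
    if (any(edge_set[, 1] >= edge_set[, 2])) abort("edges must have i < j")
    if (any(edge_set < 0L | edge_set >= n)) abort("edge index out of range")
  }
  off <- if (offset) n else 0L
  ebits <- if (nrow(edge_set)) off + n * edge_set[, 1] + edge_set[, 2] else integer()
  sort(unique(c(node_set, as.integer(ebits))))
}

#' Decode a dense bit set back to nodes and edges
#'
#' Inverse of [encode_path_dense()] (offset layout only).
#'
#' @param bits Sorted integer bit indices.
#' @param n Number of nodes.
#' @return List with `nodes` (0-based indices) and `edges` (two-column
#'   matrix).
#' @export
decode_path_dense <- function(bits, n) {
  nodes <- bits[bits < n]
  eb <- bits[bits >= n] - n
  list(nodes = as.integer(nodes),
       edges = cbind(i = as.integer(eb %/% n), j = as.integer(eb %% n)))
}

new_bit_path <- function(graph, parts, edges, interrupted) {
  structure(list(
    graph_id = graph$id,
    nodes = sort(unique(unlist(parts))),
    edges = edges,
    parts = parts,
    interrupted = interrupted
  ), class = "bit_path")
}

#' @export
print.bit_path <- function(x, ...) {
  cat(sprintf("<bit_path> nodes {%s} edges {%s}%s\n",
              paste(x$nodes, collapse = ","),
              paste(apply(x$edges, 1, paste, collapse = "-"), collapse = ","),
              if (x$interrupted) " [interrupted]" else ""))
  invisible(x)
}

# map one block matrix onto the graph: ordered node chain + edges used +
# part breaks where an expected edge is absent from the graph
chain_blocks <- function(graph, blocks) {
  nd <- graph$nodes
  edge_key <- paste(graph$edges$from, graph$edges$to)
  parts <- list()
  edges <- matrix(integer(), 0, 2)
  cur <- integer()
  interrupted <- FALSE
  push_part <- function() {
    if (length(cur)) parts[[length(parts) + 1L]] <<- cur
    cur <<- integer()
  }
  prev_last <- NA_integer_
  prev_end <- NA_real_
  for (bi in seq_len(nrow(blocks))) {
    s <- blocks[bi, 1]; e <- blocks[bi, 2]
    ids <- nodes_overlapping(graph, s, e)
    if (length(ids) == 0L) { interrupted <- TRUE; push_part(); prev_last <- NA; next }
    # junction between previous block and this one
    if (bi > 1L && !is.na(prev_last)) {
      jok <- nd$end[prev_last] == prev_end && nd$start[ids[1]] == s &&
        paste(prev_last, ids[1]) %in% edge_key
      if (jok) {
        edges <- rbind(edges, c(prev_last, ids[1]))
      } else {
        interrupted <- TRUE
        push_part()
      }
    }
    # walk nodes within the block, requiring adjacency contiguity
    for (k in seq_along(ids)) {
      if (k > 1L && length(cur)) {
        p <- cur[length(cur)]
        contiguous <- nd$end[p] == nd$start[ids[k]] &&
          paste(p, ids[k]) %in% edge_key
        if (contiguous) {
          edges <- rbind(edges, c(p, ids[k]))
        } else {
          interrupted <- TRUE
          push_part()
        }
      }
      cur <- c(cur, ids[k])
    }
    prev_last <- ids[length(ids)]
    prev_end <- e
  }
  push_part()
  list(parts = parts, edges = edges, interrupted = interrupted)
}

#' Sparse path encoding of a read or fragment
#'
#' Encodes an alignment (and optionally its mate) as the set of splice-graph
#' nodes it overlaps and the junction/adjacency edges its blocks span. When a
#' junction of the read is absent from the graph (filtered), the read is
#' re-encoded skipping that edge and flagged interrupted; mate pairs yield an
#' interrupted path with no bits for the unobserved inner gap.
#'
#' @param graph A `splice_graph`.
#' @param blocks Two-column exon-block matrix (0-based half-open).
#' @param mate_blocks Optional block matrix of the mate alignment.
#' @return A `bit_path`: list with `graph_id`, `nodes`, `edges` (two-column
#'   matrix of node-id pairs), `parts` (ordered node chains) and
#'   `interrupted`.
#' @export
encode_path_sparse <- function(graph, blocks, mate_blocks = NULL) {
  c1 <- chain_blocks(graph, blocks)
  if (is.null(mate_blocks)) {
    return(new_bit_path(graph, c1$parts, c1$edges,
                        c1$interrupted || length(c1$parts) > 1L))
  }
  inner <- c(blocks[nrow(blocks), 2], mate_blocks[1, 1])
  c2 <- chain_blocks(graph, mate_blocks)
  parts <- c(c1$parts, c2$parts)
  edges <- rbind(c1$edges, c2$edges)
  # mates overlapping on the graph: merge their chains when they agree
  if (length(c1$parts) && length(c2$parts)) {
    p1 <- c1$parts[[length(c1$parts)]]
    p2 <- c2$parts[[1]]
    hit <- match(p2[1], p1)
    if (!is.na(hit)) {
      tail1 <- p1[hit:length(p1)]
      if (identical(tail1, p2[seq_along(tail1)])) {
        merged <- c(p1[seq_len(hit - 1L)], p2)
        parts <- c(c1$parts[-length(c1$parts)], list(merged),
                   c2$parts[-1])
      }
    }
  }
  interrupted <- length(parts) > 1L || c1$interrupted || c2$interrupted
  out <- new_bit_path(graph, parts, edges, interrupted)
  attr(out, "inner") <- inner
  out
}

# transcript path (continuous node chain) -> bit_path
transcript_path <- function(graph, node_chain) {
  if (length(node_chain) < 2L) {
    return(new_bit_path(graph, list(as.integer(node_chain)),
                        matrix(integer(), 0, 2), FALSE))
  }
  edges <- cbind(node_chain[-length(node_chain)], node_chain[-1])
  new_bit_path(graph, list(as.integer(node_chain)), edges, FALSE)
}

#' Read/transcript path compatibility
#'
#' A continuous read path is compatible with a transcript path iff every node
#' and edge of the read is on the transcript and the transcript visits no
#' extra node between the read's first and last node — i.e. the read's node
#' chain is a contiguous subsequence of the transcript's. An interrupted
#' fragment only requires each of its parts to embed contiguously, in order;
#' the transcript (a connected path) bridges the unobserved gaps.
#'
#' @param read_path,transcript_path `bit_path` objects on the same graph;
#'   the transcript path must be continuous.
#' @return `TRUE` or `FALSE`.
#' @export
path_compatible <- function(read_path, transcript_path) {
  if (read_path$graph_id != transcript_path$graph_id) {
    abort("paths were encoded on different graphs")
  }
  if (length(read_path$parts) == 0L) return(FALSE)
  stopifnot(length(transcript_path$parts) == 1L)
  tseq <- transcript_path$parts[[1]]
  tedge <- paste(transcript_path$edges[, 1], transcript_path$edges[, 2])
  if (nrow(read_path$edges)) {
    if (!all(paste(read_path$edges[, 1], read_path$edges[, 2]) %in% tedge)) {
      return(FALSE)
    }
  }
  last_pos <- 0L
  for (p in read_path$parts) {
    pos <- match(p[1], tseq)
    if (is.na(pos) || pos <= last_pos) return(FALSE)
    if (pos + length(p) - 1L > length(tseq)) return(FALSE)
    if (!identical(tseq[pos:(pos + length(p) - 1L)], as.integer(p))) {
      return(FALSE)
    }
    last_pos <- pos + length(p) - 1L
  }
  TRUE
}

#' Implied inner gap of a fragment on a transcript
#'
#' For an interrupted mate-pair fragment compatible with a transcript path,
#' the unobserved inner distance the fragment spans on that transcript: the
#' transcript-space distance between the facing mate ends, i.e. the residues
#' of the flanking nodes plus the full lengths of the transcript nodes in
#' between. Continuous (merged or single-end) fragments have gap 0. Together
#' with [path_compatible()] this carries the fragment-length information a
#' pure bit-set containment check ignores: a mate pair whose implied gap on
#' a longer isoform would have to swallow a whole extra exon can be rejected
#' on that isoform.
#'
#' @param read_path,transcript_path `bit_path` objects on the same graph
#'   (the pair is assumed [path_compatible()]).
#' @param graph The `splice_graph` (for node lengths).
#' @return Implied inner gap in transcript bp (0 when not applicable).
#' @export
implied_inner_gap <- function(read_path, transcript_path, graph) {
  if (length(read_path$parts) < 2L) return(0)
  inner <- attr(read_path, "inner")   # c(end of part 1, start of part 2)
  if (is.null(inner)) return(0)
  tseq <- transcript_path$parts[[1]]
  nlen <- graph$nodes$end - graph$nodes$start
  p1 <- read_path$parts[[1]]
  p2 <- read_path$parts[[length(read_path$parts)]]
  i1 <- match(p1[length(p1)], tseq)
  i2 <- match(p2[1], tseq)
  if (is.na(i1) || is.na(i2) || i2 <= i1) return(0)
  within1 <- graph$nodes$end[tseq[i1]] - inner[1]
  within2 <- inner[2] - graph$nodes$start[tseq[i2]]
  between <- if (i2 > i1 + 1L) sum(nlen[tseq[(i1 + 1L):(i2 - 1L)]]) else 0
  within1 + between + within2
}
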