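#' Build a splice graph from a bundle's alignments
#'
#' Nodes are maximal exonic segments delimited by the union of all junction
#' donor/acceptor sites and coverage start/end points (from reads and, when
#' given, guide transcripts); edges are spliced junctions or within-exon
#' adjacencies between genomically contiguous, co-covered segments. The graph
#' is a DAG whose node order is genomic order.
#'
#' @param alignments Collapsed-alignment tibble ([collapse_alignments()]);
#'   the `count` column is the alignment weight.
#' @param guides Optional guide transcript tibble (see [read_gtf()]); guide
#'   exon boundaries and junction edges are added with zero read support —
#'   they constrain structure, not abundance.
#' @param strand Strand label stored on the graph (`"+"`, `"-"`, `"*"`).
#' @return An object of class `splice_graph`: list with `nodes` (tibble
#'   `id`, `start`, `end`, `coverage`, `unspliced_cov`), `edges` (tibble
#'   `from`, `to`, `type`, `support`, `guide`), `n`, `rname`, `strand`,
#'   `span`, and the per-bp coverage vector `covvec` (offset `span[1]`).
#' @export
build_splice_graph <- function(alignments, guides = NULL, strand = NULL) {
  rname <- if (nrow(alignments)) alignments$rname[1] else guides$rname[1]
  if (is.null(strand)) {
    s <- if (nrow(alignments)) unique(alignments$strand) else "*"
    s <- setdiff(s, "*")
    strand <- if (length(s) == 1L) s else "*"
  }
  gx <- guide_exons(guides, rname, strand)
  if (nrow(alignments) == 0L && nrow(gx) == 0L) {
    return(empty_graph(rname, strand))
  }

  starts <- unlist(lapply(alignments$blocks, function(b) b[, 1]))
  ends <- unlist(lapply(alignments$blocks, function(b) b[, 2]))
  lo <- min(c(starts, gx$start)); hi <- max(c(ends, gx$end))

  # per-bp coverage via difference arrays (offset lo)
  width <- hi - lo
  delta <- numeric(width + 1L)
  delta_un <- numeric(width + 1L)
  for (i in seq_len(nrow(alignments))) {
    b <- alignments$blocks[[i]]
    w <- alignments$count[i]
    s <- b[, 1] - lo + 1L; e <- b[, 2] - lo + 1L
    delta[s] <- delta[s] + w
    delta[e] <- delta[e] - w
    if (nrow(b) == 1L) {
      delta_un[s] <- delta_un[s] + w
      delta_un[e] <- delta_un[e] - w
    }
  }
  covvec <- cumsum(delta)[seq_len(width)]
  covvec_un <- cumsum(delta_un)[seq_len(width)]

  # node boundaries: junction donor/acceptor sites, coverage start/end
  # transitions, guide exon boundaries, and the bundle ends
  jsites <- unlist(lapply(alignments$blocks, function(b) {
    if (nrow(b) < 2L) return(numeric())
    c(b[-nrow(b), 2], b[-1, 1])
  }))
  covzero <- c(TRUE, covvec == 0, TRUE)
  trans <- which(covzero[-1] != covzero[-length(covzero)]) - 1L + lo
  bounds <- sort(unique(c(lo, hi, jsites, trans, gx$start, gx$end)))

  seg <- tibble(start = bounds[-length(bounds)], end = bounds[-1])
  seg_cov_sum <- cumsum(c(0, covvec))[seg$end - lo + 1L] -
    cumsum(c(0, covvec))[seg$start - lo + 1L]
  seg_un_sum <- cumsum(c(0, covvec_un))[seg$end - lo + 1L] -
    cumsum(c(0, covvec_un))[seg$start - lo + 1L]
  covered <- covvec[seg$start - lo + 1L] > 0
  in_guide <- vapply(seq_len(nrow(seg)), function(i) {
    any(gx$start < seg$end[i] & gx$end > seg$start[i])
  }, logical(1))
  keep <- covered | in_guide
  nodes <- seg[keep, , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  nodes$coverage <- (seg_cov_sum / (seg$end - seg$start))[keep]
  nodes$unspliced_cov <- (seg_un_sum / (seg$end - seg$start))[keep]
  nodes$alive <- TRUE
  nodes <- nodes[, c("id", "start", "end", "coverage", "unspliced_cov", "alive")]

  # junction edges (read-supported, then guide-only)
  jt <- junction_table(with_read_cols(alignments))
  gj <- guide_junctions(guides, rname, strand)
  if (nrow(gj)) {
    gj_new <- dplyr::anti_join(gj, jt, by = c("donor", "acceptor"))
  } else {
    gj_new <- gj
  }
  jall <- bind_rows(
    if (nrow(jt)) mutate(jt, guide = .data$donor %in% gj$donor &
                           paste(.data$donor, .data$acceptor) %in%
                             paste(gj$donor, gj$acceptor)) else NULL,
    if (nrow(gj_new)) tibble(donor = gj_new$donor, acceptor = gj_new$acceptor,
                             support = 0, guide = TRUE) else NULL
  )
  edges <- NULL
  if (!is.null(jall) && nrow(jall)) {
    from <- match(jall$donor, nodes$end)
    to <- match(jall$acceptor, nodes$start)
    ok <- !is.na(from) & !is.na(to)
    edges <- tibble(from = from[ok], to = to[ok], type = "junction",
                    support = jall$support[ok], guide = jall$guide[ok])
  }

  # adjacency edges between contiguous co-covered nodes
  if (nrow(nodes) > 1L) {
    cand <- which(nodes$end[-nrow(nodes)] == nodes$start[-1])
    if (length(cand)) {
      bpt <- nodes$end[cand]
      sup <- vapply(bpt, function(p) {
        sum(vapply(seq_len(nrow(alignments)), function(i) {
          b <- alignments$blocks[[i]]
          if (any(b[, 1] < p & b[, 2] > p)) alignments$count[i] else 0
        }, numeric(1)))
      }, numeric(1))
      gsp <- vapply(bpt, function(p) any(gx$start < p & gx$end > p), logical(1))
      ok <- sup > 0 | gsp
      if (any(ok)) {
        edges <- bind_rows(edges, tibble(
          from = cand[ok], to = cand[ok] + 1L, type = "adjacency",
          support = sup[ok], guide = gsp[ok]
        ))
      }
    }
  }
  if (is.null(edges)) {
    edges <- tibble(from = integer(), to = integer(), type = character(),
                    support = numeric(), guide = logical())
  }
  edges <- arrange(edges, .data$from, .data$to)
  stopifnot(nrow(edges) == 0L || all(edges$from < edges$to))

  structure(list(
    id = next_graph_id(), rname = rname, strand = strand,
    span = c(lo, hi), n = nrow(nodes), nodes = nodes, edges = edges,
    covvec = covvec
  ), class = "splice_graph")
}

empty_graph <- function(rname, strand) {
  structure(list(
    id = next_graph_id(), rname = rname, strand = strand,
    span = c(0, 0), n = 0L,
    nodes = tibble(id = integer(), start = numeric(), end = numeric(),
                   coverage = numeric(), unspliced_cov = numeric(),
                   alive = logical()),
    edges = tibble(from = integer(), to = integer(), type = character(),
                   support = numeric(), guide = logical()),
    covvec = numeric()
  ), class = "splice_graph")
}

# collapsed tibble -> shape read_junctions() expects
with_read_cols <- function(collapsed) {
  collapsed$weight <- collapsed$count
  collapsed$nm <- 0
  collapsed$aligned_len <- vapply(collapsed$blocks,
                                  function(b) sum(b[, 2] - b[, 1]), numeric(1))
  collapsed
}

guide_exons <- function(guides, rname, strand) {
  if (is.null(guides) || nrow(guides) == 0L) {
    return(tibble(start = numeric(), end = numeric()))
  }
  g <- guides[guides$rname == rname &
                (strand == "*" | guides$strand == "*" | guides$strand == strand), ]
  if (nrow(g) == 0L) return(tibble(start = numeric(), end = numeric()))
  ex <- do.call(rbind, g$exons)
  tibble(start = ex[, 1], end = ex[, 2])
}

guide_junctions <- function(guides, rname, strand) {
  if (is.null(guides) || nrow(guides) == 0L) {
    return(tibble(donor = numeric(), acceptor = numeric()))
  }
  g <- guides[guides$rname == rname &
                (strand == "*" | guides$strand == "*" | guides$strand == strand), ]
  if (nrow(g) == 0L) return(tibble(donor = numeric(), acceptor = numeric()))
  jn <- do.call(rbind, lapply(g$exons, block_introns))
  if (is.null(jn) || nrow(jn) == 0L) {
    return(tibble(donor = numeric(), acceptor = numeric()))
  }
  distinct(tibble(donor = jn[, 1], acceptor = jn[, 2]))
}

#' Split a bundle's alignments by strand
#'
#' Alignments with a known transcription strand go to their strand's graph;
#' strand-unknown (typically unspliced) alignments contribute coverage to
#' every strand present. When no stranded alignment exists the bundle stays a
#' single unknown-strand group.
#'
#' @param alignments Collapsed-alignment tibble.
#' @return Named list of tibbles, one per strand group (`"+"`, `"-"` or
#'   `"*"`).
#' @export
split_by_strand <- function(alignments) {
  strands <- setdiff(unique(alignments$strand), "*")
  if (length(strands) == 0L) return(list("*" = alignments))
  setNames(lapply(strands, function(s) {
    alignments[alignments$strand %in% c(s, "*"), , drop = FALSE]
  }), strands)
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("<splice_graph> %s:%d-%d (%s): %d nodes, %d edges\n",
              x$rname, x$span[1], x$span[2], x$strand, x$n, nrow(x$edges)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.splice_graph <- function(x, ...) {
  if (nrow(x$edges) == 0L) {
    return(tibble(from = integer(), to = integer(), type = character(),
                  support = numeric(), guide = logical(),
                  from_start = numeric(), to_end = numeric()))
  }
  x$edges %>%
    mutate(from_start = x$nodes$start[.data$from],
           to_end = x$nodes$end[.data$to])
}

#' @exportS3Method generics::glance
glance.splice_graph <- function(x, ...) {
  tibble(rname = x$rname, strand = x$strand,
         span_start = x$span[1], span_end = x$span[2],
         n_nodes = sum(x$nodes$alive), n_edges = nrow(x$edges),
         n_junctions = sum(x$edges$type == "junction"),
         max_coverage = if (x$n) max(x$nodes$coverage) else 0)
}

# nodes overlapping [s, e); returns integer ids in genomic order
nodes_overlapping <- function(graph, s, e) {
  nd <- graph$nodes
  which(nd$alive & nd$start < e & nd$end > s)
}
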