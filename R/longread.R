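#' Tabulate splice-site support
#'
#' One row per distinct donor or acceptor site observed in the bundle, with
#' total (weighted) read support and support from low-error alignments only.
#' Guide transcripts, when given, contribute weight-1 low-error support at
#' each of their splice sites.
#'
#' @param reads Alignment tibble.
#' @param low_error_rate Mismatch-rate cutoff for low-error support
#'   (default 0.02).
#' @param guides Optional guide transcript tibble.
#' @return Tibble `rname`, `site` (0-based coordinate), `side`
#'   (`"donor"`/`"acceptor"`), `support`, `low_error_support`.
#' @export
splice_site_support <- function(reads, low_error_rate = 0.02, guides = NULL) {
  jn <- read_junctions(reads)
  sites <- bind_rows(
    tibble(rname = jn$rname, site = jn$donor, side = "donor",
           weight = jn$weight, low = jn$mm_rate <= low_error_rate),
    tibble(rname = jn$rname, site = jn$acceptor, side = "acceptor",
           weight = jn$weight, low = jn$mm_rate <= low_error_rate)
  )
  if (!is.null(guides) && nrow(guides)) {
    gj <- do.call(rbind, lapply(seq_len(nrow(guides)), function(i) {
      b <- block_introns(guides$exons[[i]])
      if (nrow(b) == 0L) return(NULL)
      cbind(b, i = i)
    }))
    if (!is.null(gj) && nrow(gj)) {
      sites <- bind_rows(sites,
        tibble(rname = guides$rname[gj[, "i"]], site = gj[, "donor"],
               side = "donor", weight = 1, low = TRUE),
        tibble(rname = guides$rname[gj[, "i"]], site = gj[, "acceptor"],
               side = "acceptor", weight = 1, low = TRUE))
    }
  }
  if (nrow(sites) == 0L) {
    return(tibble(rname = character(), site = numeric(), side = character(),
                  support = numeric(), low_error_support = numeric()))
  }
  sites %>%
    group_by(.data$rname, .data$site, .data$side) %>%
    summarise(support = sum(.data$weight),
              low_error_support = sum(.data$weight[.data$low]),
              .groups = "drop") %>%
    arrange(.data$rname, .data$site)
}

#' Correct splice sites of high-error reads
#'
#' For every splice site of a read whose alignment mismatch rate exceeds
#' `high_error_threshold`: if no low-error alignment supports the site, the
#' site is moved to the nearby site (within `window` bp) that is supported by
#' the most alignments among all nearby low-error-supported sites (ties:
#' smallest distance, then smaller coordinate). Low-error reads are never
#' modified. A correction that would create an empty exon or a non-positive
#' intron is skipped and the read left unchanged at that site.
#'
#' @param reads Alignment tibble.
#' @param support Splice-site support table ([splice_site_support()]), built
#'   from all alignments of the bundle; computed from `reads` when `NULL`.
#' @param window Search window in bp (default 10).
#' @param high_error_threshold Mismatch rate above which a read is eligible
#'   for correction (default 0.02).
#' @param guides Optional guide transcripts contributing candidate sites.
#' @return List with `reads` (corrected tibble) and `log` (tibble `qname`,
#'   `side`, `old_site`, `new_site`, `support`, `applied`).
#' @export
correct_splice_sites <- function(reads, support = NULL, window = 10,
                                 high_error_threshold = 0.02, guides = NULL) {
  if (is.null(support)) {
    support <- splice_site_support(reads, low_error_rate = high_error_threshold,
                                   guides = guides)
  }
  log <- tibble(qname = character(), side = character(), old_site = numeric(),
                new_site = numeric(), support = numeric(), applied = logical())
  if (nrow(reads) == 0L) return(list(reads = reads, log = log))
  rate <- reads$nm / pmax(reads$aligned_len, 1)
  hi <- which(rate > high_error_threshold &
                vapply(reads$blocks, nrow, 0L) > 1L)
  for (i in hi) {
    b <- reads$blocks[[i]]
    stab <- support[support$rname == reads$rname[i], ]
    for (j in seq_len(nrow(b) - 1L)) {
      for (side in c("donor", "acceptor")) {
        old <- as.numeric(if (side == "donor") b[j, 2] else b[j + 1L, 1])
        s_here <- stab[stab$side == side & stab$site == old, ]
        if (nrow(s_here) && s_here$low_error_support[1] > 0) next
        cand <- stab[stab$side == side & stab$low_error_support > 0 &
                       abs(stab$site - old) <= window & stab$site != old, ]
        if (nrow(cand) == 0L) next
        cand <- cand[order(-cand$support, abs(cand$site - old), cand$site), ]
        new <- cand$site[1]
        b2 <- b
        if (side == "donor") b2[j, 2] <- new else b2[j + 1L, 1] <- new
        valid <- all(b2[, 2] > b2[, 1]) &&
          all(b2[-1, 1] > b2[-nrow(b2), 2])
        log <- bind_rows(log, tibble(
          qname = reads$qname[i], side = side, old_site = old,
          new_site = new, support = cand$support[1], applied = valid
        ))
        if (valid) b <- b2
      }
    }
    reads$blocks[[i]] <- b
    reads$start[i] <- b[1, 1]
    reads$end[i] <- b[nrow(b), 2]
    reads$aligned_len[i] <- sum(b[, 2] - b[, 1])
  }
  list(reads = reads, log = log)
}

#' Prune a splice graph to a node budget
#'
#' Removes edges from the least read-supported to the most supported until
#' the number of (live) nodes falls below `max_nodes` or no removable edge
#' remains. A node is dropped when it loses all incident edges and has no
#' unspliced read coverage, so single-exon transcripts survive. Guide-derived
#' edges are never removed. Intended for the long-read mode, where spurious
#' splice sites from random indels can blow the graph up.
#'
#' @param graph A `splice_graph`.
#' @param max_nodes Node budget (default 1000).
#' @return List with `graph` (pruned; node ids are stable, removed nodes are
#'   flagged `alive = FALSE`) and `events` (tibble `from`, `to`, `support`,
#'   `node_count_after`, in removal order).
#' @export
prune_graph <- function(graph, max_nodes = 1000) {
  events <- tibble(from = integer(), to = integer(), support = numeric(),
                   node_count_after = integer())
  n_alive <- sum(graph$nodes$alive)
  removable <- which(!graph$edges$guide)
  if (length(removable)) {
    ord <- removable[order(graph$edges$support[removable],
                           graph$edges$from[removable],
                           graph$edges$to[removable])]
  } else {
    ord <- integer()
  }
  drop_edge <- rep(FALSE, nrow(graph$edges))
  deg <- tabulate(c(graph$edges$from, graph$edges$to),
                  nbins = nrow(graph$nodes))
  ev_from <- integer(); ev_to <- integer(); ev_sup <- numeric()
  ev_n <- integer()
  for (k in ord) {
    if (n_alive < max_nodes) break
    ef <- graph$edges$from[k]; et <- graph$edges$to[k]
    drop_edge[k] <- TRUE
    for (v in c(ef, et)) {
      deg[v] <- deg[v] - 1L
      if (deg[v] == 0L && graph$nodes$unspliced_cov[v] == 0 &&
          graph$nodes$alive[v]) {
        graph$nodes$alive[v] <- FALSE
        n_alive <- n_alive - 1L
      }
    }
    ev_from <- c(ev_from, ef); ev_to <- c(ev_to, et)
    ev_sup <- c(ev_sup, graph$edges$support[k]); ev_n <- c(ev_n, n_alive)
  }
  events <- tibble(from = ev_from, to = ev_to, support = ev_sup,
                   node_count_after = ev_n)
  graph$edges <- graph$edges[!drop_edge, , drop = FALSE]
  graph$n <- n_alive
  list(graph = graph, events = events)
}

#' Re-encode a read path after graph pruning
#'
#' Clears bits for pruned nodes and removed edges. A read that spanned a node
#' no longer in the graph is represented as an interrupted read (disjoint
#' surviving parts), analogous to a mate pair; a read whose bits are all
#' pruned becomes an empty path and is excluded from assembly.
#'
#' @param read_path `bit_path` encoded on the pre-pruning graph.
#' @param pruned Pruned `splice_graph` from [prune_graph()] (same graph,
#'   stable node ids).
#' @return A `bit_path` on the pruned graph.
#' @export
reencode_after_pruning <- function(read_path, pruned) {
  edge_key <- paste(pruned$edges$from, pruned$edges$to)
  parts <- list()
  edges <- matrix(integer(), 0, 2)
  interrupted <- read_path$interrupted
  for (p in read_path$parts) {
    cur <- integer()
    for (k in seq_along(p)) {
      if (!pruned$nodes$alive[p[k]]) {
        interrupted <- TRUE
        if (length(cur)) { parts <- c(parts, list(cur)); cur <- integer() }
        next
      }
      if (length(cur)) {
        if (paste(cur[length(cur)], p[k]) %in% edge_key) {
          edges <- rbind(edges, c(cur[length(cur)], p[k]))
        } else {
          interrupted <- TRUE
          parts <- c(parts, list(cur))
          cur <- integer()
        }
      }
      cur <- c(cur, p[k])
    }
    if (length(cur)) parts <- c(parts, list(cur))
  }
  pth <- new_bit_path(pruned, parts, edges,
                      interrupted || length(parts) > 1L)
  pth
}
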