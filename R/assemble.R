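#' Heaviest path through a splice graph
#'
#' Seeds at the maximal-coverage live node and greedily extends in both
#' directions along the incident edge with maximal support (ties: larger
#' coverage on the candidate node, then smaller node index) until no incident
#' edge remains. When `fragments` is supplied, a candidate edge is scored by
#' the remaining weight of fragments that span it and do not conflict with
#' the partial path (a fragment conflicts when it touches a node the path
#' skips within its span, or an edge the path contradicts) — this keeps the
#' residual unique reads of two different isoforms from being welded into one
#' chimeric path. Edges with no scoring support left fall back to the
#' remaining, then the original, support ranking, so a residual isoform
#' sharing exons with an already-extracted one is not truncated.
#'
#' @param graph A `splice_graph`.
#' @param node_cov Remaining per-node coverage (defaults to the graph's).
#' @param edge_sup Remaining per-edge support (defaults to the graph's).
#' @param orig_sup Original per-edge support used as final fallback ranking.
#' @param fragments Optional fragment state from `encode_fragments()` with
#'   current `weight`s, used for consistency-guided extension.
#' @return Integer vector of node ids (genomic order), or `NULL` for an
#'   empty graph.
#' @export
heaviest_path <- function(graph, node_cov = NULL, edge_sup = NULL,
                          orig_sup = NULL, fragments = NULL) {
  alive <- which(graph$nodes$alive)
  if (length(alive) == 0L) return(NULL)
  if (is.null(node_cov)) node_cov <- graph$nodes$coverage
  if (is.null(edge_sup)) edge_sup <- graph$edges$support
  if (is.null(orig_sup)) orig_sup <- graph$edges$support
  cov_alive <- ifelse(graph$nodes$alive, node_cov, -Inf)
  if (all(cov_alive <= 0)) return(NULL)
  seed <- which.max(cov_alive)

  by_edge <- if (!is.null(fragments)) attr(fragments, "by_edge") else NULL

  # does active fragment fid fit on a transcript containing the partial
  # chain (ascending node ids) plus candidate edge (a, b)?
  frag_ok <- function(fid, pv, pe) {
    fn <- fragments$path[[fid]]$nodes
    fe <- fragments$path[[fid]]$edges
    lo <- pv[1]; hi <- pv[length(pv)]
    if (any(fn > lo & fn < hi & !fn %in% pv)) return(FALSE)
    if (nrow(fe)) {
      inside <- fe[, 1] >= lo & fe[, 2] <= hi
      if (any(inside & !(paste(fe[, 1], fe[, 2]) %in% pe))) return(FALSE)
      if (any(fe[, 1] < lo & fe[, 2] > lo)) return(FALSE)
      if (any(fe[, 1] < hi & fe[, 2] > hi)) return(FALSE)
    }
    TRUE
  }

  consistent_sup <- function(cand_edges, chain, pe) {
    vapply(seq_len(nrow(cand_edges)), function(k) {
      a <- cand_edges[k, 1]; b <- cand_edges[k, 2]
      key <- paste(a, b)
      fids <- by_edge[[key]]
      if (is.null(fids)) return(0)
      fids <- fids[fragments$weight[fids] > 0]
      if (length(fids) == 0L) return(0)
      pv <- sort(unique(c(chain, a, b)))
      pe2 <- c(pe, key)
      sum(fragments$weight[fids][vapply(fids, frag_ok, logical(1),
                                        pv = pv, pe = pe2)])
    }, numeric(1))
  }

  chain <- seed
  pe <- character()
  extend <- function(forward) {
    repeat {
      v <- if (forward) chain[length(chain)] else chain[1]
      cand <- if (forward) which(graph$edges$from == v) else
        which(graph$edges$to == v)
      if (length(cand) == 0L) break
      nb <- if (forward) graph$edges$to[cand] else graph$edges$from[cand]
      sup <- NULL
      if (!is.null(by_edge)) {
        ce <- cbind(ifelse(rep(forward, length(cand)), v, nb),
                    ifelse(rep(forward, length(cand)), nb, v))
        sup <- consistent_sup(ce, chain, pe)
      }
      if (is.null(sup) || all(sup <= 0)) sup <- edge_sup[cand]
      if (all(sup <= 0)) sup <- orig_sup[cand]
      k <- order(-sup, -node_cov[nb], nb)[1]
      pe <<- c(pe, paste(if (forward) v else nb[k],
                         if (forward) nb[k] else v))
      chain <<- if (forward) c(chain, nb[k]) else c(nb[k], chain)
    }
  }
  extend(TRUE)
  extend(FALSE)
  as.integer(chain)
}

# Per-fragment encoding of a strand group's collapsed alignments against a
# graph: one row per fragment with its bit path, weight, aligned bases and
# per-node base contributions.
encode_fragments <- function(graph, alignments) {
  if (nrow(alignments) == 0L) {
    return(tibble(id = integer(), path = list(), weight = numeric(),
                  bases = numeric(), node_ids = list(), node_bases = list(),
                  edge_keys = list()))
  }
  frags <- fragment_table(alignments)
  n <- nrow(frags)
  paths <- vector("list", n)
  bases <- numeric(n)
  node_ids <- vector("list", n)
  node_bases <- vector("list", n)
  edge_keys <- vector("list", n)
  blk <- setNames(alignments$blocks, alignments$key)
  for (i in seq_len(n)) {
    b1 <- blk[[frags$key1[i]]]
    b2 <- if (is.na(frags$key2[i])) NULL else blk[[frags$key2[i]]]
    if (!is.null(b2) && b2[1, 1] < b1[1, 1]) { tmp <- b1; b1 <- b2; b2 <- tmp }
    pth <- encode_path_sparse(graph, b1, b2)
    allb <- rbind(b1, b2)
    contrib <- node_overlap(graph, allb)
    paths[[i]] <- pth
    bases[i] <- sum(allb[, 2] - allb[, 1])
    node_ids[[i]] <- contrib$ids
    node_bases[[i]] <- contrib$bases
    edge_keys[[i]] <- if (nrow(pth$edges)) {
      paste(pth$edges[, 1], pth$edges[, 2])
    } else character()
  }
  out <- tibble(id = seq_len(n), path = paths, weight = frags$weight,
                bases = bases, node_ids = node_ids, node_bases = node_bases,
                edge_keys = edge_keys)
  ek <- unlist(edge_keys, use.names = FALSE)
  attr(out, "by_edge") <- split(rep.int(seq_len(n), lengths(edge_keys)), ek)
  out
}

# collapsed alignments -> fragments (key1, key2, weight), pairing via
# mate_links (each unordered pair once), leftover counts unpaired
fragment_table <- function(alignments) {
  k1 <- character(); k2 <- character(); w <- numeric()
  for (i in seq_len(nrow(alignments))) {
    k <- alignments$key[i]
    ml <- alignments$mate_links[[i]]
    paired_w <- 0
    if (!is.null(ml) && nrow(ml)) {
      sel <- ml$key >= k
      paired_w <- sum(ml$pair_count)
      if (any(sel)) {
        k1 <- c(k1, rep(k, sum(sel))); k2 <- c(k2, ml$key[sel])
        w <- c(w, ml$pair_count[sel])
      }
    }
    rest <- alignments$count[i] - paired_w
    if (rest > 1e-9) {
      k1 <- c(k1, k); k2 <- c(k2, NA_character_); w <- c(w, rest)
    }
  }
  tibble(key1 = k1, key2 = k2, weight = w)
}

node_overlap <- function(graph, blocks) {
  ids <- integer(); bases <- numeric()
  for (bi in seq_len(nrow(blocks))) {
    ov <- nodes_overlapping(graph, blocks[bi, 1], blocks[bi, 2])
    if (length(ov) == 0L) next
    w <- pmin(graph$nodes$end[ov], blocks[bi, 2]) -
      pmax(graph$nodes$start[ov], blocks[bi, 1])
    ids <- c(ids, ov); bases <- c(bases, w)
  }
  if (anyDuplicated(ids)) {
    agg <- rowsum(bases, ids)
    ids <- as.integer(rownames(agg)); bases <- as.numeric(agg)
  }
  list(ids = ids, bases = bases)
}

#' Quantify a path and subtract its reads
#'
#' Estimates the abundance of a candidate path as the minimum remaining
#' support, over the path's edges, contributed by fragments compatible with
#' the path (mean compatible node coverage for single-node paths; edges no
#' compatible fragment crosses — possible when the path traverses exhausted
#' residual structure — do not cap the estimate). The full remaining mass of
#' every compatible fragment is then assigned to the path and removed from
#' the per-node coverage and per-edge support pools, so the remaining read
#' mass decreases by exactly the assigned mass.
#'
#' @param graph A `splice_graph`.
#' @param chain Integer node chain from [heaviest_path()].
#' @param reads Fragment tibble from `encode_fragments()` with current
#'   `weight`.
#' @param node_cov,edge_sup Remaining per-node coverage / per-edge support.
#' @return List with `estimate` (numeric or `NA` if rejected), updated
#'   `reads`, `node_cov`, `edge_sup`, and `assigned_mass`.
#' @export
quantify_and_subtract <- function(graph, chain, reads, node_cov, edge_sup) {
  tpath <- transcript_path(graph, chain)
  active <- which(reads$weight > 0)
  compat <- active[vapply(active, function(i) {
    path_compatible(reads$path[[i]], tpath)
  }, logical(1))]
  if (length(compat) == 0L || sum(reads$weight[compat]) <= 0) {
    return(list(estimate = NA_real_, reads = reads, node_cov = node_cov,
                edge_sup = edge_sup, assigned_mass = 0))
  }
  w <- reads$weight[compat]
  if (length(chain) > 1L) {
    ck <- paste(chain[-length(chain)], chain[-1])
    esup <- vapply(ck, function(k) {
      sum(w[vapply(reads$edge_keys[compat], function(ks) k %in% ks, logical(1))])
    }, numeric(1))
    esup <- esup[esup > 0]
    estimate <- if (length(esup)) min(esup) else sum(w)
  } else {
    nid <- chain[1]
    len <- graph$nodes$end[nid] - graph$nodes$start[nid]
    bases <- vapply(compat, function(i) {
      j <- match(nid, reads$node_ids[[i]])
      if (is.na(j)) 0 else reads$node_bases[[i]][j]
    }, numeric(1))
    estimate <- sum(w * bases) / len
  }

  assigned <- sum(reads$weight[compat] * reads$bases[compat])
  for (i in compat) {
    wi <- reads$weight[i]
    ids <- reads$node_ids[[i]]
    lens <- graph$nodes$end[ids] - graph$nodes$start[ids]
    node_cov[ids] <- pmax(0, node_cov[ids] - wi * reads$node_bases[[i]] / lens)
    ek <- reads$edge_keys[[i]]
    if (length(ek)) {
      idx <- match(ek, paste(graph$edges$from, graph$edges$to))
      idx <- idx[!is.na(idx)]
      edge_sup[idx] <- pmax(0, edge_sup[idx] - wi)
    }
  }
  be <- attr(reads, "by_edge")
  reads$weight[compat] <- 0
  attr(reads, "by_edge") <- be
  list(estimate = estimate, reads = reads, node_cov = node_cov,
       edge_sup = edge_sup, assigned_mass = assigned)
}

chain_to_exons <- function(graph, chain) {
  nd <- graph$nodes
  ex <- list()
  cs <- nd$start[chain[1]]; ce <- nd$end[chain[1]]
  for (v in chain[-1]) {
    if (nd$start[v] == ce) {
      ce <- nd$end[v]
    } else {
      ex[[length(ex) + 1L]] <- c(cs, ce)
      cs <- nd$start[v]; ce <- nd$end[v]
    }
  }
  ex[[length(ex) + 1L]] <- c(cs, ce)
  mat <- do.call(rbind, ex)
  colnames(mat) <- c("start", "end")
  mat
}

#' Assemble one strand group of a bundle
#'
#' Iterates [heaviest_path()] + [quantify_and_subtract()] until no node
#' retains `min_transcript_coverage` unassigned coverage (or the iteration
#' cap, one more than the edge count, is hit), then re-estimates the coverage
#' of the accepted candidate set by EM over all fragments, applies the
#' isoform-fraction and coverage thresholds, optionally trims low-coverage
#' transcript ends, and labels candidates whose intron chain matches a guide.
#'
#' @param graph `splice_graph` for the strand group (pruned already in
#'   long-read mode).
#' @param alignments Collapsed alignments of the strand group.
#' @param params [assembly_params()].
#' @param guides Optional guide transcript tibble.
#' @return Transcript tibble: `rname`, `strand`, `exons`, `coverage`,
#'   `source`, `n_exons`.
#' @export
assemble_graph <- function(graph, alignments, params = assembly_params(),
                           guides = NULL) {
  empty <- tibble(rname = character(), strand = character(), exons = list(),
                  coverage = numeric(), source = character(),
                  n_exons = integer())
  if (sum(graph$nodes$alive) == 0L) return(empty)
  reads <- encode_fragments(graph, alignments)
  reads <- reads[lengths(lapply(reads$path, `[[`, "parts")) > 0, , drop = FALSE]
  if (nrow(reads) == 0L) return(empty)
  node_cov <- ifelse(graph$nodes$alive, graph$nodes$coverage, 0)
  edge_sup <- graph$edges$support
  orig_sup <- graph$edges$support
  orig_weight <- reads$weight

  chains <- list(); keys <- character()
  max_iter <- nrow(graph$edges) + 1L
  for (it in seq_len(max_iter)) {
    if (max(node_cov) < params$min_transcript_coverage) break
    chain <- heaviest_path(graph, node_cov, edge_sup, orig_sup,
                           fragments = reads)
    if (is.null(chain)) break
    res <- quantify_and_subtract(graph, chain, reads, node_cov, edge_sup)
    key <- paste(chain, collapse = "-")
    if (is.na(res$estimate)) {
      # nothing assignable on the heaviest region; retire its seed
      node_cov[chain] <- 0
      next
    }
    reads <- res$reads; node_cov <- res$node_cov; edge_sup <- res$edge_sup
    if (!key %in% keys) {
      keys <- c(keys, key)
      chains[[length(chains) + 1L]] <- chain
    }
  }
  if (length(chains) == 0L) return(empty)

  # EM re-quantification over all fragments and all candidates
  tpaths <- lapply(chains, transcript_path, graph = graph)
  tlens <- vapply(chains, function(ch) {
    sum(graph$nodes$end[ch] - graph$nodes$start[ch])
  }, numeric(1))
  names(tlens) <- paste0("t", seq_along(chains))
  # pass 1: compatibility and implied fragment spans per candidate
  nreads <- nrow(reads)
  hits <- vector("list", nreads)
  gaps <- vector("list", nreads)
  two_part <- vapply(reads$path, function(p) length(p$parts) > 1L, logical(1))
  for (i in seq_len(nreads)) {
    h <- which(vapply(tpaths, function(tp) {
      path_compatible(reads$path[[i]], tp)
    }, logical(1)))
    hits[[i]] <- h
    if (length(h)) {
      gaps[[i]] <- vapply(tpaths[h], implied_inner_gap, numeric(1),
                          read_path = reads$path[[i]], graph = graph)
    }
  }
  # fragment-length estimate from unambiguous mate pairs
  uniq2 <- which(lengths(hits) == 1L & two_part)
  fl_hat <- if (length(uniq2)) {
    stats::median(reads$bases[uniq2] +
                    vapply(gaps[uniq2], `[`, numeric(1), 1))
  } else if (any(two_part & lengths(hits) > 0)) {
    i2 <- which(two_part & lengths(hits) > 0)
    stats::median(reads$bases[i2] + vapply(gaps[i2], min, numeric(1)))
  } else NA_real_

  # pass 2: resolve gap-ambiguous mate pairs against the fragment-length
  # estimate (fall back to smallest-gap when nothing is within tolerance)
  asg <- list()
  for (i in seq_len(nreads)) {
    h <- hits[[i]]
    if (length(h) == 0L) next
    if (length(h) > 1L && two_part[i] && is.finite(params$frag_gap_tol)) {
      gp <- gaps[[i]]
      keep_g <- if (!is.na(fl_hat)) {
        abs(reads$bases[i] + gp - fl_hat) <= params$frag_gap_tol
      } else gp <= min(gp) + params$frag_gap_tol
      if (!any(keep_g)) keep_g <- gp <= min(gp) + params$frag_gap_tol
      h <- h[keep_g]
    }
    asg[[length(asg) + 1L]] <- tibble(read_id = as.character(i),
                                      item_id = paste0("t", h))
  }
  masses <- setNames(orig_weight * reads$bases, as.character(seq_len(nreads)))
  # responsibilities use effective lengths: fragment starts are drawn from
  # L - span + 1 positions, so shorter isoforms have higher start density
  eff <- if (!is.na(fl_hat)) pmax(tlens - fl_hat + 1, 1) else tlens
  em <- em_coverage(bind_rows(asg), masses, lengths = eff)
  cov <- setNames(numeric(length(chains)), names(tlens))
  cov[em$item_id] <- em$mass / tlens[em$item_id]

  keep <- cov >= params$min_transcript_coverage &
    cov >= params$min_isoform_fraction * max(cov)
  if (!any(keep)) return(empty)

  out <- tibble(
    rname = graph$rname, strand = graph$strand,
    exons = lapply(chains[keep], chain_to_exons, graph = graph),
    coverage = unname(cov[keep]), source = "assembled",
    n_exons = NA_integer_
  )
  if (params$trim_ends) {
    out$exons <- lapply(out$exons, trim_transcript_ends, graph = graph,
                        trim_fraction = params$trim_fraction)
  }
  out$n_exons <- vapply(out$exons, nrow, 0L)
  if (!is.null(guides) && nrow(guides)) {
    gkey <- chain_signature(guides$rname, guides$exons)
    okey <- chain_signature(out$rname, out$exons)
    out$source[okey %in% gkey & out$n_exons > 1L] <- "guide-matched"
  }
  arrange(out, .data$rname, vapply(out$exons, function(e) e[1, 1], numeric(1)))
}

# intron-chain signature used for guide matching (multi-exon only)
chain_signature <- function(rname, exons) {
  vapply(seq_along(exons), function(i) {
    jn <- block_introns(exons[[i]])
    paste0(rname[i], "|", paste(jn[, 1], jn[, 2], sep = "-", collapse = ","))
  }, "")
}

# trim terminal exon bases whose per-bp coverage is below trim_fraction of
# the transcript's mean coverage; a terminal exon never shrinks below 1 bp
trim_transcript_ends <- function(exons, graph, trim_fraction = 0.1) {
  lo <- graph$span[1]
  covat <- function(p) {
    i <- p - lo + 1L
    if (i < 1L || i > length(graph$covvec)) 0 else graph$covvec[i]
  }
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq(exons[i, 1], exons[i, 2] - 1L)
  }))
  m <- mean(vapply(pos, covat, numeric(1)))
  thr <- trim_fraction * m
  while (exons[1, 2] - exons[1, 1] > 1L && covat(exons[1, 1]) < thr) {
    exons[1, 1] <- exons[1, 1] + 1L
  }
  nlast <- nrow(exons)
  while (exons[nlast, 2] - exons[nlast, 1] > 1L &&
         covat(exons[nlast, 2] - 1L) < thr) {
    exons[nlast, 2] <- exons[nlast, 2] - 1L
  }
  exons
}

#' Assemble a bundle
#'
#' Splits a bundle's collapsed alignments by strand, builds the splice graph
#' per strand group (pruning it in long-read mode) and assembles each group.
#'
#' @param alignments Collapsed alignments of one bundle.
#' @param params [assembly_params()].
#' @param guides Optional guide transcript tibble.
#' @return Transcript tibble (possibly empty).
#' @export
assemble_bundle <- function(alignments, params = assembly_params(),
                            guides = NULL) {
  groups <- split_by_strand(alignments)
  bind_rows(lapply(names(groups), function(s) {
    g <- build_splice_graph(groups[[s]], guides = guides, strand = s)
    if (params$long_read_mode) {
      g <- prune_graph(g, max_nodes = params$max_nodes)$graph
    }
    assemble_graph(g, groups[[s]], params = params, guides = guides)
  }))
}

#' Assemble transcripts from a SAM file
#'
#' The full pipeline: parse spliced alignments, correct splice sites of
#' high-error reads (long-read mode), filter spurious spliced alignments,
#' collapse identical alignments, bundle, and assemble each bundle. Super-read
#' records (those with an `XC` coverage tag) are weighted by their tag and
#' have their first/last `superread_k - 1` aligned bases ignored.
#'
#' @param sam Path to a SAM file, or an alignment tibble from [read_sam()].
#' @param guides Optional guide annotation: path to a GTF file or a
#'   transcript tibble from [read_gtf()].
#' @param params [assembly_params()].
#' @return Transcript tibble with `transcript_id`, `gene_id`, `rname`,
#'   `strand`, `exons` (0-based half-open block matrices), `coverage`,
#'   `source`, `n_exons`.
#' @export
assemble_sam <- function(sam, guides = NULL, params = assembly_params()) {
  aln <- if (is.character(sam)) {
    read_sam(sam, long_reads = params$long_read_mode)
  } else sam
  if (is.character(guides)) guides <- read_gtf(guides)
  if (any(!is.na(aln$xc)) && params$superread_k > 1) {
    aln <- mask_superread_ends(aln, params$superread_k - 1L)
  }
  if (params$long_read_mode && nrow(aln)) {
    aln <- correct_splice_sites(
      aln, window = params$correction_window,
      high_error_threshold = params$high_error_threshold, guides = guides
    )$reads
  }
  aln <- filter_spliced_alignments(aln, params = params)
  aln <- aln[aln$keep, , drop = FALSE]
  collapsed <- collapse_alignments(aln)
  bundles <- build_bundles(collapsed, max_gap = params$max_gap)
  out <- bind_rows(lapply(seq_len(nrow(bundles)), function(i) {
    tx <- assemble_bundle(bundles$alignments[[i]], params = params,
                          guides = guides)
    if (nrow(tx)) tx$bundle_id <- bundles$bundle_id[i]
    tx
  }))
  if (nrow(out) == 0L) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  rname = character(), strand = character(), exons = list(),
                  coverage = numeric(), source = character(),
                  n_exons = integer()))
  }
  out <- out %>%
    group_by(.data$bundle_id, .data$strand) %>%
    mutate(gene_local = dplyr::cur_group_id()) %>%
    ungroup()
  out$gene_id <- paste0("SFLW.", out$gene_local)
  out <- out %>%
    group_by(.data$gene_id) %>%
    mutate(transcript_id = paste0(.data$gene_id, ".", dplyr::row_number())) %>%
    ungroup() %>%
    select("transcript_id", "gene_id", "rname", "strand", "exons",
           "coverage", "source", "n_exons")
  out
}

# zero out the first/last `trim` aligned bases of super-read alignments
mask_superread_ends <- function(aln, trim) {
  sr <- which(!is.na(aln$xc))
  for (i in sr) {
    b <- aln$blocks[[i]]
    left <- trim
    k <- 1L
    while (left > 0 && k <= nrow(b)) {
      w <- b[k, 2] - b[k, 1]
      cut <- min(w - 1L, left)
      b[k, 1] <- b[k, 1] + cut
      left <- left - cut
      if (cut < w - 1L || left == 0) break
      k <- k + 1L
    }
    right <- trim
    k <- nrow(b)
    while (right > 0 && k >= 1L) {
      w <- b[k, 2] - b[k, 1]
      cut <- min(w - 1L, right)
      b[k, 2] <- b[k, 2] - cut
      right <- right - cut
      if (cut < w - 1L || right == 0) break
      k <- k - 1L
    }
    aln$blocks[[i]] <- b
    aln$start[i] <- b[1, 1]
    aln$end[i] <- b[nrow(b), 2]
    aln$aligned_len[i] <- sum(b[, 2] - b[, 1])
  }
  aln
}
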