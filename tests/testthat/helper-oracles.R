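# Independent brute-force oracles and tiny builders shared across tests.
# These deliberately re-derive results by the most naive route available so
# they stay independent of the implementation code paths they check.

# --- SAM text builders -------------------------------------------------------

sam_header <- function(seqlengths = c(chr1 = 100000L)) {
  c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                           as.integer(seqlengths)))
}

sam_line <- function(qname, rname, pos1, cigar, flag = 0L, tags = character()) {
  paste(c(qname, flag, rname, pos1, 255L, cigar, "*", 0L, 0L, "*", "*", tags),
        collapse = "\t")
}

write_sam_text <- function(lines, seqlengths = c(chr1 = 100000L)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c(sam_header(seqlengths), lines), path)
  path
}

# --- alignment tibble builder ------------------------------------------------

mk_read <- function(blocks, rname = "chr1", qname = "r", strand = "*",
                    nm = 0, nh = 1, weight = 1 / nh, paired = FALSE,
                    is_first = FALSE, is_long = FALSE, xc = NA_real_) {
  b <- cbind(start = as.numeric(blocks[, 1]), end = as.numeric(blocks[, 2]))
  tibble::tibble(
    qname = qname, flag = 0L, rname = rname,
    start = b[1, 1], end = b[nrow(b), 2], blocks = list(b),
    strand = strand, nm = nm, nh = nh, xc = xc, weight = weight,
    aligned_len = sum(b[, 2] - b[, 1]),
    paired = paired, is_first = is_first, is_long = is_long
  )
}

mk_tx <- function(exons, rname = "chrS", strand = "+", id = "t1",
                  gene = "g1", coverage = NA_real_) {
  ex <- cbind(start = as.numeric(exons[, 1]), end = as.numeric(exons[, 2]))
  tibble::tibble(transcript_id = id, gene_id = gene, rname = rname,
                 strand = strand, exons = list(ex), coverage = coverage,
                 n_exons = nrow(ex))
}

# --- synthetic splice-graph builder (for pruning / path tests) ---------------

mk_graph <- function(n, edges, node_cov = rep(1, n), unspliced = rep(0, n),
                     guide = rep(FALSE, nrow(edges)), rname = "chrT",
                     strand = "+") {
  starts <- seq(0, by = 100, length.out = n)
  nodes <- tibble::tibble(
    id = seq_len(n), start = starts, end = starts + 100,
    coverage = node_cov, unspliced_cov = unspliced, alive = TRUE
  )
  ed <- tibble::tibble(
    from = as.integer(edges[, 1]), to = as.integer(edges[, 2]),
    type = "junction", support = as.numeric(edges[, 3]), guide = guide
  )
  ed <- dplyr::arrange(ed, .data$from, .data$to)
  structure(list(
    id = spliceflow:::next_graph_id(), rname = rname, strand = strand,
    span = c(0, n * 100), n = n, nodes = nodes, edges = ed,
    covvec = rep(node_cov, each = 100)
  ), class = "splice_graph")
}

# random layered DAG with a chain backbone plus skip edges
random_graph <- function(n, extra_edges = n, seed = NULL, max_support = 50) {
  if (!is.null(seed)) set.seed(seed)
  backbone <- cbind(1:(n - 1), 2:n, sample(max_support, n - 1, replace = TRUE))
  sk_from <- sample(n - 2, extra_edges, replace = TRUE)
  sk_span <- sample(2:min(5, n - 1), extra_edges, replace = TRUE)
  sk_to <- pmin(sk_from + sk_span, n)
  skips <- cbind(sk_from, sk_to, sample(max_support, extra_edges, replace = TRUE))
  skips <- skips[skips[, 1] < skips[, 2], , drop = FALSE]
  edges <- rbind(backbone, skips)
  edges <- edges[!duplicated(edges[, 1:2, drop = FALSE]), , drop = FALSE]
  mk_graph(n, edges, node_cov = runif(n, 0.5, 10))
}

# --- brute-force compatibility oracle ---------------------------------------

# embeds each read part as a contiguous subsequence of the transcript node
# sequence by scanning every offset, and checks edge containment by direct
# set comparison
oracle_compatible <- function(read_path, tx_path) {
  tseq <- tx_path$parts[[1]]
  tedges <- apply(tx_path$edges, 1, paste, collapse = "_")
  redges <- if (nrow(read_path$edges)) {
    apply(read_path$edges, 1, paste, collapse = "_")
  } else character()
  if (!all(redges %in% tedges)) return(FALSE)
  if (length(read_path$parts) == 0L) return(FALSE)
  min_next <- 1L
  for (p in read_path$parts) {
    found <- NA
    for (off in seq_len(length(tseq) - length(p) + 1L)) {
      if (off >= min_next && all(tseq[off:(off + length(p) - 1L)] == p)) {
        found <- off
        break
      }
    }
    if (is.na(found)) return(FALSE)
    min_next <- found + length(p)
  }
  TRUE
}

# --- independent greedy heaviest-path oracle ---------------------------------

# a naive re-derivation of the documented greedy rule (seed at max coverage,
# extend by max support with the documented tie-breaks), written over plain
# matrices rather than the package's graph structures
oracle_heaviest <- function(n, edges, node_cov, edge_sup) {
  seed <- which(node_cov == max(node_cov))[1]
  best_step <- function(v, forward) {
    rows <- which(if (forward) edges[, 1] == v else edges[, 2] == v)
    if (length(rows) == 0L) return(NA_integer_)
    nb <- if (forward) edges[rows, 2] else edges[rows, 1]
    sup <- edge_sup[rows]
    sc <- order(-sup, -node_cov[nb], nb)
    nb[sc[1]]
  }
  chain <- seed
  v <- seed
  repeat {
    w <- best_step(v, TRUE)
    if (is.na(w)) break
    chain <- c(chain, w); v <- w
  }
  v <- seed
  repeat {
    w <- best_step(v, FALSE)
    if (is.na(w)) break
    chain <- c(w, chain); v <- w
  }
  chain
}

# --- brute-force transcript matcher ------------------------------------------

oracle_score <- function(pred, ref, end_slack = 100) {
  introns <- function(ex) {
    if (nrow(ex) < 2L) return("")
    paste(ex[-nrow(ex), 2], ex[-1, 1], sep = "-", collapse = ",")
  }
  ok <- function(i, j) {
    pe <- pred$exons[[i]]; re <- ref$exons[[j]]
    if (pred$rname[i] != ref$rname[j]) return(FALSE)
    sp <- pred$strand[i]; sr <- ref$strand[j]
    if (sp != "*" && sr != "*" && sp != sr) return(FALSE)
    if (nrow(pe) != nrow(re)) return(FALSE)
    if (introns(pe) != introns(re)) return(FALSE)
    abs(pe[1, 1] - re[1, 1]) <= end_slack &&
      abs(pe[nrow(pe), 2] - re[nrow(re), 2]) <= end_slack
  }
  matched_ref <- rep(FALSE, nrow(ref))
  for (i in seq_len(nrow(pred))) {
    cands <- Filter(function(j) ok(i, j), seq_len(nrow(ref)))
    if (length(cands)) {
      d <- vapply(cands, function(j) {
        pe <- pred$exons[[i]]; re <- ref$exons[[j]]
        abs(pe[1, 1] - re[1, 1]) + abs(pe[nrow(pe), 2] - re[nrow(re), 2])
      }, numeric(1))
      matched_ref[cands[order(d, cands)][1]] <- TRUE
    }
  }
  TP <- sum(matched_ref)
  list(TP = TP, FP = nrow(pred) - TP, FN = nrow(ref) - TP)
}

# random transcript set on a toy genome
random_tx_set <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    starts <- cumsum(c(sample(1000, 1), sample(100:300, max(k - 1, 0), replace = TRUE) +
                         sample(100:200, max(k - 1, 0), replace = TRUE)))
    lens <- sample(80:250, k, replace = TRUE)
    mk_tx(cbind(starts, starts + lens), id = paste0("x", i),
          strand = sample(c("+", "-", "*"), 1))
  })
  dplyr::bind_rows(rows)
}
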