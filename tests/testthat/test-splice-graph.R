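collapse1 <- function(reads) collapse_alignments(reads)

test_that("bundles merge reads across gaps up to max_gap", {
  col <- collapse1(dplyr::bind_rows(
    mk_read(cbind(0, 100), qname = "a"),
    mk_read(cbind(120, 200), qname = "b")
  ))
  expect_equal(nrow(build_bundles(col, max_gap = 50)), 1L)
  expect_equal(nrow(build_bundles(col, max_gap = 10)), 2L)

  col3 <- collapse1(dplyr::bind_rows(
    mk_read(cbind(0, 100), qname = "a"),
    mk_read(cbind(140, 200), qname = "b"),
    mk_read(cbind(460, 500), qname = "c")
  ))
  # gap 40 merges the first two; gap 260 exceeds both 50 and 200
  expect_equal(nrow(build_bundles(col3, max_gap = 200)), 2L)
  expect_equal(nrow(build_bundles(col3, max_gap = 50)), 2L)
  expect_equal(nrow(build_bundles(col3, max_gap = 300)), 1L)
})

test_that("every alignment lands in exactly one bundle (property)", {
  withr::with_seed(17, {
    n <- 60
    starts <- sort(sample(0:5000, n))
    col <- collapse1(dplyr::bind_rows(lapply(seq_len(n), function(i) {
      mk_read(cbind(starts[i], starts[i] + sample(30:80, 1)),
              qname = paste0("r", i))
    })))
    bn <- build_bundles(col, max_gap = 40)
    all_keys <- unlist(lapply(bn$alignments, `[[`, "key"))
    expect_setequal(all_keys, col$key)
    expect_equal(length(all_keys), nrow(col))
  })
})

test_that("splice graph nodes and edges follow junction and coverage boundaries", {
  # single-exon coverage: one node, no edges
  g1 <- build_splice_graph(collapse1(mk_read(cbind(0, 100))))
  expect_equal(sum(g1$nodes$alive), 1L)
  expect_equal(nrow(g1$edges), 0L)

  # one junction 50 -> 200 with uncovered gap: two nodes, one junction edge
  g2 <- build_splice_graph(collapse1(dplyr::bind_rows(
    mk_read(cbind(c(0, 200), c(50, 250)), qname = "s1"),
    mk_read(cbind(c(0, 200), c(50, 250)), qname = "s2")
  )))
  expect_equal(nrow(g2$nodes), 2L)
  expect_equal(unname(as.matrix(g2$nodes[, c("start", "end")])),
               cbind(c(0, 200), c(50, 250)))
  expect_equal(g2$edges$type, "junction")
  expect_equal(g2$edges$support, 2)

  # two junctions sharing a donor: three nodes, two junction edges
  g3 <- build_splice_graph(collapse1(dplyr::bind_rows(
    mk_read(cbind(c(0, 200), c(50, 250)), qname = "a"),
    mk_read(cbind(c(0, 300), c(50, 350)), qname = "b")
  )))
  expect_equal(sum(g3$edges$type == "junction"), 2L)
  expect_equal(nrow(g3$nodes), 3L)
})

test_that("graph is a DAG ordered by genomic coordinate", {
  fix <- generate_fixture(fixture_spec(seed = 21, n_loci = 2))
  aln <- withr::with_seed(22, simulate_short_alignments(fix$transcripts, fix$spec))
  col <- collapse_alignments(aln)
  for (b in seq_len(nrow(build_bundles(col)))) {
    g <- build_splice_graph(build_bundles(col)$alignments[[b]], strand = "+")
    expect_true(all(g$edges$from < g$edges$to))
    expect_true(!is.unsorted(g$nodes$start))
  }
})

test_that("dense bit encoding follows the node/edge bit layout", {
  # the edge formula as printed: bit n*i + j
  expect_equal(encode_path_dense(4, c(1, 2), cbind(1, 2), offset = FALSE),
               c(1L, 2L, 6L))
  expect_equal(encode_path_dense(4, integer(), matrix(0L, 0, 2)), integer())
  # the offset layout avoids node/edge collisions: edge bit n + n*i + j
  expect_equal(encode_path_dense(5, integer(), cbind(0, 4)), 9L)
  expect_error(encode_path_dense(4, integer(), cbind(2, 1)), "i < j")
})

test_that("dense and sparse encodings agree on random small graphs (property)", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(3:10, 1)
      g <- random_graph(n, extra_edges = 2, max_support = 10)
      chain <- heaviest_path(g)
      tp <- spliceflow:::transcript_path(g, chain)
      dense <- encode_path_dense(
        n, tp$nodes - 1L,
        if (nrow(tp$edges)) tp$edges - 1L else matrix(0L, 0, 2)
      )
      dec <- decode_path_dense(dense, n)
      expect_equal(dec$nodes + 1L, tp$nodes)
      if (nrow(tp$edges)) {
        expect_equal(unname(dec$edges + 1L), unname(tp$edges))
      }
    }
  })
})

test_that("sparse encoding maps blocks to nodes, edges and interrupted parts", {
  reads <- dplyr::bind_rows(
    mk_read(cbind(c(0, 200), c(100, 300)), qname = "s1"),
    mk_read(cbind(c(0, 400), c(100, 500)), qname = "s2"),
    mk_read(cbind(400, 500), qname = "u")
  )
  g <- build_splice_graph(collapse1(reads), strand = "+")
  # read covering exactly one node
  p1 <- encode_path_sparse(g, cbind(410, 490))
  expect_equal(length(p1$nodes), 1L)
  expect_false(p1$interrupted)
  # spliced read via a junction
  p2 <- encode_path_sparse(g, cbind(c(0, 200), c(100, 300)))
  expect_equal(nrow(p2$edges), 1L)
  expect_false(p2$interrupted)
  # mate pair: parts for both reads, no bits for the gap
  p3 <- encode_path_sparse(g, cbind(0, 80), cbind(420, 500))
  expect_true(p3$interrupted)
  expect_equal(length(p3$parts), 2L)
  expect_equal(nrow(p3$edges), 0L)
})

test_that("a read whose junction is absent from the graph is re-encoded interrupted", {
  g <- build_splice_graph(collapse1(dplyr::bind_rows(
    mk_read(cbind(0, 100), qname = "a"),
    mk_read(cbind(150, 250), qname = "b")
  )), strand = "+")
  p <- encode_path_sparse(g, cbind(c(0, 150), c(100, 250)))
  expect_true(p$interrupted)
  expect_equal(nrow(p$edges), 0L)
  expect_equal(length(p$parts), 2L)
})

test_that("path compatibility handles containment, skipped nodes and interruptions", {
  g <- mk_graph(4, cbind(c(1, 2, 3, 1), c(2, 3, 4, 3), c(5, 5, 5, 2)))
  tx_full <- spliceflow:::transcript_path(g, 1:4)
  tx_skip <- spliceflow:::transcript_path(g, c(1, 3, 4))
  r12 <- spliceflow:::transcript_path(g, 1:2)            # continuous read 1-2
  expect_true(path_compatible(r12, tx_full))
  expect_false(path_compatible(r12, tx_skip))
  r13 <- spliceflow:::transcript_path(g, c(1, 3))        # junction 1->3
  expect_false(path_compatible(r13, tx_full))
  expect_true(path_compatible(r13, tx_skip))
  rint <- spliceflow:::new_bit_path(g, list(1L, 4L), matrix(integer(), 0, 2), TRUE)
  expect_true(path_compatible(rint, tx_full))
  expect_true(path_compatible(rint, tx_skip))
  g2 <- mk_graph(2, cbind(1, 2, 1))
  expect_error(
    path_compatible(spliceflow:::transcript_path(g2, 1:2), tx_full),
    "different graphs"
  )
})

test_that("path_compatible agrees with the brute-force oracle (property)", {
  withr::with_seed(41, {
    for (rep in 1:30) {
      n <- sample(4:8, 1)
      g <- random_graph(n, extra_edges = 3, max_support = 10)
      chain <- heaviest_path(g)
      tx <- spliceflow:::transcript_path(g, chain)
      # random read paths: contiguous runs and interrupted two-part reads
      for (k in 1:6) {
        if (runif(1) < 0.5) {
          s <- sample(n, 1); e <- min(n, s + sample(0:3, 1))
          rp <- spliceflow:::transcript_path(g, s:e)
        } else {
          a <- sample(n - 1, 1); b <- sample(a:n, 1)
          rp <- spliceflow:::new_bit_path(g, list(a, b),
                                          matrix(integer(), 0, 2), TRUE)
        }
        expect_equal(path_compatible(rp, tx), oracle_compatible(rp, tx),
                     info = sprintf("rep %d read %d", rep, k))
      }
    }
  })
})

test_that("strand splitting keeps unknown-strand coverage on both graphs", {
  reads <- dplyr::bind_rows(
    mk_read(cbind(c(0, 200), c(100, 300)), qname = "p", strand = "+"),
    mk_read(cbind(c(0, 400), c(100, 500)), qname = "m", strand = "-"),
    mk_read(cbind(50, 130), qname = "u", strand = "*")
  )
  groups <- split_by_strand(collapse_alignments(reads))
  expect_setequal(names(groups), c("+", "-"))
  expect_true(all(vapply(groups, function(gg) any(gg$strand == "*"), logical(1))))
})
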