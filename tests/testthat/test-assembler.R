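test_that("heaviest path walks chains and follows maximal support", {
  # linear 3-node chain: the unique path
  g <- mk_graph(3, cbind(1:2, 2:3, c(4, 4)), node_cov = c(1, 5, 1))
  expect_equal(heaviest_path(g), 1:3)

  # seed at node 2, out-edges 5 vs 2: extends via the heavier edge
  g2 <- mk_graph(4, cbind(c(1, 2, 2), c(2, 3, 4), c(5, 5, 2)),
                 node_cov = c(1, 9, 1, 1))
  expect_equal(heaviest_path(g2), c(1, 2, 3))

  # equal supports: deterministic, reproducible tie-break
  g3 <- mk_graph(4, cbind(c(1, 2, 2), c(2, 3, 4), c(5, 3, 3)),
                 node_cov = c(1, 9, 2, 2))
  expect_identical(heaviest_path(g3), heaviest_path(g3))
  expect_equal(heaviest_path(g3), c(1, 2, 3))   # equal cov: smaller index
})

test_that("greedy path agrees with an independent re-derivation (property)", {
  withr::with_seed(71, {
    for (rep in 1:25) {
      n <- sample(4:8, 1)
      g <- random_graph(n, extra_edges = 3, max_support = 20)
      got <- heaviest_path(g)
      want <- oracle_heaviest(n, as.matrix(g$edges[, c("from", "to")]),
                              g$nodes$coverage, g$edges$support)
      expect_equal(got, as.integer(want), info = paste("rep", rep))
    }
  })
})

mk_locus_reads <- function() {
  # two isoforms sharing terminal exons: t1 via middle exon (cov 6),
  # t2 skipping it (cov 4); junction-spanning single-end reads
  reads <- list()
  add <- function(blocks, m, pre) {
    for (i in seq_len(m)) {
      reads[[length(reads) + 1L]] <<- mk_read(blocks, qname = paste0(pre, i),
                                              strand = "+")
    }
  }
  add(cbind(c(50, 200), c(100, 250)), 6, "a")     # t1 junction 100 -> 200
  add(cbind(c(220, 400), c(270, 450)), 6, "b")    # t1 junction 270 -> 400
  add(cbind(c(50, 400), c(100, 450)), 4, "c")     # t2 junction 100 -> 400
  add(cbind(0, 90), 10, "d")                      # shared first exon
  add(cbind(410, 500), 10, "e")                   # shared last exon
  collapse_alignments(dplyr::bind_rows(reads))
}

test_that("quantify-and-subtract assigns compatible mass and conserves it", {
  # single-isoform locus at uniform coverage: estimate ~ coverage, residual 0
  fix <- generate_fixture(fixture_spec(seed = 81, n_loci = 1,
                                       isoforms_per_locus = 1,
                                       paired = FALSE))
  aln <- withr::with_seed(82, simulate_short_alignments(fix$transcripts, fix$spec))
  col <- collapse_alignments(aln)
  g <- build_splice_graph(col, strand = "+")
  reads <- spliceflow:::encode_fragments(g, col)
  chain <- heaviest_path(g)
  res <- quantify_and_subtract(g, chain, reads, g$nodes$coverage,
                               g$edges$support)
  expect_equal(res$estimate, fix$transcripts$coverage[1], tolerance = 0.1)
  expect_equal(sum(res$reads$weight), 0)
  expect_lt(max(res$node_cov), 1e-6)
  # mass conservation: assigned + residual = initial
  initial <- sum(reads$weight * reads$bases)
  residual <- sum(res$reads$weight * res$reads$bases)
  expect_equal(res$assigned_mass + residual, initial)
})

test_that("two shared-exon isoforms are extracted at ~6 and ~4", {
  col <- mk_locus_reads()
  g <- build_splice_graph(col, strand = "+")
  reads <- spliceflow:::encode_fragments(g, col)
  node_cov <- g$nodes$coverage; edge_sup <- g$edges$support
  ch1 <- heaviest_path(g, node_cov, edge_sup, edge_sup, fragments = reads)
  r1 <- quantify_and_subtract(g, ch1, reads, node_cov, edge_sup)
  ch2 <- heaviest_path(g, r1$node_cov, r1$edge_sup, edge_sup,
                       fragments = r1$reads)
  r2 <- quantify_and_subtract(g, ch2, r1$reads, r1$node_cov, r1$edge_sup)
  ests <- sort(c(r1$estimate, r2$estimate))
  expect_equal(ests[1], 4, tolerance = 0.1 * 4)
  expect_equal(ests[2], 6, tolerance = 0.1 * 6)
  # incompatible reads contribute nothing: the t2 junction reads kept their
  # full weight until the t2 path was extracted
  expect_true(r1$estimate != r2$estimate)
})

test_that("a path with no compatible coverage is rejected", {
  col <- mk_locus_reads()
  g <- build_splice_graph(col, strand = "+")
  reads <- spliceflow:::encode_fragments(g, col)
  reads$weight[] <- 0
  res <- quantify_and_subtract(g, heaviest_path(g), reads,
                               g$nodes$coverage, g$edges$support)
  expect_true(is.na(res$estimate))
})

test_that("noiseless multi-isoform loci are recovered exactly with coverage", {
  fix <- generate_fixture(fixture_spec(seed = 91, n_loci = 8))
  aln <- withr::with_seed(92, simulate_short_alignments(fix$transcripts, fix$spec))
  tx <- assemble_sam(aln)
  sc <- score_predictions(tx, fix$transcripts)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$precision, 1)
  m <- match(spliceflow:::chain_signature(fix$transcripts$rname, fix$transcripts$exons),
             spliceflow:::chain_signature(tx$rname, tx$exons))
  re <- abs(tx$coverage[m] - fix$transcripts$coverage) / fix$transcripts$coverage
  expect_lt(mean(re), 0.05)
})

test_that("bundles below the coverage threshold produce no transcripts", {
  col <- collapse_alignments(mk_read(cbind(0, 1000), qname = "lone"))
  p <- assembly_params(min_transcript_coverage = 2)
  expect_equal(nrow(assemble_bundle(col, p)), 0L)
})

test_that("guide-matched transcripts are labelled", {
  fix <- generate_fixture(fixture_spec(seed = 95, n_loci = 2))
  aln <- withr::with_seed(96, simulate_short_alignments(fix$transcripts, fix$spec))
  tx <- assemble_sam(aln, guides = fix$transcripts)
  expect_true(all(tx$source[tx$n_exons > 1] == "guide-matched"))
})

test_that("iteration count stays within the edge budget (property)", {
  # monotone stopping is structural: candidates come from at most
  # n_edges + 1 extraction rounds; verify via a dense random locus
  fix <- generate_fixture(fixture_spec(seed = 97, n_loci = 3))
  aln <- withr::with_seed(98, simulate_short_alignments(fix$transcripts, fix$spec))
  col <- collapse_alignments(aln)
  bn <- build_bundles(col)
  for (i in seq_len(nrow(bn))) {
    g <- build_splice_graph(bn$alignments[[i]], strand = "+")
    tx <- spliceflow:::assemble_graph(g, bn$alignments[[i]])
    expect_lte(nrow(tx), nrow(g$edges) + 1L)
  }
})

test_that("GTF writer uses 1-based inclusive coordinates and round-trips", {
  tx <- mk_tx(cbind(c(100, 300), c(200, 400)), coverage = 3.5)
  path <- tempfile(fileext = ".gtf")
  write_gtf(tx, path)
  lines <- readLines(path)
  exon1 <- grep("\texon\t101\t200\t", lines)
  expect_length(exon1, 1L)
  back <- read_gtf(path)
  expect_equal(unname(back$exons[[1]]), unname(tx$exons[[1]]))
  expect_equal(back$coverage, 3.5)
  expect_equal(back$strand, "+")

  # empty input: header-only file
  empty <- tempfile(fileext = ".gtf")
  write_gtf(tx[0, ], empty)
  expect_equal(length(readLines(empty)), 1L)

  # fixture round-trip preserves every exon chain
  fix <- generate_fixture(fixture_spec(seed = 99, n_loci = 3))
  p2 <- tempfile(fileext = ".gtf")
  write_gtf(fix$transcripts, p2)
  back2 <- read_gtf(p2)
  expect_equal(nrow(back2), nrow(fix$transcripts))
  k1 <- sort(spliceflow:::chain_signature(back2$rname, back2$exons))
  k2 <- sort(spliceflow:::chain_signature(fix$transcripts$rname,
                                          fix$transcripts$exons))
  expect_equal(k1, k2)
})

test_that("super-read records are weighted by XC and end-masked", {
  path <- write_sam_text(c(
    sam_line("sr1", "chr1", 1, "100M200N100M", tags = c("XC:f:7", "XS:A:+")),
    sam_line("r1", "chr1", 1, "50M")
  ))
  aln <- read_sam(path)
  expect_equal(aln$weight, c(7, 1))
  masked <- spliceflow:::mask_superread_ends(aln, 24L)
  expect_equal(unname(masked$blocks[[1]]), cbind(c(24, 300), c(100, 376)))
  expect_equal(unname(masked$blocks[[2]]), cbind(0, 50))   # plain reads untouched
})
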