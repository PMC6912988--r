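test_that("k-mer table counts canonical k-mers without a minimum threshold", {
  # ACG and CGT are reverse complements, so canonical-form counting folds
  # them into one entry with count 2; GTA/TAC stays separate
  kt <- build_kmer_table("ACGTA", k = 3)
  expect_equal(nrow(kt), 2L)
  expect_setequal(kt$kmer, spliceflow:::canonical(c("ACG", "CGT", "GTA")))
  expect_setequal(kt$count, c(2, 1))

  # duplicate reads double the counts
  kt2 <- build_kmer_table(c("ACGTA", "ACGTA"), k = 3)
  expect_equal(sort(kt2$count), sort(2 * kt$count))

  # a k-mer and its reverse complement share an entry
  kt3 <- build_kmer_table(c("ACG", "CGT"), k = 3)
  expect_equal(nrow(kt3), 1L)
  expect_equal(kt3$count, 2)

  # windows containing N are skipped
  ktn <- build_kmer_table("ACNGTA", k = 3)
  expect_setequal(ktn$kmer, spliceflow:::canonical("GTA"))

  # reads shorter than k contribute nothing
  expect_equal(nrow(build_kmer_table("AC", k = 3)), 0L)
})

test_that("k-unitigs are maximal unambiguous chains", {
  # a linear chain with no reverse-complement collisions collapses to one
  # unitig (sequences with homopolymer or reverse-complement self-adjacent
  # k-mers are degenerate at k = 3: their chains legitimately break)
  ku <- build_kunitigs(build_kmer_table("AGGTTCAT", k = 3))
  expect_equal(nrow(ku), 1L)
  expect_true(ku$seq == "AGGTTCAT" | ku$seq == revcomp("AGGTTCAT"))

  # a branch (GTT -> TTC and TTG) breaks the chain
  ku2 <- build_kunitigs(build_kmer_table(c("AGGTTCAT", "GTTG"), k = 3))
  expect_gt(nrow(ku2), 1L)

  # a single isolated k-mer is a unitig of length k
  ku3 <- build_kunitigs(build_kmer_table("ACT", k = 3))
  expect_equal(nchar(ku3$seq), 3L)
})

test_that("every k-mer occurs in exactly one unitig (property, brute force)", {
  withr::with_seed(111, {
    for (rep in 1:8) {
      k <- sample(3:7, 1)
      reads <- vapply(seq_len(sample(3:6, 1)), function(i) {
        paste(sample(c("A", "C", "G", "T"), sample(20:200, 1), replace = TRUE),
              collapse = "")
      }, "")
      kt <- build_kmer_table(reads, k)
      ku <- build_kunitigs(kt)
      seen <- unlist(lapply(ku$seq, function(u) {
        spliceflow:::canonical(spliceflow:::kmerize(u, k))
      }))
      # partition: each table k-mer appears exactly once across unitigs
      expect_setequal(unique(seen), kt$kmer)
      expect_equal(anyDuplicated(seen), 0L, info = paste("rep", rep))
      # internal k-mers have a unique predecessor and successor
      for (u in ku$seq[nchar(ku$seq) > k + 1]) {
        km <- spliceflow:::kmerize(u, k)
        internal <- km[-c(1, length(km))]
        for (x in internal) {
          expect_length(spliceflow:::succs(x, kt$kmer), 1L)
          expect_length(spliceflow:::preds(x, kt$kmer), 1L)
        }
      }
    }
  })
})

test_that("super-read extension follows unique unitig placements", {
  ku <- build_kunitigs(build_kmer_table("AGGTTCAT", k = 3))
  # a read inside the unitig extends to the whole unitig
  sr <- extend_to_superreads("GGTTCA", ku)
  expect_true(sr %in% c("AGGTTCAT", revcomp("AGGTTCAT")))
  # a read equal to its unitig maps to itself
  sr2 <- extend_to_superreads("AGGTTCAT", ku)
  expect_true(sr2 %in% c("AGGTTCAT", revcomp("AGGTTCAT")))
  # missing terminal k-mer: no super-read
  expect_true(is.na(extend_to_superreads("TTTT", ku)))
})

test_that("reads are assigned to aligned super-reads by exact substring", {
  sr <- tibble::tibble(
    id = c("s1", "s2", "s3"),
    seq = c("AAACCCGGGTTT", "CCCGGG", "TTTTTTTT"),
    aligned = c(TRUE, TRUE, FALSE)
  )
  reads <- tibble::tibble(id = c("r1", "r2", "r3"),
                          seq = c("CCCGGG", "CCCGGGTTT", "AAAAAAA"))
  asg <- assign_reads(sr, reads)
  expect_setequal(asg$superread_id[asg$read_id == "r1"], c("s1", "s2"))
  expect_equal(asg$superread_id[asg$read_id == "r2"], "s1")
  # r3 matches only the unaligned s3 (as revcomp) -> excluded
  expect_false("r3" %in% asg$read_id)

  # reverse-complement containment counts
  rc <- tibble::tibble(id = "r4", seq = revcomp("ACCCGG"))
  expect_equal(assign_reads(sr, rc)$superread_id, "s1")

  # substring soundness oracle: every assignment is a real substring hit
  for (i in seq_len(nrow(asg))) {
    s <- sr$seq[sr$id == asg$superread_id[i]]
    r <- reads$seq[reads$id == asg$read_id[i]]
    expect_true(grepl(r, s, fixed = TRUE) || grepl(revcomp(r), s, fixed = TRUE))
  }
})

test_that("EM coverage follows the unique-first update rule", {
  # r1 unique to A (mass 2), r2 shared A/B: the first iteration sends r2
  # entirely to A and the estimate is stable afterwards
  asg <- tibble::tibble(read_id = c("r1", "r2", "r2"),
                        item_id = c("A", "A", "B"))
  em <- em_coverage(asg, c(r1 = 2, r2 = 1))
  expect_equal(em$mass[em$item_id == "A"], 3)
  expect_equal(em$mass[em$item_id == "B"], 0)

  # single super-read: coverage = total read mass
  em2 <- em_coverage(tibble::tibble(read_id = c("a", "b"), item_id = "S"),
                     c(a = 1.5, b = 2.5))
  expect_equal(em2$mass, 4)

  # fully symmetric share with no unique reads: equal split
  em3 <- em_coverage(tibble::tibble(read_id = c("r", "r"),
                                    item_id = c("A", "B")),
                     c(r = 2))
  expect_equal(em3$mass, c(1, 1))

  # empty assignments
  em4 <- em_coverage(tibble::tibble(read_id = character(),
                                    item_id = character()), numeric())
  expect_equal(nrow(em4), 0L)
})

test_that("EM conserves mass at every iteration and converges (property)", {
  withr::with_seed(121, {
    for (rep in 1:20) {
      nr <- sample(5:40, 1); ni <- sample(2:6, 1)
      asg <- dplyr::bind_rows(lapply(seq_len(nr), function(r) {
        items <- sample(ni, sample(ni, 1))
        tibble::tibble(read_id = paste0("r", r), item_id = paste0("s", items))
      }))
      masses <- setNames(runif(nr, 0.5, 3), paste0("r", seq_len(nr)))
      em <- em_coverage(asg, masses)
      trace <- attr(em, "mass_trace")
      total <- sum(masses[unique(asg$read_id)])
      expect_true(all(abs(trace - total) < 1e-9 * total))
      expect_true(attr(em, "converged"))
      expect_lte(attr(em, "iterations"), 1000)
    }
  })
})

test_that("super-read SAM carries the coverage tag and round-trips", {
  sr <- tibble::tibble(id = c("s1", "s2"), coverage = c(3.5, 1))
  aln <- tibble::tibble(
    id = c("s1", "s2"), rname = "chrS", start = c(100, 500),
    blocks = list(cbind(start = c(100, 400), end = c(200, 450)),
                  cbind(start = 500, end = 600)),
    strand = c("+", "-")
  )
  path <- tempfile(fileext = ".sam")
  emit_superread_sam(sr, aln, path, c(chrS = 10000L))
  txt <- readLines(path)
  expect_true(any(grepl("XC:f:3.5", txt, fixed = TRUE)))
  back <- read_sam(path)
  expect_equal(back$weight[back$qname == "s1"], 3.5)
  expect_equal(unname(back$blocks[[which(back$qname == "s1")]]),
               cbind(c(100, 400), c(200, 450)))
})

test_that("super-reads from noiseless reads stay within their transcript", {
  fix <- generate_fixture(fixture_spec(seed = 131, n_loci = 2,
                                       isoforms_per_locus = 1))
  reads <- withr::with_seed(132, simulate_short_reads(fix$transcripts,
                                                      fix$genome, fix$spec))
  kt <- build_kmer_table(reads$seq, k = 25)
  ku <- build_kunitigs(kt)
  idx <- spliceflow:::kunitig_index(ku)
  tx_seqs <- vapply(seq_len(nrow(fix$transcripts)), function(i) {
    spliceflow:::transcript_seq(fix$genome, fix$transcripts$rname[i],
                                fix$transcripts$exons[[i]])
  }, "")
  some <- withr::with_seed(133, sample(nrow(reads), 40))
  for (i in some) {
    sr <- extend_to_superreads(reads$seq[i], ku, index = idx)
    if (is.na(sr)) next
    # the extended sequence still matches a transcript exactly, so aligning
    # it would reproduce the originating transcript's junction chain
    hit <- vapply(tx_seqs, function(ts) {
      grepl(sr, ts, fixed = TRUE) || grepl(revcomp(sr), ts, fixed = TRUE)
    }, logical(1))
    expect_true(any(hit))
  }
})
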