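#' Specification for synthetic multi-isoform fixtures
#'
#' Defines the conditions the generators emulate: toy multi-isoform loci with
#' shared and distinctive junctions, perfect short-read alignments tiling
#' each transcript uniformly, and long-read alignments with injected
#' splice-site jitter and elevated mismatch counts. The same seed yields
#' byte-identical outputs.
#'
#' @param seed Integer seed for the single pseudo-random stream.
#' @param n_loci Number of loci.
#' @param isoforms_per_locus Isoforms per locus: the full exon chain plus
#'   variants each skipping one exon of an adjacent cassette-exon run.
#' @param exon_len,intron_len Length ranges (bp).
#' @param coverage Range of per-isoform true coverage (reads per base);
#'   values are drawn as distinct integers so isoform abundances are
#'   separable.
#' @param read_len Short-read length (75 bp, a typical Illumina length).
#' @param paired Emit proper read pairs.
#' @param insert_len Fragment length for paired mode.
#' @param long_reads_per_tx Long reads simulated per transcript.
#' @param p_clean Fraction of long reads kept error-free (at least one per
#'   transcript, so every true junction has low-error support).
#' @param p_jitter Probability that a junction of a noisy long read is
#'   jittered.
#' @param max_jitter Maximum jitter magnitude J (bp).
#' @param long_mismatch_rate Mismatch rate stamped (via NM) on noisy long
#'   reads.
#' @param p_truncate Probability that a noisy long read is truncated to a
#'   suffix/prefix of its transcript.
#' @return List of class `sf_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_loci = 5L, isoforms_per_locus = 3L,
                         exon_len = c(80L, 300L), intron_len = c(60L, 400L),
                         coverage = c(10L, 30L), read_len = 75L,
                         paired = TRUE, insert_len = 250L,
                         long_reads_per_tx = 8L, p_clean = 0.4,
                         p_jitter = 0.5, max_jitter = 6L,
                         long_mismatch_rate = 0.03, p_truncate = 0) {
  stopifnot(all(c(p_clean, p_jitter, p_truncate) >= 0),
            all(c(p_clean, p_jitter, p_truncate) <= 1),
            exon_len[1] > 0, intron_len[1] > 0,
            coverage[2] - coverage[1] + 1 >= isoforms_per_locus)
  structure(as.list(environment()), class = "sf_fixture_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate one multi-isoform locus
#'
#' Draws a random exon/intron backbone, writes GT/AG at intron boundaries,
#' and derives `isoforms_per_locus` transcripts as one alternative-splicing
#' cassette region: a run of adjacent internal exons, the full chain keeping
#' all of them and each variant isoform skipping one — the classic cassette
#' pattern, under which every isoform carries a private junction and the
#' locus is resolvable from short paired-end fragments. Consumes the current
#' RNG stream (seed it, or use [generate_fixture()]).
#'
#' @param spec [fixture_spec()].
#' @param offset Genomic offset (bp) at which the locus starts.
#' @param rname Reference sequence name.
#' @param locus_id Integer label used in transcript ids.
#' @return List with `seq` (locus sequence) and `transcripts` (tibble with
#'   truth `coverage`).
#' @export
generate_locus <- function(spec, offset = 0L, rname = "chrS", locus_id = 1L) {
  n_iso <- spec$isoforms_per_locus
  n_exons <- n_iso + sample(2:3, 1L)
  ex_len <- sample(spec$exon_len[1]:spec$exon_len[2], n_exons, replace = TRUE)
  in_len <- sample(spec$intron_len[1]:spec$intron_len[2], n_exons - 1L,
                   replace = TRUE)
  starts <- offset + cumsum(c(0L, ex_len[-n_exons] + in_len))
  exons <- cbind(start = starts, end = starts + ex_len)

  seq <- random_dna(sum(ex_len) + sum(in_len))
  for (j in seq_len(n_exons - 1L)) {
    i0 <- exons[j, 2] - offset          # intron start, 0-based within locus
    i1 <- exons[j + 1L, 1] - offset     # intron end
    substr(seq, i0 + 1L, i0 + 2L) <- "GT"
    substr(seq, i1 - 1L, i1) <- "AG"
  }

  # cassette region: n_iso - 1 adjacent internal exons, each skipped by one
  # variant isoform
  if (n_iso > 1L) {
    cstart <- sample(2:(n_exons - n_iso + 1L), 1L)
    skips <- cstart + seq_len(n_iso - 1L) - 1L
  } else {
    skips <- integer()
  }
  chains <- c(list(seq_len(n_exons)),
              lapply(skips, function(s) setdiff(seq_len(n_exons), s)))
  covs <- sample(spec$coverage[1]:spec$coverage[2], n_iso)
  tibble(
    transcript_id = sprintf("TRUE.%d.%d", locus_id, seq_len(n_iso)),
    gene_id = sprintf("TRUEG.%d", locus_id),
    rname = rname, strand = "+",
    exons = lapply(chains, function(ch) exons[ch, , drop = FALSE]),
    coverage = as.numeric(covs)
  ) %>%
    mutate(n_exons = vapply(.data$exons, nrow, 0L)) -> tx
  list(seq = seq, transcripts = tx)
}

#' Generate a deterministic multi-locus fixture
#'
#' Seeds the RNG from the spec and lays `n_loci` loci on one reference
#' sequence, separated by pads wider than any bundling gap.
#'
#' @param spec [fixture_spec()].
#' @param pad Intergenic pad (bp) between loci (default 800).
#' @return List with `genome` (named character vector), `transcripts`
#'   (truth tibble), `seqlengths`, and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), pad = 800L) {
  withr::with_seed(spec$seed, {
    pieces <- character(); txs <- list()
    offset <- 0L
    for (l in seq_len(spec$n_loci)) {
      pieces <- c(pieces, random_dna(pad))
      offset <- offset + pad
      loc <- generate_locus(spec, offset = offset, locus_id = l)
      pieces <- c(pieces, loc$seq)
      offset <- offset + nchar(loc$seq)
      txs[[l]] <- loc$transcripts
    }
    pieces <- c(pieces, random_dna(pad))
    genome <- setNames(paste(pieces, collapse = ""), "chrS")
    list(genome = genome, transcripts = bind_rows(txs),
         seqlengths = setNames(nchar(genome), "chrS"), spec = spec)
  })
}

# transcript-local interval [s, e) -> genomic block matrix through the exon
# chain
tx_to_genomic <- function(exons, s, e) {
  w <- exons[, 2] - exons[, 1]
  cum <- cumsum(c(0, w))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    a <- max(s, cum[i]); b <- min(e, cum[i + 1L])
    if (a < b) {
      out[[length(out) + 1L]] <- c(exons[i, 1] + (a - cum[i]),
                                   exons[i, 1] + (b - cum[i]))
    }
  }
  mat <- do.call(rbind, out)
  colnames(mat) <- c("start", "end")
  mat
}

transcript_seq <- function(genome, rname, exons) {
  paste(substring(genome[[rname]], exons[, 1] + 1L, exons[, 2]), collapse = "")
}

#' Simulate noiseless short-read alignments
#'
#' Reads tile each transcript uniformly at its truth coverage; spliced reads
#' get the correct `N` CIGAR gaps and `XS` strand, NM = 0. Paired mode emits
#' proper pairs with the spec's insert size. Consumes the current RNG stream
#' only through transcript order (the tiling itself is deterministic).
#'
#' @param transcripts Truth tibble with `coverage`.
#' @param spec [fixture_spec()].
#' @return Alignment tibble in [read_sam()] shape (plus `mate_start`,
#'   `tlen`), with qnames encoding the originating transcript (the
#'   ground-truth manifest).
#' @export
simulate_short_alignments <- function(transcripts, spec = fixture_spec()) {
  rl <- spec$read_len
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[i]]
    L <- sum(ex[, 2] - ex[, 1])
    if (rl > L) {
      warn(sprintf("transcript %s shorter than read length; skipped",
                   transcripts$transcript_id[i]))
      next
    }
    cov <- transcripts$coverage[i]
    n_reads <- max(1L, round(cov * L / rl))
    mk <- function(s, e, qname, flag, mate_s, tlen, first) {
      b <- tx_to_genomic(ex, s, e)
      tibble(qname = qname, flag = flag, rname = transcripts$rname[i],
             start = b[1, 1], end = b[nrow(b), 2], blocks = list(b),
             strand = if (nrow(b) > 1L) transcripts$strand[i] else "*",
             nm = 0, nh = 1, xc = NA_real_, weight = 1,
             aligned_len = sum(b[, 2] - b[, 1]),
             paired = spec$paired, is_first = first, is_long = FALSE,
             mate_start = mate_s, tlen = tlen)
    }
    if (spec$paired) {
      FL <- min(spec$insert_len, L)
      n_frag <- max(1L, ceiling(n_reads / 2))
      starts <- if (n_frag == 1L) 0 else round(seq(0, L - FL, length.out = n_frag))
      for (fi in seq_along(starts)) {
        s <- starts[fi]
        qn <- sprintf("%s_f%d", transcripts$transcript_id[i], fi)
        b1 <- tx_to_genomic(ex, s, s + rl)
        b2 <- tx_to_genomic(ex, s + FL - rl, s + FL)
        out[[length(out) + 1L]] <- mk(s, s + rl, qn, 99L, b2[1, 1],
                                      b2[nrow(b2), 2] - b1[1, 1], TRUE)
        out[[length(out) + 1L]] <- mk(s + FL - rl, s + FL, qn, 147L, b1[1, 1],
                                      -(b2[nrow(b2), 2] - b1[1, 1]), FALSE)
      }
    } else {
      starts <- if (n_reads == 1L) 0 else round(seq(0, L - rl, length.out = n_reads))
      for (ri in seq_along(starts)) {
        qn <- sprintf("%s_r%d", transcripts$transcript_id[i], ri)
        out[[length(out) + 1L]] <- mk(starts[ri], starts[ri] + rl, qn, 0L,
                                      NA_real_, 0, FALSE)
      }
    }
  }
  bind_rows(out)
}

#' Simulate error-injected long-read alignments
#'
#' Emits full-length (optionally truncated) reads per transcript. A
#' configurable fraction stays error-free (NM = 0) so every true junction has
#' low-error support; the rest carry an elevated NM and have each junction
#' independently jittered by up to `max_jitter` bp with probability
#' `p_jitter`.
#'
#' @param transcripts Truth tibble.
#' @param spec [fixture_spec()].
#' @return List with `alignments` (tibble, `is_long = TRUE`) and
#'   `jitter_log` (tibble `qname`, `junction`, `side`, `true_site`,
#'   `jittered_site`).
#' @export
simulate_long_alignments <- function(transcripts, spec = fixture_spec()) {
  out <- list(); jlog <- list()
  J <- spec$max_jitter
  for (i in seq_len(nrow(transcripts))) {
    ex0 <- transcripts$exons[[i]]
    n <- spec$long_reads_per_tx
    n_clean <- max(1L, round(spec$p_clean * n))
    for (ri in seq_len(n)) {
      ex <- ex0
      clean <- ri <= n_clean
      if (!clean && spec$p_truncate > 0 && stats::runif(1) < spec$p_truncate &&
          nrow(ex) > 2L) {
        if (stats::runif(1) < 0.5) ex <- ex[-1, , drop = FALSE]
        else ex <- ex[-nrow(ex), , drop = FALSE]
      }
      qn <- sprintf("%s_L%d", transcripts$transcript_id[i], ri)
      if (!clean && nrow(ex) > 1L) {
        for (j in seq_len(nrow(ex) - 1L)) {
          if (stats::runif(1) >= spec$p_jitter) next
          side <- sample(c("donor", "acceptor"), 1L)
          delta <- sample(c(-J:-1, 1:J), 1L)
          if (side == "donor") {
            old <- ex[j, 2]; ex[j, 2] <- old + delta
          } else {
            old <- ex[j + 1L, 1]; ex[j + 1L, 1] <- old + delta
          }
          jlog[[length(jlog) + 1L]] <- tibble(
            qname = qn, junction = j, side = side, true_site = old,
            jittered_site = old + delta
          )
        }
      }
      alen <- sum(ex[, 2] - ex[, 1])
      out[[length(out) + 1L]] <- tibble(
        qname = qn, flag = 0L, rname = transcripts$rname[i],
        start = ex[1, 1], end = ex[nrow(ex), 2], blocks = list(unname_blocks(ex)),
        strand = transcripts$strand[i],
        nm = if (clean) 0 else ceiling(spec$long_mismatch_rate * alen),
        nh = 1, xc = NA_real_, weight = 1, aligned_len = alen,
        paired = FALSE, is_first = FALSE, is_long = TRUE,
        mate_start = NA_real_, tlen = 0
      )
    }
  }
  jl <- bind_rows(jlog)
  if (nrow(jl) == 0L) {
    jl <- tibble(qname = character(), junction = integer(), side = character(),
                 true_site = numeric(), jittered_site = numeric())
  }
  list(alignments = bind_rows(out), jitter_log = jl)
}

unname_blocks <- function(b) {
  m <- cbind(start = as.numeric(b[, 1]), end = as.numeric(b[, 2]))
  rownames(m) <- NULL
  m
}

#' Extract raw short reads for the super-read module
#'
#' Tiles each transcript's spliced sequence with error-free reads at the
#' truth coverage.
#'
#' @param transcripts Truth tibble with `coverage`.
#' @param genome Named character vector from [generate_fixture()].
#' @param spec [fixture_spec()].
#' @return Tibble `id`, `seq`, `transcript_id`.
#' @export
simulate_short_reads <- function(transcripts, genome, spec = fixture_spec()) {
  rl <- spec$read_len
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[i]]
    tseq <- transcript_seq(genome, transcripts$rname[i], ex)
    L <- nchar(tseq)
    if (rl > L) next
    n_reads <- max(1L, round(transcripts$coverage[i] * L / rl))
    starts <- if (n_reads == 1L) 0 else round(seq(0, L - rl, length.out = n_reads))
    out[[length(out) + 1L]] <- tibble(
      id = sprintf("%s_s%d", transcripts$transcript_id[i], seq_along(starts)),
      seq = substring(tseq, starts + 1L, starts + rl),
      transcript_id = transcripts$transcript_id[i]
    )
  }
  bind_rows(out)
}

#' Write a fixture to disk
#'
#' Writes the genome FASTA, truth GTF, simulated short-read SAM and the
#' ground-truth manifest TSV for a fixture, re-parseable by the package's own
#' readers.
#'
#' @param fix Fixture from [generate_fixture()].
#' @param dir Output directory.
#' @return Named list of written paths.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "truth.gtf"),
    sam = file.path(dir, "short.sam"),
    manifest = file.path(dir, "manifest.tsv")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fix$genome),
                              paths$genome)
  write_gtf(fix$transcripts, paths$gtf)
  aln <- withr::with_seed(fix$spec$seed + 1L,
                          simulate_short_alignments(fix$transcripts, fix$spec))
  write_sam(aln, paths$sam, fix$seqlengths)
  manifest <- tibble(qname = aln$qname,
                     transcript_id = sub("_[fr][0-9]+$", "", aln$qname))
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
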