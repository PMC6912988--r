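#' Write transcripts to GTF
#'
#' Emits GTF2.2 `transcript` and `exon` features with 1-based inclusive
#' coordinates and `gene_id`/`transcript_id`/`cov` attributes, ordered
#' deterministically by coordinate.
#'
#' @param transcripts Transcript tibble (see [assemble_sam()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##description: assembled transcripts", con)
  if (nrow(transcripts) == 0L) return(invisible(path))
  tx <- transcripts
  if (!"transcript_id" %in% names(tx)) {
    tx$transcript_id <- paste0("tx.", seq_len(nrow(tx)))
  }
  if (!"gene_id" %in% names(tx)) tx$gene_id <- tx$transcript_id
  if (!"coverage" %in% names(tx)) tx$coverage <- NA_real_
  ord <- order(tx$rname, vapply(tx$exons, function(e) e[1, 1], numeric(1)),
               tx$transcript_id)
  tx <- tx[ord, ]
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    strand <- if (tx$strand[i] %in% c("+", "-")) tx$strand[i] else "."
    covattr <- if (is.na(tx$coverage[i])) "" else
      sprintf(' cov "%.6g";', tx$coverage[i])
    attr0 <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                     tx$gene_id[i], tx$transcript_id[i], covattr)
    writeLines(sprintf("%s\tspliceflow\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tx$rname[i], as.integer(ex[1, 1]) + 1L,
                       as.integer(ex[nrow(ex), 2]), strand, attr0), con)
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf(
        "%s\tspliceflow\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
        tx$rname[i], as.integer(ex[j, 1]) + 1L, as.integer(ex[j, 2]),
        strand, attr0, j), con)
    }
  }
  invisible(path)
}

#' Read transcripts from GTF
#'
#' Imports `exon` features and reassembles per-transcript exon chains, in
#' 0-based half-open coordinates.
#'
#' @param path Path to a GTF file.
#' @return Transcript tibble: `transcript_id`, `gene_id`, `rname`, `strand`,
#'   `exons`, `coverage` (from a `cov` attribute when present), `n_exons`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  rname = character(), strand = character(), exons = list(),
                  coverage = numeric(), n_exons = integer()))
  }
  df <- tibble(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    rname = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    coverage = if ("cov" %in% names(S4Vectors::mcols(gr))) {
      suppressWarnings(as.numeric(gr$cov))
    } else NA_real_
  )
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  df %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = .data$gene_id[1], rname = .data$rname[1],
      strand = .data$strand[1],
      exons = {
        o <- order(.data$start)
        list(cbind(start = .data$start[o], end = .data$end[o]))
      },
      coverage = .data$coverage[1],
      .groups = "drop"
    ) %>%
    mutate(n_exons = vapply(.data$exons, nrow, 0L)) %>%
    arrange(.data$rname, vapply(.data$exons, function(e) e[1, 1], numeric(1)))
}
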