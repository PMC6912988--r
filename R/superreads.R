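#' Reverse complement
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

canonical <- function(kmers) {
  if (length(kmers) == 0L) return(kmers)
  rc <- revcomp(kmers)
  pmin(kmers, rc)
}

#' Build a k-mer multiplicity table
#'
#' Counts every k-mer of every read in canonical form (a k-mer and its
#' reverse complement share an entry). No minimum-count filter is applied:
#' transcripts can be covered by a single read, so count-1 k-mers are kept.
#' k-mers containing N are skipped.
#'
#' @param reads Character vector of read sequences (or a FASTA/FASTQ path).
#' @param k k-mer length (>= 2).
#' @return Tibble `kmer` (canonical), `count`.
#' @export
build_kmer_table <- function(reads, k) {
  stopifnot(k >= 2)
  if (length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  km <- unlist(lapply(toupper(reads), kmerize, k = k))
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0L) return(tibble(kmer = character(), count = numeric()))
  tab <- table(canonical(km))
  tibble(kmer = names(tab), count = as.numeric(tab)) %>%
    arrange(.data$kmer)
}

# oriented successors/predecessors present in the canonical k-mer set
succs <- function(km, kset) {
  k <- nchar(km)
  cand <- paste0(substr(km, 2, k), c("A", "C", "G", "T"))
  cand[canonical(cand) %in% kset]
}
preds <- function(km, kset) {
  cand <- paste0(c("A", "C", "G", "T"), substr(km, 1, nchar(km) - 1L))
  cand[canonical(cand) %in% kset]
}

#' Build k-unitigs from a k-mer table
#'
#' A k-unitig is a maximal sequence in which every k-mer except the first and
#' last has a unique preceding and a unique following k-mer in the table.
#' Every k-mer of the table belongs to exactly one unitig (up to reverse
#' complement).
#'
#' @param table K-mer table from [build_kmer_table()].
#' @return Tibble `id`, `seq`, `k`, `n_kmers`.
#' @export
build_kunitigs <- function(table) {
  stopifnot(nrow(table) > 0)
  k <- nchar(table$kmer[1])
  kset <- table$kmer
  visited <- new.env(parent = emptyenv())
  unitigs <- character()
  for (start in kset) {
    if (!is.null(visited[[start]])) next
    seq <- start
    assign(start, TRUE, envir = visited)
    # extend right
    cur <- start
    repeat {
      nx <- succs(cur, kset)
      if (length(nx) != 1L) break
      if (length(preds(nx, kset)) != 1L) break
      cn <- canonical(nx)
      if (!is.null(visited[[cn]])) break
      seq <- paste0(seq, substr(nx, k, k))
      assign(cn, TRUE, envir = visited)
      cur <- nx
    }
    # extend left
    cur <- start
    repeat {
      pv <- preds(cur, kset)
      if (length(pv) != 1L) break
      if (length(succs(pv, kset)) != 1L) break
      cn <- canonical(pv)
      if (!is.null(visited[[cn]])) break
      seq <- paste0(substr(pv, 1, 1), seq)
      assign(cn, TRUE, envir = visited)
      cur <- pv
    }
    unitigs <- c(unitigs, seq)
  }
  tibble(id = paste0("u", seq_along(unitigs)), seq = unitigs, k = k,
         n_kmers = nchar(unitigs) - k + 1L)
}

# canonical k-mer -> (unitig row, position, orientation) index; k-mers with
# a unique placement only
kunitig_index <- function(kunitigs) {
  k <- kunitigs$k[1]
  rows <- lapply(seq_len(nrow(kunitigs)), function(i) {
    km <- kmerize(kunitigs$seq[i], k)
    tibble(canon = canonical(km), uid = i, pos = seq_along(km),
           fwd = km == canonical(km))
  })
  idx <- bind_rows(rows)
  dup <- idx$canon[duplicated(idx$canon)]
  idx[!idx$canon %in% dup, , drop = FALSE]
}

#' Extend a short read to a super-read
#'
#' Locates the read's terminal k-mers in their containing k-unitigs and
#' extends the read left and right to the unitig ends — as far as there is a
#' unique extension. If a terminal k-mer is not in any unitig, or its
#' placement is ambiguous or inconsistent with the read, no super-read is
#' produced.
#'
#' @param read A read sequence.
#' @param kunitigs K-unitig tibble from [build_kunitigs()].
#' @param index Optional precomputed `kunitig_index(kunitigs)` for repeated
#'   calls.
#' @return The super-read sequence, or `NA_character_`.
#' @export
extend_to_superreads <- function(read, kunitigs, index = NULL) {
  k <- kunitigs$k[1]
  n <- nchar(read)
  if (n < k) return(NA_character_)
  if (is.null(index)) index <- kunitig_index(kunitigs)
  place <- function(kmer) {
    hit <- index[index$canon == canonical(kmer), ]
    if (nrow(hit) != 1L) return(NULL)
    u <- kunitigs$seq[hit$uid]
    # orient the unitig so that it contains `kmer` forward at some position
    if (substr(u, hit$pos, hit$pos + k - 1L) == kmer) {
      list(seq = u, pos = hit$pos)
    } else {
      ru <- revcomp(u)
      p <- nchar(u) - (hit$pos + k - 1L) + 1L
      if (substr(ru, p, p + k - 1L) == kmer) list(seq = ru, pos = p) else NULL
    }
  }
  left <- place(substr(read, 1, k))
  right <- place(substr(read, n - k + 1L, n))
  if (is.null(left) || is.null(right)) return(NA_character_)
  ext_l <- substr(left$seq, 1, left$pos - 1L)
  ext_r <- substr(right$seq, right$pos + k, nchar(right$seq))
  paste0(ext_l, read, ext_r)
}

#' Assign short reads to aligned super-reads
#'
#' A read is assigned to a super-read iff the read (or its reverse
#' complement) is an exact substring of the super-read sequence — equivalent
#' to its k-unitig chain being contained in the super-read in the same
#' (or reverse) order. Only super-reads flagged as aligned to the reference
#' genome are considered.
#'
#' @param superreads Tibble with `id`, `seq` and logical `aligned`.
#' @param reads Tibble with `id`, `seq`.
#' @return Assignment tibble `read_id`, `superread_id`.
#' @export
assign_reads <- function(superreads, reads) {
  sr <- superreads[superreads$aligned, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    hit <- stringr::str_detect(sr$seq, stringr::fixed(s)) |
      stringr::str_detect(sr$seq, stringr::fixed(revcomp(s)))
    if (any(hit)) {
      out[[length(out) + 1L]] <- tibble(read_id = reads$id[i],
                                        superread_id = sr$id[hit])
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(read_id = character(), superread_id = character())
  }
  res
}

#' Write super-read alignments as SAM with a coverage tag
#'
#' One record per super-read alignment, carrying the EM coverage estimate in
#' an `XC:f:` tag. Downstream assembly weights these records by the tag and
#' ignores their first/last k-1 aligned bases.
#'
#' @param superreads Tibble with `id`, `coverage`.
#' @param alignments Tibble with `id`, `rname`, `start` (0-based), `blocks`,
#'   `strand`, optional `seq`.
#' @param path Output SAM path.
#' @param seqlengths Named vector for the `@SQ` header.
#' @return `path`, invisibly.
#' @export
emit_superread_sam <- function(superreads, alignments, path, seqlengths) {
  aln <- left_join(alignments, superreads[, c("id", "coverage")], by = "id")
  aln$qname <- aln$id
  aln$flag <- ifelse(!is.na(aln$strand) & aln$strand == "-", 16L, 0L)
  aln$xc <- aln$coverage
  aln$nm <- 0
  write_sam(aln, path, seqlengths)
}
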