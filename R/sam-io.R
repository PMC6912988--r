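#' Read spliced alignments from a SAM file
#'
#' Parses primary alignment records into a tibble of exon-block alignments.
#' CIGAR `M`/`=`/`X`/`D` operations extend the current exon block on the
#' reference, `N` closes a block and opens the next, and `I`/`S` consume read
#' only. Coordinates are converted from SAM's 1-based to 0-based half-open.
#' Unmapped, secondary and supplementary records are skipped.
#'
#' Tags consumed: `NM` (mismatches; 0 when absent), `NH` (hits; alignment
#' weight is `1/NH`), `XS` (transcription strand), `XC` (super-read coverage;
#' overrides the weight when present).
#'
#' @param path Path to a SAM file (text).
#' @param long_reads Mark all parsed records as long reads (`is_long`).
#' @return A tibble with one row per primary alignment: `qname`, `flag`,
#'   `rname`, `start`, `end` (0-based half-open span), `blocks` (list of
#'   two-column integer matrices, 0-based half-open exon blocks), `strand`
#'   (`"+"`, `"-"` or `"*"`), `nm`, `nh`, `xc`, `weight`, `aligned_len`,
#'   `paired`, `is_first`, `is_long`.
#' @export
read_sam <- function(path, long_reads = FALSE) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- vapply(strsplit(hdr[startsWith(hdr, "@SQ")], "\t", fixed = TRUE),
               function(f) sub("^SN:", "", f[startsWith(f, "SN:")][1]), "")
  if (length(rec) == 0L) return(empty_alignments())

  f <- strsplit(rec, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) {
    abort(sprintf("malformed SAM record (fewer than 11 fields): %s",
                  rec[which(nf < 11L)[1]]))
  }
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)

  keep <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  if (!any(keep)) return(empty_alignments())
  f <- f[keep]; rec <- rec[keep]; qname <- qname[keep]; flag <- flag[keep]
  rname <- rname[keep]; pos <- pos[keep]; cigar <- cigar[keep]

  if (length(sq) && any(!rname %in% sq)) {
    abort(sprintf("alignment references sequence '%s' missing from the header",
                  setdiff(rname, sq)[1]))
  }
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad)) {
    abort(sprintf("malformed CIGAR '%s' in record '%s'",
                  cigar[which(bad)[1]], qname[which(bad)[1]]))
  }

  blocks <- cigar_to_blocks(cigar, pos)
  tagstr <- vapply(f, function(x) paste(x[-(1:11)], collapse = "\t"), "")
  nm <- tag_num(tagstr, "NM:i:([0-9]+)")
  nh <- tag_num(tagstr, "NH:i:([0-9]+)")
  xc <- tag_num(tagstr, "XC:f:([0-9.eE+-]+)")
  xs <- stringr::str_match(tagstr, "XS:A:([+-])")[, 2]

  nm[is.na(nm)] <- 0
  nh[is.na(nh)] <- 1
  aligned_len <- vapply(blocks, function(b) sum(b[, 2] - b[, 1]), numeric(1))
  tibble(
    qname = qname,
    flag = flag,
    rname = rname,
    start = vapply(blocks, function(b) b[1, 1], numeric(1)),
    end = vapply(blocks, function(b) b[nrow(b), 2], numeric(1)),
    blocks = blocks,
    strand = ifelse(is.na(xs), "*", xs),
    nm = nm,
    nh = nh,
    xc = xc,
    weight = ifelse(is.na(xc), 1 / nh, xc),
    aligned_len = aligned_len,
    paired = bitwAnd(flag, 1L) > 0L,
    is_first = bitwAnd(flag, 64L) > 0L,
    is_long = long_reads
  )
}

empty_alignments <- function() {
  tibble(
    qname = character(), flag = integer(), rname = character(),
    start = numeric(), end = numeric(), blocks = list(),
    strand = character(), nm = numeric(), nh = numeric(), xc = numeric(),
    weight = numeric(), aligned_len = numeric(),
    paired = logical(), is_first = logical(), is_long = logical()
  )
}

# CIGAR -> list of 0-based half-open exon-block matrices.  M/=/X/D ranges are
# merged (reduce) so only N gaps split blocks, per the SAM reference-consuming
# semantics.
cigar_to_blocks <- function(cigar, pos) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X", "D"), reduce.ranges = TRUE
  )
  starts <- unlist(IRanges::start(rl), use.names = FALSE) - 1L
  ends <- unlist(IRanges::end(rl), use.names = FALSE)
  nb <- S4Vectors::elementNROWS(rl)
  idx <- rep.int(seq_along(nb), nb)
  unname(lapply(split(seq_along(starts), idx), function(i) {
    cbind(start = starts[i], end = ends[i])
  }))
}

tag_num <- function(tagstr, pattern) {
  as.numeric(stringr::str_match(tagstr, pattern)[, 2])
}

# introns of one block matrix: two-column matrix [donor, acceptor) (0-based,
# donor = exon end, acceptor = next exon start)
block_introns <- function(blocks) {
  if (nrow(blocks) < 2L) {
    return(cbind(donor = numeric(0), acceptor = numeric(0)))
  }
  cbind(donor = blocks[-nrow(blocks), 2], acceptor = blocks[-1, 1])
}

blocks_to_cigar <- function(blocks) {
  w <- blocks[, 2] - blocks[, 1]
  if (nrow(blocks) == 1L) return(sprintf("%dM", as.integer(w)))
  gaps <- blocks[-1, 1] - blocks[-nrow(blocks), 2]
  paste0(paste0(as.integer(w[-length(w)]), "M",
                as.integer(gaps), "N", collapse = ""),
         as.integer(w[length(w)]), "M")
}

#' Write alignments to a SAM file
#'
#' Serialises an alignment tibble (as produced by [read_sam()] or the
#' simulators) back to SAM text. Exon blocks become `M`/`N` CIGAR strings;
#' `NM`, `NH`, `XS` and `XC` tags are emitted when the corresponding columns
#' are present and non-missing.
#'
#' @param aln Alignment tibble with at least `qname`, `flag`, `rname`,
#'   `start`, `blocks`; optional `seq`, `nm`, `nh`, `strand`, `xc`,
#'   `mate_start`, `tlen`.
#' @param path Output file path.
#' @param seqlengths Named integer vector of reference sequence lengths for
#'   the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  cig <- vapply(aln$blocks, blocks_to_cigar, "")
  seq <- if ("seq" %in% names(aln)) aln$seq else rep("*", nrow(aln))
  mate_pos <- if ("mate_start" %in% names(aln)) aln$mate_start else rep(NA_real_, nrow(aln))
  tlen <- if ("tlen" %in% names(aln)) aln$tlen else rep(0, nrow(aln))
  rnext <- ifelse(is.na(mate_pos), "*", "=")
  pnext <- ifelse(is.na(mate_pos), 0, mate_pos + 1)
  tags <- character(nrow(aln))
  add_tag <- function(tags, fmt, val, keep) {
    ifelse(keep, paste0(tags, sprintf(fmt, val)), tags)
  }
  if ("nm" %in% names(aln)) {
    tags <- add_tag(tags, "\tNM:i:%d", as.integer(aln$nm), !is.na(aln$nm))
  }
  if ("nh" %in% names(aln)) {
    tags <- add_tag(tags, "\tNH:i:%d", as.integer(aln$nh), !is.na(aln$nh) & aln$nh != 1)
  }
  if ("strand" %in% names(aln)) {
    spliced <- vapply(aln$blocks, nrow, 0L) > 1L
    tags <- add_tag(tags, "\tXS:A:%s", aln$strand,
                    aln$strand %in% c("+", "-") & spliced)
  }
  if ("xc" %in% names(aln)) {
    tags <- add_tag(tags, "\tXC:f:%g", aln$xc, !is.na(aln$xc))
  }
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t%s\t*%s",
                  aln$qname, as.integer(aln$flag), aln$rname,
                  as.integer(aln$start) + 1L, cig, rnext,
                  as.integer(pnext), as.integer(tlen), seq, tags)
  writeLines(c(hdr, body), path)
  invisible(path)
}
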