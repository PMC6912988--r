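location_key <- function(rname, strand, blocks) {
  paste0(rname, ":", strand, ":",
         vapply(blocks, function(b) paste(b[, 1], b[, 2], sep = "-", collapse = ","), ""))
}

#' Collapse identical alignments
#'
#' Reads aligned to the identical genomic location (same reference, strand and
#' exon-block chain) are stored once with a multiplicity count, which keeps
#' memory flat at highly expressed loci. Mate pairings are preserved as links
#' between collapsed locations: because two reads collapsed together need not
#' have their mates at the same location, each collapsed alignment records
#' every mate location observed with it, with its multiplicity.
#'
#' @param reads Alignment tibble from [read_sam()] (one reference sequence).
#' @return A tibble with one row per distinct location: `key`, `rname`,
#'   `strand`, `start`, `end`, `blocks`, `count` (sum of alignment weights),
#'   `n` (raw number of collapsed records) and `mate_links` (list of tibbles
#'   `key`, `pair_count`).
#' @export
collapse_alignments <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(key = character(), rname = character(), strand = character(),
                  start = numeric(), end = numeric(), blocks = list(),
                  count = numeric(), n = integer(), mate_links = list()))
  }
  reads$key <- location_key(reads$rname, reads$strand, reads$blocks)
  collapsed <- reads %>%
    group_by(.data$key) %>%
    summarise(
      rname = .data$rname[1], strand = .data$strand[1],
      start = .data$start[1], end = .data$end[1],
      blocks = .data$blocks[1],
      count = sum(.data$weight), n = dplyr::n(),
      .groups = "drop"
    )

  pairs <- pair_fragments(reads)
  paired <- pairs[!is.na(pairs$key2), , drop = FALSE]
  links <- bind_rows(
    tibble(key = paired$key1, mate = paired$key2, w = paired$weight),
    tibble(key = paired$key2, mate = paired$key1, w = paired$weight)
  )
  if (nrow(links)) {
    links <- links %>%
      group_by(.data$key, .data$mate) %>%
      summarise(pair_count = sum(.data$w), .groups = "drop")
  }
  empty_link <- tibble(key = character(), pair_count = numeric())
  if (nrow(links)) {
    lk <- split(tibble(key = links$mate, pair_count = links$pair_count),
                links$key)
    collapsed$mate_links <- lapply(collapsed$key, function(k) {
      lk[[k]] %||% empty_link
    })
  } else {
    collapsed$mate_links <- rep(list(empty_link), nrow(collapsed))
  }
  arrange(collapsed, .data$start, .data$end, .data$key)
}

# Resolve mate pairs by query name (cross-checked against PNEXT upstream in
# read_sam by construction); returns one row per fragment: key1, key2 (NA for
# unpaired), weight.  Qnames with anything other than exactly two primary
# records are treated as unpaired.
pair_fragments <- function(reads) {
  if (!"key" %in% names(reads)) {
    reads$key <- location_key(reads$rname, reads$strand, reads$blocks)
  }
  if (nrow(reads) == 0L) {
    return(tibble(key1 = character(), key2 = character(), weight = numeric()))
  }
  idx <- split(seq_len(nrow(reads)), reads$qname)
  is_pair <- vapply(idx, function(i) length(i) == 2L && all(reads$paired[i]),
                    logical(1))
  pr <- idx[is_pair]
  i1 <- vapply(pr, function(i) i[order(!reads$is_first[i])][1], 0L)
  i2 <- vapply(pr, function(i) i[order(!reads$is_first[i])][2], 0L)
  single <- unlist(idx[!is_pair], use.names = FALSE)
  bind_rows(
    tibble(key1 = reads$key[i1], key2 = reads$key[i2],
           weight = pmin(reads$weight[i1], reads$weight[i2])),
    tibble(key1 = reads$key[single], key2 = NA_character_,
           weight = reads$weight[single])
  )
}

#' Tabulate splice junctions
#'
#' Builds the per-bundle junction support table used by the spliced-alignment
#' filters and by splice-site correction. Support is weighted by alignment
#' weight (1/NH, or the super-read coverage tag). Anchors are the aligned
#' bases flanking the junction within each supporting read; the table keeps
#' the maximum over supporting reads on each side.
#'
#' @param reads Alignment tibble.
#' @param low_error_rate Mismatch-rate cutoff below which a read counts as
#'   low-error support (used by long-read splice-site correction).
#' @return Tibble with `rname`, `donor`, `acceptor` (0-based intron
#'   boundaries), `strand`, `support`, `low_error_support`,
#'   `max_anchor_left`, `max_anchor_right`, `intron_len`.
#' @export
junction_table <- function(reads, low_error_rate = 0.02) {
  jn <- read_junctions(reads)
  if (nrow(jn) == 0L) {
    return(tibble(rname = character(), donor = numeric(), acceptor = numeric(),
                  strand = character(), support = numeric(),
                  low_error_support = numeric(), max_anchor_left = numeric(),
                  max_anchor_right = numeric(), intron_len = numeric()))
  }
  jn %>%
    group_by(.data$rname, .data$donor, .data$acceptor) %>%
    summarise(
      strand = if (any(.data$strand != "*")) .data$strand[.data$strand != "*"][1] else "*",
      support = sum(.data$weight),
      low_error_support = sum(.data$weight[.data$mm_rate <= low_error_rate]),
      max_anchor_left = max(.data$anchor_left),
      max_anchor_right = max(.data$anchor_right),
      .groups = "drop"
    ) %>%
    mutate(intron_len = .data$acceptor - .data$donor) %>%
    arrange(.data$rname, .data$donor, .data$acceptor)
}

# one row per (read, junction)
read_junctions <- function(reads) {
  nb <- vapply(reads$blocks, nrow, 0L)
  spliced <- which(nb > 1L)
  if (length(spliced) == 0L) {
    return(tibble(read = integer(), rname = character(), strand = character(),
                  donor = numeric(), acceptor = numeric(),
                  anchor_left = numeric(), anchor_right = numeric(),
                  weight = numeric(), mm_rate = numeric()))
  }
  per <- nb[spliced] - 1L
  i <- rep.int(spliced, per)
  donor <- as.numeric(unlist(lapply(reads$blocks[spliced],
                                    function(b) b[-nrow(b), 2])))
  acceptor <- as.numeric(unlist(lapply(reads$blocks[spliced],
                                       function(b) b[-1, 1])))
  aleft <- as.numeric(unlist(lapply(reads$blocks[spliced], function(b) {
    (b[, 2] - b[, 1])[-nrow(b)]
  })))
  aright <- as.numeric(unlist(lapply(reads$blocks[spliced], function(b) {
    (b[, 2] - b[, 1])[-1]
  })))
  tibble(
    read = i, rname = reads$rname[i], strand = reads$strand[i],
    donor = donor, acceptor = acceptor,
    anchor_left = aleft, anchor_right = aright,
    weight = reads$weight[i],
    mm_rate = reads$nm[i] / pmax(reads$aligned_len[i], 1)
  )
}

#' Filter spurious spliced alignments
#'
#' Applies the spliced-alignment noise filters. Every junction needs
#' `min_junction_support` supporting reads and a `min_anchor` (10 bp) anchor
#' on each side in at least one supporting read. Reads aligned with more than
#' 1% mismatches must clear 25% more support (1.25 reads by default) at every
#' junction they span. Introns longer than 100 kb are accepted only with a
#' 25 bp anchor on both sides.
#'
#' @param reads Alignment tibble.
#' @param junctions Junction table from [junction_table()]; computed from
#'   `reads` when `NULL` (the table must be built from all reads of the
#'   bundle, before filtering).
#' @param params [assembly_params()].
#' @return `reads` with logical `keep` and character `drop_reason` columns.
#' @export
filter_spliced_alignments <- function(reads, junctions = NULL,
                                      params = assembly_params()) {
  if (is.null(junctions)) junctions <- junction_table(reads)
  reads$keep <- TRUE
  reads$drop_reason <- NA_character_
  jn <- read_junctions(reads)
  if (nrow(jn) == 0L) return(reads)
  jn <- left_join(jn, junctions,
                  by = c("rname", "donor", "acceptor"),
                  suffix = c("", ".tab"))
  need <- ifelse(jn$mm_rate > params$max_mismatch_rate,
                 params$high_mismatch_boost * params$min_junction_support,
                 params$min_junction_support)
  long_intron <- (jn$acceptor - jn$donor) > params$long_intron_length
  anchor_need <- ifelse(long_intron, params$long_intron_anchor, params$min_anchor)
  jn$reason <- case_when(
    jn$support < need & jn$mm_rate > params$max_mismatch_rate ~ "high_mismatch_low_support",
    jn$support < need ~ "low_support",
    long_intron & (jn$max_anchor_left < anchor_need |
                     jn$max_anchor_right < anchor_need) ~ "long_intron_weak_anchor",
    jn$max_anchor_left < anchor_need | jn$max_anchor_right < anchor_need ~ "weak_anchor",
    TRUE ~ NA_character_
  )
  bad <- jn %>%
    filter(!is.na(.data$reason)) %>%
    group_by(.data$read) %>%
    summarise(reason = .data$reason[1], .groups = "drop")
  reads$keep[bad$read] <- FALSE
  reads$drop_reason[bad$read] <- bad$reason
  reads
}
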