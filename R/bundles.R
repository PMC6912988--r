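#' Group alignments into bundles
#'
#' A bundle is a maximal genomic region of read alignments in which no two
#' consecutive covered regions are separated by more than `max_gap` bp — the
#' unit of assembly (a putative gene locus). Alignments spanning an intron
#' count as covering their whole genomic span for gap purposes.
#'
#' @param collapsed Collapsed-alignment tibble from [collapse_alignments()]
#'   (or any tibble with `rname`, `start`, `end`).
#' @param max_gap Maximum allowable gap between reads within one bundle
#'   (default 50 bp; 200 is typical for gap-rich genomes).
#' @return A nested tibble: one row per bundle with `bundle_id`, `rname`,
#'   `start`, `end` and an `alignments` list-column holding the rows of
#'   `collapsed` assigned to the bundle.
#' @export
build_bundles <- function(collapsed, max_gap = 50) {
  if (nrow(collapsed) == 0L) {
    return(tibble(bundle_id = integer(), rname = character(),
                  start = numeric(), end = numeric(), alignments = list()))
  }
  collapsed <- arrange(collapsed, .data$rname, .data$start, .data$end)
  out <- collapsed %>%
    group_by(.data$rname) %>%
    mutate(bundle_local = {
      cummax_end <- cummax(dplyr::lag(cummax(.data$end), default = -Inf))
      cumsum(.data$start - cummax_end > max_gap | dplyr::row_number() == 1L)
    }) %>%
    ungroup()
  nested <- out %>%
    group_by(.data$rname, .data$bundle_local) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              alignments = list(dplyr::pick(dplyr::everything())),
              .groups = "drop") %>%
    arrange(.data$rname, .data$start)
  nested$alignments <- lapply(seq_len(nrow(nested)), function(i) {
    a <- nested$alignments[[i]]
    a$bundle_local <- NULL
    a$rname <- nested$rname[i]    # grouping column, excluded by pick()
    a[, union("rname", names(a))]
  })
  nested %>%
    mutate(bundle_id = dplyr::row_number()) %>%
    select("bundle_id", "rname", "start", "end", "alignments")
}
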