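#' Plot a splice graph
#'
#' Exonic segment nodes as coverage-height boxes along the genome, junction
#' edges as arcs, adjacency edges as ticks.
#'
#' @param object A `splice_graph`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.splice_graph <- function(object, ...) {
  nd <- object$nodes[object$nodes$alive, , drop = FALSE]
  ed <- tidy(object)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = nd,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = .data$coverage),
      fill = "grey60"
    ) +
    ggplot2::labs(
      x = sprintf("%s (%s)", object$rname, object$strand),
      y = "coverage (reads/bp)",
      title = sprintf("splice graph: %d nodes, %d edges",
                      sum(object$nodes$alive), nrow(object$edges))
    ) +
    ggplot2::theme_minimal()
  jn <- ed[ed$type == "junction", , drop = FALSE]
  if (nrow(jn)) {
    jn$x <- object$nodes$end[jn$from]
    jn$xend <- object$nodes$start[jn$to]
    jn$y <- object$nodes$coverage[jn$from]
    p <- p + ggplot2::geom_curve(
      data = jn,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$y, linewidth = .data$support),
      curvature = -0.25, colour = "steelblue", lineend = "round"
    ) +
      ggplot2::scale_linewidth(range = c(0.3, 1.5))
  }
  p
}

#' Plot assembled transcripts
#'
#' One row per transcript: exon boxes joined by intron lines, shaded by
#' coverage.
#'
#' @param transcripts Transcript tibble.
#' @return A ggplot object.
#' @export
plot_transcripts <- function(transcripts) {
  stopifnot(nrow(transcripts) > 0)
  rows <- bind_rows(lapply(seq_len(nrow(transcripts)), function(i) {
    ex <- transcripts$exons[[i]]
    tibble(
      transcript = if ("transcript_id" %in% names(transcripts)) {
        transcripts$transcript_id[i]
      } else as.character(i),
      start = ex[, 1], end = ex[, 2], y = i,
      coverage = transcripts$coverage[i]
    )
  }))
  spans <- rows %>%
    group_by(.data$transcript, .data$y) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = spans,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$y, yend = .data$y),
      colour = "grey50"
    ) +
    ggplot2::geom_rect(
      data = rows,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$y - 0.35, ymax = .data$y + 0.35,
                   fill = .data$coverage)
    ) +
    ggplot2::scale_y_continuous(breaks = spans$y, labels = spans$transcript) +
    ggplot2::labs(x = "genomic position (bp)", y = NULL, fill = "cov") +
    ggplot2::theme_minimal()
}
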