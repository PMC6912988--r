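#' Transcript-level match
#'
#' A predicted transcript matches a reference transcript iff both are on the
#' same reference sequence, strands are compatible (equal, or unknown on
#' either side), their intron chains are identical coordinate-by-coordinate,
#' and each terminal exon ends within `end_slack` bp of the reference's.
#' Single-exon transcripts match when both interval ends are within the
#' slack.
#'
#' @param predicted,reference Single-row transcript tibbles (or lists with
#'   `rname`, `strand`, `exons`).
#' @param end_slack Terminal-end tolerance in bp (default 100).
#' @return `TRUE` or `FALSE`.
#' @export
match_transcript <- function(predicted, reference, end_slack = 100) {
  px <- predicted$exons[[1]]; rx <- reference$exons[[1]]
  if (predicted$rname[1] != reference$rname[1]) return(FALSE)
  sp <- predicted$strand[1]; sr <- reference$strand[1]
  if (sp %in% c("+", "-") && sr %in% c("+", "-") && sp != sr) return(FALSE)
  if (nrow(px) != nrow(rx)) return(FALSE)
  if (nrow(px) > 1L) {
    jp <- block_introns(px); jr <- block_introns(rx)
    if (!all(as.numeric(jp) == as.numeric(jr))) return(FALSE)
  }
  abs(px[1, 1] - rx[1, 1]) <= end_slack &&
    abs(px[nrow(px), 2] - rx[nrow(rx), 2]) <= end_slack
}

#' Score predictions against a reference set (transcript level)
#'
#' Each prediction is assigned to at most one reference transcript (its best
#' match, ties by smallest total end difference). TP is the number of
#' reference transcripts matched by at least one prediction; surplus
#' predictions matching an already-matched reference count as FP, as do
#' predictions matching nothing. Sensitivity = TP/(TP+FN), precision =
#' TP/(TP+FP).
#'
#' @param predictions,reference Transcript tibbles.
#' @param end_slack Terminal-end tolerance in bp (default 100).
#' @return One-row tibble `level`, `TP`, `FP`, `FN`, `sensitivity`,
#'   `precision`, `flag` (`"no_predictions"` when precision is undefined and
#'   reported as 0).
#' @export
score_predictions <- function(predictions, reference, end_slack = 100) {
  n_ref <- nrow(reference)
  stopifnot(n_ref > 0)
  if (nrow(predictions) == 0L) {
    return(tibble(level = "transcript", TP = 0L, FP = 0L, FN = n_ref,
                  sensitivity = 0, precision = 0, flag = "no_predictions"))
  }
  cand <- candidate_matches(predictions, reference, end_slack)
  matched_ref <- logical(n_ref)
  if (nrow(cand)) {
    cand <- arrange(cand, .data$pred, .data$end_diff, .data$ref)
    best <- cand[!duplicated(cand$pred), ]    # best reference per prediction
    matched_ref[unique(best$ref)] <- TRUE
  }
  TP <- sum(matched_ref)
  FP <- nrow(predictions) - TP
  FN <- n_ref - TP
  tibble(level = "transcript", TP = TP, FP = FP, FN = FN,
         sensitivity = TP / (TP + FN), precision = TP / (TP + FP),
         flag = NA_character_)
}

# all (prediction, reference) pairs satisfying match_transcript, with the
# summed terminal end difference for tie-breaking
candidate_matches <- function(predictions, reference, end_slack) {
  pk <- chain_signature(predictions$rname, predictions$exons)
  rk <- chain_signature(reference$rname, reference$exons)
  p_multi <- vapply(predictions$exons, nrow, 0L) > 1L
  r_multi <- vapply(reference$exons, nrow, 0L) > 1L
  out <- list()
  for (i in seq_len(nrow(predictions))) {
    js <- if (p_multi[i]) which(r_multi & rk == pk[i]) else which(!r_multi)
    for (j in js) {
      if (match_transcript(predictions[i, ], reference[j, ], end_slack)) {
        px <- predictions$exons[[i]]; rx <- reference$exons[[j]]
        d <- abs(px[1, 1] - rx[1, 1]) + abs(px[nrow(px), 2] - rx[nrow(rx), 2])
        out[[length(out) + 1L]] <- tibble(pred = i, ref = j, end_diff = d)
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(pred = integer(), ref = integer(), end_diff = numeric())
  }
  res
}

#' Score predictions at the intron level
#'
#' An intron is correct iff both its ends precisely match a reference
#' intron. TP/FP/FN are computed over the deduplicated intron sets of each
#' side (strand is not part of the intron identity, so unknown-strand
#' predictions can score).
#'
#' @param predictions,reference Transcript tibbles.
#' @return One-row tibble as in [score_predictions()], `level = "intron"`.
#' @export
score_introns <- function(predictions, reference) {
  pset <- intron_set(predictions)
  rset <- intron_set(reference)
  TP <- length(intersect(pset, rset))
  FP <- length(setdiff(pset, rset))
  FN <- length(setdiff(rset, pset))
  tibble(level = "intron", TP = TP, FP = FP, FN = FN,
         sensitivity = if (TP + FN > 0) TP / (TP + FN) else 0,
         precision = if (TP + FP > 0) TP / (TP + FP) else 0,
         flag = if (TP + FP == 0) "no_predicted_introns" else NA_character_)
}

intron_set <- function(transcripts) {
  unique(unlist(lapply(seq_len(nrow(transcripts)), function(i) {
    jn <- block_introns(transcripts$exons[[i]])
    if (nrow(jn) == 0L) return(character())
    paste0(transcripts$rname[i], ":", jn[, 1], "-", jn[, 2])
  })))
}

#' Relative percent change
#'
#' `100 * (x1 - x2) / x2`: e.g. an absolute sensitivity increase from 20% to
#' 30% is a relative increase of 50%.
#'
#' @param x1 Value for the method under test.
#' @param x2 Baseline value (> 0).
#' @return The relative change in percent.
#' @export
relative_change <- function(x1, x2) {
  if (any(x2 <= 0)) abort("relative change is undefined for a baseline <= 0")
  100 * (x1 - x2) / x2
}

#' Union reference set
#'
#' Builds the reference ("true") transcript set for benchmarking on real
#' data as the union of the annotated transcripts correctly predicted by each
#' tool, deduplicated by structural identity (reference sequence, intron
#' chain and terminal ends).
#'
#' @param per_tool_correct A list of transcript tibbles (each a subset of the
#'   annotation).
#' @return A deduplicated transcript tibble; attribute `flag` is
#'   `"empty_reference"` when every input set is empty.
#' @export
union_reference <- function(per_tool_correct) {
  all <- bind_rows(per_tool_correct)
  if (nrow(all) == 0L) {
    attr(all, "flag") <- "empty_reference"
    return(all)
  }
  key <- paste0(chain_signature(all$rname, all$exons), "|",
                vapply(all$exons, function(e) {
                  paste(e[1, 1], e[nrow(e), 2])
                }, ""))
  out <- all[!duplicated(key), , drop = FALSE]
  attr(out, "flag") <- NA_character_
  out
}
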