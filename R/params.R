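#' Assembly parameters
#'
#' Bundles every tunable threshold of the assembler into one list, mirroring
#' the command-line surface of reference-guided short/long-read assemblers.
#' All coordinates are bp; all coverages are reads per base.
#'
#' @param min_junction_support Minimum read support required for a spliced
#'   junction (default 1 read). Reads aligned with more than
#'   `max_mismatch_rate` mismatches need `high_mismatch_boost` times this
#'   support at every one of their junctions.
#' @param max_gap Maximum allowable gap (bp) between reads grouped into one
#'   bundle/locus (default 50; `-g`).
#' @param trim_ends Trim terminal exons where per-bp coverage drops below
#'   `trim_fraction` of the transcript mean (default TRUE; `-t` disables).
#' @param trim_fraction Fraction of transcript mean coverage below which
#'   terminal bases are trimmed (default 0.1).
#' @param long_read_mode Enable long-read processing: splice-site correction,
#'   graph pruning, no end trimming (`-L`).
#' @param min_transcript_coverage Stop extracting paths when no node retains
#'   this much unassigned coverage, and drop transcripts quantified below it
#'   (default 1; `-c`).
#' @param min_isoform_fraction Drop transcripts whose coverage is below this
#'   fraction of the most abundant transcript at the locus (default 0.01;
#'   `-f`).
#' @param max_mismatch_rate Mismatch rate above which a spliced read is
#'   treated as error-prone by the junction filter (default 0.01).
#' @param high_mismatch_boost Junction-support multiplier applied to
#'   error-prone spliced reads (default 1.25, i.e. 25% more reads).
#' @param min_anchor Default minimum anchor (aligned bases flanking a
#'   junction) required on each side, in at least one supporting read
#'   (default 10 bp).
#' @param long_intron_anchor Larger anchor required on both sides of introns
#'   longer than `long_intron_length` (default 25 bp).
#' @param long_intron_length Intron length (bp) above which the larger anchor
#'   is required (default 100000).
#' @param max_nodes Node budget for long-read graph pruning (default 1000).
#' @param correction_window Search window (bp) for splice-site correction of
#'   high-error reads (default 10).
#' @param high_error_threshold Alignment mismatch rate above which a long read
#'   is considered high-error and eligible for splice-site correction
#'   (default 0.02).
#' @param frag_gap_tol When a mate-pair fragment is compatible with several
#'   candidate transcripts, candidates whose implied fragment inner gap
#'   exceeds the smallest implied gap by more than this tolerance (bp) are
#'   dropped from its EM assignment (default 60; `Inf` disables).
#' @param superread_k k-mer length used when super-reads were built; the
#'   first/last `superread_k - 1` aligned bases of super-read records (those
#'   carrying an `XC` coverage tag) are ignored during graph construction
#'   (default 25).
#'
#' @return A named list of class `sf_params`.
#' @export
assembly_params <- function(min_junction_support = 1,
                            max_gap = 50,
                            trim_ends = TRUE,
                            trim_fraction = 0.1,
                            long_read_mode = FALSE,
                            min_transcript_coverage = 1,
                            min_isoform_fraction = 0.01,
                            max_mismatch_rate = 0.01,
                            high_mismatch_boost = 1.25,
                            min_anchor = 10,
                            long_intron_anchor = 25,
                            long_intron_length = 100000,
                            max_nodes = 1000,
                            correction_window = 10,
                            high_error_threshold = 0.02,
                            frag_gap_tol = 60,
                            superread_k = 25) {
  p <- list(
    min_junction_support = min_junction_support,
    max_gap = max_gap,
    trim_ends = trim_ends && !long_read_mode,
    trim_fraction = trim_fraction,
    long_read_mode = long_read_mode,
    min_transcript_coverage = min_transcript_coverage,
    min_isoform_fraction = min_isoform_fraction,
    max_mismatch_rate = max_mismatch_rate,
    high_mismatch_boost = high_mismatch_boost,
    min_anchor = min_anchor,
    long_intron_anchor = long_intron_anchor,
    long_intron_length = long_intron_length,
    max_nodes = max_nodes,
    correction_window = correction_window,
    high_error_threshold = high_error_threshold,
    frag_gap_tol = frag_gap_tol,
    superread_k = superread_k
  )
  stopifnot(all(vapply(p[!names(p) %in% c("trim_ends", "long_read_mode")],
                       function(x) is.numeric(x) && x >= 0, logical(1))))
  structure(p, class = "sf_params")
}
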