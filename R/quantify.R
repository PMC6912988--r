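#' EM distribution of read mass over items
#'
#' Distributes read (or fragment) mass over ambiguously assigned items —
#' super-reads or candidate transcripts. The initial estimate sums the mass
#' of reads uniquely assigned to one item; each iteration redistributes every
#' read's mass proportionally to the previous coverage estimates of the items
#' it is assigned to (per-base rates when `lengths` is given). Reads whose
#' items all have zero estimate are split equally. Total distributed mass
#' equals total read mass after every iteration.
#'
#' @param assignments Tibble with `read_id` and `item_id` (one row per
#'   read-item assignment).
#' @param read_masses Named numeric vector of per-read masses (> 0).
#' @param lengths Optional named numeric vector of item lengths; when given,
#'   responsibilities are proportional to mass/length (a per-base rate),
#'   appropriate when items of unequal length compete for reads.
#' @param tol Convergence tolerance on the maximum coverage change, relative
#'   to total mass (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return Tibble `item_id`, `mass` with attributes `iterations`,
#'   `converged`, and `mass_trace` (total distributed mass after each
#'   iteration).
#' @export
em_coverage <- function(assignments, read_masses, lengths = NULL,
                        tol = 1e-6, max_iter = 1000) {
  if (nrow(assignments) == 0L) {
    out <- tibble(item_id = character(), mass = numeric())
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    attr(out, "mass_trace") <- numeric()
    return(out)
  }
  assignments <- distinct(assignments, .data$read_id, .data$item_id)
  items <- sort(unique(assignments$item_id))
  ridx <- split(match(assignments$item_id, items), assignments$read_id)
  m <- read_masses[names(ridx)]
  stopifnot(!anyNA(m), all(m > 0))
  len <- if (is.null(lengths)) rep(1, length(items)) else lengths[items]
  total <- sum(m)

  uniq <- lengths(ridx) == 1L
  cov <- numeric(length(items))
  for (r in which(uniq)) cov[ridx[[r]]] <- cov[ridx[[r]]] + m[r]

  trace <- numeric()
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    rate <- cov / len
    newc <- numeric(length(items))
    for (r in seq_along(ridx)) {
      ii <- ridx[[r]]
      w <- rate[ii]
      s <- sum(w)
      share <- if (s > 0) w / s else rep(1 / length(ii), length(ii))
      newc[ii] <- newc[ii] + m[r] * share
    }
    trace <- c(trace, sum(newc))
    delta <- max(abs(newc - cov))
    cov <- newc
    if (delta <= tol * max(total, 1)) { converged <- TRUE; break }
  }
  out <- tibble(item_id = items, mass = cov)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "mass_trace") <- trace
  out
}
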