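#' Select candidate alignment contigs for a read
#'
#' Phase 1, client side. Fingerprints the read with the index's hash family,
#' looks up its `T` buckets, merges the retrieved contig entries with an
#' n-way heap merge (entries whose genomic extents overlap or abut within
#' `W` bp, in the same reference sequence, become one candidate) and counts
#' `b_hits`, the number of distinct tables contributing to each candidate.
#' Candidates are kept if `b_hits >= b_min_hits` and
#' `b_hits >= max(b_min_hits, ceiling(b_best_hits / 2))`, where
#' `b_best_hits` is the best count seen for this read.
#'
#' @param read read sequence (character) or a row of a [load_reads()] tibble.
#' @param index an `mv_index`.
#' @param b_min_hits minimum bucket hits; defaults to the index parameters.
#' @return Tibble of candidates sorted by decreasing `b_hits`: `gstart`,
#'   `gend` (0-based half-open global interval, length >= the read length)
#'   and `b_hits`. An invalid read fingerprint yields zero rows (the read is
#'   unmappable in phase 1).
#' @examples
#' sim <- simulate_reads(genome_len = 5000, n_reads = 5, seed = 3)
#' idx <- build_index(sim$ref, mv_params(W = 150, seed = 7))
#' select_candidates(sim$reads$seq[1], idx)
#' @export
select_candidates <- function(read, index, b_min_hits = NULL) {
  stopifnot(inherits(index, "mv_index"))
  if (is.data.frame(read)) read <- read$seq[1]
  if (is.null(b_min_hits)) b_min_hits <- index$params$b_min_hits
  fp <- fingerprint_read(index, read)
  if (!fp$valid)
    return(tibble::tibble(gstart = numeric(), gend = numeric(),
                          b_hits = integer()))
  res <- cpp_select_candidates(index$ptr, unclass(fp), nchar(read),
                               as.integer(b_min_hits))
  tibble::tibble(gstart = res$gstart, gend = res$gend, b_hits = res$b_hits)
}
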