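#' Evaluate alignments against simulation truth
#'
#' Computes the standard pair of accuracy numbers: `pct_q10`, the percentage
#' of reads mapped with mapping quality at least `qmin`, and `err_q10`, the
#' percentage of those mappings placed farther than `tol` bp from the true
#' position.
#'
#' @param alignments an `mv_alignments` tibble, or a SAM path (then `ref`
#'   is required to recover global coordinates).
#' @param truth truth tibble from [simulate_reads()] (`id`, `true_pos`).
#' @param qmin mapping-quality threshold.
#' @param tol distance tolerance in bp for a correct placement.
#' @param ref reference, only needed when `alignments` is a SAM path.
#' @return One-row tibble: `pct_q10`, `err_q10`, `n_q10`, `n_reads`.
#' @examples
#' sim <- simulate_reads(genome_len = 5000, n_reads = 20, seed = 1)
#' p <- mv_params(W = 150, seed = 7)
#' idx <- build_index(sim$ref, p)
#' al <- align_reads(sim$reads, idx, sim$ref, p)
#' evaluate_alignments(al, sim$truth)
#' @export
evaluate_alignments <- function(alignments, truth, qmin = 10L, tol = 20L,
                                ref = NULL) {
  if (is.character(alignments)) {
    if (is.null(ref)) stop("reading a SAM file requires 'ref'")
    alignments <- read_sam_minimal(alignments, as_reference(ref))
  }
  if (!all(alignments$id %in% truth$id))
    stop("alignment ids missing from truth records")
  tp <- truth$true_pos[match(alignments$id, truth$id)]
  q <- alignments$mapped & alignments$mapq >= qmin
  n_q <- sum(q)
  err <- if (n_q == 0) 0 else
    100 * sum(abs(alignments$gpos[q] - tp[q]) > tol) / n_q
  tibble::tibble(pct_q10 = 100 * n_q / nrow(alignments), err_q10 = err,
                 n_q10 = n_q, n_reads = nrow(alignments))
}

# minimal SAM reader (QNAME/FLAG/RNAME/POS/MAPQ) back to global coordinates
read_sam_minimal <- function(path, ref) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0)
    return(tibble::tibble(id = character(), mapped = logical(),
                          gpos = numeric(), mapq = integer()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  id <- vapply(f, `[[`, "", 1)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  rname <- vapply(f, `[[`, "", 3)
  pos <- as.numeric(vapply(f, `[[`, "", 4))
  mapq <- as.integer(vapply(f, `[[`, "", 5))
  mapped <- bitwAnd(flag, 4L) == 0L
  off <- ref$offset[match(rname, ref$name)]
  tibble::tibble(id = id, mapped = mapped,
                 gpos = ifelse(mapped, off + pos - 1, NA_real_),
                 mapq = mapq)
}
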