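#' Align reads against an indexed reference
#'
#' Runs the full two-phase protocol over a read set. Phase 1 (client):
#' fingerprint each read and select candidate contigs from the index. Phase 2
#' (cloud): for every read/candidate pair and both read orientations, apply
#' the secure transform, serialize the voting tasks, and score the serialized
#' bytes — the voting code never sees sequences or keys. Finalization
#' (client): best and second-best scores, final global position, mapping
#' quality. Per-phase wall times and exact task/result byte counts are
#' recorded.
#'
#' @param reads a [load_reads()] tibble, a character vector of sequences, or
#'   a FASTQ path.
#' @param index an `mv_index` built from `ref` with the same parameters.
#' @param ref the reference used to build the index (tibble, named character
#'   vector or FASTA path).
#' @param params an [mv_params()] object; must match the index's phase-1
#'   parameters.
#' @param mode `"secure"` or `"vanilla"`; defaults to `params$mode`.
#' @param sam optional path; when given, alignments are written as SAM.
#' @param via_serialization route every voting task through its serialized
#'   byte representation (the client/cloud boundary); disable only for
#'   debugging.
#' @return A tibble of class `mv_alignments`: `id`, `mapped`, `gpos`
#'   (0-based global), `strand` (`"+"`/`"-"`), `mapq`, `r1`, `r2`,
#'   `n_candidates`, `n_tasks`. Attributes `bandwidth` (task/result byte
#'   counts) and `timings` (per-phase seconds) carry the run accounting.
#' @examples
#' sim <- simulate_reads(genome_len = 5000, n_reads = 20, seed = 1)
#' p <- mv_params(W = 150, seed = 7)
#' idx <- build_index(sim$ref, p)
#' al <- align_reads(sim$reads, idx, sim$ref, p)
#' head(al)
#' @export
align_reads <- function(reads, index, ref, params = index$params,
                        mode = params$mode, sam = NULL,
                        via_serialization = TRUE) {
  stopifnot(inherits(index, "mv_index"), inherits(params, "mv_params"))
  ref <- as_reference(ref)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- load_reads(reads)
  if (is.character(reads))
    reads <- tibble::tibble(id = sprintf("read_%06d", seq_along(reads)),
                            seq = reads, qual = strrep("I", nchar(reads)))
  for (f in c("W", "k_mh", "L", "T", "b", "M", "min_kmers", "C_max"))
    if (!identical(as.numeric(params[[f]]),
                   as.numeric(index$params[[f]])))
      stop("parameter '", f, "' differs between index and config")
  if (!identical(params$seed, index$params$seed))
    stop("parameter 'seed' differs between index and config")

  res <- cpp_align_batch(index$ptr, reads$seq, ref$seq, unclass(params),
                         mode == "secure", params$seed, via_serialization)
  al <- tibble::tibble(
    id = reads$id, mapped = res$mapped, gpos = res$gpos,
    strand = c("+", "-")[res$strand + 1L], mapq = res$mapq,
    r1 = res$r1, r2 = res$r2, n_candidates = res$n_candidates,
    n_tasks = res$n_tasks)
  attr(al, "bandwidth") <- list(task_bytes = res$task_bytes,
                                result_bytes = res$result_bytes)
  attr(al, "timings") <- res$timings
  attr(al, "mode") <- mode
  class(al) <- c("mv_alignments", class(al))
  if (!is.null(sam)) write_sam(al, ref, reads, sam, mode = mode)
  al
}

#' Write alignments as SAM
#'
#' Emits a SAM 1.6 file with `@HD`, `@SQ` and `@PG` headers and one record
#' per read. Positions are converted from the package's 0-based global
#' coordinates to 1-based per-sequence SAM coordinates (clamped so the
#' aligned span stays within the sequence); reverse-strand reads store the
#' reverse-complemented sequence with flag 16; unmapped reads get flag 4.
#'
#' @param alignments an `mv_alignments` tibble.
#' @param ref the reference (for `@SQ` lines and coordinate conversion).
#' @param reads the read tibble that was aligned (`id`, `seq`, `qual`).
#' @param path output path.
#' @param mode mode string recorded in the `@PG` line.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, ref, reads, path, mode = "secure") {
  ref <- as_reference(ref)
  stopifnot(identical(alignments$id, reads$id))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$name, as.integer(ref$length)),
           sprintf("@PG\tID:minivote\tPN:minivote\tVN:%s\tCL:align --mode %s",
                   as.character(utils::packageVersion("minivote")), mode))
  n <- nrow(alignments)
  flag <- integer(n); rname <- rep("*", n); pos <- integer(n)
  cigar <- rep("*", n); seqs <- reads$seq; quals <- reads$qual
  rlen <- nchar(reads$seq)
  m <- alignments$mapped
  if (any(m)) {
    si <- findInterval(alignments$gpos[m], ref$offset)
    lpos <- alignments$gpos[m] - ref$offset[si] + 1
    lpos <- pmax(1, pmin(lpos, ref$length[si] - rlen[m] + 1))
    pos[m] <- as.integer(lpos)
    rname[m] <- ref$name[si]
    cigar[m] <- paste0(rlen[m], "M")
    rev <- m & alignments$strand == "-"
    flag[rev] <- 16L
    if (any(rev)) {
      seqs[rev] <- revcomp(seqs[rev])
      quals[rev] <- vapply(strsplit(quals[rev], "", fixed = TRUE),
                           function(q) paste(rev(q), collapse = ""), "")
    }
  }
  flag[!m] <- 4L
  mapq <- ifelse(m, alignments$mapq, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 alignments$id, flag, rname, pos, mapq, cigar, seqs, quals)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Bandwidth accounting of an alignment run
#'
#' Exact serialized byte counts of the client-to-cloud voting-task payload
#' and the cloud-to-client result payload.
#'
#' @param alignments an `mv_alignments` tibble from [align_reads()].
#' @return Tibble with `phase` and `bytes`.
#' @export
bandwidth_report <- function(alignments) {
  bw <- attr(alignments, "bandwidth")
  if (is.null(bw)) stop("no bandwidth attribute; was this produced by align_reads()?")
  tibble::tibble(
    phase = c("tasks_client_to_cloud", "results_cloud_to_client"),
    bytes = c(bw$task_bytes, bw$result_bytes))
}

#' Per-phase timing of an alignment run
#'
#' @param alignments an `mv_alignments` tibble from [align_reads()].
#' @return Tibble with `phase` and `seconds` (fingerprinting, candidate
#'   selection, encryption/masking, voting, reporting).
#' @export
timing_report <- function(alignments) {
  tm <- attr(alignments, "timings")
  if (is.null(tm)) stop("no timings attribute; was this produced by align_reads()?")
  tibble::tibble(phase = names(tm), seconds = as.numeric(tm))
}

#' @export
print.mv_alignments <- function(x, ...) {
  cat(sprintf("<mv_alignments> %d reads, %.1f%% mapped (mode: %s)\n",
              nrow(x), 100 * mean(x$mapped), attr(x, "mode") %||% "?"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
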