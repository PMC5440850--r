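#' Per-task voting keys
#'
#' Every voting run uses one 256-bit session secret `K` (derived from the
#' master seed) and, per task, a fresh pair of 64-bit keys `(k1, k2)` with
#' `k2` odd. The shipped hash of a kmer `s` is
#' `((h_K(s) XOR k1) * k2) mod 2^64`, where `h_K(s)` is the first 64 bits of
#' `SHA-1(K || s)`. Because `k2` is odd the per-task map is a bijection, so
#' matches within a task are preserved while equal kmers in different tasks
#' hash to unrelated values.
#'
#' @param master_seed the run's master seed.
#' @param task_id task counter.
#' @return An object of class `mv_task_keys`: `K` (raw, 32 bytes), and
#'   `k1`/`k2` as `hi`/`lo` 32-bit halves.
#' @export
make_task_keys <- function(master_seed, task_id) {
  res <- cpp_make_task_keys(as.numeric(master_seed), as.numeric(task_id))
  structure(res, class = "mv_task_keys")
}

#' Keyed kmer hash
#'
#' @param kmers numeric kmer codes, [kmer_set()] tibble, or character kmers.
#' @param keys an `mv_task_keys` object.
#' @return Tibble with the 64-bit hashed values as `hi`/`lo` halves.
#' @export
keyed_kmer_hash <- function(kmers, keys) {
  stopifnot(inherits(keys, "mv_task_keys"))
  res <- cpp_keyed_kmer_hash(as_codes(kmers), keys$K, keys$k1_hi, keys$k1_lo,
                             keys$k2_hi, keys$k2_lo)
  tibble::tibble(hi = res$hi, lo = res$lo)
}

#' Prepare the voting task(s) for one read/contig pair
#'
#' Applies the client-side transform before a task is shipped: voting kmers
#' are extracted at stride 1 and hashed (keyed hash in secure mode, plain
#' 64-bit mix in vanilla mode); within the read and within the contig every
#' locally repeated kmer is masked together with enough neighbours that each
#' maximal masked run spans at least `v` kmers; positions are collapsed to
#' bins of `beta` consecutive positions and shuffled within bins; contig bins
#' ship `max(1, floor(n_bin * rho))` sampled kmers each, or random values if
#' the bin cannot supply that many unmasked kmers; contigs longer than
#' `chunk_cap_mult * read length` are split into overlapping chunks (one task
#' each) padded with random kmers to a uniform record count.
#'
#' @param read_seq read sequence (its length defines the chunk cap).
#' @param contig_seq candidate contig sequence (>= read length).
#' @param params an [mv_params()] object (`v`, `beta`, `rho`, `mode`, `seed`,
#'   `chunk_cap_mult` are used).
#' @param task_id0 id assigned to the first produced task; per-task keys and
#'   randomness derive from `(params$seed, task id)`.
#' @return A list of `mv_voting_task` objects (one per chunk). Each carries
#'   the shipped payload (`read_hi/lo/bin/masked`, `contig_hi/lo/bin/masked`)
#'   plus client-side per-position mask vectors used by the leak diagnostics.
#' @export
prepare_task <- function(read_seq, contig_seq, params, task_id0 = 1) {
  stopifnot(inherits(params, "mv_params"))
  res <- cpp_prepare_tasks(as.character(read_seq), as.character(contig_seq),
                           params$v, params$beta, params$rho,
                           params$mode == "secure", params$seed,
                           as.numeric(task_id0), params$chunk_cap_mult)
  lapply(res, function(t) structure(t, class = "mv_voting_task"))
}

#' @export
print.mv_voting_task <- function(x, ...) {
  cat(sprintf(
    "<mv_voting_task> id=%.0f beta=%d rho=%.2f read kmers=%d contig kmers=%d (pad=%d) chunk_off=%.0f\n",
    x$task_id, x$beta, x$rho, length(x$read_bin), length(x$contig_bin),
    x$pad, x$chunk_off))
  invisible(x)
}

#' Cast kmer votes for a task
#'
#' Every unmasked read/contig kmer pair with equal hashed value votes. With
#' `beta = 1` a match at read position `p^R` and contig position `p^C` adds
#' one vote at displacement `phi = p^C - p^R`; with binning, a match between
#' read bin `[l^R, h^R)` and contig bin `[l^C, h^C)` adds one vote at every
#' displacement in `[l^C - h^R + 1, h^C - l^R)`, the range generated by all
#' position pairs in the two bins. Masked kmers carry random values and never
#' match.
#'
#' @param task an `mv_voting_task`.
#' @return An object of class `mv_votes`: integer vote vector `V` and the
#'   displacement `phi0` of its first element.
#' @export
cast_votes <- function(task) {
  stopifnot(inherits(task, "mv_voting_task"))
  res <- cpp_cast_votes(unclass(task))
  structure(list(phi0 = res$phi0, V = res$V), class = "mv_votes")
}

#' Collect neighbouring votes
#'
#' Symmetric window sum: `Vconv[j] = sum(V[j - n_conv .. j + n_conv])`, with
#' out-of-range entries treated as zero (indels split votes across nearby
#' displacements; the window sum re-collects them).
#'
#' @param votes an `mv_votes` object or a plain integer vector.
#' @param n_conv window radius (>= 0).
#' @return Same shape as the input (`mv_votes` in, `mv_votes` out).
#' @export
convolve_votes <- function(votes, n_conv = 10L) {
  if (inherits(votes, "mv_votes")) {
    out <- votes
    out$V <- cpp_convolve(votes$V, as.integer(n_conv))
    return(out)
  }
  cpp_convolve(as.integer(votes), as.integer(n_conv))
}

#' Best displacement and score of a convolved vote vector
#'
#' Returns the displacement with the maximum vote count; on a plateau of
#' equal maxima the middle position (lower median) is taken. An all-zero
#' vector is flagged `no_evidence` with score 0.
#'
#' @param votes an `mv_votes` object (typically after [convolve_votes()]).
#' @return List with `phi` (best displacement, `NA` when no evidence),
#'   `score` and `no_evidence`.
#' @export
score_task <- function(votes) {
  stopifnot(inherits(votes, "mv_votes"))
  cpp_score_votes(votes$V, votes$phi0)
}

#' Serialize voting tasks
#'
#' The byte stream the untrusted side receives: per task a 40-byte header
#' (task id, beta, rho, record counts, padding count, chunk offset) followed
#' by 12 bytes per kmer record (64-bit hashed value, 32-bit bin id). Keys
#' and mask flags are never serialized.
#'
#' @param tasks an `mv_voting_task` or list of them.
#' @return A raw vector.
#' @export
serialize_tasks <- function(tasks) {
  if (inherits(tasks, "mv_voting_task")) tasks <- list(tasks)
  do.call(c, lapply(tasks, function(t) cpp_serialize_task(unclass(t))))
}

#' Score a serialized task stream ("cloud side")
#'
#' Deserializes tasks from raw bytes and runs vote casting, convolution and
#' scoring on each — the entire computation available to the untrusted
#' worker, which never sees sequences, positions beyond bins, or keys.
#'
#' @param stream raw vector from [serialize_tasks()].
#' @param n_conv convolution radius.
#' @return Tibble with `task_id`, `chunk_off`, `phi` (best local
#'   displacement) and `score` per task.
#' @export
score_task_stream <- function(stream, n_conv = 10L) {
  res <- cpp_score_serialized_stream(stream, as.integer(n_conv))
  tibble::tibble(task_id = res$task_id, chunk_off = res$chunk_off,
                 phi = res$phi, score = res$score)
}

#' Combine task results into a final alignment
#'
#' Client side: the best task score is `r1`; `r2` is the best score among
#' tasks whose implied genome position lies more than one read length away
#' from the best position (a genuinely alternative locus). The mapping
#' quality is `round(alpha * (r1 - r2) / r1)`, clamped to `[0, alpha]`; it is
#' 0 when `r1 == r2` and `alpha` when the read has a single candidate
#' (`r2 == 0`).
#'
#' @param results data frame with one row per task: `gpos` (implied global
#'   position: candidate start + chunk offset + best displacement), `score`,
#'   and `strand` (0 forward, 1 reverse).
#' @param read_len read length in bp (also the `r2` exclusion distance).
#' @param alpha mapping-quality scale.
#' @return List with `mapped`, `gpos`, `strand`, `r1`, `r2`, `mapq`.
#' @export
finalize_alignment <- function(results, read_len, alpha = 60L) {
  results <- results[!is.na(results$score) & results$score > 0, , drop = FALSE]
  if (nrow(results) == 0)
    return(list(mapped = FALSE, gpos = NA_real_, strand = NA_integer_,
                r1 = 0L, r2 = 0L, mapq = 0L))
  best <- which.max(results$score)
  r1 <- results$score[best]
  p1 <- results$gpos[best]
  alt <- abs(results$gpos - p1) > read_len
  r2 <- if (any(alt)) max(results$score[alt]) else 0L
  mapq <- max(0L, min(as.integer(alpha),
                      as.integer(round(alpha * (r1 - r2) / r1))))
  list(mapped = TRUE, gpos = p1, strand = results$strand[best],
       r1 = as.integer(r1), r2 = as.integer(r2), mapq = mapq)
}
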