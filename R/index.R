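#' Initialize the index projections
#'
#' Draws `T` fixed `b`-dimensional vectors of distinct fingerprint indices
#' (one per hash table) and the vector `A` of random odd 64-bit multipliers
#' used by the multiply-shift bucket hash, reproducibly from `seed`.
#'
#' @param T_tables number of hash tables.
#' @param b projection dimension.
#' @param L fingerprint length.
#' @param M bucket-address bits.
#' @param seed integer seed.
#' @return An object of class `mv_projections`: list with integer matrix `P`
#'   (`T x b`, 0-based indices into the fingerprint), `A_hi`/`A_lo`, and `M`.
#' @export
init_projections <- function(T_tables, b, L, M, seed) {
  res <- cpp_init_projections(as.integer(T_tables), as.integer(b),
                              as.integer(L), as.integer(M), as.numeric(seed))
  structure(res, class = "mv_projections")
}

#' Bucket address of a fingerprint projection
#'
#' Multiply-shift hash of the `b` projected fingerprint entries of table `t`:
#' the dot product with `A` modulo 2^64, shifted right by `64 - M` bits.
#'
#' @param F_ a valid `mv_fingerprint`.
#' @param t table id (0-based).
#' @param proj an `mv_projections` object or an `mv_index`.
#' @return Bucket id in `[0, 2^M)`.
#' @export
bucket_hash <- function(F_, t, proj) {
  if (inherits(proj, "mv_index")) proj <- proj$projections
  stopifnot(inherits(proj, "mv_projections"), inherits(F_, "mv_fingerprint"))
  cpp_bucket_hash(unclass(F_), as.integer(t), unclass(proj))
}

#' Build the MinHash genome index (MHG)
#'
#' Fingerprints every length-`W` window of the reference with the rolling
#' MinHash, places each valid window in one bucket per hash table via its
#' fingerprint projections, and compresses runs of consecutive windows that
#' landed in the same bucket into single contig entries `(start, length)`.
#'
#' @param ref an `mv_reference` tibble, named character vector, or FASTA path.
#' @param params an [mv_params()] object.
#' @return An object of class `mv_index`. The index holds an external
#'   pointer; persist it with [save_index()], not `saveRDS()`.
#' @examples
#' sim <- simulate_reads(genome_len = 2000, n_reads = 0, seed = 1)
#' idx <- build_index(sim$ref, mv_params(W = 150, seed = 7))
#' idx
#' @export
build_index <- function(ref, params) {
  stopifnot(inherits(params, "mv_params"))
  ref <- as_reference(ref)
  ptr <- cpp_build_index(ref$seq, ref$name, unclass(params))
  new_index(ptr, params)
}

new_index <- function(ptr, params) {
  info <- cpp_index_info(ptr)
  structure(list(
    ptr = ptr, params = params,
    projections = structure(
      cpp_init_projections(params$T, params$b, params$L, params$M,
                           params$seed),
      class = "mv_projections"),
    seq_names = info$seq_names, seq_offsets = info$seq_offsets,
    seq_lens = info$seq_lens, genome_len = info$genome_len,
    n_valid_windows = info$n_valid_windows, n_entries = info$n_entries
  ), class = "mv_index")
}

#' @export
print.mv_index <- function(x, ...) {
  cat(sprintf("<mv_index> %d sequence(s), %.0f bp genome\n",
              length(x$seq_names), x$genome_len))
  cat(sprintf("  windows (valid): %.0f  tables: %d  entries: %.0f  (%.1fx compression)\n",
              x$n_valid_windows, x$params$T, x$n_entries,
              x$n_valid_windows * x$params$T / max(1, x$n_entries)))
  print(x$params)
  invisible(x)
}

#' Index summary statistics
#'
#' @param index an `mv_index`.
#' @return A named list (window counts, entry counts, bucket occupancy,
#'   repetitive-kmer count, sequence layout).
#' @export
index_info <- function(index) {
  stopifnot(inherits(index, "mv_index"))
  cpp_index_info(index$ptr)
}

#' Fingerprint a read with an index's hash family and repeat filter
#'
#' @param index an `mv_index`.
#' @param seq read sequence.
#' @param min_kmers validity threshold; `NULL` uses the index default for
#'   reads of length `W` and 80% of the read's kmer count otherwise.
#' @return An `mv_fingerprint`.
#' @export
fingerprint_read <- function(index, seq, min_kmers = NULL) {
  stopifnot(inherits(index, "mv_index"))
  if (is.null(min_kmers)) {
    n <- nchar(seq)
    min_kmers <- if (n == index$params$W) index$params$min_kmers
                 else max(1L, as.integer(ceiling(0.8 * (n - index$params$k_mh + 1))))
  }
  new_fingerprint(cpp_index_fingerprint(index$ptr, as.character(seq),
                                        as.integer(min_kmers)))
}

#' Look up a fingerprint in the index
#'
#' Returns the contents of the `T` buckets addressed by the fingerprint's
#' projections. High-frequency buckets (more than `bucket_cap` entries) are
#' returned empty.
#'
#' @param index an `mv_index`.
#' @param F_ a valid `mv_fingerprint` from the index's family.
#' @return Tibble with one row per contig entry: `table` (0-based), `bucket`,
#'   `start` (global window position) and `len` (merged window count).
#' @export
index_lookup <- function(index, F_) {
  stopifnot(inherits(index, "mv_index"), inherits(F_, "mv_fingerprint"))
  res <- cpp_index_lookup(index$ptr, unclass(F_))
  tibble::tibble(
    table = rep(seq_along(res) - 1L,
                vapply(res, function(x) length(x$start), 0L)),
    bucket = unlist(lapply(res, function(x) rep(x$bucket, length(x$start)))),
    start = unlist(lapply(res, function(x) x$start)),
    len = unlist(lapply(res, function(x) x$len))
  )
}

#' All contig entries of an index
#'
#' @param index an `mv_index`.
#' @return Tibble with `table`, `bucket`, `start`, `len` for every stored
#'   contig entry (buckets in ascending id order within each table).
#' @export
index_entries <- function(index) {
  stopifnot(inherits(index, "mv_index"))
  tibble::as_tibble(cpp_index_entries(index$ptr))
}

#' Brute-force per-window bucket assignments
#'
#' Recomputes, with direct (non-rolling) per-window fingerprints and no
#' contig compression, the `(window, table, bucket)` assignment of every
#' valid window. This is the independent oracle against which the built
#' index's compressed buckets can be expanded and compared.
#'
#' @param ref reference (tibble, named character vector or FASTA path).
#' @param params an [mv_params()] object.
#' @return Tibble with `gpos`, `table`, `bucket`.
#' @export
window_buckets_direct <- function(ref, params) {
  stopifnot(inherits(params, "mv_params"))
  ref <- as_reference(ref)
  tibble::as_tibble(cpp_window_buckets_direct(ref$seq, unclass(params)))
}

#' Save / load an index
#'
#' The on-disk format is a versioned little-endian binary with a JSON text
#' header carrying the build parameters; a round trip restores the index
#' bit-identically (tables, parameters, seeds, projections).
#'
#' @param index an `mv_index`.
#' @param path file path.
#' @return `load_index()` returns the restored `mv_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "mv_index"))
  header <- jsonlite::toJSON(unclass(index$params), auto_unbox = TRUE)
  cpp_save_index(index$ptr, path.expand(path), as.character(header))
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  res <- cpp_load_index(path.expand(path))
  pl <- jsonlite::fromJSON(res$header)
  params <- mv_params(
    W = pl$W, k_mh = pl$k_mh, v = pl$v, L = pl$L, T_tables = pl$T, b = pl$b,
    M = pl$M, beta = pl$beta, rho = pl$rho, n_conv = pl$n_conv,
    b_min_hits = pl$b_min_hits, alpha = pl$alpha, C_max = pl$C_max,
    seed = pl$seed, mode = pl$mode, min_kmers = pl$min_kmers,
    bucket_cap = pl$bucket_cap, chunk_cap_mult = pl$chunk_cap_mult)
  new_index(res$ptr, params)
}
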