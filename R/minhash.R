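#' Initialize a MinHash hash family
#'
#' Draws `L` universal hash functions `h_i(x) = a_i * x + b_i (mod 2^64)`
#' with odd `a_i` (so each `h_i` is a bijection), reproducibly from `seed`.
#' Kmer codes are first passed through a fixed 64-bit mixer before the
#' family is applied.
#'
#' @param L number of hash functions (fingerprint length).
#' @param seed integer seed.
#' @return An object of class `mv_hash_family`.
#' @examples
#' fam <- init_hash_family(128, 42)
#' @export
init_hash_family <- function(L, seed) {
  stopifnot(L >= 1)
  structure(list(ptr = cpp_hash_family(as.integer(L), as.numeric(seed)),
                 L = as.integer(L), seed = as.numeric(seed)),
            class = "mv_hash_family")
}

#' @export
print.mv_hash_family <- function(x, ...) {
  cat(sprintf("<mv_hash_family> L=%d seed=%.0f\n", x$L, x$seed))
  invisible(x)
}

#' Coefficients of a hash family
#'
#' @param family an `mv_hash_family`.
#' @return Tibble with the 64-bit `a_i`, `b_i` split into 32-bit halves
#'   (`a_hi`, `a_lo`, `b_hi`, `b_lo`).
#' @export
family_coeffs <- function(family) {
  stopifnot(inherits(family, "mv_hash_family"))
  tibble::as_tibble(cpp_family_coeffs(family$ptr))
}

as_codes <- function(kmers) {
  if (is.numeric(kmers)) return(as.numeric(kmers))
  if (is.data.frame(kmers) && "code" %in% names(kmers)) return(kmers$code)
  if (is.character(kmers)) {
    k <- unique(nchar(kmers))
    stopifnot("kmers must share one length" = length(k) <= 1)
    if (length(kmers) == 0) return(numeric(0))
    return(vapply(kmers,
                  function(s) cpp_kmer_set(s, k, NULL)$code[1], 0,
                  USE.NAMES = FALSE))
  }
  stop("cannot interpret 'kmers' as kmer codes")
}

new_fingerprint <- function(res) {
  structure(list(hi = res$hi, lo = res$lo, valid = res$valid,
                 n_kmers = res$n_kmers, L = length(res$hi)),
            class = "mv_fingerprint")
}

#' MinHash fingerprint of a kmer set
#'
#' Entry `i` of the fingerprint is the minimum of `h_i` over the hashed kmer
#' set. A fingerprint is valid only if the set has at least `min_kmers`
#' entries.
#'
#' @param kmers numeric kmer codes, a [kmer_set()] tibble, or a character
#'   vector of equal-length kmers.
#' @param family an `mv_hash_family`.
#' @param min_kmers validity threshold on the kmer-set size.
#' @return An object of class `mv_fingerprint`: 64-bit minima as `hi`/`lo`
#'   32-bit halves, plus `valid` and `n_kmers`.
#' @examples
#' fam <- init_hash_family(16, 1)
#' fingerprint(kmer_set("ACGTACGTACGT", 4), fam)
#' @export
fingerprint <- function(kmers, family, min_kmers = 1L) {
  stopifnot(inherits(family, "mv_hash_family"))
  new_fingerprint(cpp_fingerprint(as_codes(kmers), family$ptr,
                                  as.integer(min_kmers)))
}

#' @export
print.mv_fingerprint <- function(x, ...) {
  cat(sprintf("<mv_fingerprint> L=%d valid=%s n_kmers=%d\n",
              x$L, x$valid, x$n_kmers))
  invisible(x)
}

#' Fingerprint a sequence directly
#'
#' Convenience wrapper: canonical kmer set (with optional repeat filter),
#' then [fingerprint()].
#'
#' @inheritParams kmer_set
#' @inheritParams fingerprint
#' @export
fingerprint_seq <- function(seq, k, family, filter = NULL, min_kmers = 1L) {
  fingerprint(kmer_set(seq, k, filter), family, min_kmers)
}

#' Exact Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty.
#'
#' @param A,B vectors (kmer codes or any atomic type).
#' @return Similarity in \[0, 1\].
#' @examples
#' jaccard_exact(c(1, 2, 3), c(2, 3, 4))
#' @export
jaccard_exact <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) return(0)
  length(intersect(A, B)) / u
}

#' MinHash estimate of Jaccard similarity
#'
#' The fraction of fingerprint entries shared by two fingerprints from the
#' same family estimates the Jaccard similarity of the underlying sets.
#'
#' @param Fa,Fb valid `mv_fingerprint`s from the same family.
#' @return Estimate in \[0, 1\].
#' @export
jaccard_estimate <- function(Fa, Fb) {
  stopifnot(inherits(Fa, "mv_fingerprint"), inherits(Fb, "mv_fingerprint"))
  if (!Fa$valid || !Fb$valid) stop("both fingerprints must be valid")
  if (Fa$L != Fb$L) stop("fingerprints have different lengths")
  mean(Fa$hi == Fb$hi & Fa$lo == Fb$lo)
}

#' Rolling MinHash fingerprints of every window of a sequence
#'
#' Streams one fingerprint per window start position, each bit-identical to
#' the direct fingerprint of that window's filtered kmer set, using a
#' per-hash-function monotone queue (amortized O(L) per window instead of
#' O(L * W)).
#'
#' @param seq a DNA string of length >= `W`.
#' @param W window length.
#' @param k kmer length (<= `W`).
#' @param family an `mv_hash_family`.
#' @param filter optional `mv_kmer_filter`.
#' @param min_kmers validity threshold per window.
#' @return An object of class `mv_fingerprint_stream` with fields `pos`
#'   (0-based window starts), `valid`, `n_kmers` and the minima matrices;
#'   extract single fingerprints with [fp_at()].
#' @export
rolling_fingerprints <- function(seq, W, k, family, filter = NULL,
                                 min_kmers = 1L) {
  stopifnot(inherits(family, "mv_hash_family"))
  ptr <- if (is.null(filter)) NULL else {
    stopifnot(inherits(filter, "mv_kmer_filter"), filter$k == k)
    filter$ptr
  }
  res <- cpp_rolling_fingerprints(as.character(seq), as.integer(W),
                                  as.integer(k), family$ptr, ptr,
                                  as.integer(min_kmers))
  structure(list(pos = res$pos, valid = res$valid, n_kmers = res$n_kmers,
                 hi = res$hi, lo = res$lo, L = family$L),
            class = "mv_fingerprint_stream")
}

#' @export
print.mv_fingerprint_stream <- function(x, ...) {
  cat(sprintf("<mv_fingerprint_stream> windows=%d valid=%d L=%d\n",
              length(x$pos), sum(x$valid), x$L))
  invisible(x)
}

#' Extract one fingerprint from a stream
#'
#' @param stream an `mv_fingerprint_stream` from [rolling_fingerprints()].
#' @param i window index (1-based position in the stream).
#' @return An `mv_fingerprint`.
#' @export
fp_at <- function(stream, i) {
  stopifnot(inherits(stream, "mv_fingerprint_stream"),
            i >= 1, i <= length(stream$pos))
  new_fingerprint(list(hi = stream$hi[, i], lo = stream$lo[, i],
                       valid = stream$valid[i], n_kmers = stream$n_kmers[i]))
}
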