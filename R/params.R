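#' Aligner parameters
#'
#' Bundles every tunable of the two-phase aligner. Defaults follow the
#' published operating point for 150 bp reads: fingerprint length `L = 128`,
#' `T = 78` hash tables over `b = 2`-dimensional fingerprint projections with
#' `M = 18` bucket-address bits, 20 bp MinHash and voting kmers, bin size
#' `beta = 20`, vote-convolution radius `n_conv = 10`, and a minimum of
#' `b_min_hits = 2` bucket hits per candidate.
#'
#' @param W window length in bp; equals the read length.
#' @param k_mh MinHash kmer length in bp.
#' @param v voting kmer length in bp.
#' @param L fingerprint length (number of universal hash functions).
#' @param T_tables number of index hash tables (projections).
#' @param b projection dimension; candidate windows share at least `b`
#'   fingerprint entries with the read.
#' @param M bucket-address bits; each table has `2^M` buckets.
#' @param beta position-bin size for secure voting (kmer positions are
#'   revealed only up to membership in bins of `beta` consecutive positions).
#' @param rho contig kmer sampling rate in (0, 1].
#' @param n_conv convolution radius used to collect neighbouring votes.
#' @param b_min_hits minimum number of distinct tables whose buckets must
#'   contain a contig for it to become a candidate.
#' @param alpha mapping-quality scale: `mapq = round(alpha * (r1 - r2) / r1)`.
#' @param C_max repetitive-kmer cutoff: canonical kmers occurring more than
#'   `C_max` times genome-wide are dropped from fingerprinting.
#' @param seed master seed; all hashing, key generation, masking and
#'   shuffling derive from it deterministically.
#' @param mode `"secure"` (keyed hashing, masking, binning, sampling) or
#'   `"vanilla"` (plain hashing, exact positions, no masking).
#' @param min_kmers minimum surviving kmers for a valid fingerprint;
#'   `NULL` means 80% of the `W - k_mh + 1` window kmers.
#' @param bucket_cap buckets holding more entries than this are treated as
#'   high-frequency and skipped at lookup time.
#' @param chunk_cap_mult contigs longer than `chunk_cap_mult * read length`
#'   are split into overlapping chunks, one voting task each, padded with
#'   random kmers to a uniform size.
#'
#' @return An object of class `mv_params` (a validated named list).
#' @examples
#' p <- mv_params(W = 150, seed = 7)
#' p$min_kmers
#' @export
mv_params <- function(W = 150L, k_mh = 20L, v = 20L, L = 128L,
                      T_tables = 78L, b = 2L, M = 18L, beta = 20L,
                      rho = 1.0, n_conv = 10L, b_min_hits = 2L,
                      alpha = 60L, C_max = 1000L, seed = 1,
                      mode = c("secure", "vanilla"), min_kmers = NULL,
                      bucket_cap = 5000L, chunk_cap_mult = 2L) {
  mode <- match.arg(mode)
  p <- list(
    W = as.integer(W), k_mh = as.integer(k_mh), v = as.integer(v),
    L = as.integer(L), T = as.integer(T_tables), b = as.integer(b),
    M = as.integer(M), beta = as.integer(beta), rho = as.numeric(rho),
    n_conv = as.integer(n_conv), b_min_hits = as.integer(b_min_hits),
    alpha = as.integer(alpha), C_max = as.integer(C_max),
    seed = as.numeric(seed), mode = mode,
    min_kmers = if (is.null(min_kmers)) {
      as.integer(ceiling(0.8 * (as.integer(W) - as.integer(k_mh) + 1L)))
    } else as.integer(min_kmers),
    bucket_cap = as.integer(bucket_cap),
    chunk_cap_mult = as.integer(chunk_cap_mult)
  )
  validate_params(p)
  structure(p, class = c("mv_params", "list"))
}

validate_params <- function(p) {
  stopifnot(
    "b must be <= L" = p$b <= p$L,
    "beta must be >= 1" = p$beta >= 1L,
    "rho must be in (0, 1]" = p$rho > 0 && p$rho <= 1,
    "M must be in [1, 32]" = p$M >= 1L && p$M <= 32L,
    "v must be <= W" = p$v <= p$W,
    "k_mh must be <= W" = p$k_mh <= p$W,
    "k_mh must be <= 26 (2-bit packed in a double)" = p$k_mh <= 26L,
    "v must be <= 26 (2-bit packed in a double)" = p$v <= 26L,
    "L must be >= 1" = p$L >= 1L,
    "T must be >= 1" = p$T >= 1L,
    "min_kmers must be >= 1" = p$min_kmers >= 1L,
    "seed must be a non-negative number below 2^53" =
      p$seed >= 0 && p$seed < 2^53,
    "mode must be 'secure' or 'vanilla'" = p$mode %in% c("secure", "vanilla")
  )
  invisible(p)
}

#' @export
print.mv_params <- function(x, ...) {
  cat("<mv_params>\n")
  cat(sprintf("  phase 1: W=%d k_mh=%d L=%d T=%d b=%d M=%d min_kmers=%d C_max=%d\n",
              x$W, x$k_mh, x$L, x$T, x$b, x$M, x$min_kmers, x$C_max))
  cat(sprintf("  phase 2: v=%d beta=%d rho=%.2f n_conv=%d b_min_hits=%d alpha=%d\n",
              x$v, x$beta, x$rho, x$n_conv, x$b_min_hits, x$alpha))
  cat(sprintf("  mode=%s seed=%.0f\n", x$mode, x$seed))
  invisible(x)
}
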