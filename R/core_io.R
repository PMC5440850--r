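#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-record, line-wrapped, gzipped) FASTA file,
#' uppercases the sequences, maps IUPAC ambiguity codes to `N`, and assigns
#' each record its 0-based offset in the concatenated reference coordinate
#' space used throughout the package.
#'
#' @param path FASTA file (plain or gzip).
#' @return A tibble of class `mv_reference` with columns `name`, `seq`,
#'   `offset` (0-based global start) and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTACGTacgt", ">c2", "TTTTTNNACGT"), fa)
#' load_reference(fa)
#' @export
load_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(ss) == 0) stop("FASTA file '", path, "' contains no sequences")
  seqs <- toupper(as.character(ss))
  # DNAStringSet already rejects non-IUPAC characters; collapse ambiguity to N
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  lens <- unname(nchar(seqs))
  ref <- tibble::tibble(
    name = sub("\\s.*$", "", names(ss)),
    seq = unname(seqs),
    offset = cumsum(c(0, lens[-length(lens)])),
    length = lens
  )
  class(ref) <- c("mv_reference", class(ref))
  ref
}

as_reference <- function(ref) {
  if (is.character(ref) && length(ref) == 1 && file.exists(ref))
    return(load_reference(ref))
  if (is.character(ref)) {
    nm <- names(ref)
    if (is.null(nm)) nm <- paste0("seq", seq_along(ref))
    lens <- nchar(ref)
    ref <- tibble::tibble(name = nm, seq = toupper(unname(ref)),
                          offset = cumsum(c(0, lens[-length(lens)])),
                          length = lens)
  }
  stopifnot(all(c("name", "seq", "offset") %in% names(ref)))
  ref
}

#' Load single-end reads from FASTQ
#'
#' @param path FASTQ file (4-line records, plain or gzip).
#' @return A tibble with columns `id`, `seq`, `qual`. An empty file yields an
#'   empty tibble. A record whose quality string length differs from its
#'   sequence length is an error.
#' @export
load_reads <- function(path) {
  n_lines <- length(readLines(path, n = 1L, warn = FALSE))
  if (n_lines == 0)
    return(tibble::tibble(id = character(), seq = character(),
                          qual = character()))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  seq <- toupper(as.character(ss))
  qual <- as.character(S4Vectors::mcols(ss)$qualities)
  bad <- nchar(seq) != nchar(qual)
  if (any(bad))
    stop("FASTQ record ", which(bad)[1],
         " has mismatched sequence/quality lengths")
  tibble::tibble(id = sub("\\s.*$", "", names(ss)), seq = unname(seq),
                 qual = unname(qual))
}

#' Build the genome-wide repetitive-kmer filter
#'
#' Counts every canonical kmer across the reference and marks those occurring
#' more than `C_max` times as repetitive; repetitive kmers (and any kmer
#' containing `N`) are excluded from fingerprinting.
#'
#' @param ref an `mv_reference` tibble ([load_reference()]), a named
#'   character vector of sequences, or a FASTA path.
#' @param k kmer length (<= 26).
#' @param C_max occurrence cutoff; kmers with genome-wide count > `C_max`
#'   are filtered.
#' @return An object of class `mv_kmer_filter`.
#' @export
build_kmer_filter <- function(ref, k, C_max = 1000L) {
  ref <- as_reference(ref)
  ptr <- cpp_build_kmer_filter(ref$seq, as.integer(k), as.integer(C_max))
  structure(list(ptr = ptr, k = as.integer(k), C_max = as.integer(C_max),
                 n_repetitive = cpp_filter_size(ptr)),
            class = "mv_kmer_filter")
}

#' @export
print.mv_kmer_filter <- function(x, ...) {
  cat(sprintf("<mv_kmer_filter> k=%d C_max=%d repetitive kmers=%d\n",
              x$k, x$C_max, x$n_repetitive))
  invisible(x)
}

#' Test kmers against a repetitive-kmer filter
#'
#' @param filter an `mv_kmer_filter`.
#' @param kmers character vector of kmers of the filter's `k`.
#' @return Logical vector: `TRUE` where the canonical kmer is repetitive or
#'   contains `N`.
#' @export
kmer_is_repetitive <- function(filter, kmers) {
  stopifnot(inherits(filter, "mv_kmer_filter"))
  cpp_kmer_is_repetitive(filter$ptr, as.character(kmers))
}

#' Extract the canonical kmer set of a sequence
#'
#' One entry per position whose canonical kmer (the lexicographic minimum of
#' the kmer and its reverse complement) passes the filter; kmers overlapping
#' `N` are always dropped.
#'
#' @param seq a DNA string.
#' @param k kmer length (<= 26).
#' @param filter optional `mv_kmer_filter`.
#' @return Tibble with columns `pos` (0-based), `kmer` (canonical sequence)
#'   and `code` (its 2-bit packed integer, exact in a double).
#' @examples
#' kmer_set("ACGTT", 4)
#' @export
kmer_set <- function(seq, k, filter = NULL) {
  ptr <- if (is.null(filter)) NULL else {
    stopifnot(inherits(filter, "mv_kmer_filter"), filter$k == k)
    filter$ptr
  }
  res <- cpp_kmer_set(as.character(seq), as.integer(k), ptr)
  tibble::tibble(pos = res$pos, kmer = res$kmer, code = res$code)
}

#' Canonicalize kmers
#'
#' @param kmers character vector (each <= 26 bp).
#' @return The lexicographic minimum of each kmer and its reverse complement;
#'   `NA` for kmers containing non-ACGT characters.
#' @examples
#' canonical_kmer(c("ACGT", "CGTT"))
#' @export
canonical_kmer <- function(kmers) {
  as.character(cpp_canonical_kmer(as.character(kmers)))
}

#' Reverse complement
#'
#' @param seq character vector of DNA strings.
#' @return The reverse complements (N maps to N).
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
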