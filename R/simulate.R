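#' Simulate a genome and a mutated read set with ground truth
#'
#' wgsim-style simulator: a uniform random genome; a mutated copy carrying
#' SNPs at `mutation_rate`, of which `indel_frac` are indels instead
#' (insertion or deletion with equal probability, length 1 plus a geometric
#' extension with continuation probability 0.3); reads drawn uniformly from
#' either strand of the mutated copy with independent per-base substitution
#' errors at rate `error_rate`. Truth records carry the 0-based position of
#' each read's leftmost base in the ORIGINAL genome coordinates, which is
#' what an aligner against the original reference should report.
#'
#' @param genome_len genome length in bp (single chromosome).
#' @param n_reads number of reads.
#' @param read_len read length in bp.
#' @param error_rate per-base sequencing substitution error rate.
#' @param mutation_rate per-base polymorphism rate of the mutated copy.
#' @param indel_frac fraction of polymorphisms that are indels.
#' @param seed RNG seed; the same seed reproduces the output byte for byte.
#' @param chrom_name name of the simulated chromosome.
#' @param fasta,fastq,truth_file optional output paths; when given, the
#'   genome FASTA, read FASTQ and a tab-separated truth table are written.
#' @return List with `ref` (an `mv_reference` tibble), `reads` (tibble
#'   `id`, `seq`, `qual`) and `truth` (tibble `id`, `true_pos` 0-based,
#'   `true_strand` 0 forward / 1 reverse).
#' @examples
#' sim <- simulate_reads(genome_len = 2000, n_reads = 10, seed = 1)
#' sim$truth
#' @export
simulate_reads <- function(genome_len, n_reads, read_len = 150L,
                           error_rate = 0.01, mutation_rate = 0.001,
                           indel_frac = 0.15, seed = 1,
                           chrom_name = "sim1", fasta = NULL, fastq = NULL,
                           truth_file = NULL) {
  stopifnot(read_len <= genome_len,
            error_rate >= 0, error_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            indel_frac >= 0, indel_frac <= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))

  bases <- c("A", "C", "G", "T")
  genome <- sample(bases, genome_len, replace = TRUE)

  # mutated copy + (mutated -> original) coordinate map as segment offsets
  n_mut <- stats::rbinom(1, genome_len, mutation_rate)
  mut_pos <- sort(sample.int(genome_len, n_mut))
  is_indel <- stats::runif(n_mut) < indel_frac
  mutated <- genome
  snp_pos <- mut_pos[!is_indel]
  if (length(snp_pos)) {
    shift <- sample.int(3, length(snp_pos), replace = TRUE)
    cur <- match(mutated[snp_pos], bases)
    mutated[snp_pos] <- bases[((cur - 1 + shift) %% 4) + 1]
  }
  seg_m <- 1; seg_o <- 1 # segment start breakpoints (1-based)
  if (any(is_indel)) {
    pieces <- list(); map_m <- integer(0); map_o <- integer(0)
    cur_o <- 1L; cur_m <- 1L
    for (p in mut_pos[is_indel]) {
      if (p < cur_o) next # swallowed by a previous deletion
      len <- 1L + stats::rgeom(1, 0.7)
      insertion <- stats::runif(1) < 0.5
      if (p > cur_o)
        pieces[[length(pieces) + 1]] <- mutated[cur_o:(p - 1)]
      map_m <- c(map_m, cur_m); map_o <- c(map_o, cur_o)
      cur_m <- cur_m + (p - cur_o)
      if (insertion) {
        pieces[[length(pieces) + 1]] <- sample(bases, len, replace = TRUE)
        cur_m <- cur_m + len
        cur_o <- p
      } else {
        cur_o <- min(genome_len + 1L, p + len)
      }
    }
    pieces[[length(pieces) + 1]] <- if (cur_o <= genome_len) mutated[cur_o:genome_len] else character(0)
    map_m <- c(map_m, cur_m); map_o <- c(map_o, cur_o)
    mutated <- unlist(pieces)
    seg_m <- map_m; seg_o <- map_o
  }
  mut_str <- paste(mutated, collapse = "")
  genome_str <- paste(genome, collapse = "")
  gm <- nchar(mut_str)
  if (n_reads > 0 && gm < read_len)
    stop("mutated genome shorter than the read length; increase genome_len")

  ref <- tibble::tibble(name = chrom_name, seq = genome_str, offset = 0,
                        length = genome_len)
  class(ref) <- c("mv_reference", class(ref))

  if (n_reads == 0) {
    reads <- tibble::tibble(id = character(), seq = character(),
                            qual = character())
    truth <- tibble::tibble(id = character(), true_pos = numeric(),
                            true_strand = integer())
  } else {
    starts <- sample.int(gm - read_len + 1L, n_reads, replace = TRUE)
    strands <- as.integer(stats::runif(n_reads) < 0.5)
    seqs <- substring(mut_str, starts, starts + read_len - 1L)
    rev_i <- strands == 1L
    if (any(rev_i)) seqs[rev_i] <- revcomp(seqs[rev_i])
    # sequencing errors: independent substitutions at error_rate
    n_err <- stats::rbinom(n_reads, read_len, error_rate)
    for (i in which(n_err > 0)) {
      at <- sample.int(read_len, n_err[i])
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      shift <- sample.int(3, n_err[i], replace = TRUE)
      s[at] <- bases[((match(s[at], bases) - 1 + shift) %% 4) + 1]
      seqs[i] <- paste(s, collapse = "")
    }
    seg <- findInterval(starts, seg_m)
    true_pos <- (seg_o[seg] + (starts - seg_m[seg])) - 1 # 0-based original
    true_pos <- pmin(pmax(true_pos, 0), genome_len - 1)
    ids <- sprintf("read_%06d", seq_len(n_reads))
    reads <- tibble::tibble(id = ids, seq = seqs,
                            qual = strrep("I", read_len))
    truth <- tibble::tibble(id = ids, true_pos = as.numeric(true_pos),
                            true_strand = strands)
  }

  if (!is.null(fasta))
    writeLines(c(paste0(">", chrom_name), genome_str), fasta)
  if (!is.null(fastq))
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+",
                               reads$qual)), fastq)
  if (!is.null(truth_file))
    utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(ref = ref, reads = reads, truth = truth)
}
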