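# Pure-R oracles, independent of the compiled implementation.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# reverse complement, character by character
rc_str <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

canon_str <- function(x) pmin(x, rc_str(x))

# all kmers of a sequence as strings (1 per position)
kmers_str <- function(seq, k) {
  n <- nchar(seq) - k + 1
  if (n < 1) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1)
}

# mutate a sequence: per-base substitutions at rate e, then n_ins/n_del
# single-base indels at random positions
mutate_seq <- function(seq, e = 0, n_indel = 0) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  hit <- which(stats::runif(length(s)) < e)
  if (length(hit)) {
    shift <- sample.int(3, length(hit), replace = TRUE)
    s[hit] <- bases[((match(s[hit], bases) - 1 + shift) %% 4) + 1]
  }
  if (n_indel > 0) {
    for (i in seq_len(n_indel)) {
      at <- sample.int(length(s) - 1, 1)
      if (stats::runif(1) < 0.5) {
        s <- append(s, sample(bases, 1), after = at)
      } else {
        s <- s[-at]
      }
    }
  }
  paste(s, collapse = "")
}

# Brute-force kmer-voting oracle (vanilla semantics): exact canonical kmer
# matches vote at displacement j - i, window-sum convolution of radius
# n_conv, maximum with lower-median tie break. Returns list(phi, score).
vote_oracle <- function(read_seq, contig_seq, v, n_conv) {
  rk <- canon_str(kmers_str(read_seq, v))
  ck <- canon_str(kmers_str(contig_seq, v))
  nr <- length(rk); nc <- length(ck)
  cmap <- split(seq_len(nc) - 1L, ck)
  phimin <- -(nr - 1L); phimax <- nc - 1L
  V <- integer(phimax - phimin + 1L)
  for (i in seq_len(nr)) {
    js <- cmap[[rk[i]]]
    if (is.null(js)) next
    phi <- js - (i - 1L)
    V[phi - phimin + 1L] <- V[phi - phimin + 1L] + 1L
  }
  # convolution with zero padding beyond the range
  Vp <- c(integer(n_conv), V, integer(n_conv))
  cs <- cumsum(c(0L, Vp))
  idx <- seq_along(V) + n_conv
  Vc <- cs[idx + n_conv + 1L] - cs[idx - n_conv]
  mx <- max(Vc)
  if (mx == 0) return(list(phi = NA_integer_, score = 0L))
  at <- which(Vc == mx)
  mid <- (at[1] + at[length(at)]) %/% 2
  list(phi = phimin + mid - 1L, score = mx)
}

# small simulated genome + index fixture shared across tests
make_fixture <- function(genome_len = 20000, n_reads = 50, seed = 42,
                         error_rate = 0.01, params = NULL) {
  sim <- simulate_reads(genome_len = genome_len, n_reads = n_reads,
                        read_len = 150, error_rate = error_rate, seed = seed)
  if (is.null(params)) params <- mv_params(W = 150, seed = 7)
  idx <- build_index(sim$ref, params)
  list(sim = sim, idx = idx, params = params)
}

hv_key <- function(hi, lo) paste(hi, lo, sep = ":")
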