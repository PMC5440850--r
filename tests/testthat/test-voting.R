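test_that("keyed kmer hashing is deterministic, task-separated and bijective", {
  ks <- kmer_set(random_seq(200), 20)
  k1 <- make_task_keys(11, 1)
  k2 <- make_task_keys(11, 2)
  h1a <- keyed_kmer_hash(ks, k1)
  h1b <- keyed_kmer_hash(ks, k1)
  expect_identical(h1a, h1b)
  # rekeying: the same kmers hash to unrelated values in another task
  h2 <- keyed_kmer_hash(ks, k2)
  expect_false(any(h1a$hi == h2$hi & h1a$lo == h2$lo))
  # x -> (x XOR k1) * k2 is a bijection for odd k2: distinct in, distinct out
  set.seed(51)
  codes <- sample(2^40, 1e5)
  h <- keyed_kmer_hash(codes, k1)
  expect_equal(anyDuplicated(hv_key(h$hi, h$lo)), 0)
  # even k2 rejected
  bad <- k1
  bad$k2_lo <- 2 * (bad$k2_lo %/% 2)
  class(bad) <- "mv_task_keys"
  expect_error(keyed_kmer_hash(codes[1:2], bad), "odd")
})

test_that("repeat-free pairs at beta=1, rho=1 are unmasked and fully ordered", {
  set.seed(52)
  read <- random_seq(150)
  contig <- paste0(random_seq(60), read, random_seq(60))
  p <- mv_params(W = 150, beta = 1, seed = 3)
  ts <- prepare_task(read, contig, p)
  expect_length(ts, 1)
  t <- ts[[1]]
  expect_false(any(t$read_pos_mask))
  expect_false(any(t$contig_pos_mask))
  expect_equal(t$read_bin, 0:(length(t$read_bin) - 1)) # full ordering revealed
  expect_equal(t$pad, 0)
  # determinism
  t2 <- prepare_task(read, contig, p)[[1]]
  expect_identical(unclass(t), unclass(t2))
})

test_that("an all-repeat read is fully masked", {
  p <- mv_params(W = 150, beta = 1, seed = 3)
  ts <- prepare_task(strrep("A", 40), strrep("A", 150), p, task_id0 = 5)
  expect_true(all(ts[[1]]$read_pos_mask))
  expect_true(all(ts[[1]]$read_masked))
})

test_that("repeat masking covers neighbourhoods with runs of at least v kmers", {
  set.seed(53)
  v <- 20
  # a single 20-mer repeated at positions 5 and 50 of an otherwise unique contig
  repeat_kmer <- random_seq(v)
  base <- random_seq(120)
  contig <- paste0(substr(base, 1, 5), repeat_kmer,
                   substr(base, 6, 30), repeat_kmer, substr(base, 31, 120))
  read <- random_seq(150)
  contig <- paste0(contig, random_seq(30)) # >= read length
  p <- mv_params(W = 150, beta = 1, seed = 9)
  t <- prepare_task(read, contig, p)[[1]]
  m <- t$contig_pos_mask
  expect_true(any(m))
  runs <- rle(m)
  expect_true(all(runs$lengths[runs$values] >= v))
  # each repeat occurrence is masked
  occ <- gregexpr(repeat_kmer, contig, fixed = TRUE)[[1]] - 1
  expect_true(all(m[occ + 1]))
  # unmasked payload values are unique within each list
  expect_equal(anyDuplicated(hv_key(t$contig_hi, t$contig_lo)[!t$contig_masked]), 0)
  expect_equal(anyDuplicated(hv_key(t$read_hi, t$read_lo)[!t$read_masked]), 0)
})

test_that("bin sampling ships max(1, floor(n_bin*rho)) kmers per bin or masks the bin", {
  set.seed(54)
  read <- random_seq(150)
  contig <- paste0(random_seq(50), read, random_seq(50))
  for (rho in c(0.25, 0.5, 1)) {
    p <- mv_params(W = 150, beta = 20, rho = rho, seed = 4)
    t <- prepare_task(read, contig, p)[[1]]
    n_pos <- t$n_contig_pos
    bins <- split(seq_len(n_pos) - 1, (seq_len(n_pos) - 1) %/% 20)
    counts <- table(t$contig_bin)
    for (b in names(bins)) {
      s <- max(1, floor(length(bins[[b]]) * rho))
      expect_equal(unname(counts[b]), s)
    }
  }
})

test_that("vote casting matches the stated point and range semantics", {
  set.seed(55)
  read <- random_seq(150)
  p1 <- mv_params(W = 150, beta = 1, seed = 6)
  # contig == read: single peak at phi = 0 of height = kmer count
  t <- prepare_task(read, read, p1)[[1]]
  v <- cast_votes(t)
  phis <- v$phi0 + seq_along(v$V) - 1
  expect_equal(max(v$V), 131)
  expect_equal(phis[which.max(v$V)], 0)
  expect_equal(sum(v$V > 0), 1)
  # no shared kmers -> identically zero
  t0 <- prepare_task(random_seq(150), random_seq(200), p1)[[1]]
  expect_true(all(cast_votes(t0)$V == 0))
  s0 <- score_task(convolve_votes(cast_votes(t0), 10))
  expect_true(s0$no_evidence)
  expect_equal(s0$score, 0)
})

test_that("a binned match votes over exactly [lC-hR+1, hC-lR)", {
  # one matching kmer pair: read bin [0,20), contig bin [40,60)
  task <- structure(list(
    task_id = 1, beta = 20L, rho = 1, v = 20L, n_read_pos = 20L,
    n_contig_pos = 60L, pad = 0L, chunk_off = 0,
    read_hi = 7, read_lo = 7, read_bin = 0L, read_masked = FALSE,
    contig_hi = 7, contig_lo = 7, contig_bin = 2L, contig_masked = FALSE,
    read_pos_mask = logical(20), contig_pos_mask = logical(60)),
    class = "mv_voting_task")
  v <- cast_votes(task)
  phis <- v$phi0 + seq_along(v$V) - 1
  voted <- phis[v$V > 0]
  expect_equal(range(voted), c(21, 59)) # min 40-19, max 59-0
  expect_true(all(v$V[v$V > 0] == 1))
})

test_that("convolution is a symmetric window sum", {
  expect_equal(convolve_votes(c(0L, 3L, 0L, 1L), 0), c(0L, 3L, 0L, 1L))
  # impulse response: ones exactly on [phi0-n, phi0+n]
  V <- integer(41); V[21] <- 1L
  expect_equal(convolve_votes(V, 10), as.integer(abs(seq_len(41) - 21) <= 10))
  # two unit votes 5 apart overlap to a plateau of 2
  V2 <- integer(41); V2[18] <- 1L; V2[23] <- 1L
  vc <- convolve_votes(V2, 10)
  expect_equal(max(vc), 2L)
  expect_equal(which(vc == 2L), 13:28)
  # random vector against a direct R window-sum oracle
  set.seed(56)
  V3 <- as.integer(rpois(100, 2))
  for (n in c(0, 3, 10)) {
    oracle <- vapply(seq_along(V3), function(j) {
      sum(V3[max(1, j - n):min(length(V3), j + n)])
    }, 0L)
    expect_equal(convolve_votes(V3, n), oracle)
  }
})

test_that("scoring picks the argmax with the middle-of-plateau tie rule", {
  mk <- function(V, phi0 = 0L) structure(list(phi0 = phi0, V = as.integer(V)),
                                         class = "mv_votes")
  expect_equal(score_task(mk(c(0, 5, 1)))$phi, 1)
  # plateau on indices 10..14 (phi 10..14) -> middle 12
  V <- integer(20); V[11:15] <- 7L
  expect_equal(score_task(mk(V))$phi, 12)
  expect_equal(score_task(mk(V))$score, 7)
  # random vectors against a direct R argmax oracle
  set.seed(57)
  for (i in 1:25) {
    V <- as.integer(rpois(60, 1))
    s <- score_task(mk(V, phi0 = -13L))
    if (max(V) == 0) {
      expect_true(s$no_evidence)
    } else {
      at <- which(V == max(V))
      expect_equal(s$phi, -13L + (at[1] + at[length(at)]) %/% 2 - 1L)
      expect_equal(s$score, max(V))
    }
  }
})

test_that("vanilla task scores equal the brute-force voting oracle", {
  set.seed(58)
  p <- mv_params(W = 150, mode = "vanilla", seed = 12, chunk_cap_mult = 10)
  for (i in 1:25) {
    clen <- sample(170:1000, 1)
    contig <- random_seq(clen)
    off <- sample(clen - 150 + 1, 1)
    read <- mutate_seq(substr(contig, off, off + 149), e = 0.03,
                       n_indel = sample(0:2, 1))
    t <- prepare_task(read, contig, p)[[1]]
    got <- score_task(convolve_votes(cast_votes(t), 10))
    want <- vote_oracle(read, contig, v = 20, n_conv = 10)
    expect_equal(got$score, want$score)
    expect_equal(got$phi, want$phi)
  }
})

test_that("mapping quality follows alpha*(r1-r2)/r1 with clamping", {
  one <- data.frame(gpos = 100, score = 50L, strand = 0L)
  r <- finalize_alignment(one, read_len = 150, alpha = 60)
  expect_equal(r$mapq, 60L) # single candidate: r2 == 0
  two <- data.frame(gpos = c(100, 5000), score = c(50L, 50L), strand = 0L)
  expect_equal(finalize_alignment(two, 150, 60)$mapq, 0L) # r1 == r2
  half <- data.frame(gpos = c(100, 5000), score = c(50L, 25L), strand = 0L)
  expect_equal(finalize_alignment(half, 150, 60)$mapq, 30L)
  # a same-locus echo (e.g. the other orientation) does not count as r2
  echo <- data.frame(gpos = c(100, 130), score = c(50L, 40L), strand = c(0L, 1L))
  expect_equal(finalize_alignment(echo, 150, 60)$mapq, 60L)
  none <- data.frame(gpos = numeric(0), score = integer(0), strand = integer(0))
  expect_false(finalize_alignment(none, 150, 60)$mapped)
})

test_that("secure and vanilla voting agree on repeat-free pairs with rho=1", {
  set.seed(59)
  for (i in 1:15) {
    contig <- random_seq(400)
    off <- sample(250, 1)
    read <- mutate_seq(substr(contig, off, off + 149), e = 0.01)
    pv <- mv_params(W = 150, mode = "vanilla", seed = 21, chunk_cap_mult = 4)
    p1 <- mv_params(W = 150, mode = "secure", beta = 1, seed = 21,
                    chunk_cap_mult = 4)
    p20 <- mv_params(W = 150, mode = "secure", beta = 20, seed = 21,
                     chunk_cap_mult = 4)
    sv <- score_task(convolve_votes(cast_votes(prepare_task(read, contig, pv)[[1]]), 10))
    s1 <- score_task(convolve_votes(cast_votes(prepare_task(read, contig, p1)[[1]]), 10))
    s20 <- score_task(convolve_votes(cast_votes(prepare_task(read, contig, p20)[[1]]), 10))
    expect_equal(s1$phi, sv$phi)     # beta = 1: identical
    expect_lte(abs(s20$phi - sv$phi), 20) # beta = 20: within one bin
  }
})

test_that("chunk splitting and padding change no final alignment", {
  set.seed(60)
  for (i in 1:10) {
    contig <- random_seq(900)
    off <- sample(700, 1)
    read <- mutate_seq(substr(contig, off, off + 149), e = 0.01)
    p_split <- mv_params(W = 150, beta = 1, seed = 31, chunk_cap_mult = 2)
    p_whole <- mv_params(W = 150, beta = 1, seed = 31, chunk_cap_mult = 8)
    score_all <- function(p) {
      ts <- prepare_task(read, contig, p)
      res <- do.call(rbind, lapply(ts, function(t) {
        s <- score_task(convolve_votes(cast_votes(t), 10))
        data.frame(gpos = t$chunk_off + ifelse(s$no_evidence, NA_integer_, s$phi),
                   score = s$score, strand = 0L)
      }))
      finalize_alignment(res[!is.na(res$gpos), , drop = FALSE], 150, 60)
    }
    a <- score_all(p_split)
    b <- score_all(p_whole)
    expect_length(prepare_task(read, contig, p_whole), 1)
    expect_gt(length(prepare_task(read, contig, p_split)), 1)
    expect_equal(a$gpos, b$gpos)
    expect_equal(a$mapq, b$mapq)
    # padded chunks all ship the same number of contig records
    lens <- vapply(prepare_task(read, contig, p_split),
                   function(t) length(t$contig_bin), 0L)
    expect_equal(length(unique(lens)), 1L)
  }
})

test_that("serialized payload is header plus fixed-size kmer records, and the
           cloud scores the bytes identically", {
  set.seed(61)
  read <- random_seq(150)
  contig <- paste0(random_seq(40), read, random_seq(40))
  p <- mv_params(W = 150, beta = 20, seed = 41)
  ts <- prepare_task(read, contig, p)
  stream <- serialize_tasks(ts)
  expect_equal(length(stream),
               sum(vapply(ts, function(t) {
                 40 + 12 * (length(t$read_bin) + length(t$contig_bin))
               }, 0)))
  direct <- lapply(ts, function(t) score_task(convolve_votes(cast_votes(t), 10)))
  from_bytes <- score_task_stream(stream, n_conv = 10)
  expect_equal(from_bytes$score, vapply(direct, `[[`, 0L, "score"))
  expect_equal(from_bytes$phi, vapply(direct, `[[`, 0L, "phi"))
})
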