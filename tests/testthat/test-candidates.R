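test_that("a read identical to a unique indexed window self-retrieves with b_hits == T", {
  set.seed(31)
  p <- mv_params(W = 150, T_tables = 20, seed = 6)
  g <- random_seq(3000)
  idx <- build_index(c(chr = g), p)
  pos <- 1200
  read <- substr(g, pos + 1, pos + 150)
  cand <- select_candidates(read, idx, b_min_hits = 1)
  hit <- cand[cand$gstart <= pos & pos + 150 <= cand$gend, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$b_hits, 20L)
  expect_gte(hit$gend - hit$gstart, 150)
  # interval invariant over all candidates
  expect_true(all(cand$gend - cand$gstart >= 150))
  expect_true(all(cand$b_hits >= 1 & cand$b_hits <= 20))
  expect_true(all(diff(cand$b_hits) <= 0)) # sorted by descending b_hits
})

test_that("reads of all N have no valid fingerprint and get no candidates", {
  fix <- make_fixture(genome_len = 2000, n_reads = 0, seed = 33)
  cand <- select_candidates(strrep("N", 150), fix$idx)
  expect_equal(nrow(cand), 0)
})

test_that("b_hits equals a brute-force count of distinct tables over merged intervals", {
  set.seed(34)
  fix <- make_fixture(genome_len = 10000, n_reads = 30, seed = 35)
  W <- 150
  for (i in seq_len(10)) {
    read <- fix$sim$reads$seq[i]
    cand <- select_candidates(read, fix$idx, b_min_hits = 1)
    hits <- index_lookup(fix$idx, fingerprint_read(fix$idx, read))
    if (nrow(hits) == 0) {
      expect_equal(nrow(cand), 0)
      next
    }
    # oracle: merge contig extents that overlap or abut within W bp
    ext <- data.frame(s = hits$start, e = hits$start + hits$len - 1 + W,
                      t = hits$table)
    ext <- ext[order(ext$s, ext$t), ]
    merged <- data.frame(s = numeric(0), e = numeric(0), b = integer(0))
    gs <- ext$s[1]; ce <- ext$e[1]; tabs <- ext$t[1]
    for (r in seq_len(nrow(ext))[-1]) {
      if (ext$s[r] <= ce + W) {
        ce <- max(ce, ext$e[r]); tabs <- c(tabs, ext$t[r])
      } else {
        merged <- rbind(merged, data.frame(s = gs, e = ce,
                                           b = length(unique(tabs))))
        gs <- ext$s[r]; ce <- ext$e[r]; tabs <- ext$t[r]
      }
    }
    merged <- rbind(merged, data.frame(s = gs, e = ce,
                                       b = length(unique(tabs))))
    bbest <- max(merged$b)
    keep <- merged[merged$b >= max(1, ceiling(bbest / 2)), ]
    keep <- keep[order(-keep$b, keep$s), ]
    expect_equal(cand$b_hits, keep$b)
    expect_equal(cand$gstart, keep$s)
  }
})

test_that("the b_min_hits and b_best_hits thresholds are applied", {
  set.seed(36)
  fix <- make_fixture(genome_len = 10000, n_reads = 40, seed = 37)
  for (i in seq_len(20)) {
    read <- fix$sim$reads$seq[i]
    c1 <- select_candidates(read, fix$idx, b_min_hits = 1)
    if (nrow(c1) == 0) next
    bbest <- max(c1$b_hits)
    c2 <- select_candidates(read, fix$idx, b_min_hits = 2)
    expect_true(all(c2$b_hits >= 2))
    expect_true(all(c2$b_hits >= ceiling(bbest / 2) | c2$b_hits >= bbest))
    # raising the threshold can only remove candidates
    expect_true(all(c2$gstart %in% c1$gstart))
    expect_true(all(c1$b_hits >= max(1, ceiling(bbest / 2))))
  }
})

test_that("no returned candidate is a dominated sub-interval of another", {
  fix <- make_fixture(genome_len = 20000, n_reads = 40, seed = 39)
  dominated <- 0
  for (i in seq_len(40)) {
    cand <- select_candidates(fix$sim$reads$seq[i], fix$idx, b_min_hits = 1)
    if (nrow(cand) < 2) next
    for (a in seq_len(nrow(cand))) {
      inside <- cand$gstart > cand$gstart[a] & cand$gend < cand$gend[a] &
        cand$b_hits <= cand$b_hits[a]
      inside[a] <- FALSE
      dominated <- dominated + sum(inside)
    }
  }
  expect_equal(dominated, 0)
})

test_that("candidate selection is selective and sensitive on mutated reads", {
  fix <- make_fixture(genome_len = 50000, n_reads = 300, seed = 41,
                      error_rate = 0.01)
  n_cand <- integer(0)
  found <- logical(0)
  for (i in seq_len(nrow(fix$sim$reads))) {
    cand <- select_candidates(fix$sim$reads$seq[i], fix$idx, b_min_hits = 1)
    n_cand <- c(n_cand, nrow(cand))
    tp <- fix$sim$truth$true_pos[i]
    found <- c(found, any(cand$gstart - 20 <= tp & tp <= cand$gend - 130))
  }
  # scaled-down analogs of the genome-scale phase-1 behaviour
  expect_gte(mean(found), 0.97)   # true contig retrieved for >= 97% of reads
  expect_lte(median(n_cand), 10)  # few candidates per read
})
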