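test_that("hash family is reproducible, seed-sensitive, with odd multipliers", {
  f1 <- init_hash_family(128, 42)
  f2 <- init_hash_family(128, 42)
  expect_identical(family_coeffs(f1), family_coeffs(f2))
  f3 <- init_hash_family(128, 43)
  expect_false(identical(family_coeffs(f1), family_coeffs(f3)))
  expect_true(all(family_coeffs(f1)$a_lo %% 2 == 1))
  expect_error(init_hash_family(0, 1))
})

test_that("fingerprint minima equal the brute-force minimum over the set", {
  fam <- init_hash_family(64, 5)
  set.seed(5)
  codes <- sample(1e6, 3)
  fp_all <- fingerprint(codes, fam)
  singles <- lapply(codes, function(s) fingerprint(s, fam))
  # min over a set == elementwise (lexicographic on hi,lo) min of singletons
  hi <- sapply(singles, `[[`, "hi")
  lo <- sapply(singles, `[[`, "lo")
  pick <- max.col(-(hi * 2^32 + lo), ties.method = "first")
  expect_equal(fp_all$hi, hi[cbind(seq_len(64), pick)])
  expect_equal(fp_all$lo, lo[cbind(seq_len(64), pick)])

  # determinism and the singleton case
  expect_identical(unclass(fingerprint(codes, fam))[c("hi", "lo")],
                   unclass(fingerprint(rev(codes), fam))[c("hi", "lo")])
  expect_identical(singles[[1]]$hi, fingerprint(c(codes[1], codes[1]), fam)$hi)

  # validity threshold
  expect_false(fingerprint(codes, fam, min_kmers = 4)$valid)
  expect_true(fingerprint(codes, fam, min_kmers = 3)$valid)
})

test_that("monotone containment: adding elements never increases any minimum", {
  fam <- init_hash_family(128, 9)
  set.seed(9)
  for (rep in 1:10) {
    A <- sample(1e9, 20)
    B <- c(A, sample(1e9, 30))
    fa <- fingerprint(A, fam)
    fb <- fingerprint(B, fam)
    va <- fa$hi * 2^32 + fa$lo
    vb <- fb$hi * 2^32 + fb$lo
    expect_true(all(vb <= va))
  }
})

test_that("exact Jaccard matches enumeration", {
  expect_equal(jaccard_exact(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard_exact(c(1, 2), c(1, 2)), 1)
  expect_equal(jaccard_exact(1:3, 4:6), 0)
  expect_equal(jaccard_exact(numeric(0), numeric(0)), 0)
})

test_that("MinHash estimator is calibrated against exact Jaccard", {
  fam <- init_hash_family(128, 77)
  set.seed(77)
  n_pairs <- 60
  errs <- bounds <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    J <- stats::runif(1, 0.1, 0.9)
    m <- 300
    c_shared <- round(2 * m * J / (1 + J))
    pool <- sample(2^48, 2 * m, replace = FALSE)
    shared <- pool[seq_len(c_shared)]
    A <- c(shared, pool[(c_shared + 1):m])
    B <- c(shared, pool[(m + 1):(2 * m - c_shared)])
    Jx <- jaccard_exact(A, B)
    est <- jaccard_estimate(fingerprint(A, fam), fingerprint(B, fam))
    errs[i] <- abs(est - Jx)
    bounds[i] <- 3 * sqrt(Jx * (1 - Jx) / 128)
  }
  expect_lte(mean(errs), mean(bounds))

  # identical and disjoint limits
  A <- sample(2^48, 100)
  fa <- fingerprint(A, fam)
  expect_equal(jaccard_estimate(fa, fa), 1)
  B <- sample(2^48, 100) + 2^50
  expect_lte(jaccard_estimate(fa, fingerprint(B, fam)), 0.05)

  # errors: invalid or mismatched fingerprints
  expect_error(jaccard_estimate(fa, fingerprint(B, init_hash_family(64, 1))))
  expect_error(jaccard_estimate(fingerprint(A, fam, min_kmers = 1000), fa))
})

test_that("rolling fingerprints are bit-identical to direct per-window ones", {
  set.seed(13)
  fam <- init_hash_family(64, 13)
  seq <- random_seq(400)
  W <- 60; k <- 12
  st <- rolling_fingerprints(seq, W, k, fam, min_kmers = 1)
  expect_equal(length(st$pos), 400 - W + 1)
  for (i in seq_along(st$pos)) {
    w <- substr(seq, st$pos[i] + 1, st$pos[i] + W)
    direct <- fingerprint(kmer_set(w, k), fam, min_kmers = 1)
    got <- fp_at(st, i)
    expect_identical(got$hi, direct$hi)
    expect_identical(got$lo, direct$lo)
    expect_identical(got$valid, direct$valid)
  }

  # a sequence of exactly one window
  one <- rolling_fingerprints(substr(seq, 1, W), W, k, fam)
  expect_equal(length(one$pos), 1)
  expect_identical(fp_at(one, 1)$hi,
                   fingerprint(kmer_set(substr(seq, 1, W), k), fam)$hi)
  expect_error(rolling_fingerprints(substr(seq, 1, W - 1), W, k, fam))
})

test_that("N-rich windows yield invalid fingerprints at the validity threshold", {
  set.seed(14)
  fam <- init_hash_family(32, 14)
  seq <- paste0(random_seq(100), strrep("N", 80), random_seq(100))
  W <- 60; k <- 12
  min_k <- as.integer(ceiling(0.8 * (W - k + 1)))
  st <- rolling_fingerprints(seq, W, k, fam, min_kmers = min_k)
  # windows fully inside the N block have no surviving kmers
  expect_false(any(st$valid[st$pos >= 100 & st$pos + W <= 180]))
  expect_true(all(st$valid[st$pos + W <= 90]))
  # validity is exactly n_kmers >= min_kmers
  expect_equal(st$valid, st$n_kmers >= min_k & st$n_kmers > 0)
})
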