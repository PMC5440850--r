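test_that("projections are reproducible with distinct in-range indices", {
  p1 <- init_projections(78, 2, 128, 18, 3)
  p2 <- init_projections(78, 2, 128, 18, 3)
  expect_identical(unclass(p1), unclass(p2))
  expect_equal(dim(p1$P), c(78, 2))
  expect_true(all(p1$P >= 0 & p1$P < 128))
  expect_true(all(p1$P[, 1] != p1$P[, 2]))
  expect_true(all(p1$A_lo %% 2 == 1))
  # T=1, b=L: the projection is a permutation of all indices
  pp <- init_projections(1, 16, 16, 8, 1)
  expect_setequal(as.integer(pp$P), 0:15)
  expect_error(init_projections(4, 20, 16, 8, 1))
})

test_that("bucket hash depends only on the projected entries and stays in range", {
  set.seed(21)
  proj <- init_projections(10, 2, 32, 18, 2)
  fam <- init_hash_family(32, 2)
  fp1 <- fingerprint(sample(1e9, 40), fam)
  expect_equal(bucket_hash(fp1, 3, proj), bucket_hash(fp1, 3, proj))
  # perturb entries NOT in table 3's projection: bucket unchanged
  keep <- proj$P[4, ] + 1 # row t=3 (0-based), 1-based rows/entries
  fp2 <- fp1
  other <- setdiff(seq_len(32), keep)
  fp2$hi[other] <- (fp2$hi[other] + 1) %% 2^32
  expect_equal(bucket_hash(fp1, 3, proj), bucket_hash(fp2, 3, proj))
  # perturbing a projected entry changes the bucket (w.h.p.)
  fp3 <- fp1
  fp3$lo[keep[1]] <- (fp3$lo[keep[1]] + 1) %% 2^32
  expect_false(bucket_hash(fp1, 3, proj) == bucket_hash(fp3, 3, proj))
  # range over random fingerprints
  ids <- vapply(1:50, function(i) {
    bucket_hash(fingerprint(sample(1e9, 30), fam), sample(0:9, 1), proj)
  }, 0)
  expect_true(all(ids >= 0 & ids < 2^18))
  expect_error(bucket_hash(fingerprint(1:2, fam, min_kmers = 5), 0, proj))
})

test_that("a one-window genome yields one ContigEntry(start=0, len=1) per table", {
  set.seed(22)
  p <- mv_params(W = 150, T_tables = 12, seed = 4)
  idx <- build_index(c(chr = random_seq(150)), p)
  ent <- index_entries(idx)
  expect_equal(nrow(ent), 12)
  expect_equal(unique(ent$start), 0)
  expect_equal(unique(ent$len), 1L)
  expect_setequal(ent$table, 0:11)
  expect_error(build_index(c(chr = random_seq(100)), p))
})

test_that("contig compression is lossless and maximally merged", {
  set.seed(23)
  p <- mv_params(W = 150, T_tables = 20, seed = 8)
  ref <- c(c1 = random_seq(1000), c2 = random_seq(700))
  idx <- build_index(ref, p)
  ent <- index_entries(idx)

  # expansion reproduces the brute-force per-window assignment exactly
  expanded <- tibble::tibble(
    gpos = rep(ent$start, ent$len) + sequence(ent$len) - 1,
    table = rep(ent$table, ent$len),
    bucket = rep(ent$bucket, ent$len))
  oracle <- window_buckets_direct(ref, p)
  o1 <- expanded[order(expanded$table, expanded$gpos), ]
  o2 <- oracle[order(oracle$table, oracle$gpos), c("gpos", "table", "bucket")]
  expect_equal(as.data.frame(o1), as.data.frame(o2), ignore_attr = TRUE)

  # per-table losslessness: total merged length == number of valid windows
  nw <- index_info(idx)$n_valid_windows
  lens <- tapply(ent$len, ent$table, sum)
  expect_true(all(lens == nw))

  # maximal merging: no two adjacent entries in one bucket are mergeable
  by_bucket <- split(ent[order(ent$start), ], paste(ent$table, ent$bucket))
  mergeable <- vapply(by_bucket, function(b) {
    if (nrow(b) < 2) return(FALSE)
    any(b$start[-1] == head(b$start, -1) + head(b$len, -1))
  }, TRUE)
  expect_false(any(mergeable))
})

test_that("indexed windows self-retrieve through lookup in all T tables", {
  set.seed(24)
  p <- mv_params(W = 150, T_tables = 20, seed = 8)
  g <- random_seq(2000)
  idx <- build_index(c(chr = g), p)
  for (pos in sample(0:(2000 - 150), 25)) {
    w <- substr(g, pos + 1, pos + 150)
    hits <- index_lookup(idx, fingerprint_read(idx, w))
    covered <- hits$start <= pos & pos <= hits$start + hits$len - 1
    expect_setequal(unique(hits$table[covered]), 0:19)
  }
  # a random foreign sequence finds (almost) nothing on a small genome
  foreign <- index_lookup(idx, fingerprint_read(idx, random_seq(150)))
  expect_lte(nrow(foreign), 2)
})

test_that("two identical distant windows share all T buckets", {
  set.seed(25)
  block <- random_seq(150)
  g <- paste0(block, random_seq(1000), block)
  p <- mv_params(W = 150, T_tables = 15, seed = 2)
  idx <- build_index(c(chr = g), p)
  hits <- index_lookup(idx, fingerprint_read(idx, block))
  pos2 <- 150 + 1000
  for (t in 0:14) {
    h <- hits[hits$table == t, ]
    expect_true(any(h$start <= 0 & 0 <= h$start + h$len - 1))
    expect_true(any(h$start <= pos2 & pos2 <= h$start + h$len - 1))
  }
})

test_that("index serialization round-trips bit-identically", {
  set.seed(26)
  fix <- make_fixture(genome_len = 3000, n_reads = 10, seed = 31)
  path <- withr::local_tempfile(fileext = ".mhg")
  save_index(fix$idx, path)
  idx2 <- load_index(path)
  expect_identical(index_entries(fix$idx), index_entries(idx2))
  expect_identical(unclass(fix$idx$params), unclass(idx2$params))
  expect_identical(index_info(fix$idx), index_info(idx2))

  # aligning with the restored index gives identical results
  al1 <- align_reads(fix$sim$reads, fix$idx, fix$sim$ref, fix$params)
  al2 <- align_reads(fix$sim$reads, idx2, fix$sim$ref, fix$params)
  expect_identical(lapply(al1, c), lapply(al2, c))

  # corrupt/foreign files are rejected with explicit errors
  bad <- withr::local_tempfile()
  writeLines("not an index", bad)
  expect_error(load_index(bad), "not an MHG index")
  raw <- readBin(path, "raw", file.size(path))
  raw[9:12] <- as.raw(c(99, 0, 0, 0)) # bump the version field
  writeBin(raw, bad)
  expect_error(load_index(bad), "version")
})
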