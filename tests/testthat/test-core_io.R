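test_that("FASTA loading assigns offsets, uppercases, and maps ambiguity to N", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 description here", "ACGT"), fa)
  ref <- load_reference(fa)
  expect_equal(ref$name, "c1")
  expect_equal(ref$seq, "ACGT")
  expect_equal(ref$offset, 0)

  writeLines(c(">a", "ACGTACGTAC", ">b", "GGGGG"), fa)
  ref <- load_reference(fa)
  expect_equal(ref$offset, c(0, 10))
  expect_equal(ref$length, c(10, 5))

  writeLines(c(">a", "acgtRYacgt"), fa)
  ref <- load_reference(fa)
  expect_equal(ref$seq, "ACGTNNACGT")

  # line-wrapped records concatenate
  writeLines(c(">a", "ACGTAC", "GTACGT"), fa)
  expect_equal(load_reference(fa)$seq, "ACGTACGTACGT")

  writeLines(character(0), fa)
  expect_error(load_reference(fa))
})

test_that("FASTQ loading yields records in order and enforces the length invariant", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "TTTT", "+", "!!!!"), fq)
  rd <- load_reads(fq)
  expect_equal(rd$id, c("r1", "r2"))
  expect_equal(nchar(rd$seq), nchar(rd$qual))

  writeLines(character(0), fq)
  expect_equal(nrow(load_reads(fq)), 0)

  writeLines(c("@r1", "ACGTACGT", "+", "III"), fq)
  expect_error(load_reads(fq))

  # gzip-transparent
  gz <- withr::local_tempfile(fileext = ".fq.gz")
  con <- gzfile(gz, "w")
  writeLines(c("@r1", "ACGT", "+", "IIII"), con)
  close(con)
  expect_equal(load_reads(gz)$seq, "ACGT")
})

test_that("repetitive-kmer filter matches brute-force genome-wide counts", {
  # stated examples
  f <- build_kmer_filter(c(g = "AAAAAAAA"), k = 4, C_max = 3)
  expect_true(kmer_is_repetitive(f, "AAAA"))
  f <- build_kmer_filter(c(g = "ACGTACGT"), k = 4, C_max = 3)
  expect_false(any(kmer_is_repetitive(f, c("ACGT", "CGTA", "GTAC", "TACG"))))
  # kmers containing N are always filtered
  expect_true(kmer_is_repetitive(f, "ACNT"))

  # brute-force dictionary oracle on a random genome with planted repeats
  set.seed(101)
  rep_block <- random_seq(12)
  g <- paste0(random_seq(3000), strrep(rep_block, 10), random_seq(3000))
  k <- 8
  counts <- table(canon_str(kmers_str(g, k)))
  f <- build_kmer_filter(c(g = g), k = k, C_max = 5)
  probe <- names(counts)
  expect_equal(unname(kmer_is_repetitive(f, probe)),
               as.vector(counts > 5))
  expect_equal(f$n_repetitive, sum(counts > 5))

  expect_error(build_kmer_filter(c(g = "ACGT"), k = 10, C_max = 1))
})

test_that("kmer_set extracts canonical kmers and respects the filter", {
  ks <- kmer_set("ACGTT", 4)
  expect_equal(ks$pos, c(0, 1))
  expect_equal(ks$kmer, c("ACGT", "AACG")) # canonical(CGTT) == AACG
  expect_equal(nrow(kmer_set("ACGT", 4)), 1)
  expect_equal(kmer_set("ACGT", 4)$pos, 0)

  # kmers overlapping N are dropped
  expect_equal(nrow(kmer_set("ACGNACG", 4)), 0)
  # all kmers filtered -> empty set
  f <- build_kmer_filter(c(g = strrep("ACGT", 30)), k = 4, C_max = 2)
  expect_equal(nrow(kmer_set("ACGTACGT", 4, f)), 0)
  # cardinality bound
  set.seed(7)
  s <- random_seq(100)
  expect_lte(nrow(kmer_set(s, 12)), 100 - 12 + 1)
})

test_that("canonicalization is strand-insensitive (property over random kmers)", {
  set.seed(11)
  for (k in c(4, 9, 20)) {
    km <- vapply(1:50, function(i) random_seq(k), "")
    expect_equal(canonical_kmer(km), canonical_kmer(rc_str(km)))
    expect_equal(canonical_kmer(km), canon_str(km)) # matches the R oracle
  }
  expect_true(is.na(canonical_kmer("ACNT")))
})
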