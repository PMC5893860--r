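test_that("query k-mer extraction takes the 5' window and flags ineligibility", {
  expect_equal(extract_query_kmer("ACGTACGTAC", 4), "ACGT")
  expect_true(is.na(extract_query_kmer(strrep("A", 20), 24)))
  expect_true(is.na(extract_query_kmer("ANGTACGT", 4)))
  expect_error(extract_query_kmer("ACGT", 33), "\\[1, 32\\]")
})

test_that("k-mer counting matches hand-derived cases", {
  # forward self-hit excluded, reverse-complement hit in the other read counts
  rs <- read_set(c("a", "b"), c("AACCG", "TGGTT"))
  expect_equal(count_kmer_matches(rs, "AACC", 1L, 4), 1L)

  # query k-mer occurring nowhere else
  expect_equal(count_kmer_matches(rs, "CCGA", 0L, 4), 0L)

  # three identical reads, k = read length
  rs3 <- read_set(letters[1:3], rep("ACGGTTCA", 3))
  expect_equal(count_kmer_matches(rs3, "ACGGTTCA", 2L, 8), 2L)

  # palindromic window counted once per position
  rs4 <- read_set("a", "TACGTA")
  expect_equal(count_kmer_matches(rs4, "ACGT", 0L, 4), 1L)

  expect_error(count_kmer_matches(rs, "AAC", 1L, 4), "length k")
})

test_that("k-mer counting equals the naive window-scan oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    k <- sample(c(4L, 6L, 8L), 1)
    n <- sample(10:50, 1)
    rs <- rand_reads(n, sample(15:40, 1), seed = seed + 1000,
                     with_n = seed %% 5 == 0)
    src <- sample.int(n, 5)
    kmers <- substr(rs$seq[src], 1, k)
    ok <- nchar(rs$seq[src]) >= k & !grepl("N", kmers, fixed = TRUE)
    if (!any(ok)) next
    src <- src[ok]; kmers <- kmers[ok]
    expect_equal(count_kmer_matches(rs, kmers, src, k),
                 naive_kmer_counts(rs$seq, kmers, src, k))
  }
})

test_that("k-mer counting is strand symmetric", {
  rs <- rand_reads(40, 30, seed = 5)
  kmers <- substr(rs$seq[1:8], 1, 8)
  ext <- rep(0L, 8)  # external queries: no self-match exclusion
  m_fwd <- count_kmer_matches(rs, kmers, ext, 8)
  rs_rc <- read_set(rs$id, revcomp(rs$seq))
  m_rc <- count_kmer_matches(rs_rc, kmers, ext, 8)
  expect_identical(m_fwd, m_rc)
})

test_that("adding reads never decreases any match count", {
  rs <- rand_reads(30, 25, seed = 9)
  extra <- rand_reads(20, 25, seed = 10)
  src <- 1:6
  kmers <- substr(rs$seq[src], 1, 6)
  m1 <- count_kmer_matches(rs, kmers, src, 6)
  rs2 <- read_set(c(rs$id, extra$id), c(rs$seq, extra$seq))
  m2 <- count_kmer_matches(rs2, kmers, src, 6)
  expect_true(all(m2 >= m1))
})

test_that("expected error k-mer mass follows the quality product formula", {
  q40 <- read_set("a", strrep("A", 30), strrep("I", 30))
  expect_equal(expected_error_kmers(q40, 24), 1 - (1 - 1e-4)^24,
               tolerance = 1e-12)
  # any Q0 base makes the query contribute exactly 1
  q0 <- read_set("a", strrep("A", 30), paste0("!", strrep("I", 29)))
  expect_equal(expected_error_kmers(q0, 24), 1)
  # FASTA input (no qualities) contributes nothing
  fa <- read_set("a", strrep("A", 30))
  expect_equal(expected_error_kmers(fa, 24), 0)
})

test_that("error-correction arithmetic removes E zero-coverage queries", {
  prof <- fake_profile(c(rep(0, 40), rep(2, 60)))
  expect_equal(apply_error_correction(prof, 0), prof)

  cor <- apply_error_correction(prof, 10)
  expect_equal(cor$n_zero_effective, 30)
  expect_equal(cor$n_queries_effective, 90)
  expect_equal(cor$effective_positions,
               prof$effective_positions - 10 * (101 - 24 + 1))

  expect_warning(cl <- apply_error_correction(prof, 50), "clamping")
  expect_equal(cl$n_zero_effective, 0)
  expect_equal(cl$n_queries_effective, 60)
  expect_error(apply_error_correction(prof, -1), "non-negative")
})

test_that("kmer_profile redraws ineligible queries and reports E", {
  rs <- rand_reads(60, 30, seed = 3)
  rs$seq[1:20] <- paste0("N", substr(rs$seq[1:20], 2, 30))  # ineligible prefix
  prof <- kmer_profile(rs, k = 8, q_target = 30, seed = 1)
  expect_equal(prof$n_queries, 30)
  expect_true(all(substr(rs$seq[prof$source_idx], 1, 1) != "N"))
  expect_equal(prof$error_mass, 30 * (1 - (1 - 1e-3)^8), tolerance = 1e-10)
  expect_equal(prof$effective_positions,
               60 * (30 - 8 + 1) - prof$error_mass * (30 - 8 + 1))
})

test_that("ungapped alignment applies overlap and identity thresholds", {
  a <- paste(rep("ACGT", 25), collapse = "")
  expect_true(align_ungapped(a, a))

  # subject = last 50 bp of query + unrelated tail: exact 50-col overlap
  # at the >= 50% boundary (inclusive)
  set.seed(1)
  q <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  tail50 <- substr(q, 51, 100)
  subj <- paste0(tail50, strrep("A", 50))
  # guard against chance secondary alignments in the random tail
  expect_true(naive_align_match(q, subj, 0.95, 0.5))
  expect_true(align_ungapped(q, subj, 0.95, 0.5))

  # 94 matches over a 100-column overlap misses 95% identity
  qv <- strsplit(q, "")[[1]]
  sv <- qv
  flip <- c(5, 15, 25, 35, 45, 55)
  sv[flip] <- chartr("ACGT", "GTAC", qv[flip])  # always a different base
  s94 <- paste(sv, collapse = "")
  expect_false(align_ungapped(q, s94, 0.95, 1.0))
  expect_false(naive_align_match(q, s94, 0.95, 1.0))

  # N never matches anything
  expect_false(align_ungapped("NNNNNNNNNN", "NNNNNNNNNN", 0.95, 0.5))
})

test_that("alignment counting equals the quadratic all-pairs oracle", {
  toy <- c("ACGTACGTACGTACGTACGT",
           "ACGTACGTACGTACGTACGA",
           "TTTTGGGGCCCCAAAATTTT",
           "AAAATTTTGGGGCCCCAAAA",
           "ACGTACGTAC",
           "GTACGTACGT",
           "CCCCCCCCCCCCCCCCCCCC",
           "GGGGGGGGGGGGGGGGGGGG")
  rs <- read_set(paste0("t", 1:8), toy)
  src <- 1:8
  got <- .alignment_counts_cpp(rs$seq, as.integer(src), 0.95, 0.5)
  expect_equal(got, naive_align_counts(rs$seq, src, 0.95, 0.5))

  for (seed in 1:3) {
    rs <- rand_reads(12, 40, seed = seed + 50)
    src <- 1:12
    got <- .alignment_counts_cpp(rs$seq, as.integer(src), 0.9, 0.5)
    expect_equal(got, naive_align_counts(rs$seq, src, 0.9, 0.5))
  }
})

test_that("alignment profile counts reads, not positions, and excludes self", {
  rs <- read_set(paste0("c", 1:5), rep(strrep("ACGT", 10), 5))
  prof <- alignment_profile(rs, q_target = 5, seed = 1)
  expect_true(all(prof$counts == 4))
  expect_equal(prof$error_mass, 0)
  expect_equal(prof$effective_positions, read_stats(rs)$total_bp)

  # all-unique random 100-mers: no chance matches at 95% identity
  rs <- rand_reads(50, 100, seed = 77)
  prof <- alignment_profile(rs, q_target = 50, seed = 1)
  expect_true(all(prof$counts == 0))
})
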