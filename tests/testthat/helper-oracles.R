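# Shared fixtures and independent brute-force oracles, all pure R so they
# never share code with the compiled counting paths they check.

rand_reads <- function(n, len, seed, with_n = FALSE, qual_q = 30) {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T", if (with_n) "N")
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
  read_set(paste0("r", seq_len(n)), seqs,
           rep(strrep(intToUtf8(qual_q + 33L), len), n))
}

revcomp_r <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Naive O(N * L * Q) window scan: counts positions whose window equals the
# query k-mer or its reverse complement, skipping the query's own source
# window (read src, offset 1). src = 0 marks an external query.
naive_kmer_counts <- function(seqs, kmers, src, k) {
  vapply(seq_along(kmers), function(q) {
    targets <- unique(c(kmers[q], revcomp_r(kmers[q])))
    m <- 0L
    for (i in seq_along(seqs)) {
      L <- nchar(seqs[i])
      if (L < k) next
      for (off in seq_len(L - k + 1)) {
        if (i == src[q] && off == 1) next
        win <- substr(seqs[i], off, off + k - 1)
        if (grepl("N", win, fixed = TRUE)) next
        if (win %in% targets) m <- m + 1L
      }
    }
    m
  }, integer(1))
}

# Naive ungapped all-offset aligner (both strands), counting matching columns
# over the overlap; N never matches.
naive_align_match <- function(q, s, min_id, min_ov) {
  qv <- strsplit(q, "")[[1]]
  lq <- length(qv)
  need <- ceiling(min_ov * lq - 1e-9)
  for (subj in c(s, revcomp_r(s))) {
    sv <- strsplit(subj, "")[[1]]
    ls <- length(sv)
    for (d in seq(-ls + 1, lq - 1)) {
      lo <- max(1, d + 1)
      hi <- min(lq, d + ls)
      ov <- hi - lo + 1
      if (ov < need) next
      qs <- qv[lo:hi]
      ss <- sv[(lo - d):(hi - d)]
      matches <- sum(qs == ss & qs != "N")
      if (matches / ov >= min_id - 1e-12) return(TRUE)
    }
  }
  FALSE
}

naive_align_counts <- function(seqs, src, min_id, min_ov) {
  vapply(seq_along(src), function(q) {
    sum(vapply(seq_along(seqs), function(i) {
      i != src[q] && naive_align_match(seqs[src[q]], seqs[i], min_id, min_ov)
    }, logical(1)))
  }, integer(1))
}

# Deterministic profile builder for hand-set match counts.
fake_profile <- function(counts, kernel = "kmer", k = 24, read_len = 101,
                         n_reads = 1000) {
  stats <- list(n_reads = n_reads, total_bp = n_reads * read_len,
                mean_length = read_len)
  structure(list(
    counts = as.numeric(counts), source_idx = seq_along(counts),
    kernel = kernel, k = as.integer(k), transform_factor = 1,
    n_queries = length(counts), n_zero_raw = sum(counts == 0),
    n_queries_effective = length(counts), n_zero_effective = sum(counts == 0),
    error_mass = 0,
    effective_positions = if (kernel == "kmer") n_reads * (read_len - k + 1)
                          else n_reads * read_len,
    stats = stats), class = "match_profile")
}

# Noiseless gamma-CDF curve points for parameter-recovery tests.
model_curve <- function(alpha, beta, n_points = 15, lo = 0.02, hi = 0.995,
                        sd = 0.01) {
  q <- seq(qgamma(lo, alpha, rate = beta), qgamma(hi, alpha, rate = beta),
           length.out = n_points)
  data.frame(effort_bp = exp(q) - 1,
             coverage_mean = pgamma(q, alpha, rate = beta),
             coverage_sd = sd)
}
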