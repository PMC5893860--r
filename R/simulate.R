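# Synthetic-community simulator: multi-genome communities with lognormal
# abundances, abundance-weighted read sampling with per-base substitution
# error, and the closed-form Poisson (Lander-Waterman) coverage oracle.

#' Generate a synthetic multi-genome community
#'
#' Genomes are i.i.d. uniform-random DNA of lengths drawn uniformly from
#' `size_range_bp`; abundances are lognormal(0, `abundance_sigma`). The DNA
#' fraction of genome g is `f_g = a_g G_g / sum_h a_h G_h`.
#'
#' @param n_genomes number of genomes (`>= 1`).
#' @param size_range_bp length-2 vector of genome size bounds in bp.
#' @param abundance_sigma lognormal sigma of the abundances (0 for even).
#' @param seed RNG seed.
#' @return object of class `community`: list with `seq`, `length`,
#'   `abundance`, `dna_fraction`.
#' @export
make_community <- function(n_genomes, size_range_bp = c(20000, 50000),
                           abundance_sigma = 1, seed = 1) {
  if (!is_count(n_genomes)) stop("n_genomes must be a positive integer", call. = FALSE)
  if (length(size_range_bp) != 2 || any(size_range_bp < 100) ||
      size_range_bp[1] > size_range_bp[2]) {
    stop("size_range_bp must be an increasing pair of sizes >= 100 bp", call. = FALSE)
  }
  if (!is.numeric(abundance_sigma) || abundance_sigma < 0) {
    stop("abundance_sigma must be >= 0", call. = FALSE)
  }
  local_seed(seed, {
    lens <- sample.int(size_range_bp[2] - size_range_bp[1] + 1, n_genomes,
                       replace = TRUE) + size_range_bp[1] - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    ab <- if (abundance_sigma == 0) rep(1, n_genomes) else
      stats::rlnorm(n_genomes, 0, abundance_sigma)
    w <- ab * lens
    structure(list(seq = seqs, length = as.numeric(lens), abundance = ab,
                   dna_fraction = w / sum(w)),
              class = "community")
  })
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("community: %d genomes, %.0f bp total, top DNA fraction %.3f\n",
              length(x$seq), sum(x$length), max(x$dna_fraction)))
  invisible(x)
}

#' Simulate shotgun reads from a community
#'
#' Per read: the genome is drawn proportionally to its DNA fraction, the
#' start uniformly over valid positions, the strand uniformly; substitutions
#' are i.i.d. at `error_rate` to a uniformly chosen different base. Quality
#' strings are a constant Phred score; when `quality_q` is omitted it is
#' derived from the error rate (`-10 log10(error_rate)`, rounded, capped at
#' 40) so the k-mer kernel's error model sees accurate probabilities. Read
#' ids encode genome, start, strand and number of injected errors for truth
#' tracking.
#'
#' @param community a `community`.
#' @param n_reads number of reads (0 allowed).
#' @param read_len read length in bp, default 101.
#' @param error_rate per-base substitution probability in `[0, 1)`, default 0.
#' @param quality_q constant Phred quality of the quality strings, or NULL to
#'   derive from `error_rate`.
#' @param seed RNG seed.
#' @return list with `reads` (a `read_set`) and `truth` (data.frame with
#'   read_id, genome, start, strand, n_errors).
#' @export
simulate_reads <- function(community, n_reads, read_len = 101, error_rate = 0,
                           quality_q = NULL, seed = 1) {
  stopifnot(inherits(community, "community"))
  if (!is.numeric(n_reads) || n_reads < 0 || n_reads != floor(n_reads)) {
    stop("n_reads must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  if (read_len > min(community$length)) {
    stop("read_len exceeds the smallest genome", call. = FALSE)
  }
  if (is.null(quality_q)) {
    quality_q <- if (error_rate <= 0) 40L else
      min(40L, as.integer(round(-10 * log10(error_rate))))
  }
  if (n_reads == 0) {
    return(list(reads = read_set(character(0), character(0), character(0)),
                truth = data.frame(read_id = character(0), genome = integer(0),
                                   start = integer(0), strand = character(0),
                                   n_errors = integer(0))))
  }
  local_seed(seed, {
    g <- sample.int(length(community$seq), n_reads, replace = TRUE,
                    prob = community$dna_fraction)
    start <- floor(stats::runif(n_reads) * (community$length[g] - read_len + 1)) + 1
    strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
    seqs <- substring(community$seq[g], start, start + read_len - 1)
    minus <- strand == "-"
    if (any(minus)) seqs[minus] <- .revcomp_cpp(seqs[minus])
    n_err <- if (error_rate > 0) stats::rbinom(n_reads, read_len, error_rate)
             else integer(n_reads)
    for (i in which(n_err > 0)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(read_len, n_err[i])
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
      seqs[i] <- paste(ch, collapse = "")
    }
    ids <- sprintf("r%d|g=%d|s=%d|str=%s|e=%d", seq_len(n_reads), g, start,
                   strand, n_err)
    qual <- strrep(intToUtf8(quality_q + 33L), read_len)
    list(reads = read_set(ids, seqs, rep(qual, n_reads)),
         truth = data.frame(read_id = ids, genome = g, start = start,
                            strand = strand, n_errors = n_err))
  })
}

#' Inject substitution errors into reads
#'
#' Mirrors the query-mutation experiment used to validate the error
#' correction: i.i.d. per-base substitutions at `rate`, with the quality
#' strings replaced by a constant Phred score matching the rate so E is
#' estimated from accurate probabilities.
#'
#' @param reads a `read_set`.
#' @param rate per-base substitution probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param quality_q constant Phred quality for the rewritten quality strings,
#'   or NULL to derive from `rate`.
#' @return the mutated `read_set`.
#' @export
inject_errors <- function(reads, rate, seed = 1, quality_q = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must be in [0, 1)", call. = FALSE)
  }
  if (is.null(quality_q)) {
    quality_q <- if (rate <= 0) 40L else
      min(40L, as.integer(round(-10 * log10(rate))))
  }
  seqs <- reads$seq
  lens <- nchar(seqs)
  if (rate > 0 && length(seqs) > 0) {
    seqs <- local_seed(seed, {
      n_err <- stats::rbinom(length(seqs), lens, rate)
      for (i in which(n_err > 0)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(lens[i], n_err[i])
        for (p in pos) {
          from <- if (ch[p] %in% c("A", "C", "G", "T")) ch[p] else "A"
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), from), 1)
        }
        seqs[i] <- paste(ch, collapse = "")
      }
      seqs
    })
  }
  read_set(reads$id, seqs, strrep(intToUtf8(quality_q + 33L), lens))
}

#' Closed-form expected abundance-weighted coverage
#'
#' Poisson (Lander-Waterman) oracle: with expected depth
#' `d_g = n_reads * f_g * read_len / G_g`, the probability that a random
#' community base is sequenced is `sum_g f_g (1 - exp(-d_g))`. This is the
#' ground truth the redundancy-based estimators are benchmarked against.
#'
#' @param community a `community`.
#' @param n_reads number of reads.
#' @param read_len read length in bp.
#' @return expected coverage in `[0, 1]`.
#' @export
expected_poisson_coverage <- function(community, n_reads, read_len = 101) {
  stopifnot(inherits(community, "community"))
  f <- community$dna_fraction
  d <- n_reads * f * read_len / community$length
  sum(f * (1 - exp(-d)))
}

#' Number of reads needed for a target true coverage
#'
#' Numerically inverts [expected_poisson_coverage()] in `n_reads`.
#'
#' @param community a `community`.
#' @param target target true coverage in (0, 1).
#' @param read_len read length in bp.
#' @return integer number of reads.
#' @export
reads_for_coverage <- function(community, target, read_len = 101) {
  if (!is.numeric(target) || target <= 0 || target >= 1) {
    stop("target must be in (0, 1)", call. = FALSE)
  }
  f <- function(n) expected_poisson_coverage(community, n, read_len) - target
  upper <- 10
  while (f(upper) < 0) upper <- upper * 10
  as.integer(ceiling(stats::uniroot(f, c(1, upper), tol = 0.5)$root))
}

#' Write a simulation truth table
#'
#' @param truth the `truth` data.frame from [simulate_reads()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
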