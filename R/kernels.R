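# Redundancy kernels: count, for each query read, how many other reads in the
# dataset are redundant with it, either by exact matching of the query's
# 5'-end k-mer (default) or by ungapped alignment.

new_match_profile <- function(counts, src, kernel, k, stats,
                              n_queries, n_zero_raw, effective_positions,
                              transform_factor = 1) {
  structure(list(
    counts = as.numeric(counts),
    source_idx = as.integer(src),
    kernel = kernel,
    k = as.integer(k),
    transform_factor = transform_factor,
    n_queries = n_queries,
    n_zero_raw = n_zero_raw,
    n_queries_effective = n_queries,
    n_zero_effective = n_zero_raw,
    error_mass = 0,
    effective_positions = effective_positions,
    stats = stats
  ), class = "match_profile")
}

#' @export
print.match_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "match_profile (%s kernel%s)\n",
    "  dataset: %d reads, %.0f bp\n",
    "  queries: %d (%.2f effective after error correction, E = %.3f)\n",
    "  zero-match queries: %d raw, %.2f effective\n"),
    x$kernel, if (x$kernel == "kmer") sprintf(", k = %d", x$k) else "",
    x$stats$n_reads, x$stats$total_bp,
    x$n_queries, x$n_queries_effective, x$error_mass,
    x$n_zero_raw, x$n_zero_effective))
  invisible(x)
}

#' Extract the 5'-end query k-mer of a read
#'
#' @param seq a single DNA string.
#' @param k k-mer length.
#' @return the first `k` bases, or `NA_character_` when the read is
#'   ineligible as a query (shorter than `k`, or an N inside the window).
#'   Ineligibility is a value, not an error: ineligible reads are replaced by
#'   redrawing during query selection.
#' @export
extract_query_kmer <- function(seq, k) {
  if (!is_count(k) || k > 32) stop("k must be an integer in [1, 32]", call. = FALSE)
  if (length(seq) != 1L) stop("seq must be a single string", call. = FALSE)
  if (nchar(seq) < k) return(NA_character_)
  km <- substr(seq, 1L, k)
  if (grepl("N", km, fixed = TRUE)) return(NA_character_)
  km
}

#' Count exact k-mer matches of query k-mers across a dataset
#'
#' Low-level counting pass of the k-mer kernel: `m[i]` is the number of
#' (read, offset) windows in `reads` equal to `query_kmers[i]` or its reverse
#' complement, excluding the query's own source window (read
#' `query_src[i]`, offset 0). A palindromic window is counted once per
#' position. The scan is a single pass over the dataset with a query lookup
#' table, so the runtime is proportional to dataset size and independent of
#' the number of queries.
#'
#' @param reads a `read_set` (the full dataset).
#' @param query_kmers character vector of N-free k-mers, all of length `k`.
#' @param query_src integer vector of 1-based source-read indices.
#' @param k k-mer length (1..32).
#' @return integer vector of match counts `m`.
#' @export
count_kmer_matches <- function(reads, query_kmers, query_src, k) {
  if (!is_count(k) || k > 32) stop("k must be an integer in [1, 32]", call. = FALSE)
  if (any(nchar(query_kmers) != k)) {
    stop("all query k-mers must have length k", call. = FALSE)
  }
  .kmer_counts_cpp(reads$seq, as.character(query_kmers), as.integer(query_src),
                   as.integer(k))
}

#' Expected number of erroneous query k-mers (E)
#'
#' From the Phred qualities of each query read's 5'-end window:
#' `E = sum_i [1 - prod_j (1 - e_ij)]`, `j = 1..k`. Reads without qualities
#' contribute 0 (and error correction is unavailable for FASTA input).
#'
#' @param queries a `read_set` of query reads (with qualities).
#' @param k k-mer length.
#' @return E, a non-negative real.
#' @export
expected_error_kmers <- function(queries, k) {
  if (is.null(queries$qual) || length(queries) == 0) return(0)
  probs <- phred_error_probs(substr(queries$qual, 1L, k))
  sum(vapply(probs, function(e) 1 - prod(1 - e), numeric(1)))
}

#' Remove the expected erroneous k-mers from a match profile
#'
#' Erroneous query k-mers almost always match nothing, so they inflate the
#' zero-match tally. The correction removes `E` zero-coverage queries as a
#' deterministic fractional mass: `n_zero_effective = max(n_zero - E, 0)`,
#' `n_queries_effective = Q - min(E, n_zero)`, and (k-mer kernel) the
#' effective dataset positions are reduced by `E * (mean_length - k + 1)`.
#'
#' @param profile a `match_profile`.
#' @param E expected number of erroneous query k-mers (`>= 0`).
#' @return the corrected `match_profile`.
#' @export
apply_error_correction <- function(profile, E) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E < 0) {
    stop("E must be a single non-negative number", call. = FALSE)
  }
  if (E > profile$n_zero_raw) {
    warning(sprintf(
      "error mass E = %.3f exceeds the %d zero-match queries; clamping", E,
      profile$n_zero_raw), call. = FALSE)
  }
  profile$error_mass <- E
  profile$n_zero_effective <- max(profile$n_zero_raw - E, 0)
  profile$n_queries_effective <- profile$n_queries - min(E, profile$n_zero_raw)
  if (profile$kernel == "kmer") {
    red <- E * max(profile$stats$mean_length - profile$k + 1, 0)
    profile$effective_positions <- max(profile$effective_positions - red, 0)
  }
  profile
}

#' k-mer redundancy profile of a read set
#'
#' The default redundancy kernel: one target k-mer is taken from the 5' end
#' of each query read, and the whole dataset is scanned for exact occurrences
#' of each target (or its reverse complement) at any position of any read.
#' Queries whose 5' window is ineligible (read shorter than `k`, or N in the
#' window) are replaced by redrawing from the remaining reads, keeping the
#' realised query count at `q_target` when possible. With qualities present,
#' the expected erroneous-k-mer mass E is estimated from the query windows'
#' Phred scores and removed from the zero-match tally
#' (see [apply_error_correction()]).
#'
#' @param reads a `read_set` (the dataset).
#' @param k k-mer length, default 24.
#' @param q_target number of query reads, default 10000.
#' @param queries optional externally supplied query `read_set` (its
#'   qualities drive E); requires `query_src`.
#' @param query_src 1-based dataset indices the external queries came from.
#' @param error_correction logical; default on when qualities are available,
#'   forced off otherwise.
#' @param transform_factor redundancy-to-coverage multiplier applied to the
#'   match counts before rarefaction (default 1).
#' @param seed RNG seed for query selection.
#' @return a `match_profile`.
#' @export
kmer_profile <- function(reads, k = 24, q_target = 10000, queries = NULL,
                         query_src = NULL, error_correction = NULL,
                         transform_factor = 1, seed = 1) {
  if (!is_count(k) || k > 32) stop("k must be an integer in [1, 32]", call. = FALSE)
  if (!is.numeric(transform_factor) || transform_factor <= 0) {
    stop("transform_factor must be > 0", call. = FALSE)
  }
  stats <- read_stats(reads)
  if (stats$n_reads == 0) stop("empty read set", call. = FALSE)

  if (is.null(queries)) {
    lens <- nchar(reads$seq)
    pref_ok <- !vapply(substr(reads$seq, 1L, k), grepl, logical(1),
                       pattern = "N", fixed = TRUE)
    idx <- select_query_indices(reads, q_target, seed,
                                eligible = function(i) lens[i] >= k & pref_ok[i])
    queries <- subset_reads(reads, idx)
    query_src <- idx
  } else {
    if (is.null(query_src) || length(query_src) != length(queries)) {
      stop("external queries require matching query_src indices", call. = FALSE)
    }
  }
  kmers <- substr(queries$seq, 1L, k)
  elig <- nchar(queries$seq) >= k & !grepl("N", kmers, fixed = TRUE)
  if (!all(elig)) {
    queries <- subset_reads(queries, which(elig))
    query_src <- query_src[elig]
    kmers <- kmers[elig]
  }
  if (length(kmers) == 0) stop("no eligible query k-mers", call. = FALSE)

  counts <- count_kmer_matches(reads, kmers, query_src, k)
  prof <- new_match_profile(
    counts, query_src, kernel = "kmer", k = k, stats = stats,
    n_queries = length(counts), n_zero_raw = sum(counts == 0),
    effective_positions = sum(pmax(nchar(reads$seq) - k + 1, 0)),
    transform_factor = transform_factor)

  if (is.null(error_correction)) error_correction <- !is.null(queries$qual)
  if (error_correction && is.null(queries$qual)) {
    warning("error correction disabled: no qualities available", call. = FALSE)
    error_correction <- FALSE
  }
  E <- if (error_correction) expected_error_kmers(queries, k) else 0
  apply_error_correction(prof, E)
}

#' Ungapped alignment of two reads
#'
#' TRUE iff some offset of the subject (or its reverse complement) against
#' the query yields an overlap of at least `min_overlap * nchar(query)`
#' aligned columns with identity (matching columns / overlap) of at least
#' `min_identity`. All offsets are scanned; N never matches anything.
#'
#' @param query,subject DNA strings.
#' @param min_identity identity threshold, default 0.95.
#' @param min_overlap overlap threshold as a fraction of the query length,
#'   default 0.5.
#' @return logical scalar.
#' @export
align_ungapped <- function(query, subject, min_identity = 0.95, min_overlap = 0.5) {
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0, 1]", call. = FALSE)
  if (min_overlap <= 0 || min_overlap > 1) stop("min_overlap must be in (0, 1]", call. = FALSE)
  .align_match_cpp(toupper(query), toupper(subject), min_identity, min_overlap)
}

#' Alignment redundancy profile of a read set
#'
#' The original redundancy kernel: `m[i]` is the number of dataset reads
#' (excluding the query's own source read) for which [align_ungapped()] is
#' TRUE. No error correction is applied (it is specific to the k-mer kernel).
#' Runtime is proportional to `N * Q * L^2`.
#'
#' @inheritParams kmer_profile
#' @param q_target number of query reads, default 1000.
#' @param min_identity,min_overlap alignment thresholds (defaults 0.95, 0.5).
#' @return a `match_profile`.
#' @export
alignment_profile <- function(reads, q_target = 1000, min_identity = 0.95,
                              min_overlap = 0.5, transform_factor = 1, seed = 1) {
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0, 1]", call. = FALSE)
  if (min_overlap <= 0 || min_overlap > 1) stop("min_overlap must be in (0, 1]", call. = FALSE)
  if (!is.numeric(transform_factor) || transform_factor <= 0) {
    stop("transform_factor must be > 0", call. = FALSE)
  }
  stats <- read_stats(reads)
  if (stats$n_reads == 0) stop("empty read set", call. = FALSE)
  lens <- nchar(reads$seq)
  idx <- select_query_indices(reads, q_target, seed,
                              eligible = function(i) lens[i] > 0)
  if (length(idx) == 0) stop("no eligible query reads", call. = FALSE)
  counts <- .alignment_counts_cpp(reads$seq, as.integer(idx),
                                  min_identity, min_overlap)
  new_match_profile(
    counts, idx, kernel = "alignment", k = 0L, stats = stats,
    n_queries = length(counts), n_zero_raw = sum(counts == 0),
    effective_positions = stats$total_bp,
    transform_factor = transform_factor)
}
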