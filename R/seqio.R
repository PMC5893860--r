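# Sequence input/output: FASTQ (4-line, Phred+33) and FASTA, plus the seeded
# query subsampling used by the redundancy kernels.

IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")

# Uppercase and restrict to {A,C,G,T,N}: IUPAC degeneracies are mapped to N
# with a warning, anything else is a parse error.
clean_bases <- function(x, where = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGTN]", "", x[bad]), "")))
    extra <- setdiff(chars, IUPAC_EXTRA)
    if (length(extra) > 0) {
      stop(sprintf("invalid %s characters: %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("%d %s(s) contained IUPAC degeneracy codes; mapped to N",
                    sum(bad), where), call. = FALSE)
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Construct a read set
#'
#' A read set is the package's in-memory container for sequencing reads: a
#' list with parallel character vectors `id`, `seq` (uppercase DNA over
#' `{A,C,G,T,N}`) and, for FASTQ input, `qual` (Phred+33 quality strings of
#' the same lengths as `seq`).
#'
#' @param id character vector of read labels.
#' @param seq character vector of DNA sequences.
#' @param qual optional character vector of Phred+33 quality strings.
#' @return an object of class `read_set`.
#' @export
read_set <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- clean_bases(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ", call. = FALSE)
  if (!is.null(qual)) {
    qual <- as.character(qual)
    if (length(qual) != length(seq)) stop("qual and seq lengths differ", call. = FALSE)
    if (any(nchar(qual) != nchar(seq))) {
      stop("quality strings must match sequence lengths", call. = FALSE)
    }
  }
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$seq)

#' @export
print.read_set <- function(x, ...) {
  s <- read_stats(x)
  cat(sprintf("read_set: %d reads, %.0f bp total, mean length %.1f bp%s\n",
              s$n_reads, s$total_bp, s$mean_length,
              if (is.null(x$qual)) " (no qualities)" else ""))
  invisible(x)
}

subset_reads <- function(rs, idx) {
  read_set(rs$id[idx], rs$seq[idx],
           if (is.null(rs$qual)) NULL else rs$qual[idx])
}

#' Summary statistics of a read set
#'
#' @param reads a `read_set`.
#' @return list with `n_reads` (N), `total_bp` and `mean_length` (bp).
#' @export
read_stats <- function(reads) {
  lens <- nchar(reads$seq)
  n <- length(lens)
  list(n_reads = n,
       total_bp = sum(as.numeric(lens)),
       mean_length = if (n > 0) mean(lens) else 0)
}

#' Decode Phred+33 quality strings to error probabilities
#'
#' @param qual character vector of quality strings.
#' @return list of numeric vectors of per-base error probabilities
#'   `10^(-(Q)/10)` where `Q = ASCII - 33`.
#' @export
phred_error_probs <- function(qual) {
  lapply(qual, function(q) {
    if (nchar(q) == 0) return(numeric(0))
    sc <- utf8ToInt(q) - 33L
    if (any(sc < 0L)) stop("quality character below '!': not Phred+33", call. = FALSE)
    10^(-sc / 10)
  })
}

#' Read a FASTQ file
#'
#' Strict 4-line records with Phred+33 qualities (gzip read transparently).
#' Phred+64 input is not auto-detected and will be rejected downstream when a
#' quality character decodes below zero.
#'
#' @param path file path (`.gz` allowed).
#' @return a `read_set` with qualities.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 0 && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) return(read_set(character(0), character(0), character(0)))
  if (length(lines) %% 4 != 0) {
    stop(sprintf("malformed FASTQ record %d: truncated record",
                 length(lines) %/% 4 + 1), call. = FALSE)
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seq <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0) {
    stop(sprintf("malformed FASTQ record %d: header does not start with '@'",
                 bad[1]), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop(sprintf("malformed FASTQ record %d: separator does not start with '+'",
                 bad[1]), call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    stop(sprintf("malformed FASTQ record %d: sequence/quality length mismatch",
                 bad[1]), call. = FALSE)
  }
  read_set(sub("^@", "", hdr), seq, qual)
}

#' Write a FASTQ file
#'
#' Inverse of [read_fastq()]: round-trips sequences and quality strings
#' byte-identically for well-formed input.
#'
#' @param reads a `read_set` with qualities.
#' @param path output path (`.gz` to compress).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.null(reads$qual)) stop("read set has no qualities", call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  n <- length(reads)
  if (n > 0) {
    out <- character(4 * n)
    out[seq(1, by = 4, length.out = n)] <- paste0("@", reads$id)
    out[seq(2, by = 4, length.out = n)] <- reads$seq
    out[seq(3, by = 4, length.out = n)] <- "+"
    out[seq(4, by = 4, length.out = n)] <- reads$qual
    writeLines(out, con)
  }
  invisible(path)
}

#' Read a FASTA file
#'
#' Line wrapping is handled; sequences are uppercased; records with empty
#' sequences are skipped with a warning; IUPAC degeneracies are mapped to N
#' with a warning. The returned reads carry no qualities, so the k-mer
#' kernel's error correction is unavailable for FASTA input.
#'
#' @param path file path (`.gz` allowed).
#' @return a `read_set` without qualities.
#' @export
read_fasta <- function(path) {
  recs <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("invalid sequence characters in FASTA input", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(recs) == 0) return(read_set(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- as.character(recs)
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    warning(sprintf("skipped %d FASTA record(s) with empty sequence", sum(empty)),
            call. = FALSE)
    ids <- ids[!empty]
    seqs <- seqs[!empty]
  }
  read_set(unname(ids), unname(seqs))
}

#' Read sequences from FASTA or FASTQ by file suffix
#'
#' @param path input path; `.fq`/`.fastq` (optionally `.gz`) is parsed as
#'   FASTQ, anything else as FASTA.
#' @return a `read_set`.
#' @export
read_sequences <- function(path) {
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
    read_fastq(path)
  } else {
    read_fasta(path)
  }
}

#' Draw the random query subset
#'
#' Uniform sample of `min(q_target, N)` reads without replacement,
#' deterministic given `seed`. The sampled reads remember their source
#' indices (attribute `source_idx`) so the kernels can exclude self-matches.
#'
#' @param reads a `read_set`.
#' @param q_target number of query reads wanted (default 10000).
#' @param seed RNG seed.
#' @return a `read_set` of queries with attribute `source_idx`.
#' @export
sample_queries <- function(reads, q_target = 10000, seed = 1) {
  if (!is_count(q_target)) stop("q_target must be a positive integer", call. = FALSE)
  n <- length(reads)
  idx <- local_seed(seed, sample.int(n, min(q_target, n)))
  out <- subset_reads(reads, idx)
  attr(out, "source_idx") <- idx
  out
}

# Seeded permutation walk that skips ineligible reads (too short, or N in the
# 5' k-mer window) and redraws until q_target eligible queries are found (or
# the pool is exhausted). Returns source indices.
select_query_indices <- function(reads, q_target, seed, eligible) {
  n <- length(reads)
  perm <- local_seed(seed, sample.int(n))
  ok <- eligible(perm)
  idx <- perm[ok]
  if (length(idx) > q_target) idx <- idx[seq_len(q_target)]
  idx
}
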