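# Taxonomic-side diversity estimators used to benchmark the sequence
# diversity index: Shannon H' (maximum likelihood and Dirichlet-pseudocount)
# and the Turing-Good coverage of an OTU count profile.

check_counts <- function(counts, require_positive = TRUE) {
  if (length(counts) == 0) stop("empty OTU count vector", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (require_positive && sum(counts) <= 0) {
    stop("all counts are zero", call. = FALSE)
  }
  as.numeric(counts)
}

#' Maximum-likelihood Shannon index
#'
#' `H' = -sum p_i ln p_i` over the observed frequencies
#' `p_i = count_i / sum(counts)`; zero-count OTUs are ignored. Natural-log
#' (nats) units throughout, to match Nd.
#'
#' @param counts non-negative integer vector (reads per OTU, one sample).
#' @return H' in nats.
#' @export
shannon_mle <- function(counts) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Bayesian (Dirichlet pseudocount) Shannon index
#'
#' Plug-in entropy of the posterior-mean frequencies under a symmetric
#' Dirichlet prior (Laplace prior by default):
#' `p_i = (count_i + prior) / (sum(counts) + S * prior)` over all `S` listed
#' OTUs, explicit zeros included.
#'
#' @param counts non-negative integer vector (reads per OTU, one sample).
#' @param prior Dirichlet pseudocount (> 0), default 1 (Laplace).
#' @return H' in nats.
#' @export
shannon_bayes <- function(counts, prior = 1) {
  counts <- check_counts(counts, require_positive = FALSE)
  if (!is.numeric(prior) || prior <= 0) stop("prior must be > 0", call. = FALSE)
  p <- (counts + prior) / (sum(counts) + length(counts) * prior)
  -sum(p * log(p))
}

#' Turing-Good coverage of an OTU profile
#'
#' `1 - F1 / n` where `F1` is the number of OTUs observed exactly once and
#' `n` the total count: the estimated probability that the next read belongs
#' to an already-observed OTU.
#'
#' @param counts non-negative integer vector (reads per OTU, one sample).
#' @return coverage fraction in `[0, 1]`.
#' @export
turing_good_coverage <- function(counts) {
  counts <- check_counts(counts)
  1 - sum(counts == 1) / sum(counts)
}

#' Read an OTU count table
#'
#' Tab-separated, `#` comment lines skipped. With two or more columns the
#' first column holds OTU ids and the rest per-sample counts; a single-column
#' file is taken as one sample's counts.
#'
#' @param path TSV path.
#' @return numeric matrix (OTUs x samples) with row/column names when
#'   available.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 1 && is.numeric(df[[1]])) {
    m <- as.matrix(df)
  } else if (ncol(df) >= 2) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  } else {
    stop("OTU table must have a count column", call. = FALSE)
  }
  storage.mode(m) <- "numeric"
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("OTU table contains negative or non-numeric counts", call. = FALSE)
  }
  m
}

#' Per-sample diversity summary of an OTU table
#'
#' @param table numeric matrix (OTUs x samples) or a count vector.
#' @param prior Dirichlet pseudocount for [shannon_bayes()].
#' @return data.frame with one row per sample: `shannon_mle`,
#'   `shannon_bayes`, `turing_good_coverage`.
#' @export
otu_diversity <- function(table, prior = 1) {
  if (is.vector(table)) table <- matrix(table, ncol = 1,
                                        dimnames = list(NULL, "sample1"))
  data.frame(
    sample = colnames(table),
    shannon_mle = apply(table, 2, shannon_mle),
    shannon_bayes = apply(table, 2, shannon_bayes, prior = prior),
    turing_good_coverage = apply(table, 2, turing_good_coverage),
    row.names = NULL)
}
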