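# End-to-end pipeline: reads -> query sampling -> redundancy kernel ->
# error correction -> rarefaction curve -> gamma-CDF fit -> summary.

#' Estimate metagenome coverage and sequence diversity from reads
#'
#' The package's main entry point: runs the full pipeline on a read file (or
#' an in-memory `read_set`) and returns the fitted coverage model, with the
#' rarefaction curve attached. Apply it to single reads only (one mate of a
#' pair, or merged pairs): the rarefaction model assumes reads are sampled
#' independently, which paired mates violate.
#'
#' @param input path to a FASTQ/FASTA file (gzip allowed) or a `read_set`.
#' @param kernel `"kmer"` (default) or `"alignment"`.
#' @param k k-mer length for the k-mer kernel, default 24.
#' @param q_target number of query reads (default 10000 for the k-mer kernel,
#'   1000 for the alignment kernel).
#' @param min_identity,min_overlap alignment-kernel thresholds
#'   (defaults 0.95, 0.5).
#' @param transform_factor redundancy-to-coverage multiplier, default 1.
#' @param error_correction logical or NULL (auto: on when qualities exist).
#' @param density_factor rarefaction density factor, default 0.7.
#' @param seed RNG seed for query selection.
#' @param npo optional path: write the rarefaction curve there.
#' @param verbose print progress lines to stderr.
#' @return a `coverage_fit` (see [fit_coverage()]); its `$curve` holds the
#'   rarefaction curve and run metadata.
#' @examples
#' cm <- make_community(5, c(5000, 10000), abundance_sigma = 1, seed = 4)
#' sim <- simulate_reads(cm, n_reads = 3000, read_len = 101, seed = 5)
#' fit <- rarecov(sim$reads, q_target = 1000, seed = 6)
#' summary(fit)
#' @export
rarecov <- function(input, kernel = c("kmer", "alignment"), k = 24,
                    q_target = NULL, min_identity = 0.95, min_overlap = 0.5,
                    transform_factor = 1, error_correction = NULL,
                    density_factor = 0.7, seed = 1, npo = NULL,
                    verbose = FALSE) {
  kernel <- match.arg(kernel)
  say <- function(...) if (verbose) message(sprintf(...))
  reads <- if (inherits(input, "read_set")) input else read_sequences(input)
  st <- read_stats(reads)
  say("reads: %d (%.0f bp, mean length %.1f)", st$n_reads, st$total_bp,
      st$mean_length)
  if (is.null(q_target)) q_target <- if (kernel == "kmer") 10000 else 1000
  profile <- if (kernel == "kmer") {
    kmer_profile(reads, k = k, q_target = q_target,
                 error_correction = error_correction,
                 transform_factor = transform_factor, seed = seed)
  } else {
    alignment_profile(reads, q_target = q_target, min_identity = min_identity,
                      min_overlap = min_overlap,
                      transform_factor = transform_factor, seed = seed)
  }
  say("queries: %d (Q' = %.2f, E = %.3f)", profile$n_queries,
      profile$n_queries_effective, profile$error_mass)
  curve <- build_curve(profile, density_factor = density_factor, seed = seed)
  if (!is.null(npo)) {
    write_npo(curve, npo)
    say("curve written to %s", npo)
  }
  fit <- fit_coverage(curve)
  say("fit: alpha = %.4f, beta = %.4f, converged = %s", fit$alpha, fit$beta,
      fit$converged)
  fit
}

#' Refit a stored rarefaction curve
#'
#' @param path a `.npo`-style TSV written by [write_npo()].
#' @return a `coverage_fit`.
#' @export
refit_npo <- function(path) {
  fit_coverage(read_npo(path))
}

#' Single-line machine-readable summary of a fit
#'
#' @param model a `coverage_fit`.
#' @param targets coverage targets for the effort projection.
#' @return named list `{coverage, Nd, LR95[, LR99...], alpha, beta,
#'   converged}` suitable for JSON serialisation.
#' @export
fit_summary <- function(model, targets = c(0.95, 0.99)) {
  stopifnot(inherits(model, "coverage_fit"))
  ndv <- if (model$alpha > 1) (model$alpha - 1) / model$beta else 0
  lr <- as.list(project_effort(model, targets))
  names(lr) <- paste0("LR", targets * 100)
  c(list(coverage = estimated_coverage(model), Nd = ndv), lr,
    list(alpha = model$alpha, beta = model$beta, converged = model$converged))
}
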