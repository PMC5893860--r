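# Rarefaction: turn a match profile into a coverage-vs-effort curve via the
# Turing-Good principle, and read/write the curve in the '#'-headed TSV
# format used by the redundancy step.

#' Logarithmic subsampling series
#'
#' Starting at `n_reads`, the sample size is iteratively multiplied by the
#' density factor (floored) until fewer than two reads remain; the series is
#' returned ascending with duplicates removed.
#'
#' @param n_reads dataset size in reads (`>= 2`).
#' @param density_factor multiplicative step in (0, 1), default 0.7.
#' @return ascending integer vector of subsample sizes, max `n_reads`, min
#'   `>= 2`.
#' @export
logarithmic_efforts <- function(n_reads, density_factor = 0.7) {
  if (!is_count(n_reads, min = 2)) stop("n_reads must be an integer >= 2", call. = FALSE)
  if (!is.numeric(density_factor) || length(density_factor) != 1L ||
      density_factor <= 0 || density_factor >= 1) {
    stop("density_factor must be in (0, 1)", call. = FALSE)
  }
  sizes <- numeric(0)
  s <- n_reads
  while (s >= 2) {
    sizes <- c(sizes, s)
    s <- floor(s * density_factor)
  }
  sort(unique(as.integer(sizes)))
}

#' Coverage estimate at a subsample fraction
#'
#' Turing-Good covered fraction at subsample fraction `p`: a query is covered
#' when at least one of its `m` matches falls inside the subsample, which
#' happens with probability `1 - (1-p)^m`. The closed-form mean is
#' `1 - (sum_i (1-p)^(m_i) - E) / Q'` (the error-corrected zero mass E is
#' removed from the uncovered tally), clamped to `[0, 1]`; the SD uses the
#' independent-Bernoulli approximation
#' `sqrt(sum_i u_i (1 - u_i)) / Q'` with `u_i = (1-p)^(m_i)`. A Monte-Carlo
#' estimator over binomial subsamples is available as a cross-check.
#'
#' @param profile a `match_profile`.
#' @param p subsample fraction in (0, 1].
#' @param method `"closed"` (default) or `"montecarlo"`.
#' @param n_rep Monte-Carlo replicates (default 2000).
#' @param seed RNG seed for the Monte-Carlo method.
#' @return list with `mean` and `sd`.
#' @export
coverage_at_effort <- function(profile, p, method = c("closed", "montecarlo"),
                               n_rep = 2000, seed = 1) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("p must be in (0, 1]", call. = FALSE)
  }
  method <- match.arg(method)
  Q <- profile$n_queries_effective
  if (Q <= 0) stop("profile has no effective queries", call. = FALSE)
  m <- profile$counts * profile$transform_factor
  E <- profile$error_mass
  if (method == "closed") {
    u <- (1 - p)^m
    raw <- 1 - (sum(u) - E) / Q
    if (raw < -1e-9) {
      warning("error-mass overshoot: clamping coverage to [0, 1]", call. = FALSE)
    }
    list(mean = min(max(raw, 0), 1),
         sd = sqrt(sum(u * (1 - u))) / Q)
  } else {
    mi <- as.integer(round(m))
    covered <- local_seed(seed, {
      vapply(seq_len(n_rep), function(r) sum(stats::rbinom(length(mi), mi, p) > 0),
             numeric(1))
    })
    est <- pmin(pmax(covered / Q, 0), 1)
    list(mean = mean(est), sd = stats::sd(est))
  }
}

#' Construct a rarefaction curve object
#'
#' @param points data.frame with columns `effort_bp`, `coverage_mean`,
#'   `coverage_sd`.
#' @param meta named list of run metadata (kernel settings, dataset size...).
#' @return object of class `rarefaction_curve`.
#' @export
rarefaction_curve <- function(points, meta = list()) {
  stopifnot(is.data.frame(points),
            all(c("effort_bp", "coverage_mean", "coverage_sd") %in% names(points)))
  if (is.unsorted(points$effort_bp, strictly = TRUE)) {
    stop("efforts must be strictly increasing", call. = FALSE)
  }
  if (any(points$coverage_mean < 0 | points$coverage_mean > 1)) {
    stop("coverage must lie in [0, 1]", call. = FALSE)
  }
  structure(list(points = points, meta = meta), class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  m <- x$meta
  cat(sprintf("rarefaction_curve: %d points, effort %.3g..%.3g bp\n",
              nrow(x$points), min(x$points$effort_bp), max(x$points$effort_bp)))
  if (length(m) > 0) {
    cat(sprintf("  kernel %s (k = %s), %s reads, %.0f bp, Q' = %.2f, E = %.3f\n",
                m$kernel, m$k, m$reads, m$bases, m$queries_effective, m$error_mass))
  }
  cat(sprintf("  final point coverage: %.4f\n",
              x$points$coverage_mean[nrow(x$points)]))
  invisible(x)
}

#' @export
plot.rarefaction_curve <- function(x, log = "x", ...) {
  pts <- x$points
  graphics::plot(pts$effort_bp, pts$coverage_mean, log = log, type = "b",
                 pch = 16, ylim = c(0, 1),
                 xlab = "Sequencing effort (bp)",
                 ylab = "Estimated average coverage", ...)
  graphics::arrows(pts$effort_bp, pmax(pts$coverage_mean - pts$coverage_sd, 0),
                   pts$effort_bp, pmin(pts$coverage_mean + pts$coverage_sd, 1),
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  invisible(x)
}

#' Build the rarefied coverage curve of a match profile
#'
#' Subsample sizes follow [logarithmic_efforts()]. For the k-mer kernel only
#' `L - k + 1` window starts per read of length `L` are testable, so the
#' redundancy observed at subsample fraction `p` corresponds to an
#' alignment-equivalent sequencing effort of
#' `p * total_bp * (mean_length - k + 1) / mean_length`; curve efforts are
#' expressed on that corrected bp scale (no correction for the alignment
#' kernel, whose effort at `p = 1` is exactly `total_bp`). The metadata keeps
#' the dataset's actual `bases`, where the fitted model is later evaluated
#' for the headline coverage.
#'
#' @param profile a `match_profile`.
#' @param density_factor subsampling density factor, default 0.7.
#' @param seed seed recorded in the metadata (the closed-form estimator
#'   itself is deterministic).
#' @return a `rarefaction_curve`.
#' @export
build_curve <- function(profile, density_factor = 0.7, seed = 1) {
  st <- profile$stats
  sizes <- logarithmic_efforts(st$n_reads, density_factor)
  scale <- if (profile$kernel == "kmer") {
    max(st$mean_length - profile$k + 1, 0) / st$mean_length
  } else 1
  p <- sizes / st$n_reads
  cov <- lapply(p, function(pp) coverage_at_effort(profile, pp))
  pts <- data.frame(
    effort_bp = p * st$total_bp * scale,
    coverage_mean = vapply(cov, `[[`, numeric(1), "mean"),
    coverage_sd = vapply(cov, `[[`, numeric(1), "sd"))
  meta <- list(
    version = pkg_version_string(),
    kernel = profile$kernel,
    k = profile$k,
    reads = st$n_reads,
    bases = st$total_bp,
    mean_length = st$mean_length,
    queries_effective = profile$n_queries_effective,
    error_mass = profile$error_mass,
    seed = seed)
  rarefaction_curve(pts, meta)
}

NPO_HEADER_KEYS <- c("version", "kernel", "k", "reads", "bases", "mean_length",
                     "queries_effective", "error_mass", "seed")

#' Write a rarefaction curve to a .npo-style TSV
#'
#' `#`-prefixed `key<TAB>value` header lines (version, kernel, k, reads,
#' bases, mean_length, queries_effective, error_mass, seed) followed by
#' `effort_bp<TAB>coverage_mean<TAB>coverage_sd` rows. Numbers are written
#' with 12 significant digits so `read_npo(write_npo(x))` round-trips.
#'
#' @param curve a `rarefaction_curve`.
#' @param path output path (`.gz` to compress).
#' @return `path`, invisibly.
#' @export
write_npo <- function(curve, path) {
  m <- curve$meta
  num <- function(x) {
    if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
  }
  hdr <- vapply(NPO_HEADER_KEYS, function(key) {
    val <- m[[key]]
    if (is.null(val)) stop(sprintf("curve metadata lacks '%s'", key), call. = FALSE)
    sprintf("# %s\t%s", key, num(val))
  }, character(1))
  rows <- sprintf("%.12g\t%.12g\t%.12g", curve$points$effort_bp,
                  curve$points$coverage_mean, curve$points$coverage_sd)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Read a .npo-style TSV rarefaction curve
#'
#' @param path path written by [write_npo()].
#' @return a `rarefaction_curve`.
#' @export
read_npo <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    kv <- strsplit(sub("^#[ \t]*", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("malformed header line: '%s'", h), call. = FALSE)
    meta[[kv[1]]] <- kv[2]
  }
  for (key in NPO_HEADER_KEYS) {
    if (is.null(meta[[key]])) stop(sprintf("missing header: %s", key), call. = FALSE)
  }
  for (key in c("k", "reads", "bases", "mean_length", "queries_effective",
                "error_mass", "seed")) {
    meta[[key]] <- as.numeric(meta[[key]])
  }
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body) == 0) stop("no curve points in file", call. = FALSE)
  pts <- utils::read.table(text = body, sep = "\t",
                           col.names = c("effort_bp", "coverage_mean", "coverage_sd"))
  rarefaction_curve(pts, meta)
}
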