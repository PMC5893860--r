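# Gamma-CDF coverage model: fit the rarefied coverage curve, derive the
# sequence-diversity index Nd, and project sequencing effort.

#' Gamma-CDF coverage model
#'
#' The model value is the regularised lower incomplete gamma function of
#' `beta * log(LR + 1)` with shape `alpha` (natural log):
#' `C(LR) = pgamma(log(LR + 1), shape = alpha, rate = beta)`. It is 0 at
#' `LR = 0` and tends to 1 as `LR` grows.
#'
#' @param effort_bp sequencing effort LR in bp (`>= 0`), vectorised.
#' @param alpha gamma shape (> 0).
#' @param beta gamma rate (> 0).
#' @return predicted coverage in `[0, 1]`.
#' @export
gamma_coverage <- function(effort_bp, alpha, beta) {
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0) {
    stop("alpha and beta must be positive", call. = FALSE)
  }
  if (any(effort_bp < 0)) stop("effort_bp must be >= 0", call. = FALSE)
  stats::pgamma(log(effort_bp + 1), shape = alpha, rate = beta)
}

#' Fit the gamma-CDF coverage model to a rarefaction curve
#'
#' Weighted nonlinear least squares of [gamma_coverage()] against the curve
#' points, on log-parameters via the Levenberg-Marquardt algorithm. Point
#' weights are `1 / max(coverage_sd^2, var_floor)`; points with coverage at
#' exactly 0 or 1 are kept but demoted to the floor weight 1 so they cannot
#' dominate. Initialisation is a fixed multi-start grid over
#' `alpha0 in {1.5, 3, 5, 10, 20}` with `beta0` chosen so the model median
#' matches the curve's half-coverage effort; the best-SSE start wins, making
#' the fit fully deterministic.
#'
#' @param curve a `rarefaction_curve`, or a data.frame with columns
#'   `effort_bp`, `coverage_mean`, `coverage_sd`.
#' @param var_floor variance floor for the weights (default 1e-4).
#' @param alphas multi-start shape grid.
#' @return an object of class `coverage_fit` with elements `alpha`, `beta`,
#'   `fit_sse` (unweighted residual sum of squares over the points used),
#'   `n_points_used`, `converged`, and the input `curve`.
#' @seealso [nd()], [project_effort()], [estimated_coverage()],
#'   [predict.coverage_fit()]
#' @export
fit_coverage <- function(curve, var_floor = 1e-4, alphas = c(1.5, 3, 5, 10, 20)) {
  pts <- if (inherits(curve, "rarefaction_curve")) curve$points else curve
  stopifnot(all(c("effort_bp", "coverage_mean", "coverage_sd") %in% names(pts)))
  x <- pts$effort_bp
  y <- pts$coverage_mean
  core <- y > 0 & y < 1
  if (all(y == 0)) stop("insufficient coverage signal: all-zero curve", call. = FALSE)
  if (sum(core) < 3) {
    stop("need at least 3 curve points with coverage strictly inside (0, 1)",
         call. = FALSE)
  }
  w <- 1 / pmax(pts$coverage_sd^2, var_floor)
  w[!core] <- 1  # floor weight for exact 0/1 points
  sw <- sqrt(w)
  lx <- log(x + 1)

  resid_fn <- function(par) {
    sw * (y - stats::pgamma(lx, shape = exp(par[1]), rate = exp(par[2])))
  }
  # half-coverage effort for the beta initialisation
  target <- max(y) / 2
  x_half <- x[which.min(abs(y - target))]
  lx_half <- max(log(x_half + 1), 1e-6)

  best <- NULL
  for (a0 in alphas) {
    b0 <- stats::qgamma(0.5, shape = a0) / lx_half
    ans <- tryCatch(
      minpack.lm::nls.lm(par = c(log(a0), log(max(b0, 1e-8))), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(ans)) next
    sse <- ans$deviance
    if (is.null(best) || sse < best$deviance) best <- ans
  }
  if (is.null(best)) stop("model fit failed for every start", call. = FALSE)

  alpha <- exp(best$par[1])
  beta <- exp(best$par[2])
  fitted <- stats::pgamma(lx, shape = alpha, rate = beta)
  structure(list(
    alpha = alpha,
    beta = beta,
    fit_sse = sum((y - fitted)^2),
    weighted_sse = best$deviance,
    n_points_used = length(y),
    converged = best$info %in% 1:4,
    curve = if (inherits(curve, "rarefaction_curve")) curve else
      rarefaction_curve(pts[order(pts$effort_bp), , drop = FALSE], list())
  ), class = "coverage_fit")
}

#' Sequence-diversity index Nd
#'
#' The mode of the gamma distribution whose CDF fits the coverage curve:
#' `Nd = (alpha - 1) / beta`, in units of the natural logarithm of base
#' pairs. When `alpha <= 1` the mode sits at the origin and Nd is reported as
#' 0 with a warning.
#'
#' @param model a `coverage_fit`.
#' @return Nd (ln-bp units).
#' @export
nd <- function(model) {
  stopifnot(inherits(model, "coverage_fit"))
  if (model$alpha <= 1) {
    warning("alpha <= 1: gamma mode at the origin, reporting Nd = 0", call. = FALSE)
    return(0)
  }
  (model$alpha - 1) / model$beta
}

#' Project the sequencing effort needed for a target coverage
#'
#' Exact inverse of the fitted model:
#' `LR* = exp(qgamma(target, shape = alpha, rate = beta)) - 1`, monotone
#' increasing in the target. A target of exactly 1 yields infinite effort.
#'
#' @param model a `coverage_fit`.
#' @param target_coverage target in (0, 1); default 0.95.
#' @return required effort LR* in bp.
#' @export
project_effort <- function(model, target_coverage = 0.95) {
  stopifnot(inherits(model, "coverage_fit"))
  if (!is.numeric(target_coverage) || length(target_coverage) < 1 ||
      any(target_coverage <= 0 | target_coverage > 1)) {
    stop("target_coverage must lie in (0, 1]", call. = FALSE)
  }
  exp(stats::qgamma(target_coverage, shape = model$alpha, rate = model$beta)) - 1
}

#' Headline coverage at the dataset's actual sequencing effort
#'
#' The fitted model evaluated at the dataset's full effort in bp (the curve
#' metadata's `bases` when available, else the curve's maximum effort). Using
#' the model rather than the raw last curve point smooths subsampling noise;
#' the raw value is reported alongside in [summary.coverage_fit()].
#'
#' @param model a `coverage_fit`.
#' @param effort_bp optional explicit effort (bp) at which to evaluate.
#' @return estimated coverage in `[0, 1]`.
#' @export
estimated_coverage <- function(model, effort_bp = NULL) {
  stopifnot(inherits(model, "coverage_fit"))
  if (is.null(effort_bp)) effort_bp <- actual_effort(model)
  gamma_coverage(effort_bp, model$alpha, model$beta)
}

actual_effort <- function(model) {
  b <- model$curve$meta$bases
  if (!is.null(b) && is.finite(as.numeric(b))) as.numeric(b)
  else max(model$curve$points$effort_bp)
}

#' @export
coef.coverage_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' Predict coverage at given sequencing efforts
#'
#' @param object a `coverage_fit`.
#' @param effort_bp efforts in bp; defaults to the fitted curve's efforts.
#' @param ... ignored.
#' @return numeric vector of predicted coverages.
#' @export
predict.coverage_fit <- function(object, effort_bp = NULL, ...) {
  if (is.null(effort_bp)) effort_bp <- object$curve$points$effort_bp
  gamma_coverage(effort_bp, object$alpha, object$beta)
}

#' @export
fitted.coverage_fit <- function(object, ...) {
  predict.coverage_fit(object)
}

#' @export
residuals.coverage_fit <- function(object, ...) {
  object$curve$points$coverage_mean - fitted.coverage_fit(object)
}

#' @export
print.coverage_fit <- function(x, ...) {
  cat("Gamma-CDF coverage model\n")
  cat(sprintf("  alpha = %.4f, beta = %.4f (%sconverged, %d points)\n",
              x$alpha, x$beta, if (x$converged) "" else "NOT ",
              x$n_points_used))
  cat(sprintf("  estimated coverage at %.4g bp: %.4f\n",
              actual_effort(x), estimated_coverage(x)))
  ndv <- if (x$alpha > 1) (x$alpha - 1) / x$beta else 0
  cat(sprintf("  sequence diversity Nd = %.3f ln-bp\n", ndv))
  cat(sprintf("  projected effort for 95%% coverage: %.4g bp\n",
              project_effort(x, 0.95)))
  invisible(x)
}

#' @export
summary.coverage_fit <- function(object, targets = c(0.95, 0.99), ...) {
  pts <- object$curve$points
  ndv <- if (object$alpha > 1) (object$alpha - 1) / object$beta else 0
  out <- list(
    alpha = object$alpha,
    beta = object$beta,
    nd = ndv,
    coverage = estimated_coverage(object),
    coverage_raw_final_point = pts$coverage_mean[nrow(pts)],
    actual_effort_bp = actual_effort(object),
    projected_effort_bp = stats::setNames(
      project_effort(object, targets), paste0("LR", targets * 100)),
    fit_sse = object$fit_sse,
    n_points_used = object$n_points_used,
    converged = object$converged)
  class(out) <- "summary.coverage_fit"
  out
}

#' @export
print.summary.coverage_fit <- function(x, ...) {
  cat("Gamma-CDF coverage model summary\n")
  cat(sprintf("  alpha = %.6g, beta = %.6g, SSE = %.3g, points = %d, converged = %s\n",
              x$alpha, x$beta, x$fit_sse, x$n_points_used, x$converged))
  cat(sprintf("  coverage at actual effort (%.4g bp): %.4f (raw final point %.4f)\n",
              x$actual_effort_bp, x$coverage, x$coverage_raw_final_point))
  cat(sprintf("  Nd = %.4f ln-bp\n", x$nd))
  for (i in seq_along(x$projected_effort_bp)) {
    cat(sprintf("  %s: %.4g bp\n", names(x$projected_effort_bp)[i],
                x$projected_effort_bp[i]))
  }
  invisible(x)
}

#' @export
plot.coverage_fit <- function(x, log = "x", ...) {
  pts <- x$curve$points
  xmax <- max(actual_effort(x), max(pts$effort_bp))
  grid <- exp(seq(log(max(min(pts$effort_bp), 1)), log(xmax * 1.5), length.out = 200)) - 1
  graphics::plot(pts$effort_bp, pts$coverage_mean, log = log, pch = 16,
                 ylim = c(0, 1), xlim = c(max(min(pts$effort_bp), 1), xmax * 1.5),
                 xlab = "Sequencing effort (bp)",
                 ylab = "Estimated average coverage", ...)
  graphics::lines(grid + 1, gamma_coverage(grid, x$alpha, x$beta),
                  col = "red3", lwd = 2, lty = 2)
  graphics::abline(h = c(0.95, 0.99), col = "grey60", lty = 3)
  graphics::abline(v = actual_effort(x), col = "grey40", lty = 3)
  invisible(x)
}
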