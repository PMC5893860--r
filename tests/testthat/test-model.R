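test_that("gamma-CDF model matches closed forms", {
  # LR = 0 gives zero coverage for any parameters
  expect_equal(gamma_coverage(0, 3, 2), 0)
  # alpha = 1: C = 1 - (LR + 1)^(-beta)
  expect_equal(gamma_coverage(exp(1) - 1, 1, 1), 1 - exp(-1), tolerance = 1e-12)
  # alpha = 2, x = beta * ln(LR + 1) = 1: C = 1 - (1 + x) e^(-x)
  expect_equal(gamma_coverage(exp(1) - 1, 2, 1), 1 - 2 * exp(-1),
               tolerance = 1e-12)
  expect_equal(gamma_coverage(1e12, 2, 1), 1, tolerance = 1e-4)
  expect_error(gamma_coverage(10, -1, 1), "positive")
  expect_error(gamma_coverage(-5, 1, 1), ">= 0")
})

test_that("fit recovers parameters from noiseless model curves", {
  crv <- model_curve(5, 0.5, n_points = 15, sd = 0)
  fit <- fit_coverage(crv)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - 5) / 5, 1e-3)
  expect_lt(abs(fit$beta - 0.5) / 0.5, 1e-3)

  expect_error(fit_coverage(crv[1:2, ]), "at least 3")
  allzero <- data.frame(effort_bp = c(10, 100, 1000),
                        coverage_mean = 0, coverage_sd = 0.01)
  expect_error(fit_coverage(allzero), "insufficient coverage signal")
})

test_that("median Nd from 50 noisy replicate fits is within 2% of truth", {
  set.seed(202)
  nds <- replicate(50, {
    crv <- model_curve(22, 1, n_points = 20)
    crv$coverage_mean <- pmin(pmax(crv$coverage_mean + rnorm(20, 0, 0.01), 0), 1)
    nd(fit_coverage(crv))
  })
  expect_lt(abs(median(nds) - 21) / 21, 0.02)
})

test_that("Nd is the gamma mode with the alpha <= 1 convention", {
  fit <- structure(list(alpha = 2, beta = 1,
                        curve = list(points = data.frame(), meta = list())),
                   class = "coverage_fit")
  expect_equal(nd(fit), 1)
  fit$alpha <- 23
  expect_equal(nd(fit), 22)
  fit$alpha <- 1; fit$beta <- 5
  expect_warning(v <- nd(fit), "alpha <= 1")
  expect_equal(v, 0)
})

test_that("effort projection inverts the model exactly", {
  fit <- structure(list(alpha = 1, beta = 1,
                        curve = list(points = data.frame(), meta = list())),
                   class = "coverage_fit")
  expect_equal(project_effort(fit, 1 - exp(-1)), exp(1) - 1, tolerance = 1e-10)
  expect_lt(project_effort(fit, 1e-9), 1e-6)
  expect_equal(project_effort(fit, 1), Inf)
  expect_error(project_effort(fit, 0), "\\(0, 1\\]")

  set.seed(11)
  for (i in 1:100) {
    a <- runif(1, 1.2, 30); b <- runif(1, 0.3, 3); t <- runif(1, 0.05, 0.99)
    m <- structure(list(alpha = a, beta = b), class = "coverage_fit")
    expect_equal(gamma_coverage(project_effort(m, t), a, b), t,
                 tolerance = 1e-10)
  }
  # monotone increasing in the target
  m <- structure(list(alpha = 5, beta = 1), class = "coverage_fit")
  lr <- project_effort(m, c(0.5, 0.8, 0.95, 0.99))
  expect_true(all(diff(lr) > 0))
})

test_that("parameter recovery holds for 100 random models with 1% noise", {
  set.seed(303)
  relerr <- replicate(100, {
    a <- runif(1, 1.5, 30); b <- runif(1, 0.3, 3)
    crv <- model_curve(a, b, n_points = 20)
    crv$coverage_mean <- pmin(pmax(crv$coverage_mean + rnorm(20, 0, 0.01), 0), 1)
    fit <- fit_coverage(crv)
    abs(nd(fit) - (a - 1) / b) / ((a - 1) / b)
  })
  expect_lt(median(relerr), 0.05)
})

test_that("rescaling efforts rescales the projected effort consistently", {
  # a tenfold effort rescale shifts the model by ln 10 in log-effort space,
  # which re-enters the gamma family only asymptotically; at the concentrated
  # shapes the pipeline actually fits (alpha in the tens) the projection
  # scales to within 2%
  crv <- model_curve(80, 6, n_points = 18, sd = 0.005)
  set.seed(5)
  crv$coverage_mean <- pmin(pmax(crv$coverage_mean + rnorm(18, 0, 0.005), 0), 1)
  f1 <- fit_coverage(crv)
  crv10 <- crv
  crv10$effort_bp <- crv10$effort_bp * 10
  f10 <- fit_coverage(crv10)
  expect_lt(abs(project_effort(f10, 0.95) / project_effort(f1, 0.95) - 10) / 10,
            0.02)
  # Nd shifts upward under the rescale (by about ln 10)
  expect_gt(nd(f10), nd(f1))
})

test_that("headline coverage is the model value at the actual effort", {
  crv <- model_curve(1, 1, n_points = 10, sd = 0)
  fit <- fit_coverage(crv)
  expect_equal(estimated_coverage(fit, exp(1) - 1), 1 - exp(-1),
               tolerance = 1e-4)

  # saturated dataset: thousands of copies of a small read pool
  pool <- rand_reads(20, 80, seed = 88)
  rs <- read_set(paste0("r", 1:5000), rep(pool$seq, length.out = 5000),
                 rep(pool$qual, length.out = 5000))
  # every query matches, so the expected error mass overshoots the (empty)
  # zero-match tally and is clamped with a warning
  expect_warning(fit <- rarecov(rs, q_target = 500, seed = 1),
                 "clamping")
  expect_gte(estimated_coverage(fit), 0.99)

  # depth << 1: estimate stays near the tiny true coverage
  cm <- make_community(1, c(2e6, 2e6), 0, seed = 89)
  n <- 600  # expected depth ~0.03
  sim <- simulate_reads(cm, n, 101, seed = 90)
  truth <- expected_poisson_coverage(cm, n, 101)
  expect_lt(truth, 0.031)
  fit <- rarecov(sim$reads, q_target = 600, seed = 2)
  expect_lte(estimated_coverage(fit), 0.05)
})

test_that("fit object provides the standard modelling methods", {
  crv <- model_curve(5, 0.8, n_points = 15, sd = 0.01)
  meta <- list(version = "x", kernel = "kmer", k = 24, reads = 1000,
               bases = max(crv$effort_bp), mean_length = 101,
               queries_effective = 1000, error_mass = 0, seed = 1)
  fit <- fit_coverage(rarefaction_curve(crv, meta))
  expect_s3_class(fit, "coverage_fit")
  expect_named(coef(fit), c("alpha", "beta"))
  expect_equal(unname(coef(fit))[1], 5, tolerance = 0.05)
  expect_length(fitted(fit), 15)
  expect_equal(fitted(fit) + residuals(fit), crv$coverage_mean)
  expect_equal(predict(fit, crv$effort_bp[3]),
               gamma_coverage(crv$effort_bp[3], fit$alpha, fit$beta))
  s <- summary(fit)
  expect_s3_class(s, "summary.coverage_fit")
  expect_true(all(c("alpha", "beta", "nd", "coverage",
                    "projected_effort_bp") %in% names(s)))
  expect_output(print(fit), "Gamma-CDF coverage model")
  expect_output(print(s), "Nd")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
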