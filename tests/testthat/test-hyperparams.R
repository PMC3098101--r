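test_that("empirical quantile interpolates order statistics", {
  expect_equal(empirical_quantile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(empirical_quantile(c(0, 10), 0.75), 7.5)
  expect_equal(empirical_quantile(rep(4.2, 10), 0.31), 4.2)
  expect_error(empirical_quantile(c(1), 0.5), "at least 2")
  expect_error(empirical_quantile(1:5, 1.2), "in \\(0, 1\\)")
})

test_that("quantile-matching alpha is exact on exponential quantile inputs", {
  q <- seq(0.0005, 0.9995, by = 0.0005)
  lam <- -log(1 - q)  # Exp(rate 1, shift 0) quantile function
  est <- estimate_alpha_quantile(lam, 0.8, 0.9)
  expect_equal(est$alpha, 1, tolerance = 5e-3)
  expect_equal(est$lambda0, 0, tolerance = 1e-2)

  shifted <- estimate_alpha_quantile(lam + 1.2, 0.8, 0.9)
  expect_equal(shifted$alpha, est$alpha)          # shift invariance, exact
  expect_equal(shifted$lambda0, est$lambda0 + 1.2)

  scaled <- estimate_alpha_quantile(lam * 2, 0.8, 0.9)
  expect_equal(scaled$alpha, est$alpha / 2)       # scale covariance

  expect_error(estimate_alpha_quantile(rep(1, 50), 0.8, 0.9), "tied")
  expect_error(estimate_alpha_quantile(lam, 0.9, 0.8), "q1 < q2")
})

test_that("both alpha estimators recover the rate from random draws", {
  draws <- withr::with_seed(2024, stats::rexp(1e5, rate = 2.5) - 0.4)
  est <- estimate_alpha_quantile(draws, 0.8, 0.9)
  expect_equal(est$alpha, 2.5, tolerance = 0.05 / 2.5)
  expect_equal(est$lambda0, -0.4, tolerance = 0.02)
  expect_equal(estimate_alpha_moment(draws, 0.8), 2.5, tolerance = 0.05 / 2.5)
})

test_that("moment estimator follows its closed form and memorylessness", {
  # 8 values at/below the q = 0.8 threshold (1.2), exceedances {2, 3}:
  # mean excess = 2.5 - 1.2 = 1.3, so alpha = 1/1.3
  x <- c(rep(1, 8), 2, 3)
  expect_equal(estimate_alpha_moment(x, 0.8), 1 / 1.3, tolerance = 1e-12)

  q <- seq(0.0005, 0.9995, by = 0.0005)
  expect_equal(estimate_alpha_moment(-log(1 - q), 0.8), 1, tolerance = 2e-2)

  expect_error(estimate_alpha_moment(c(1, 1, 1, 2), 0.9), "exceed")
})

test_that("tau equals 1 on an IQR-1.34898 construction", {
  z <- qnorm(0.75)  # 0.674490
  d <- rep(c(-z, z), each = 10)
  x2 <- rep(10000, 20)
  x1 <- round(10^(4 + d))
  tbl <- make_table(x1, x2, n1 = 10^7, n2 = 10^7)
  expect_equal(estimate_tau(tbl, min_total = 1000), 1, tolerance = 1e-3)
})

test_that("tau estimation rejects thin data and ignores low-count genes", {
  tbl <- make_table(c(10, 20, 400), c(12, 18, 500), n1 = 1e6, n2 = 1e6)
  expect_error(estimate_tau(tbl, min_total = 1000), "0 gene")

  # adding sub-threshold genes must not move tau
  set.seed(77)
  x1 <- rpois(200, 2000)
  x2 <- rpois(200, 2000)
  big <- make_table(x1, x2, n1 = 1e7, n2 = 1e7)
  tau_big <- estimate_tau(big)
  aug <- make_table(c(x1, rpois(300, 5)), c(x2, rpois(300, 5)),
                    n1 = 1e7, n2 = 1e7)
  expect_equal(estimate_tau(aug), tau_big)
})

test_that("tau is robust to extreme differential expression", {
  set.seed(88)
  n <- 5000
  lam <- runif(n, -4, -2.5)
  sim <- simulate_fig1b(lam, sigma = 0.15, n1 = 1e7, n2 = 1e7, seed = 5)
  tau0 <- estimate_tau(sim$counts)
  # corrupt 1% of qualifying genes with a huge fold change
  tbl <- sim$counts
  qual <- which(tbl$x1 + tbl$x2 > 1000)
  hit <- sample(qual, length(qual) %/% 100)
  tbl$x1[hit] <- pmin(round(tbl$x1[hit] * 1e10), 1e7)
  tbl2 <- make_table(tbl$x1, tbl$x2, n1 = 1e7, n2 = 1e7)
  expect_lt(abs(estimate_tau(tbl2) - tau0) / tau0, 0.05)
})

test_that("estimate_hyperparams bundles alpha and tau with provenance", {
  sim <- simulate_generative(sim_config(n_genes = 5000, seed = 3))
  hyp <- estimate_hyperparams(sim$counts, min_total = 200)
  expect_s3_class(hyp, "asc_hyper")
  expect_gt(hyp$alpha, 0)
  expect_gt(hyp$tau, 0)
  td <- tidy(hyp)
  expect_equal(td$term, c("alpha", "tau", "lambda0"))
  expect_error(new_hyperparams(alpha = -1, tau = 0.1), "positive")
  expect_error(new_hyperparams(alpha = 1, tau = 0), "positive")
})

test_that("hyperparameter recovery from the generative model", {
  sim <- simulate_generative(
    sim_config(n_genes = 30000, alpha = 2.0, lambda_min = -6.0,
               sigma = 0.122, de_fraction = 0, seed = 19)
  )
  hyp <- estimate_hyperparams(sim$counts)
  # alpha: quantile matching on average log rpm of noisy counts
  expect_equal(hyp$alpha, 2.0, tolerance = 0.15)
  expect_equal(
    estimate_alpha_moment(
      average_log_rpm(sim$counts$x1, sim$counts$x2,
                      library_sizes(sim$counts)[["n1"]],
                      library_sizes(sim$counts)[["n2"]])
    ),
    2.0, tolerance = 0.15
  )
  # tau within 10% (thousands of qualifying genes at this lambda_min)
  expect_gt(sum(sim$counts$x1 + sim$counts$x2 > 1000), 400)
  expect_equal(hyp$tau, 0.122, tolerance = 0.10)
})

test_that("log-base conversion is exact", {
  expect_equal(convert_log_base(1), log(10))
  expect_equal(convert_log_base(log(10), from = exp(1), to = 10), 1)
})
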