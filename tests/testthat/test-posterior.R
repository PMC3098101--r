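hyp_default <- new_hyperparams(alpha = 2, tau = 0.122)

test_that("log unnormalized posterior respects model symmetry and support", {
  # swapping counts and negating delta leaves the density unchanged (N1 = N2)
  g <- expand.grid(d = c(-0.4, -0.1, 0.2, 0.5), l = c(-5, -4, -3))
  a <- log_unnormalized_posterior(20, 5, 1e6, 1e6, g$d, g$l, hyp_default)
  b <- log_unnormalized_posterior(5, 20, 1e6, 1e6, -g$d, g$l, hyp_default)
  expect_equal(a, b)

  # proportions above 1 are impossible
  expect_identical(
    log_unnormalized_posterior(3, 3, 1e6, 1e6, 1.0, 0, hyp_default),
    -Inf
  )
  # zero counts still give a finite density at finite (delta, lambda)
  expect_true(is.finite(
    log_unnormalized_posterior(0, 0, 1e6, 1e6, 0.1, -5, hyp_default)
  ))
  # poisson switch agrees closely with binomial at small proportions
  expect_equal(
    log_unnormalized_posterior(20, 5, 1e6, 1e6, 0.3, -4.8, hyp_default),
    log_unnormalized_posterior(20, 5, 1e6, 1e6, 0.3, -4.8, hyp_default,
                               likelihood = "poisson"),
    tolerance = 1e-4
  )
})

test_that("posterior marginal is proper, symmetric cases land on zero", {
  p <- compute_posterior(100, 100, 1e6, 1e6, hyp_default)
  expect_lt(abs(sum(p$mass) - 1), 1e-6)
  expect_lt(abs(p$delta_hat), 1e-6)

  a <- compute_posterior(20, 5, 1e6, 1e6, hyp_default)
  b <- compute_posterior(5, 20, 1e6, 1e6, hyp_default)
  expect_equal(a$delta_hat, -b$delta_hat, tolerance = 1e-12)

  expect_error(compute_posterior(0, 0, 1e6, 1e6, hyp_default), "no fold-change")
})

test_that("posterior mean matches the brute-force fine-grid oracle", {
  # the frozen reference case, integrated on the oracle's wide fixed grid
  orc <- oracle_posterior(20, 5, 1e6, 1e6, alpha = 2, tau = 0.122,
                          lam_lo = -9, lam_hi = 0, d_lo = -3, d_hi = 3)
  p <- compute_posterior(20, 5, 1e6, 1e6, hyp_default)
  expect_lt(abs(p$delta_hat - orc$delta_hat), 1e-4)
  expect_gt(p$delta_hat, 0)
  expect_lt(p$delta_hat, log10(20 / 5))
  expect_lt(
    abs(prob_exceeds(p, log10(2)) - oracle_prob_exceeds(orc, log10(2))),
    1e-4
  )
})

test_that("posterior mean is stable under grid refinement", {
  fine <- grid_config(delta_points_per_sd = 20, lambda_points_per_sd = 8)
  for (cc in list(c(20, 5), c(3, 1), c(500, 100), c(7, 0))) {
    p1 <- compute_posterior(cc[1], cc[2], 1e6, 1e6, hyp_default)
    p2 <- compute_posterior(cc[1], cc[2], 1e6, 1e6, hyp_default, grid = fine)
    expect_lt(abs(p1$delta_hat - p2$delta_hat), 1e-3)
  }
})

test_that("exceedance probability behaves as a tail functional", {
  p <- compute_posterior(20, 5, 1e6, 1e6, hyp_default)
  expect_equal(prob_exceeds(p, 0), 1, tolerance = 1e-6)
  expect_equal(prob_exceeds(p, 99), 0)
  expect_error(prob_exceeds(p, -0.1), "non-negative")

  probs <- vapply(seq(0, 1.2, by = 0.01), function(t) prob_exceeds(p, t),
                  numeric(1))
  expect_true(all(diff(probs) <= 1e-12))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("grid expands once when squeezed and errors when hopeless", {
  squeezed <- compute_posterior(
    20, 5, 1e6, 1e6, hyp_default,
    grid = grid_config(delta_halfwidth = 0.25)
  )
  expect_true(squeezed$expanded)
  free <- compute_posterior(20, 5, 1e6, 1e6, hyp_default)
  expect_equal(squeezed$delta_hat, free$delta_hat, tolerance = 1e-3)

  expect_error(
    compute_posterior(20, 5, 1e6, 1e6, hyp_default,
                      grid = grid_config(delta_halfwidth = 0.05)),
    "boundary"
  )
})

test_that("shrinkage bounds and monotonicity hold on small counts", {
  # |delta_hat| never exceeds the apparent log fold change (equal depths)
  for (cc in list(c(2, 1), c(9, 3), c(40, 11), c(120, 20))) {
    p <- compute_posterior(cc[1], cc[2], 1e6, 1e6, hyp_default)
    expect_gte(p$delta_hat, 0)
    expect_lte(p$delta_hat, log10(cc[1] / cc[2]))
  }
  # strictly increasing in x1 at fixed x2
  dh <- vapply(
    c(5, 10, 20, 40, 80),
    function(x1) compute_posterior(x1, 10, 1e6, 1e6, hyp_default)$delta_hat,
    numeric(1)
  )
  expect_true(all(diff(dh) > 0))
})

test_that("run_asc is deterministic, order-preserving, flags no-signal genes", {
  tbl <- make_table(c(10, 10, 0, 25), c(3, 3, 0, 30), n1 = 1e6, n2 = 1e6)
  fit <- run_asc(tbl, hyp_default)
  r <- tidy(fit)
  expect_equal(r$gene_id, tbl$gene_id)
  expect_equal(r$delta_hat[1], r$delta_hat[2])   # identical rows, identical results
  expect_equal(r$post_prob[1], r$post_prob[2])
  expect_equal(r$flag[3], "no-signal")
  expect_equal(r$delta_hat[3], 0)
  expect_equal(r$post_prob[3], 0)
  expect_true(all(r$post_prob >= 0 & r$post_prob <= 1))

  zero <- run_asc(make_table(c(0, 0), c(0, 0), n1 = 10, n2 = 10), hyp_default)
  expect_true(all(tidy(zero)$flag == "no-signal"))

  g <- glance(fit)
  expect_equal(g$n_genes, 4)
  expect_equal(g$n_no_signal, 1)
})

test_that("direct-posterior FDR averages the selected non-exceedance", {
  r <- tibble::tibble(gene_id = letters[1:4],
                      post_prob = c(0.95, 0.91, 0.5, 0.2))
  out <- bayesian_fdr(r, 0.9)
  expect_equal(out$fdr, 0.07)
  expect_equal(out$n_selected, 2)

  all_one <- bayesian_fdr(tibble::tibble(post_prob = rep(1, 5)), 0.9)
  expect_equal(all_one$fdr, 0)

  none <- bayesian_fdr(r, 0.99)
  expect_equal(none$n_selected, 0)
  expect_true(is.na(none$fdr))

  # FDR non-increasing in the cutoff
  set.seed(9)
  probs <- tibble::tibble(post_prob = runif(500)^0.3)
  fdrs <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95),
                 function(ct) bayesian_fdr(probs, ct)$fdr, numeric(1))
  expect_true(all(diff(fdrs) <= 1e-12))
})
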