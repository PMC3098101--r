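#' Empirical quantile with linear interpolation
#'
#' Continuous sample quantile (order statistics, linear interpolation
#' between them; `stats::quantile()` type 7). Wrapped so the quantile
#' definition used by the hyperparameter estimators lives in one place.
#'
#' @param values Numeric vector (at least 2 finite values).
#' @param q Quantile level(s) in (0, 1).
#' @return The empirical quantile(s) F^-1(q).
#' @export
empirical_quantile <- function(values, q) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("need at least 2 finite values to form an empirical quantile")
  }
  if (any(q <= 0 | q >= 1)) abort("`q` must lie strictly in (0, 1)")
  unname(quantile(values, probs = q, type = 7, names = FALSE))
}

#' Estimate the expression-prior decay rate by quantile matching
#'
#' The average log10 rpm across a transcriptome is strongly right-skewed
#' and is modelled as a shifted exponential with rate `alpha` and shift
#' `lambda0`. Matching the closed-form CDF `F(l) = 1 - exp(-alpha (l -
#' lambda0))` at two empirical quantiles `l_i = F^-1(q_i)` gives
#' \deqn{\hat\alpha = -[\log(1-q_1) - \log(1-q_2)] / (l_1 - l_2)}
#' \deqn{\hat\lambda_0 = l_1 + \log(1-q_1)/\hat\alpha}
#' Because the exponential is memoryless, only `alpha` matters downstream:
#' the shift cancels out of the posterior.
#'
#' @param avg_log_rpm Per-gene average log10 rpm values (see
#'   [average_log_rpm()]).
#' @param q1,q2 Quantile levels, `0 < q1 < q2 < 1`. Defaults 0.8 and 0.9.
#' @return List with `alpha` (rate per log10 unit) and `lambda0` (shift, on
#'   the same scale as the input).
#' @examples
#' lam <- -log(1 - seq(0.001, 0.999, by = 0.001))  # Exp(1) quantiles
#' estimate_alpha_quantile(lam)$alpha  # ~1
#' @export
estimate_alpha_quantile <- function(avg_log_rpm, q1 = 0.8, q2 = 0.9) {
  if (!(q1 > 0 && q1 < q2 && q2 < 1)) {
    abort("need 0 < q1 < q2 < 1")
  }
  l <- empirical_quantile(avg_log_rpm, c(q1, q2))
  if (l[1] >= l[2]) {
    abort(paste0(
      "empirical quantiles at q1 and q2 are tied (", signif(l[1], 6),
      "); choose quantile levels that separate the data"
    ))
  }
  alpha <- -(log(1 - q1) - log(1 - q2)) / (l[1] - l[2])
  lambda0 <- l[1] + log(1 - q1) / alpha
  list(alpha = alpha, lambda0 = lambda0)
}

#' Estimate the expression-prior decay rate by the method of moments
#'
#' Uses the memorylessness of the exponential: the mean exceedance above
#' any threshold equals `1/alpha`, so with `t = F^-1(q)`,
#' `alpha-hat = 1 / (mean(values above t) - t)`.
#'
#' @inheritParams estimate_alpha_quantile
#' @param q Threshold quantile level in (0, 1). Default 0.8.
#' @return `alpha` (rate per log10 unit).
#' @export
estimate_alpha_moment <- function(avg_log_rpm, q = 0.8) {
  t0 <- empirical_quantile(avg_log_rpm, q)
  above <- avg_log_rpm[is.finite(avg_log_rpm) & avg_log_rpm > t0]
  if (length(above) < 2) {
    abort(paste0(
      "only ", length(above), " value(s) exceed the q = ", q,
      " threshold; cannot estimate alpha by moments"
    ))
  }
  excess <- mean(above) - t0
  if (excess <= 0) abort("mean exceedance is not positive; check the data")
  1 / excess
}

# IQR of the standard Gaussian, 2 * qnorm(0.75)
gaussian_iqr <- 2 * qnorm(0.75)

#' Estimate the biological-variation scale from high-count genes
#'
#' `tau` is the prior SD (log10 scale) of the gene-wise log fold change
#' among biological replicates. For genes with high total counts the
#' binomial sampling noise in `log10(p1) - log10(p2)` is negligible, so the
#' spread of those differences is biological. The interquartile range is
#' used instead of the SD to resist genes with genuinely extreme
#' differential expression:
#' `tau-hat = IQR[log10(p1) - log10(p2)] / 1.34898`
#' over genes with `x1 + x2 > min_total`.
#'
#' @param table An `asc_counts` count table.
#' @param min_total Total-count threshold; genes with `x1 + x2 > min_total`
#'   qualify. Default 1000.
#' @param min_genes Minimum number of qualifying genes required. Default 20.
#' @return `tau` (> 0), in log10 units.
#' @export
estimate_tau <- function(table, min_total = 1000, min_genes = 20) {
  ls <- library_sizes(table)
  keep <- (table$x1 + table$x2) > min_total
  n_keep <- sum(keep)
  if (n_keep < min_genes) {
    abort(paste0(
      "only ", n_keep, " gene(s) have total counts above ", min_total,
      " (need at least ", min_genes, "); lower `min_total`"
    ))
  }
  # 0.5 floor only matters for the (rare) qualifying gene with a zero count
  d <- log10(pmax(table$x1[keep], 0.5) / ls[["n1"]]) -
    log10(pmax(table$x2[keep], 0.5) / ls[["n2"]])
  iqr <- diff(empirical_quantile(d, c(0.25, 0.75)))
  if (iqr <= 0) {
    abort("interquartile range of high-count log ratios is zero")
  }
  iqr / gaussian_iqr
}

#' Estimate all model hyperparameters from a count table
#'
#' Convenience wrapper: `alpha` (and the unused shift `lambda0`) by
#' quantile matching on the average log10 rpm, and `tau` from the
#' high-count interquartile range.
#'
#' @inheritParams estimate_tau
#' @inheritParams estimate_alpha_quantile
#' @param exclude_zero Drop genes with a zero count in either sample before
#'   estimating `alpha` (their average log rpm carries the 0.5 floor).
#'   Default `FALSE`.
#' @return An `asc_hyper` list: `alpha`, `lambda0`, `tau`, plus the
#'   settings used (`q1`, `q2`, `min_total`, `n_tau_genes`).
#' @examples
#' sim <- simulate_generative(sim_config(n_genes = 2000, seed = 1))
#' estimate_hyperparams(sim$counts)
#' @export
estimate_hyperparams <- function(table, q1 = 0.8, q2 = 0.9,
                                 min_total = 1000, min_genes = 20,
                                 exclude_zero = FALSE) {
  ls <- library_sizes(table)
  x1 <- table$x1
  x2 <- table$x2
  if (exclude_zero) {
    keep <- x1 > 0 & x2 > 0
    x1 <- x1[keep]
    x2 <- x2[keep]
  }
  v <- average_log_rpm(x1, x2, ls[["n1"]], ls[["n2"]])
  a <- estimate_alpha_quantile(v, q1, q2)
  tau <- estimate_tau(table, min_total = min_total, min_genes = min_genes)
  new_hyperparams(
    alpha = a$alpha, tau = tau, lambda0 = a$lambda0,
    q1 = q1, q2 = q2, min_total = min_total,
    n_tau_genes = sum(table$x1 + table$x2 > min_total)
  )
}

#' Construct a hyperparameter object
#'
#' @param alpha Exponential decay rate of the expression-level prior, per
#'   log10 unit (> 0).
#' @param tau SD of the log fold change prior, log10 units (> 0).
#' @param lambda0 Optional shift of the exponential prior; irrelevant to
#'   the posterior (memorylessness) and kept for reporting only.
#' @param q1,q2,min_total,n_tau_genes Settings recorded for provenance.
#' @return An `asc_hyper` list.
#' @export
new_hyperparams <- function(alpha, tau, lambda0 = NA_real_,
                            q1 = 0.8, q2 = 0.9, min_total = 1000,
                            n_tau_genes = NA_integer_) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0) {
    abort("`alpha` must be a single positive number")
  }
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    abort("`tau` must be a single positive number")
  }
  if (!(q1 > 0 && q1 < q2 && q2 < 1)) abort("need 0 < q1 < q2 < 1")
  if (min_total < 1) abort("`min_total` must be >= 1")
  structure(
    list(
      alpha = alpha, tau = tau, lambda0 = lambda0,
      q1 = q1, q2 = q2, min_total = min_total, n_tau_genes = n_tau_genes
    ),
    class = "asc_hyper"
  )
}

#' @export
print.asc_hyper <- function(x, ...) {
  cat("Hyperparameters (log10 scale)\n")
  cat(sprintf("  alpha   = %.6g  (expression prior decay rate)\n", x$alpha))
  cat(sprintf("  tau     = %.6g  (biological-variation SD)\n", x$tau))
  cat(sprintf("  lambda0 = %.6g  (shift; not used by the posterior)\n",
              x$lambda0))
  cat(sprintf("  settings: q1 = %g, q2 = %g, min_total = %g\n",
              x$q1, x$q2, x$min_total))
  invisible(x)
}

#' @export
tidy.asc_hyper <- function(x, ...) {
  tibble(
    term = c("alpha", "tau", "lambda0"),
    estimate = c(x$alpha, x$tau, x$lambda0)
  )
}

#' Convert a log-scale quantity between logarithm bases
#'
#' Spreads and slopes reported on the log10 scale (the package's working
#' scale) can be compared with natural-log analyses via an exact factor:
#' e.g. a log10-scale SD of 0.122 corresponds to `0.122 * ln 10 = 0.281`
#' on the natural-log scale.
#'
#' @param x Numeric value(s) on the `from` log scale.
#' @param from,to Logarithm bases. Defaults convert log10 to natural log.
#' @return `x * log(from) / log(to)`.
#' @export
convert_log_base <- function(x, from = 10, to = exp(1)) {
  x * log(from) / log(to)
}
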