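#' Integration grid configuration for the posterior
#'
#' The posterior over (lambda, delta) has no closed form and is integrated
#' by a 2-D rectangle rule on a per-gene grid in log10 space. Because the
#' posterior width varies by orders of magnitude with the counts (roughly
#' as `1/sqrt(x1 + x2)` in lambda), the grid is sized per gene: spacings
#' are a fixed number of points per posterior standard deviation and the
#' delta range is centered on an approximate posterior mode, wide enough
#' to also cover the apparent log fold change plus six binomial standard
#' errors. A fixed global spacing would either alias the narrow
#' high-count posteriors or waste enormous grids on low-count genes.
#'
#' @param delta_points_per_sd Grid points per posterior SD of delta.
#'   Default 10.
#' @param delta_halfwidth_sds Halfwidth of the delta grid in posterior
#'   SDs (the range also always covers `|apparent lfc| + 6 SE`). Default 12.
#' @param lambda_points_per_sd Grid points per likelihood SD of lambda
#'   (`1/(ln 10 sqrt(x1 + x2))`). Default 4.
#' @param lambda_halfwidth Cap on the lambda halfwidth around the
#'   per-gene anchor, log10 units. Default 3.
#' @param delta_step,lambda_step Optional hard upper bounds on the
#'   spacings (log10 units); `NULL` (default) leaves them fully adaptive.
#' @param delta_halfwidth Optional fixed delta halfwidth override.
#' @param lambda_floor Hard lower bound on lambda; `NULL` (default) means
#'   `log10(0.25 / (N1 + N2))` ("a quarter of a read" proportion). Needed
#'   because for very small totals the prior-times-likelihood product need
#'   not be integrable as lambda falls to -Inf.
#' @param boundary_tol Maximum posterior mass tolerated in the two
#'   outermost cells of either marginal before a one-time grid expansion.
#'   Default 1e-4.
#' @return An `asc_grid` list of settings.
#' @export
grid_config <- function(delta_points_per_sd = 10, delta_halfwidth_sds = 12,
                        lambda_points_per_sd = 4, lambda_halfwidth = 3.0,
                        delta_step = NULL, lambda_step = NULL,
                        delta_halfwidth = NULL, lambda_floor = NULL,
                        boundary_tol = 1e-4) {
  stopifnot(
    delta_points_per_sd >= 2, delta_halfwidth_sds >= 4,
    lambda_points_per_sd >= 2, lambda_halfwidth > 0,
    is.null(delta_step) || delta_step > 0,
    is.null(lambda_step) || lambda_step > 0,
    is.null(delta_halfwidth) || delta_halfwidth > 0,
    is.null(lambda_floor) || lambda_floor < 0,
    boundary_tol > 0
  )
  structure(
    list(
      delta_points_per_sd = delta_points_per_sd,
      delta_halfwidth_sds = delta_halfwidth_sds,
      lambda_points_per_sd = lambda_points_per_sd,
      lambda_halfwidth = lambda_halfwidth,
      delta_step = delta_step, lambda_step = lambda_step,
      delta_halfwidth = delta_halfwidth, lambda_floor = lambda_floor,
      boundary_tol = boundary_tol
    ),
    class = "asc_grid"
  )
}

#' Log unnormalized joint posterior density at (delta, lambda)
#'
#' The hierarchical model: counts are binomial given the per-sample
#' proportions, `log10(pi1) = lambda + delta/2`, `log10(pi2) = lambda -
#' delta/2`; priors `delta ~ N(0, tau^2)` and `lambda ~ Exp(alpha)`
#' (shifted exponential; by memorylessness the shift drops out and only
#' the decay `exp(-alpha * lambda)` enters). Returns
#' `log Binom(x1; N1, pi1) + log Binom(x2; N2, pi2) + log phi(delta; 0,
#' tau) - alpha * lambda`, computed stably via the exact binomial log-pmf
#' (no Gaussian approximation). `-Inf` wherever a proportion would exceed
#' 1, i.e. `lambda + |delta|/2 > 0`.
#'
#' @param x1,x2 Counts. @param n1,n2 Library sizes.
#' @param delta log10 fold change (vectorized with `lambda`).
#' @param lambda log10 average proportion.
#' @param hyper An `asc_hyper` object (see [new_hyperparams()]).
#' @param likelihood `"binomial"` (exact, default) or `"poisson"` (the
#'   usual small-proportion approximation, slightly faster).
#' @return Log density values (same length as `delta`/`lambda`).
#' @export
log_unnormalized_posterior <- function(x1, x2, n1, n2, delta, lambda, hyper,
                                       likelihood = c("binomial", "poisson")) {
  likelihood <- match.arg(likelihood)
  stopifnot(n1 > 0, n2 > 0)
  k <- max(length(delta), length(lambda))
  delta <- rep_len(delta, k)
  lambda <- rep_len(lambda, k)
  l1 <- lambda + delta / 2
  l2 <- lambda - delta / 2
  out <- rep(-Inf, k)
  ok <- l1 <= 0 & l2 <= 0
  if (any(ok)) {
    if (likelihood == "binomial") {
      ll <- dbinom(x1, n1, 10^l1[ok], log = TRUE) +
        dbinom(x2, n2, 10^l2[ok], log = TRUE)
    } else {
      ll <- dpois(x1, n1 * 10^l1[ok], log = TRUE) +
        dpois(x2, n2 * 10^l2[ok], log = TRUE)
    }
    out[ok] <- ll + dnorm(delta[ok], 0, hyper$tau, log = TRUE) -
      hyper$alpha * lambda[ok]
  }
  out
}

# Per-gene grid geometry. The delta and lambda spacings share a common
# half-delta unit `s` (lambda step = k * s) so that every lambda + delta/2
# (and lambda - delta/2) value lands on one shared axis and the binomial
# log-pmf is evaluated once per axis point instead of once per grid cell.
posterior_grid_geometry <- function(x1, x2, n1, n2, hyper, grid,
                                    hw_d_override = NULL,
                                    hw_l_override = NULL) {
  total <- x1 + x2
  tau <- hyper$tau
  floor_l <- grid$lambda_floor %||% log10(0.25 / (n1 + n2))
  # per-gene ML anchor for lambda: mean of the per-sample log proportions
  # (0.5-floored); the pooled proportion would miss the profile centre for
  # strongly imbalanced genes
  anchor <- max(
    (log10(pmax(x1, 0.5) / n1) + log10(pmax(x2, 0.5) / n2)) / 2,
    floor_l
  )
  sig_lam <- 1 / (log(10) * sqrt(total))
  alr <- apparent_log_ratio(x1, x2, n1, n2)
  se_d <- sqrt(1 / max(x1, 0.5) + 1 / max(x2, 0.5)) / log(10)

  # Gaussian-approximation center and SD of the delta posterior; the grid
  # is centered there and must also cover the apparent lfc generously.
  centre <- alr * tau^2 / (tau^2 + se_d^2)
  sd_post <- sqrt(tau^2 * se_d^2 / (tau^2 + se_d^2))

  hw_d <- hw_d_override %||% grid$delta_halfwidth %||%
    max(grid$delta_halfwidth_sds * sd_post, abs(alr) + 6 * se_d - abs(centre))
  s_d <- sd_post / grid$delta_points_per_sd
  if (!is.null(grid$delta_step)) s_d <- min(s_d, grid$delta_step)
  s_d <- max(s_d, hw_d / 5000)  # guard against degenerate huge grids
  s <- s_d / 2
  m_d <- ceiling(hw_d / s_d)

  s_l_target <- sig_lam / grid$lambda_points_per_sd
  if (!is.null(grid$lambda_step)) s_l_target <- min(s_l_target, grid$lambda_step)
  k <- max(1L, as.integer(round(s_l_target / s)))
  s_l <- k * s
  hw_l <- hw_l_override %||%
    min(grid$lambda_halfwidth, hw_d / 2 + 10 * sig_lam)
  m_l <- ceiling(hw_l / s_l)

  list(
    anchor = anchor, floor_l = floor_l, centre = centre,
    s = s, k = k, m_d = m_d, m_l = m_l,
    delta = centre + (-m_d:m_d) * 2 * s,
    lambda = anchor + (-m_l:m_l) * k * s,
    delta_step = 2 * s, hw_d = m_d * 2 * s, hw_l = m_l * k * s
  )
}

# One grid pass: returns the normalized delta marginal plus boundary masses.
posterior_grid_pass <- function(x1, x2, n1, n2, hyper, geom, likelihood) {
  s <- geom$s
  L <- geom$k * (-geom$m_l:geom$m_l)
  D <- -geom$m_d:geom$m_d
  R <- geom$k * geom$m_l + geom$m_d
  ax <- s * (-R:R)
  u <- geom$anchor + geom$centre / 2 + ax   # lambda + delta/2 axis
  v <- geom$anchor - geom$centre / 2 + ax   # lambda - delta/2 axis

  log_pmf_axis <- function(x, n, axis) {
    lp <- rep(-Inf, length(axis))
    ok <- axis <= 0
    if (likelihood == "binomial") {
      lp[ok] <- dbinom(x, n, 10^axis[ok], log = TRUE)
    } else {
      lp[ok] <- dpois(x, n * 10^axis[ok], log = TRUE)
    }
    lp
  }
  lp1 <- log_pmf_axis(x1, n1, u)
  lp2 <- log_pmf_axis(x2, n2, v)

  idx_u <- outer(L, D, "+") + (R + 1L)
  idx_v <- outer(L, D, "-") + (R + 1L)
  M <- lp1[idx_u] + lp2[idx_v]
  dim(M) <- dim(idx_u)

  prior_l <- -hyper$alpha * geom$lambda
  prior_l[geom$lambda < geom$floor_l] <- -Inf
  prior_d <- dnorm(geom$delta, 0, hyper$tau, log = TRUE)
  M <- M + prior_l + rep(prior_d, each = length(L))

  mx <- max(M)
  if (!is.finite(mx)) {
    abort(paste0(
      "posterior has no support on the grid for counts (", x1, ", ", x2,
      "); check hyperparameters and grid configuration"
    ))
  }
  W <- exp(M - mx)
  Z <- sum(W)
  mass_d <- colSums(W) / Z
  mass_l <- rowSums(W) / Z
  nd <- length(mass_d)
  nl <- length(mass_l)
  list(
    mass = mass_d,
    edge_d = sum(mass_d[c(1L, 2L, nd - 1L, nd)]),
    edge_l = sum(mass_l[c(1L, 2L, nl - 1L, nl)])
  )
}

#' Posterior of the log fold change for one gene
#'
#' Integrates the joint density of (lambda, delta) numerically and returns
#' the normalized delta marginal together with its mean, the shrinkage
#' estimate of log10 fold change. If more than `boundary_tol` of the mass
#' lands in the outermost two cells of either marginal, the affected
#' halfwidth is doubled once and the integration repeated; a second hit is
#' an error.
#'
#' @inheritParams log_unnormalized_posterior
#' @param grid An `asc_grid` configuration, see [grid_config()].
#' @return An `asc_posterior` list: `delta` (grid midpoints), `mass`
#'   (probability mass per cell, sums to 1), `delta_hat` (posterior mean),
#'   `step`, `expanded` (logical), plus the inputs.
#' @examples
#' hyp <- new_hyperparams(alpha = 2, tau = 0.122)
#' post <- compute_posterior(20, 5, 1e6, 1e6, hyp)
#' post$delta_hat                 # shrunk below log10(20/5)
#' prob_exceeds(post, log10(2))
#' @export
compute_posterior <- function(x1, x2, n1, n2, hyper, grid = grid_config(),
                              likelihood = c("binomial", "poisson")) {
  likelihood <- match.arg(likelihood)
  stopifnot(inherits(hyper, "asc_hyper"))
  if (x1 + x2 < 1) {
    abort("x1 + x2 must be >= 1: a zero-zero gene carries no fold-change signal")
  }
  geom <- posterior_grid_geometry(x1, x2, n1, n2, hyper, grid)
  pass <- posterior_grid_pass(x1, x2, n1, n2, hyper, geom, likelihood)
  expanded <- FALSE
  if (pass$edge_d > grid$boundary_tol || pass$edge_l > grid$boundary_tol) {
    expanded <- TRUE
    geom <- posterior_grid_geometry(
      x1, x2, n1, n2, hyper, grid,
      hw_d_override = if (pass$edge_d > grid$boundary_tol) 2 * geom$hw_d,
      hw_l_override = if (pass$edge_l > grid$boundary_tol) 2 * geom$hw_l
    )
    pass <- posterior_grid_pass(x1, x2, n1, n2, hyper, geom, likelihood)
    if (pass$edge_d > grid$boundary_tol || pass$edge_l > grid$boundary_tol) {
      abort(paste0(
        "posterior mass still reaches the grid boundary after expansion ",
        "for counts (", x1, ", ", x2, "); widen the grid configuration"
      ))
    }
  }
  structure(
    list(
      delta = geom$delta, mass = pass$mass,
      delta_hat = sum(geom$delta * pass$mass),
      step = geom$delta_step, expanded = expanded,
      x1 = x1, x2 = x2, n1 = n1, n2 = n2
    ),
    class = "asc_posterior"
  )
}

#' @export
print.asc_posterior <- function(x, ...) {
  cat(sprintf(
    "Posterior of log10 fold change for counts (%g, %g), N = (%g, %g)\n",
    x$x1, x$x2, x$n1, x$n2
  ))
  cat(sprintf("  delta_hat = %.6g  (grid: %d cells, step %.4g%s)\n",
              x$delta_hat, length(x$delta), x$step,
              if (x$expanded) ", expanded once" else ""))
  invisible(x)
}

#' @export
tidy.asc_posterior <- function(x, ...) {
  tibble(delta = x$delta, mass = x$mass, density = x$mass / x$step)
}

#' Posterior probability that |delta| exceeds a threshold
#'
#' `P(|delta| > delta0 | x)` from a computed posterior. The density is
#' treated as piecewise linear within the grid cell that straddles each
#' cut point (slope from the neighbouring cell masses, clamped so the
#' within-cell density stays non-negative), so the result is continuous
#' and non-increasing in `delta0`, equals 1 at `delta0 = 0`, and is 0
#' beyond the grid.
#'
#' @param posterior An `asc_posterior` from [compute_posterior()].
#' @param delta0 Threshold (log10 fold change), `>= 0`. `log10(2)` asks for
#'   more than a two-fold change.
#' @return Probability in `[0, 1]`.
#' @export
prob_exceeds <- function(posterior, delta0) {
  stopifnot(inherits(posterior, "asc_posterior"))
  if (!is.numeric(delta0) || length(delta0) != 1 || is.na(delta0) ||
      delta0 < 0) {
    abort("`delta0` must be a single non-negative number")
  }
  if (delta0 == 0) return(1)  # continuous density: |delta| > 0 a.s.
  d <- posterior$delta
  m <- posterior$mass
  h <- posterior$step
  p <- tail_mass_above(d, m, h, delta0) +
    tail_mass_above(-rev(d), rev(m), h, delta0)
  min(max(p, 0), 1)
}

# P(X > t) for a gridded mass function whose cells are midpoint samples of
# a smooth density: full mass of the cells beyond t, a linear-density
# partial contribution from the straddling cell, and the midpoint-rule
# boundary correction -(h^2/24) f'(edge) (Euler-Maclaurin), which would
# otherwise dominate the error.
tail_mass_above <- function(d, m, h, t) {
  n <- length(d)
  hi <- d + h / 2
  if (t >= hi[n]) return(0)
  lo1 <- d[1] - h / 2
  if (t < lo1) return(sum(m))
  i <- which(t < hi)[1]
  full <- if (i < n) sum(m[(i + 1):n]) else 0
  # within-cell linear density, slope from neighbours, kept non-negative
  g <- (m[min(i + 1, n)] - m[max(i - 1, 1)]) / (2 * h^2)
  g <- sign(g) * min(abs(g), 2 * m[i] / h^2)
  part <- m[i] / h * (hi[i] - t) + g * ((hi[i] - d[i])^2 - (t - d[i])^2) / 2
  part <- min(max(part, 0), m[i])
  g_edge <- if (i < n) (m[i + 1] - m[i]) / h^2 else 0
  full + part - h^2 / 24 * g_edge
}
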