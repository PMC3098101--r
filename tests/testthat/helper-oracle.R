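# Independent brute-force oracle for the (lambda, delta) posterior:
# a plain fine-grid rectangle rule built directly from the model densities,
# sharing no code with the package's integration path. Written before the
# implementation it checks; deliberately naive and slow.

oracle_posterior <- function(x1, x2, n1, n2, alpha, tau,
                             lam_lo = NULL, lam_hi = NULL, lam_step = 1e-3,
                             d_lo = NULL, d_hi = NULL, d_step = 1e-3) {
  floor_l <- log10(0.25 / (n1 + n2))
  anchor <- (log10(max(x1, 0.5) / n1) + log10(max(x2, 0.5) / n2)) / 2
  alr <- log10(max(x1, 0.5) / n1) - log10(max(x2, 0.5) / n2)
  lam_lo <- if (is.null(lam_lo)) max(anchor - 2.5, floor_l) else lam_lo
  lam_hi <- if (is.null(lam_hi)) min(0, anchor + 2.5) else lam_hi
  if (is.null(d_hi)) d_hi <- max(1.5, abs(alr) + 1)
  if (is.null(d_lo)) d_lo <- -d_hi
  lam <- seq(lam_lo, lam_hi, by = lam_step)
  lam <- lam[lam >= floor_l]  # hard prior support bound
  dd <- seq(d_lo, d_hi, by = d_step)
  lse <- numeric(length(dd))
  for (s in seq(1, length(dd), by = 300)) {
    ii <- s:min(s + 299, length(dd))
    A1 <- outer(lam, dd[ii] / 2, "+")
    A2 <- outer(lam, dd[ii] / 2, "-")
    M <- matrix(-Inf, nrow(A1), ncol(A1))
    ok <- A1 <= 0 & A2 <= 0
    M[ok] <- dbinom(x1, n1, 10^A1[ok], log = TRUE) +
      dbinom(x2, n2, 10^A2[ok], log = TRUE)
    M <- M - alpha * lam +
      rep(dnorm(dd[ii], 0, tau, log = TRUE), each = length(lam))
    mx <- apply(M, 2, max)
    lse[ii] <- ifelse(
      is.finite(mx),
      mx + log(colSums(exp(sweep(M, 2, mx)))),
      -Inf
    )
  }
  w <- exp(lse - max(lse))
  mass <- w / sum(w)
  list(delta = dd, mass = mass, step = d_step, delta_hat = sum(dd * mass))
}

# Exceedance probability from the oracle grid (uniform mass within cells;
# at the oracle's fine step the cell treatment is immaterial).
oracle_prob_exceeds <- function(orc, delta0) {
  lo <- orc$delta - orc$step / 2
  hi <- orc$delta + orc$step / 2
  out_len <- pmax(0, hi - pmax(lo, delta0)) +
    pmax(0, pmin(hi, -delta0) - lo)
  sum(orc$mass * pmin(out_len / orc$step, 1))
}

# Small helper shared by several test files: a valid in-memory count table.
make_table <- function(x1, x2, n1 = NULL, n2 = NULL) {
  as_count_table(
    tibble::tibble(
      gene_id = sprintf("g%04d", seq_along(x1)),
      x1 = x1, x2 = x2
    ),
    n1 = n1, n2 = n2
  )
}
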