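#' Two-proportion Z-test for equal expression
#'
#' The classical test of `pi1 = pi2` using the Gaussian approximation to
#' the binomial with the pooled proportion: `Z = (p1 - p2) /
#' sqrt(pbar (1 - pbar) (1/N1 + 1/N2))`, two-sided p-value from the
#' standard normal. A gene with `x1 + x2 = 0` carries no evidence and
#' returns `Z = 0, p = 1` so whole-table runs never abort.
#'
#' @param x1,x2 Counts (vectorized).
#' @param n1,n2 Library sizes.
#' @return A tibble with `statistic` (Z) and `p_value`.
#' @export
z_test_equal_proportions <- function(x1, x2, n1, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0))
  pbar <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- ifelse(x1 + x2 == 0, 0, (x1 / n1 - x2 / n2) / se)
  tibble(statistic = z, p_value = 2 * pnorm(-abs(z)))
}

#' Fisher's exact test on the 2x2 count table
#'
#' Tests the table `(x1, N1 - x1; x2, N2 - x2)` with the
#' minimum-likelihood two-sided convention (all tables with the same
#' margins whose hypergeometric probability does not exceed the observed
#' one), as implemented by [stats::fisher.test()].
#'
#' @inheritParams z_test_equal_proportions
#' @return A tibble with `p_value`.
#' @export
fisher_exact <- function(x1, x2, n1, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0))
  k <- max(length(x1), length(x2))
  x1 <- rep_len(x1, k)
  x2 <- rep_len(x2, k)
  n1 <- rep_len(n1, k)
  n2 <- rep_len(n2, k)
  p <- vapply(seq_len(k), function(i) {
    m <- matrix(c(x1[i], n1[i] - x1[i], x2[i], n2[i] - x2[i]), nrow = 2,
                byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  tibble(p_value = pmin(p, 1))
}

#' Bonferroni correction
#'
#' @param p_values p-values in `[0, 1]`.
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

#' Run a baseline test on every gene of a count table
#'
#' @param table An `asc_counts` count table.
#' @param method `"z"` or `"fisher"`.
#' @return A tibble `gene_id`, `statistic` (Z only), `p_value`,
#'   `p_adjusted` (Bonferroni over the table).
#' @export
run_baseline <- function(table, method = c("z", "fisher")) {
  method <- match.arg(method)
  ls <- library_sizes(table)
  res <- if (method == "z") {
    z_test_equal_proportions(table$x1, table$x2, ls[["n1"]], ls[["n2"]])
  } else {
    fisher_exact(table$x1, table$x2, ls[["n1"]], ls[["n2"]])
  }
  out <- dplyr::bind_cols(tibble(gene_id = table$gene_id), res)
  out$p_adjusted <- bonferroni(out$p_value)
  out
}

#' Overlap between the heads of two ranked gene lists
#'
#' @param ranking_a,ranking_b Character vectors of gene ids, best first;
#'   no duplicates allowed within a ranking.
#' @param k Prefix length, `k <= length()` of both.
#' @return Size of the intersection of the two length-`k` prefixes.
#' @export
top_k_overlap <- function(ranking_a, ranking_b, k) {
  if (anyDuplicated(ranking_a)) abort("duplicate ids in `ranking_a`")
  if (anyDuplicated(ranking_b)) abort("duplicate ids in `ranking_b`")
  if (k > length(ranking_a) || k > length(ranking_b)) {
    abort("`k` exceeds the length of a ranking")
  }
  length(intersect(head(ranking_a, k), head(ranking_b, k)))
}

#' Pairwise top-k overlap matrix for several rankings
#'
#' The machinery behind method-comparison tables: how many genes the
#' length-k heads of each pair of rankings share.
#'
#' @param rankings Named list of character vectors (gene ids, best first).
#' @param ks Integer vector of prefix lengths.
#' @return A tibble `method_a`, `method_b`, `k`, `overlap` over all
#'   ordered pairs (including self-pairs, which equal `k`).
#' @export
overlap_table <- function(rankings, ks) {
  stopifnot(is.list(rankings), length(rankings) >= 1, !is.null(names(rankings)))
  combos <- tidyr::expand_grid(
    method_a = names(rankings), method_b = names(rankings), k = as.integer(ks)
  )
  combos$overlap <- purrr::pmap_int(combos, function(method_a, method_b, k) {
    top_k_overlap(rankings[[method_a]], rankings[[method_b]], k)
  })
  combos
}

#' Rank genes for method comparison
#'
#' ASC ranks by the magnitude of the shrinkage estimate `|delta_hat|`
#' (largest first); the baseline tests rank by p-value (smallest first).
#'
#' @param results A tidy per-gene tibble (from [run_asc()]/[tidy()] or
#'   [run_baseline()]).
#' @param by Column to rank on: `"delta_hat"` (by absolute value,
#'   decreasing) or `"p_value"` (increasing).
#' @return Character vector of gene ids, best first.
#' @export
rank_genes <- function(results, by = c("delta_hat", "p_value")) {
  by <- match.arg(by)
  if (inherits(results, "asc_fit")) results <- results$results
  if (by == "delta_hat") {
    results$gene_id[order(-abs(results$delta_hat), results$gene_id)]
  } else {
    results$gene_id[order(results$p_value, results$gene_id)]
  }
}
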