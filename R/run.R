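#' Run the full empirical-Bayes analysis on a count table
#'
#' For every gene, computes the shrinkage estimate of log10 fold change
#' (posterior mean `delta_hat`) and the posterior probability that the
#' absolute log fold change exceeds `delta0`. Genes observed in neither
#' sample carry no fold-change signal and are flagged `"no-signal"` with
#' `delta_hat = 0`, `post_prob = 0` rather than integrated. The run is
#' fully deterministic.
#'
#' @param table An `asc_counts` count table (see [as_count_table()]).
#' @param hyper An `asc_hyper` object; `NULL` (default) estimates the
#'   hyperparameters from `table` via [estimate_hyperparams()].
#' @param delta0 Effect-size threshold, log10 scale. Default `log10(2)`
#'   (a two-fold change).
#' @param prob_cutoff Posterior-probability cutoff used to mark genes as
#'   selected. Default 0.9.
#' @param grid Integration settings, see [grid_config()].
#' @param likelihood `"binomial"` (exact) or `"poisson"`.
#' @param verbose Log hyperparameters and grid expansions via `message()`.
#' @return An `asc_fit` object. `tidy()` returns the per-gene tibble with
#'   columns `gene_id`, `x1`, `x2`, `rpm1`, `rpm2`, `avg_log_rpm`,
#'   `apparent_lfc`, `delta_hat`, `post_prob`, `selected`, `flag`;
#'   `glance()` a one-row summary.
#' @examples
#' sim <- simulate_generative(sim_config(n_genes = 200, seed = 1))
#' fit <- run_asc(sim$counts, new_hyperparams(alpha = 2.8, tau = 0.122))
#' tidy(fit)
#' glance(fit)
#' @export
run_asc <- function(table, hyper = NULL, delta0 = log10(2),
                    prob_cutoff = 0.9, grid = grid_config(),
                    likelihood = c("binomial", "poisson"),
                    verbose = FALSE) {
  likelihood <- match.arg(likelihood)
  if (!inherits(table, "asc_counts")) table <- as_count_table(table)
  if (is.null(hyper)) hyper <- estimate_hyperparams(table)
  stopifnot(inherits(hyper, "asc_hyper"))
  if (delta0 < 0) abort("`delta0` must be >= 0")
  if (prob_cutoff < 0 || prob_cutoff > 1) {
    abort("`prob_cutoff` must be in [0, 1]")
  }
  ls <- library_sizes(table)
  n1 <- ls[["n1"]]
  n2 <- ls[["n2"]]
  if (verbose) {
    message(sprintf(
      "ascount: alpha = %.4g, tau = %.4g, delta0 = %.4g, cutoff = %.2f, %s likelihood",
      hyper$alpha, hyper$tau, delta0, prob_cutoff, likelihood
    ))
  }

  n <- nrow(table)
  delta_hat <- numeric(n)
  post_prob <- numeric(n)
  flag <- character(n)
  n_expanded <- 0L
  for (i in seq_len(n)) {
    x1 <- table$x1[i]
    x2 <- table$x2[i]
    if (x1 + x2 == 0) {
      delta_hat[i] <- 0
      post_prob[i] <- 0
      flag[i] <- "no-signal"
      next
    }
    post <- compute_posterior(x1, x2, n1, n2, hyper, grid, likelihood)
    delta_hat[i] <- post$delta_hat
    post_prob[i] <- prob_exceeds(post, delta0)
    flag[i] <- ""
    if (post$expanded) n_expanded <- n_expanded + 1L
  }
  if (verbose && n_expanded > 0) {
    message(sprintf("ascount: grid expanded for %d gene(s)", n_expanded))
  }

  results <- tibble(
    gene_id = table$gene_id,
    x1 = table$x1, x2 = table$x2,
    rpm1 = table$x1 * 1e6 / n1,
    rpm2 = table$x2 * 1e6 / n2,
    avg_log_rpm = average_log_rpm(table$x1, table$x2, n1, n2),
    apparent_lfc = apparent_log_ratio(table$x1, table$x2, n1, n2),
    delta_hat = delta_hat,
    post_prob = post_prob,
    selected = as.integer(post_prob >= prob_cutoff),
    flag = flag
  )
  structure(
    list(
      results = results, hyper = hyper, delta0 = delta0,
      prob_cutoff = prob_cutoff, grid = grid, likelihood = likelihood,
      n1 = n1, n2 = n2, n_expanded = n_expanded
    ),
    class = "asc_fit"
  )
}

#' @export
print.asc_fit <- function(x, ...) {
  cat(sprintf(
    "ascount fit: %d genes, alpha = %.4g, tau = %.4g, delta0 = %.4g\n",
    nrow(x$results), x$hyper$alpha, x$hyper$tau, x$delta0
  ))
  cat(sprintf(
    "  %d selected at P(|delta| > delta0) >= %.2f; %d flagged no-signal\n",
    sum(x$results$selected), x$prob_cutoff,
    sum(x$results$flag == "no-signal")
  ))
  invisible(x)
}

#' @export
tidy.asc_fit <- function(x, ...) {
  x$results
}

#' @export
glance.asc_fit <- function(x, ...) {
  fdr <- bayesian_fdr(x$results, x$prob_cutoff)
  tibble(
    n_genes = nrow(x$results),
    n_no_signal = sum(x$results$flag == "no-signal"),
    n_selected = sum(x$results$selected),
    alpha = x$hyper$alpha,
    tau = x$hyper$tau,
    delta0 = x$delta0,
    prob_cutoff = x$prob_cutoff,
    fdr = fdr$fdr
  )
}

#' Direct-posterior false discovery rate
#'
#' Selects the genes whose posterior probability of exceeding the
#' fold-change threshold is at least `prob_cutoff` and estimates the FDR
#' of that list as the mean posterior probability of *non*-exceedance,
#' `mean(1 - post_prob)`, among the selected genes. The estimate is
#' non-increasing in the cutoff.
#'
#' @param results Per-gene results: an `asc_fit` or its `tidy()` tibble
#'   (needs `post_prob`, all computed at a common `delta0`).
#' @param prob_cutoff Selection cutoff in `[0, 1]`. Default 0.9.
#' @return List with `selected` (the selected rows, a tibble), `fdr`
#'   (estimated FDR; `NA` when nothing is selected) and `n_selected`.
#' @export
bayesian_fdr <- function(results, prob_cutoff = 0.9) {
  if (inherits(results, "asc_fit")) results <- results$results
  stopifnot(is.data.frame(results), "post_prob" %in% names(results))
  if (prob_cutoff < 0 || prob_cutoff > 1) {
    abort("`prob_cutoff` must be in [0, 1]")
  }
  sel <- dplyr::filter(as_tibble(results), .data$post_prob >= prob_cutoff)
  list(
    selected = sel,
    fdr = if (nrow(sel) == 0) NA_real_ else mean(1 - sel$post_prob),
    n_selected = nrow(sel)
  )
}

#' Write per-gene results to TSV
#'
#' Column order follows the fit's tidy tibble: `gene_id, x1, x2, rpm1,
#' rpm2, avg_log_rpm, apparent_lfc, delta_hat, post_prob, selected, flag`,
#' one header line, floating-point values at 6 significant digits.
#'
#' @param results An `asc_fit` or its `tidy()` tibble.
#' @param path Output file path.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "asc_fit")) results <- results$results
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) abort("no results to write")
  out <- dplyr::mutate(
    as_tibble(results),
    dplyr::across(dplyr::where(is.double), ~ signif(.x, 6))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
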