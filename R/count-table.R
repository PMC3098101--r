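#' Build a two-sample count table
#'
#' A count table holds, for every gene (or tag), the observed counts `x1` and
#' `x2` in the two samples being compared, together with the two library
#' sizes `N1` and `N2` (total sequenced reads or tags per sample). The
#' library sizes are stored as attributes so the object pipes like an
#' ordinary tibble.
#'
#' Library sizes default to the column sums, but can be overridden: the
#' total number of sequenced tags in an experiment often exceeds the sum of
#' the tabulated counts once tags have been filtered.
#'
#' @param data A data frame with columns `gene_id`, `x1`, `x2` (extra
#'   columns are kept).
#' @param n1,n2 Library sizes for samples 1 and 2. Default: column sums.
#' @return A tibble of class `asc_counts` with attributes `n1` and `n2`.
#' @examples
#' tbl <- as_count_table(
#'   data.frame(gene_id = c("g1", "g2"), x1 = c(10, 0), x2 = c(5, 2))
#' )
#' library_sizes(tbl)
#' @export
as_count_table <- function(data, n1 = NULL, n2 = NULL) {
  data <- as_tibble(data)
  required <- c("gene_id", "x1", "x2")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`data` must have columns gene_id, x1, x2; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data$gene_id <- as.character(data$gene_id)
  validate_counts_column(data$x1, "x1")
  validate_counts_column(data$x2, "x2")
  dup <- duplicated(data$gene_id)
  if (any(dup)) {
    abort(paste0(
      "duplicate gene_id at row ", which(dup)[1], ": '",
      data$gene_id[which(dup)[1]], "'"
    ))
  }
  n1 <- n1 %||% sum(data$x1)
  n2 <- n2 %||% sum(data$x2)
  if (!is.numeric(n1) || length(n1) != 1 || is.na(n1) || n1 <= 0 ||
      n1 != trunc(n1)) {
    abort("`n1` must be a single positive integer")
  }
  if (!is.numeric(n2) || length(n2) != 1 || is.na(n2) || n2 <= 0 ||
      n2 != trunc(n2)) {
    abort("`n2` must be a single positive integer")
  }
  if (any(data$x1 > n1)) {
    abort(paste0("x1 exceeds library size N1 at row ", which(data$x1 > n1)[1]))
  }
  if (any(data$x2 > n2)) {
    abort(paste0("x2 exceeds library size N2 at row ", which(data$x2 > n2)[1]))
  }
  structure(
    data,
    n1 = as.numeric(n1),
    n2 = as.numeric(n2),
    class = c("asc_counts", class(data))
  )
}

validate_counts_column <- function(x, name) {
  if (!is.numeric(x)) {
    abort(paste0("column `", name, "` must be numeric counts"))
  }
  bad <- which(is.na(x) | x < 0 | x != trunc(x))
  if (length(bad) > 0) {
    abort(paste0(
      "column `", name, "` must hold non-negative integer counts; ",
      "offending row ", bad[1], " (value ", x[bad[1]], ")"
    ))
  }
  invisible(x)
}

#' Library sizes of a count table
#'
#' @param table An `asc_counts` count table.
#' @return Named numeric vector `c(n1 = , n2 = )`.
#' @export
library_sizes <- function(table) {
  c(n1 = attr(table, "n1"), n2 = attr(table, "n2"))
}

#' @export
print.asc_counts <- function(x, ...) {
  ls <- library_sizes(x)
  cat(sprintf(
    "# A count table: %d genes; library sizes N1 = %s, N2 = %s\n",
    nrow(x), format(ls[["n1"]], big.mark = ","),
    format(ls[["n2"]], big.mark = ",")
  ))
  NextMethod()
}

#' Read a two-sample count table from TSV
#'
#' Expects at least three tab-separated columns: identifier, count in sample
#' 1, count in sample 2. A header line is detected by a non-numeric second
#' field and skipped. Rows with negative, fractional or unparseable counts
#' and duplicate identifiers are rejected with the offending row named.
#'
#' @param path Path to a TSV file.
#' @param n1_override,n2_override Optional library sizes; default column sums.
#' @return An [as_count_table()] tibble.
#' @export
read_count_table <- function(path, n1_override = NULL, n2_override = NULL) {
  if (!file.exists(path)) {
    abort(paste0("counts file not found: ", path))
  }
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) abort(paste0("empty counts file: ", path))
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 3) {
    abort("counts file must have at least 3 tab-separated columns (row 1)")
  }
  has_header <- is.na(suppressWarnings(as.numeric(fields[2])))
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, skip = as.integer(has_header),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 3) {
    abort("counts file must have at least 3 tab-separated columns")
  }
  offset <- as.integer(has_header)  # convert back to file row numbers
  parse_count <- function(chr, col_label) {
    val <- suppressWarnings(as.numeric(chr))
    bad <- which(is.na(val) | val < 0 | val != trunc(val))
    if (length(bad) > 0) {
      abort(paste0(
        "malformed ", col_label, " at file row ", bad[1] + offset,
        ": '", chr[bad[1]], "' (counts must be non-negative integers)"
      ))
    }
    val
  }
  tbl <- tibble(
    gene_id = raw[[1]],
    x1 = parse_count(raw[[2]], "count_1"),
    x2 = parse_count(raw[[3]], "count_2")
  )
  dup <- which(duplicated(tbl$gene_id))
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate gene_id '", tbl$gene_id[dup[1]], "' at file row ",
      dup[1] + offset
    ))
  }
  as_count_table(tbl, n1 = n1_override, n2 = n2_override)
}

#' Apparent log fold change between two samples
#'
#' The log10 ratio of the two sample proportions, with counts floored at 0.5
#' so genes observed in only one sample still get a finite value:
#' `log10((max(x1, 0.5)/N1) / (max(x2, 0.5)/N2))`. This is a descriptive
#' statistic (the raw, unshrunk log fold change); the posterior machinery
#' consumes raw counts and needs no flooring.
#'
#' @param x1,x2 Non-negative counts (vectorized).
#' @param n1,n2 Positive library sizes.
#' @return log10 fold change, finite for all inputs including zeros.
#' @examples
#' apparent_log_ratio(10, 1, 1e6, 1e6)  # 1
#' apparent_log_ratio(0, 5, 1e6, 1e6)   # log10(0.5/5) = -1
#' @export
apparent_log_ratio <- function(x1, x2, n1, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0))
  log10(pmax(x1, 0.5) / n1) - log10(pmax(x2, 0.5) / n2)
}

#' Average log10 reads-per-million
#'
#' Mean of the two per-sample log10 rpm values, counts floored at 0.5:
#' `[log10(max(x1,0.5) * 1e6 / N1) + log10(max(x2,0.5) * 1e6 / N2)] / 2`.
#' This is the expression-level axis used throughout: hyperparameter
#' estimation fits a shifted exponential to its empirical distribution.
#'
#' @inheritParams apparent_log_ratio
#' @return Mean log10 rpm (vectorized).
#' @export
average_log_rpm <- function(x1, x2, n1, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0))
  (log10(pmax(x1, 0.5) * 1e6 / n1) + log10(pmax(x2, 0.5) * 1e6 / n2)) / 2
}

#' Add per-gene descriptive statistics to a count table
#'
#' Appends `rpm1`, `rpm2` (raw reads-per-million, no flooring),
#' `avg_log_rpm` and `apparent_lfc` columns.
#'
#' @param table An `asc_counts` count table.
#' @return The table with four added columns (still an `asc_counts`).
#' @export
count_descriptives <- function(table) {
  ls <- library_sizes(table)
  out <- dplyr::mutate(
    table,
    rpm1 = .data$x1 * 1e6 / ls[["n1"]],
    rpm2 = .data$x2 * 1e6 / ls[["n2"]],
    avg_log_rpm = average_log_rpm(.data$x1, .data$x2, ls[["n1"]], ls[["n2"]]),
    apparent_lfc = apparent_log_ratio(.data$x1, .data$x2, ls[["n1"]], ls[["n2"]])
  )
  structure(out, n1 = ls[["n1"]], n2 = ls[["n2"]],
            class = c("asc_counts", class(tibble())))
}
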