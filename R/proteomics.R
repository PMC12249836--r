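# Proteomics module: differential abundance, Benjamini-Hochberg adjustment,
# and the conjunctive fold-change / p-value / FDR filter.

#' Differential protein abundance between two groups
#'
#' For each gene, computes the log2 fold change (injured vs sham, on group
#' means of the linear-scale abundances) and a two-sided Welch t-test
#' p-value on log2 abundances. Groups with zero within-group variance are
#' handled by a small variance inflation (1e-12 on the log2 scale) so the
#' test remains defined.
#'
#' @param expt a `proteomics_experiment` (see
#'   [generate_synthetic_proteomics()]), or a list with `abundance`
#'   (positive genes x samples matrix) and `group` (two-level factor, first
#'   level = reference/sham).
#' @return data.frame of class `"dep_table"` with columns `gene`, `log2fc`,
#'   `pvalue`, `qvalue` (`NA` until [bh_fill()]).
#' @export
compute_differential <- function(expt) {
  ab <- expt$abundance
  group <- expt$group
  stopifnot(is.matrix(ab), is.factor(group), nlevels(group) == 2L,
            ncol(ab) == length(group))
  if (any(!is.finite(ab)) || any(ab <= 0)) {
    stop("abundances must be positive finite values", call. = FALSE)
  }
  if (any(table(group) < 2L)) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  ref <- levels(group)[1]; alt <- levels(group)[2]
  la <- log2(ab)
  welch <- function(x, y) {
    eps <- 1e-12
    vx <- stats::var(x) + eps; vy <- stats::var(y) + eps
    nx <- length(x); ny <- length(y)
    se2 <- vx / nx + vy / ny
    t <- (mean(y) - mean(x)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    2 * stats::pt(-abs(t), df)
  }
  out <- data.frame(
    gene = rownames(ab),
    log2fc = log2(rowMeans(ab[, group == alt, drop = FALSE]) /
                    rowMeans(ab[, group == ref, drop = FALSE])),
    pvalue = vapply(seq_len(nrow(ab)), function(i) {
      welch(la[i, group == ref], la[i, group == alt])
    }, numeric(1)),
    qvalue = NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dep_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, returned in the input
#' order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Fill the q-value column of a DEP table
#'
#' @param records a `dep_table`.
#' @return the table with `qvalue = bh_adjust(pvalue)`.
#' @export
bh_fill <- function(records) {
  stopifnot(inherits(records, "dep_table"))
  records$qvalue <- bh_adjust(records$pvalue)
  records
}

#' Filter differentially expressed proteins
#'
#' Applies the conjunctive differential-expression criterion: linear fold
#' change of at least `fc_min` in magnitude (boundary inclusive, i.e.
#' `|log2FC| >= log2(fc_min)`), p-value strictly below `p_max`, and
#' BH-adjusted q-value at most `q_max`. All three thresholds are applied
#' independently and per-criterion rejection counts are reported, so either
#' reading of "adjusted p-value" versus "FDR" can be reproduced from the
#' output.
#'
#' @param records a `dep_table` with `qvalue` filled (see [bh_fill()]).
#' @param fc_min minimum linear fold-change magnitude (default 1.2).
#' @param p_max strict upper bound on the p-value (default 0.10).
#' @param q_max inclusive upper bound on the q-value (default 0.05).
#' @return list of class `"dep_filter"`: `records` (input plus logical
#'   columns `pass_fc`, `pass_p`, `pass_q`, `passes`), `passing` (subset
#'   passing all three) and `counts` (named: `n`, `n_pass`, `fail_fc`,
#'   `fail_p`, `fail_q`).
#' @export
filter_deps <- function(records, fc_min = 1.2, p_max = 0.10, q_max = 0.05) {
  stopifnot(inherits(records, "dep_table"))
  if (fc_min <= 0 || p_max <= 0 || q_max <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (nrow(records) > 0 && any(is.na(records$qvalue))) {
    stop("q-values not filled; call bh_fill() first", call. = FALSE)
  }
  records$pass_fc <- abs(records$log2fc) >= log2(fc_min)
  records$pass_p <- records$pvalue < p_max
  records$pass_q <- records$qvalue <= q_max
  records$passes <- records$pass_fc & records$pass_p & records$pass_q
  structure(list(
    records = records,
    passing = records[records$passes, , drop = FALSE],
    counts = c(n = nrow(records), n_pass = sum(records$passes),
               fail_fc = sum(!records$pass_fc),
               fail_p = sum(!records$pass_p),
               fail_q = sum(!records$pass_q))
  ), class = "dep_filter")
}

#' @export
print.dep_filter <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("DEP filter: %d of %d proteins pass (fold change, p, FDR)\n",
              ct[["n_pass"]], ct[["n"]]))
  cat(sprintf("  rejected by |FC|: %d, by p: %d, by q: %d (non-exclusive)\n",
              ct[["fail_fc"]], ct[["fail_p"]], ct[["fail_q"]]))
  invisible(x)
}

#' Read a DEP table from TSV
#'
#' Requires columns `gene`, `log2fc`, `pvalue`; an optional `qvalue` column
#' is kept, otherwise q-values are left `NA` for [bh_fill()]. Extra columns
#' are ignored (with a message); a header-only file yields an empty table.
#'
#' @param path TSV file path.
#' @return a `dep_table`.
#' @export
read_dep_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("DEP table misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(tab), c(need, "qvalue"))
  if (length(extra)) {
    message("ignoring extra DEP-table column(s): ",
            paste(extra, collapse = ", "))
  }
  out <- tab[intersect(c(need, "qvalue"), names(tab))]
  if (is.null(out$qvalue)) out$qvalue <- rep(NA_real_, nrow(out))
  class(out) <- c("dep_table", "data.frame")
  out
}
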