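#' Build a 2xK contingency table
#'
#' Container for the exact-test input: row 1 holds in-category counts, row 2
#' not-in-category counts, one column per gene set. Margins are derived and
#' fixed; the exact test conditions on them.
#'
#' @param cells Numeric matrix with 2 rows and at least 2 columns of
#'   non-negative integer counts.
#' @return An object of class `contingency_2xk` with elements `cells`,
#'   `row_totals`, `col_totals`, `grand_total`.
#' @examples
#' contingency_2xk(rbind(c(194, 94, 13), c(879, 473, 82)))
#' @export
contingency_2xk <- function(cells) {
  cells <- as.matrix(cells)
  if (nrow(cells) != 2L || ncol(cells) < 2L) {
    stop("cells must be a 2 x K matrix with K >= 2", call. = FALSE)
  }
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cells must be non-negative integer counts", call. = FALSE)
  }
  storage.mode(cells) <- "double"
  structure(
    list(cells = cells,
         row_totals = rowSums(cells),
         col_totals = colSums(cells),
         grand_total = sum(cells)),
    class = "contingency_2xk"
  )
}

#' @export
print.contingency_2xk <- function(x, ...) {
  cat("2 x", ncol(x$cells), "contingency table (fixed margins, N =",
      x$grand_total, ")\n")
  print(x$cells)
  invisible(x)
}

#' Contingency table of a category across gene sets
#'
#' Builds the 2xK table tested for over/underrepresentation: in-category
#' versus not-in-category counts among *annotated* genes, one column per
#' gene set. Unannotated genes are excluded, since a gene without functional
#' annotation is uninformative about category membership.
#'
#' @param summary A `count_summary`.
#' @param category Category name, e.g. `"N-mt"` or `"N-cp"`.
#' @param sets Gene sets to include as columns (default all three).
#' @return A `contingency_2xk`.
#' @examples
#' category_table(summarize_counts(generate_table1_fixture()), "N-mt")
#' @export
category_table <- function(summary, category, sets = summary$gene_set) {
  .check_summary(summary)
  col <- .category_col(summary, category)
  idx <- match(sets, summary$gene_set)
  if (anyNA(idx)) {
    stop("unknown gene set(s): ", paste(sets[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  inc <- summary[[col]][idx]
  out <- summary$n_annotated[idx] - inc
  cells <- rbind(inc, out)
  dimnames(cells) <- list(c(category, paste0("not ", category)),
                          summary$gene_set[idx])
  contingency_2xk(cells)
}

#' Log-probability of a table under fixed margins
#'
#' Conditional probability of a 2xK cell configuration given all margins
#' (the multivariate hypergeometric kernel of Fisher's exact test), on the
#' log scale via log-factorials:
#' \eqn{\sum_j \log c_j! + \sum_i \log r_i! - \log N! - \sum_{ij} \log n_{ij}!}.
#' Log-gamma keeps the computation exact in floating point at totals in the
#' thousands, where factorials themselves overflow.
#'
#' @param table A `contingency_2xk` (or a bare 2xK count matrix).
#' @return The log-probability (a single non-positive number).
#' @examples
#' exp(log_table_probability(rbind(c(3, 1), c(1, 3))))  # 16/70
#' @export
log_table_probability <- function(table) {
  if (!inherits(table, "contingency_2xk")) table <- contingency_2xk(table)
  sum(lfactorial(table$col_totals)) + sum(lfactorial(table$row_totals)) -
    lfactorial(table$grand_total) - sum(lfactorial(table$cells))
}

## All row-1 cell configurations compatible with row total r1 and column
## totals ct, as an integer matrix (one row per table). The last cell is
## determined; earlier cells iterate within feasibility bounds.
.enum_row1 <- function(r1, ct) {
  K <- length(ct)
  lo <- max(0, r1 - sum(ct[-1L]))
  hi <- min(r1, ct[1L])
  if (lo > hi) return(matrix(numeric(0), 0L, K))
  if (K == 1L) return(matrix(hi, 1L, 1L))
  if (K == 2L) {
    a <- lo:hi
    return(cbind(a, r1 - a, deparse.level = 0))
  }
  parts <- lapply(lo:hi, function(a) {
    cbind(a, .enum_row1(r1 - a, ct[-1L]), deparse.level = 0)
  })
  do.call(rbind, parts)
}

## Upper bound on the number of margin-consistent tables, used as the
## enumeration guard before any memory is committed.
.enum_bound <- function(r1, ct) {
  prod(pmin(r1, ct[-length(ct)]) + 1)
}

#' Enumerate all 2xK tables with given margins
#'
#' Yields every non-negative integer 2xK table with exactly the requested
#' margins, each once. This is the support of the exact null distribution.
#'
#' @param row_totals Length-2 vector of row margins.
#' @param col_totals Length-K (K >= 2) vector of column margins; must sum to
#'   `sum(row_totals)`.
#' @param max_tables Guard on the enumeration size (default `1e7`).
#' @return A list of `contingency_2xk` objects.
#' @examples
#' length(enumerate_tables(c(2, 2), c(2, 2)))  # 3 tables
#' @export
enumerate_tables <- function(row_totals, col_totals, max_tables = 1e7) {
  if (length(row_totals) != 2L || any(row_totals < 0)) {
    stop("row_totals must be two non-negative counts", call. = FALSE)
  }
  if (length(col_totals) < 2L || any(col_totals < 0)) {
    stop("col_totals must be K >= 2 non-negative counts", call. = FALSE)
  }
  if (sum(row_totals) != sum(col_totals)) {
    stop("inconsistent margins: sum(row_totals) != sum(col_totals)",
         call. = FALSE)
  }
  if (.enum_bound(row_totals[1L], col_totals) > max_tables) {
    stop("enumeration bound exceeds max_tables (", format(max_tables),
         "); use chisq_pvalue() as the asymptotic fallback", call. = FALSE)
  }
  top <- .enum_row1(row_totals[1L], col_totals)
  lapply(seq_len(nrow(top)), function(i) {
    contingency_2xk(rbind(top[i, ], col_totals - top[i, ]))
  })
}

## Shared exact-test kernel. cells: 2xK count matrix; lf: lookup of
## lfactorial(0:N) (built when NULL). Two-sided by probability ordering:
## sum over tables whose probability is <= observed * (1 + tie_tol).
.ffh_pvalue <- function(cells, lf = NULL, tie_tol = 1e-7) {
  ct <- colSums(cells)
  rt <- rowSums(cells)
  N <- sum(cells)
  if (is.null(lf)) lf <- lfactorial(0:N)
  const <- sum(lf[ct + 1]) + sum(lf[rt + 1]) - lf[N + 1]
  top <- .enum_row1(rt[1L], ct)
  bot <- rep(ct, each = nrow(top)) - top
  lp <- const -
    rowSums(matrix(lf[top + 1], nrow(top))) -
    rowSums(matrix(lf[bot + 1], nrow(top)))
  obs <- const - sum(lf[cells + 1])
  p <- sum(exp(lp[lp <= obs + log1p(tie_tol)]))
  list(p_value = min(max(p, exp(obs)), 1), n_tables = nrow(top),
       observed_log_prob = obs)
}

#' Freeman-Halton exact test on a 2xK table
#'
#' Two-sided exact test of association between category membership and gene
#' set, the r x c generalisation of Fisher's exact test. Every table with
#' the observed margins is enumerated; the p-value is the total probability
#' of tables no more probable than the observed one. A relative tie
#' tolerance guards the floating-point comparison of equal-probability
#' tables.
#'
#' @param table A `contingency_2xk` (or 2xK count matrix).
#' @param tie_tol Relative tolerance for counting a table as tied with the
#'   observed probability (default `1e-7`).
#' @param max_tables Enumeration guard (default `1e7` tables); exceeding it
#'   raises an error advising the asymptotic fallback [chisq_pvalue()].
#' @return An `exact_test_result`: list with `p_value` (in (0, 1]),
#'   `n_tables_enumerated`, and `observed_log_prob`.
#' @examples
#' tab <- category_table(summarize_counts(generate_table1_fixture()), "N-mt")
#' fisher_exact_2xk(tab)
#' @export
fisher_exact_2xk <- function(table, tie_tol = 1e-7, max_tables = 1e7) {
  if (!inherits(table, "contingency_2xk")) table <- contingency_2xk(table)
  if (.enum_bound(table$row_totals[1L], table$col_totals) > max_tables) {
    stop("enumeration bound exceeds max_tables (", format(max_tables),
         "); use chisq_pvalue() as the asymptotic fallback", call. = FALSE)
  }
  res <- .ffh_pvalue(table$cells, tie_tol = tie_tol)
  structure(
    list(p_value = res$p_value,
         n_tables_enumerated = res$n_tables,
         observed_log_prob = res$observed_log_prob),
    class = "exact_test_result"
  )
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat("Freeman-Halton exact test: p =", format(x$p_value, digits = 4),
      "(", x$n_tables_enumerated, "tables enumerated )\n")
  invisible(x)
}

#' Pearson chi-square p-value for a 2xK table
#'
#' Asymptotic cross-check of [fisher_exact_2xk()]: the Pearson chi-square
#' statistic on the 2xK table with K - 1 degrees of freedom, without
#' continuity correction.
#'
#' @inheritParams fisher_exact_2xk
#' @return Upper-tail p-value, with the statistic and degrees of freedom
#'   attached as attributes `statistic` and `df`.
#' @export
chisq_pvalue <- function(table) {
  if (!inherits(table, "contingency_2xk")) table <- contingency_2xk(table)
  expected <- outer(table$row_totals, table$col_totals) / table$grand_total
  if (any(expected == 0)) {
    stop("chi-square undefined: zero expected cell count", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table$cells, correct = FALSE))
  structure(unname(ht$p.value),
            statistic = unname(ht$statistic), df = unname(ht$parameter))
}
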