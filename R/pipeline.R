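#' Run the full cytonuclear distribution analysis
#'
#' End-to-end orchestration: classify genes into GO categories, tabulate
#' counts per gene set, estimate observed/expected ratios with percentile
#' bootstrap intervals, and test homogeneity of category membership across
#' the three gene sets with the Freeman-Halton exact test on the 2x3 table
#' of annotated genes (plus optional pairwise 2x2 tests). Deterministic
#' given `seed`.
#'
#' @param records Gene table (e.g. from [read_annotation_table()],
#'   [generate_annotation_table()] or [generate_table1_fixture()]).
#'   Exactly one of `records` and `input` must be supplied.
#' @param input Path to an annotation table to read.
#' @param target_terms Category-to-GO-identifier map (defaults to
#'   mitochondrion and chloroplast).
#' @param n_boot Bootstrap replicates per confidence interval (default
#'   10000).
#' @param seed Integer seed for all stochastic steps (default 1).
#' @param level Confidence level of the bootstrap intervals (default 0.95).
#' @param alpha Rejection level recorded for downstream use (default 0.05).
#' @param pairwise Also run the three pairwise 2x2 exact tests per category
#'   (default `TRUE`).
#' @param tie_tol Exact-test tie tolerance.
#' @return A `cytonuclear_report`: list with `counts` (a `count_summary`),
#'   `ratios` (data frame: gene_set, category, observed, expected, ratio,
#'   ci_low, ci_high, n_boot, level), `tests` (data frame: category,
#'   comparison, p_value, p_bonferroni, n_tables), and `provenance`. The
#'   Bonferroni column is an extension (the primary per-category p-values
#'   are reported unadjusted); it multiplies by the number of categories.
#' @examples
#' rep1 <- run_analysis(generate_table1_fixture(), n_boot = 500, seed = 1)
#' rep1
#' @export
run_analysis <- function(records = NULL, input = NULL,
                         target_terms = DEFAULT_TARGET_TERMS,
                         n_boot = 10000L, seed = 1L, level = 0.95,
                         alpha = 0.05, pairwise = TRUE, tie_tol = 1e-7) {
  if (is.null(records) == is.null(input)) {
    stop("supply exactly one of 'records' or 'input'", call. = FALSE)
  }
  if (!is.null(input)) records <- read_annotation_table(input)
  .validate_gene_table(records)
  set.seed(seed)

  flags <- assign_category_flags(records, target_terms)
  counts <- summarize_counts(records, flags)
  categories <- names(target_terms)

  ratio_rows <- list()
  for (cat in categories) {
    for (s in counts$gene_set) {
      est <- bootstrap_ci(records, s, cat, flags = flags, n_boot = n_boot,
                          seed = NULL, level = level)
      ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
        gene_set = s, category = cat,
        observed = est$observed, expected = est$expected,
        ratio = est$ratio, ci_low = est$ci_low, ci_high = est$ci_high,
        n_boot = est$n_boot, level = est$level,
        stringsAsFactors = FALSE
      )
    }
  }
  ratios <- do.call(rbind, ratio_rows)

  test_rows <- list()
  for (cat in categories) {
    ft <- fisher_exact_2xk(category_table(counts, cat), tie_tol = tie_tol)
    test_rows[[length(test_rows) + 1L]] <- data.frame(
      category = cat, comparison = paste(counts$gene_set, collapse = "|"),
      p_value = ft$p_value,
      p_bonferroni = min(1, ft$p_value * length(categories)),
      n_tables = ft$n_tables_enumerated,
      stringsAsFactors = FALSE
    )
    if (pairwise) {
      prs <- utils::combn(counts$gene_set, 2L, simplify = FALSE)
      for (pr in prs) {
        ft2 <- fisher_exact_2xk(category_table(counts, cat, sets = pr),
                                tie_tol = tie_tol)
        test_rows[[length(test_rows) + 1L]] <- data.frame(
          category = cat, comparison = paste(pr, collapse = "|"),
          p_value = ft2$p_value,
          p_bonferroni = min(1, ft2$p_value * length(categories)),
          n_tables = ft2$n_tables_enumerated,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tests <- do.call(rbind, test_rows)

  structure(
    list(counts = counts, ratios = ratios, tests = tests,
         provenance = list(
           input = if (is.null(input)) "in-memory records" else input,
           seed = seed, n_boot = n_boot, level = level, alpha = alpha,
           target_terms = as.list(target_terms), tie_tol = tie_tol,
           package_version = as.character(utils::packageVersion("cytonuclear"))
         )),
    class = "cytonuclear_report"
  )
}

#' @export
print.cytonuclear_report <- function(x, ...) {
  print(x$counts)
  cat("\nObserved/expected ratios (", 100 * x$ratios$level[1],
      "% percentile bootstrap CIs, ", x$ratios$n_boot[1],
      " replicates)\n", sep = "")
  r <- x$ratios
  r$expected <- round(r$expected, 2)
  r$ratio <- round(r$ratio, 3)
  r$ci_low <- round(r$ci_low, 3)
  r$ci_high <- round(r$ci_high, 3)
  print(r[, c("gene_set", "category", "observed", "expected", "ratio",
              "ci_low", "ci_high")], row.names = FALSE)
  cat("\nFreeman-Halton exact tests\n")
  t <- x$tests
  t$p_value <- signif(t$p_value, 4)
  t$p_bonferroni <- signif(t$p_bonferroni, 4)
  print(t[, c("category", "comparison", "p_value", "p_bonferroni")],
        row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes the report as JSON (full precision, machine-readable) and TSV
#' (`counts.tsv`, `ratios.tsv`, `tests.tsv`), plus `fig_ratios.tsv`, a
#' plot-data file with one row per gene set x category (ratio, CI bounds)
#' for a dot-and-whisker figure with a reference line at 1.
#'
#' @param report A `cytonuclear_report`.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("json", "tsv")`.
#' @param plot_data Also write the plot-data TSV (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, formats = c("json", "tsv"),
                         plot_data = TRUE) {
  stopifnot(inherits(report, "cytonuclear_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- character(0)
  if ("json" %in% formats) {
    p <- file.path(out_dir, "report.json")
    counts_df <- report$counts
    attr(counts_df, "categories") <- NULL
    class(counts_df) <- "data.frame"
    body <- list(
      counts = counts_df,
      categories = as.list(attr(report$counts, "categories")),
      ratios = report$ratios,
      tests = report$tests,
      provenance = report$provenance
    )
    jsonlite::write_json(body, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    tsv <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    counts_df <- report$counts
    attr(counts_df, "categories") <- NULL
    class(counts_df) <- "data.frame"
    paths <- c(paths,
               tsv(counts_df, "counts.tsv"),
               tsv(report$ratios, "ratios.tsv"),
               tsv(report$tests, "tests.tsv"))
  }
  if (plot_data) {
    pd <- report$ratios[, c("gene_set", "category", "ratio",
                            "ci_low", "ci_high")]
    p <- file.path(out_dir, "fig_ratios.tsv")
    utils::write.table(pd, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a JSON analysis report back
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A `cytonuclear_report`.
#' @export
read_report <- function(path) {
  body <- jsonlite::fromJSON(path)
  counts <- body$counts
  attr(counts, "categories") <- unlist(body$categories)
  class(counts) <- c("count_summary", "data.frame")
  structure(
    list(counts = counts, ratios = body$ratios, tests = body$tests,
         provenance = body$provenance),
    class = "cytonuclear_report"
  )
}

#' Dot-and-whisker plot of observed/expected ratios
#'
#' Ratio point estimates with bootstrap CIs per gene set and category, and
#' a dashed reference line at 1 (no over/underrepresentation). Requires
#' ggplot2.
#'
#' @param report A `cytonuclear_report`.
#' @return A ggplot object.
#' @export
plot_ratios <- function(report) {
  stopifnot(inherits(report, "cytonuclear_report"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ratios() requires the ggplot2 package", call. = FALSE)
  }
  df <- report$ratios
  df$gene_set <- factor(df$gene_set, levels = rev(GENE_SETS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$gene_set)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "observed / expected", y = NULL)
}
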