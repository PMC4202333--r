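#' Pooled category proportion across all gene sets
#'
#' The fraction of annotated genes, over the whole data set, that carry the
#' category's GO identifier. This is the null proportion against which each
#' gene set is compared: under no over/underrepresentation, every set is
#' expected to carry categories at this pooled rate.
#'
#' @param summary A `count_summary`.
#' @param category Category name, e.g. `"N-mt"` or `"N-cp"`.
#' @return A proportion in \[0, 1\].
#' @examples
#' pooled_proportion(summarize_counts(generate_table1_fixture()), "N-mt")
#' @export
pooled_proportion <- function(summary, category) {
  .check_summary(summary)
  col <- .category_col(summary, category)
  denom <- sum(summary$n_annotated)
  if (denom == 0) {
    stop("pooled proportion undefined: no annotated genes", call. = FALSE)
  }
  sum(summary[[col]]) / denom
}

#' Expected in-category count for a gene set
#'
#' The product of the pooled category proportion and the number of annotated
#' genes in the set: the count the set would show if category membership
#' were distributed homogeneously across sets. Returned as a real number,
#' not rounded.
#'
#' @inheritParams pooled_proportion
#' @param gene_set One of `"autosomal"`, `"X-linked"`, `"X-hemizygous"`.
#' @return A non-negative real number.
#' @examples
#' expected_count(summarize_counts(generate_table1_fixture()),
#'                "X-linked", "N-mt")
#' @export
expected_count <- function(summary, gene_set, category) {
  .check_summary(summary)
  idx <- match(gene_set, summary$gene_set)
  if (is.na(idx)) {
    stop("unknown gene set '", gene_set, "'; expected one of: ",
         paste(summary$gene_set, collapse = ", "), call. = FALSE)
  }
  pooled_proportion(summary, category) * summary$n_annotated[idx]
}

.new_ratio_estimate <- function(gene_set, category, observed, expected,
                                ci_low = NA_real_, ci_high = NA_real_,
                                n_boot = 0L, level = NA_real_) {
  structure(
    list(gene_set = gene_set, category = category,
         observed = observed, expected = expected,
         ratio = observed / expected,
         ci_low = ci_low, ci_high = ci_high,
         n_boot = n_boot, level = level),
    class = "ratio_estimate"
  )
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("%s %s: observed %d / expected %.2f = ratio %.3f",
              x$gene_set, x$category, as.integer(x$observed), x$expected,
              x$ratio))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  [%.0f%% CI %.3f-%.3f, %d bootstrap replicates]",
                100 * x$level, x$ci_low, x$ci_high, x$n_boot))
  }
  cat("\n")
  invisible(x)
}

#' Observed-to-expected ratio for a gene set and category
#'
#' The set's observed in-category count divided by its expected count under
#' homogeneity. A ratio of 1 indicates no over/underrepresentation; above 1,
#' overrepresentation.
#'
#' @inheritParams expected_count
#' @return A `ratio_estimate` (point estimate only; see [bootstrap_ci()] for
#'   confidence intervals).
#' @examples
#' obs_exp_ratio(summarize_counts(generate_table1_fixture()),
#'               "X-hemizygous", "N-cp")
#' @export
obs_exp_ratio <- function(summary, gene_set, category) {
  expected <- expected_count(summary, gene_set, category)
  if (expected == 0) {
    stop("observed/expected ratio undefined: expected count is zero",
         call. = FALSE)
  }
  col <- .category_col(summary, category)
  observed <- summary[[col]][match(gene_set, summary$gene_set)]
  .new_ratio_estimate(gene_set, category, observed, expected)
}

#' Percentile bootstrap confidence interval for an observed/expected ratio
#'
#' Resamples the annotated genes of the focal set with replacement (same
#' size), recomputes the observed in-category count per replicate, and
#' divides by the expected count held fixed at its full-data value, so the
#' interval reflects sampling variation of the observed count. Because each
#' replicate count is the number of in-category genes among `n` draws with
#' replacement from a set with in-category fraction `p-hat`, it is generated
#' as a Binomial(`n`, `p-hat`) draw -- an exact distributional identity, not
#' an approximation. Bounds are the (1 - level)/2 and 1 - (1 - level)/2
#' percentiles of the replicate ratios.
#'
#' @param records Gene table.
#' @param gene_set Focal gene set.
#' @param category Category name.
#' @param flags Optional precomputed [assign_category_flags()] output.
#' @param target_terms Category-to-GO-identifier map used when `flags` is
#'   not supplied.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so a caller can seed once for a whole analysis).
#' @param level Confidence level (default 0.95).
#' @param recompute_expected When `TRUE`, all gene sets are resampled and
#'   the pooled proportion (hence the expected count) is recomputed per
#'   replicate -- a sensitivity variant in which uncertainty in the null
#'   proportion propagates into the ratio and covaries with the focal
#'   count (since the focal set contributes to the pooled proportion, the
#'   resulting interval is typically narrower). Default `FALSE`.
#' @return A `ratio_estimate` with `ci_low`/`ci_high` filled in.
#' @examples
#' tab <- generate_table1_fixture()
#' bootstrap_ci(tab, "X-linked", "N-mt", n_boot = 1000, seed = 1)
#' @export
bootstrap_ci <- function(records, gene_set, category, flags = NULL,
                         target_terms = DEFAULT_TARGET_TERMS,
                         n_boot = 10000L, seed = NULL, level = 0.95,
                         recompute_expected = FALSE) {
  if (n_boot < 1L) stop("n_boot must be at least 1", call. = FALSE)
  if (level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  if (is.null(flags)) flags <- assign_category_flags(records, target_terms)
  keep <- records$set_label == gene_set & records$annotated
  n <- sum(keep)
  if (n == 0L) {
    stop("no annotated genes in set '", gene_set, "'", call. = FALSE)
  }
  summary <- summarize_counts(records, flags)
  est <- obs_exp_ratio(summary, gene_set, category)
  if (!is.null(seed)) set.seed(seed)

  col <- .category_col(summary, category)
  idx <- match(gene_set, summary$gene_set)
  p_hat <- summary[[col]][idx] / n
  obs_b <- stats::rbinom(n_boot, n, p_hat)

  if (recompute_expected) {
    other <- summary$gene_set[-idx]
    cat_b <- obs_b
    ann_b <- rep(n, n_boot)
    for (s in other) {
      ns <- summary$n_annotated[match(s, summary$gene_set)]
      if (ns > 0L) {
        ps <- summary[[col]][match(s, summary$gene_set)] / ns
        cat_b <- cat_b + stats::rbinom(n_boot, ns, ps)
        ann_b <- ann_b + ns
      }
    }
    expected_b <- cat_b / ann_b * n
    ratio_b <- obs_b / expected_b
  } else {
    ratio_b <- obs_b / est$expected
  }

  qs <- stats::quantile(ratio_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  .new_ratio_estimate(gene_set, category, est$observed, est$expected,
                      ci_low = qs[1L], ci_high = qs[2L],
                      n_boot = as.integer(n_boot), level = level)
}
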