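# Independent oracles used across the suite. These deliberately avoid the
# package's own log-factorial enumeration path.

# Two-sided Fisher p for a 2x2 table by direct summation of the
# hypergeometric density over the single free cell.
fisher22_oracle <- function(cells, tie_tol = 1e-7) {
  m1 <- sum(cells[, 1]); m2 <- sum(cells[, 2]); k <- sum(cells[1, ])
  supp <- max(0, k - m2):min(k, m1)
  d <- stats::dhyper(supp, m1, m2, k)
  obs <- d[supp == cells[1, 1]]
  sum(d[d <= obs * (1 + tie_tol)])
}

# Random 2x2 count table with margins bounded by max_margin.
random_table22 <- function(max_margin = 30) {
  repeat {
    cells <- matrix(sample(0:max_margin, 4, replace = TRUE), 2)
    if (all(colSums(cells) <= max_margin) && all(rowSums(cells) <= max_margin) &&
        sum(cells) > 0 && all(colSums(cells) > 0)) {
      return(cells)
    }
  }
}

# Brute-force count of 2x3 tables with the given margins: double loop over
# the two free cells of row 1.
count_tables_2x3 <- function(row_totals, col_totals) {
  r1 <- row_totals[1]
  n <- 0L
  for (a in 0:min(r1, col_totals[1])) {
    for (b in 0:min(r1 - a, col_totals[2])) {
      cc <- r1 - a - b
      if (cc <= col_totals[3]) n <- n + 1L
    }
  }
  n
}

# Small in-memory gene table for IO tests.
tiny_gene_table <- function() {
  df <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    set_label = factor(c("autosomal", "X-linked", "X-hemizygous", "autosomal"),
                       levels = c("autosomal", "X-linked", "X-hemizygous")),
    annotated = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  df$go_terms <- list(c("GO:0005739", "GO:0009507"), "GO:0009507",
                      character(0), character(0))
  df
}
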