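cs_study <- summarize_counts(generate_table1_fixture())

test_that("pooled proportions and expected counts match direct arithmetic", {
  expect_equal(pooled_proportion(cs_study, "N-mt"), 301 / 1735,
               tolerance = 1e-12)
  expect_equal(pooled_proportion(cs_study, "N-cp"), 346 / 1735,
               tolerance = 1e-12)
  expect_equal(expected_count(cs_study, "X-linked", "N-mt"),
               567 * 301 / 1735, tolerance = 1e-12)
  expect_equal(expected_count(cs_study, "X-hemizygous", "N-cp"),
               95 * 346 / 1735, tolerance = 1e-12)
  expect_error(expected_count(cs_study, "Y-linked", "N-mt"), "unknown gene set")
  expect_error(pooled_proportion(cs_study, "N-xx"), "unknown category")
})

test_that("pooled proportion hits the boundary cases", {
  rec <- tiny_gene_table()
  rec$go_terms <- replicate(4, "GO:0005739", simplify = FALSE)
  rec$annotated <- rep(TRUE, 4)
  expect_equal(pooled_proportion(summarize_counts(rec), "N-mt"), 1)

  rec$annotated <- rep(FALSE, 4)
  rec$go_terms <- replicate(4, character(0), simplify = FALSE)
  expect_error(pooled_proportion(summarize_counts(rec), "N-mt"),
               "no annotated genes")
})

test_that("observed/expected ratios match direct arithmetic", {
  r1 <- obs_exp_ratio(cs_study, "X-linked", "N-mt")
  expect_equal(r1$ratio, 94 / (567 * 301 / 1735), tolerance = 1e-12)
  expect_equal(r1$observed, 94)
  r2 <- obs_exp_ratio(cs_study, "X-hemizygous", "N-cp")
  expect_equal(r2$ratio, 22 / (95 * 346 / 1735), tolerance = 1e-12)

  # equal composition in every set: each ratio is exactly one
  rec <- generate_table1_fixture()
  flags <- assign_category_flags(rec)
  cs <- summarize_counts(rec, flags)
  balanced <- cs
  balanced$n_mt <- balanced$n_annotated  # observed == expected (pooled = 1)
  expect_equal(obs_exp_ratio(balanced, "X-linked", "N-mt")$ratio, 1)
})

test_that("ratios are invariant to proportional duplication of the data", {
  rec <- generate_table1_fixture()
  dup <- rec
  dup$gene_id <- paste0("dup_", dup$gene_id)
  cs2 <- summarize_counts(rbind(rec, dup))
  for (s in cs_study$gene_set) {
    for (cat in c("N-mt", "N-cp")) {
      expect_equal(obs_exp_ratio(cs2, s, cat)$ratio,
                   obs_exp_ratio(cs_study, s, cat)$ratio, tolerance = 1e-12)
    }
  }
})

test_that("bootstrap CIs are seeded, ordered, and degenerate when variance is zero", {
  rec <- generate_table1_fixture()
  a <- bootstrap_ci(rec, "X-linked", "N-mt", n_boot = 500, seed = 7)
  b <- bootstrap_ci(rec, "X-linked", "N-mt", n_boot = 500, seed = 7)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$ci_high)
  # point estimate is bracketed for a large replicate count
  c1 <- bootstrap_ci(rec, "X-linked", "N-mt", n_boot = 5000, seed = 8)
  expect_lte(c1$ci_low, c1$ratio)
  expect_gte(c1$ci_high, c1$ratio)
  # study data: the X-linked mitochondrial interval straddles one
  expect_lt(c1$ci_low, 1)
  expect_gt(c1$ci_high, 1)

  # every gene in-category: zero-variance resamples collapse the interval
  rec2 <- tiny_gene_table()
  rec2$annotated <- rep(TRUE, 4)
  rec2$go_terms <- replicate(4, "GO:0005739", simplify = FALSE)
  z <- bootstrap_ci(rec2, "autosomal", "N-mt", n_boot = 200, seed = 1)
  expect_equal(z$ci_low, z$ratio)
  expect_equal(z$ci_high, z$ratio)

  expect_error(bootstrap_ci(rec2[rec2$set_label == "autosomal", ],
                            "X-linked", "N-mt", n_boot = 10),
               "no annotated genes")
})

test_that("more bootstrap replicates shrink the Monte-Carlo jitter of the bounds", {
  rec <- generate_table1_fixture()
  lows <- function(n_boot, seeds) {
    vapply(seeds, function(s) {
      bootstrap_ci(rec, "X-linked", "N-mt", n_boot = n_boot, seed = s)$ci_low
    }, numeric(1))
  }
  sd_small <- stats::sd(lows(1000, 1:12))
  sd_big <- stats::sd(lows(100000, 1:12))
  expect_lt(sd_big, sd_small)
})

test_that("recomputing the expected count per replicate is a distinct, valid variant", {
  rec <- generate_table1_fixture()
  fixed <- bootstrap_ci(rec, "X-linked", "N-mt", n_boot = 20000, seed = 3)
  resamp <- bootstrap_ci(rec, "X-linked", "N-mt", n_boot = 20000, seed = 3,
                         recompute_expected = TRUE)
  # point estimates are untouched; only the interval construction changes
  expect_equal(resamp$observed, fixed$observed)
  expect_equal(resamp$expected, fixed$expected)
  expect_lte(resamp$ci_low, resamp$ratio)
  expect_gte(resamp$ci_high, resamp$ratio)
  # the focal count covaries with the recomputed pooled proportion, which
  # dampens replicate ratios: the interval narrows rather than widens
  expect_lt(resamp$ci_high - resamp$ci_low, fixed$ci_high - fixed$ci_low)
  # reproducible under the same seed
  expect_identical(resamp,
                   bootstrap_ci(rec, "X-linked", "N-mt", n_boot = 20000,
                                seed = 3, recompute_expected = TRUE))
})
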