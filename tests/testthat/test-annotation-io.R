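test_that("reading preserves rows, labels and multi-term GO fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tset_label\tannotated\tgo_terms",
    "g1\tautosomal\tTRUE\tGO:0005739;GO:0009507",
    "g2\tX-linked\t1\tGO:0009507",
    "g3\tx_hemizygous\tno\t"
  ), path)
  rec <- read_annotation_table(path)
  expect_equal(rec$gene_id, c("g1", "g2", "g3"))
  expect_equal(as.character(rec$set_label),
               c("autosomal", "X-linked", "X-hemizygous"))
  expect_equal(rec$annotated, c(TRUE, TRUE, FALSE))
  expect_equal(rec$go_terms[[1]], c("GO:0005739", "GO:0009507"))
  expect_equal(rec$go_terms[[3]], character(0))
})

test_that("malformed tables are rejected with informative errors", {
  write_tbl <- function(lines) {
    p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
    writeLines(lines, p)
    p
  }
  expect_error(
    read_annotation_table(write_tbl(c("gene_id\tset_label\tannotated",
                                      "g1\tautosomal\tTRUE"))),
    "go_terms")
  expect_error(
    read_annotation_table(write_tbl(c("gene_id\tset_label\tannotated\tgo_terms",
                                      "g1\tautosomal\tTRUE\t",
                                      "g1\tX-linked\tTRUE\t"))),
    "duplicate.*g1")
  expect_error(
    read_annotation_table(write_tbl(c("gene_id\tset_label\tannotated\tgo_terms",
                                      "g1\tY-linked\tTRUE\t"))),
    "set_label at row\\(s\\) 1")
  expect_error(
    read_annotation_table(write_tbl(c("gene_id\tset_label\tannotated\tgo_terms",
                                      "g1\tautosomal\tTRUE\tGO:123"))),
    "GO identifier")
  expect_error(
    read_annotation_table(write_tbl(c("gene_id\tset_label\tannotated\tgo_terms",
                                      "g1\tautosomal\tFALSE\tGO:0005739"))),
    "unannotated")
  expect_error(read_annotation_table(tempfile()), "not found")
})

test_that("write then read round-trips randomly generated tables", {
  for (seed in c(101, 102, 103)) {
    cfg <- synthetic_config(
      set_sizes = c("autosomal" = 40L, "X-linked" = 25L, "X-hemizygous" = 10L),
      seed = seed)
    orig <- generate_annotation_table(cfg)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_annotation_table(orig, path)
    back <- read_annotation_table(path)
    expect_equal(back$gene_id, orig$gene_id)
    expect_equal(back$set_label, orig$set_label)
    expect_equal(back$annotated, orig$annotated)
    expect_equal(back$go_terms, orig$go_terms)
  }
})

test_that("category flags are exact identifier membership", {
  rec <- tiny_gene_table()
  flags <- assign_category_flags(rec)
  expect_named(flags, c("N-mt", "N-cp"))
  expect_equal(flags[["N-mt"]], c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(flags[["N-cp"]], c(TRUE, TRUE, FALSE, FALSE))
  # near-miss identifiers must not match
  rec$go_terms[[4]] <- "GO:0005740"
  flags2 <- assign_category_flags(rec)
  expect_false(flags2[["N-mt"]][4])
  expect_error(assign_category_flags(rec, c("N-mt" = "GO:57")), "malformed")
  expect_error(assign_category_flags(rec, "GO:0005739"), "named")
})

test_that("count summary matches direct tallies and is order-invariant", {
  rec <- tiny_gene_table()
  cs <- summarize_counts(rec)
  expect_s3_class(cs, "count_summary")
  expect_equal(cs$n_total, c(2L, 1L, 1L))
  expect_equal(cs$n_annotated, c(2L, 1L, 0L))
  expect_equal(cs$n_mt, c(1L, 0L, 0L))
  expect_equal(cs$n_cp, c(1L, 1L, 0L))

  perm <- sample(nrow(rec))
  cs2 <- summarize_counts(rec[perm, ])
  expect_equal(as.data.frame(cs2), as.data.frame(cs))

  expect_error(summarize_counts(rec[0, ]), "no gene records")
})

test_that("count summaries are additive under table concatenation", {
  cfg1 <- synthetic_config(
    set_sizes = c("autosomal" = 30L, "X-linked" = 20L, "X-hemizygous" = 10L),
    seed = 11)
  cfg2 <- synthetic_config(
    set_sizes = c("autosomal" = 15L, "X-linked" = 25L, "X-hemizygous" = 5L),
    seed = 12)
  a <- generate_annotation_table(cfg1)
  b <- generate_annotation_table(cfg2)
  b$gene_id <- paste0("b_", b$gene_id)
  both <- rbind(a, b)
  cs <- summarize_counts(both)
  csa <- summarize_counts(a)
  csb <- summarize_counts(b)
  for (col in c("n_total", "n_annotated", "n_mt", "n_cp")) {
    expect_equal(cs[[col]], csa[[col]] + csb[[col]])
  }
  # per-set category counts never exceed annotated counts
  expect_true(all(cs$n_mt <= cs$n_annotated))
  expect_true(all(cs$n_cp <= cs$n_annotated))
  expect_true(all(cs$n_annotated <= cs$n_total))
})

test_that("packaged fixture reproduces the published count table", {
  path <- system.file("extdata", "rumex_table1.tsv", package = "cytonuclear")
  expect_true(nzchar(path))
  cs <- summarize_counts(read_annotation_table(path))
  expect_equal(cs$n_total, c(1167L, 624L, 107L))
  expect_equal(cs$n_annotated, c(1073L, 567L, 95L))
  expect_equal(cs$n_mt, c(194L, 94L, 13L))
  expect_equal(cs$n_cp, c(222L, 102L, 22L))
})
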