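#' @keywords internal
"_PACKAGE"

## Canonical gene-set labels. X-linked genes retain a Y allele; X-hemizygous
## genes have lost theirs, so the two labels are disjoint by construction.
GENE_SETS <- c("autosomal", "X-linked", "X-hemizygous")

## Default target cellular-component terms: mitochondrion and chloroplast.
DEFAULT_TARGET_TERMS <- c("N-mt" = "GO:0005739", "N-cp" = "GO:0009507")

GO_PATTERN <- "^GO:[0-9]{7}$"

.norm_set_label <- function(x) {
  key <- gsub("[^a-z]+", "", tolower(x))
  map <- c(
    autosomal    = "autosomal", autosome = "autosomal", a = "autosomal",
    xlinked      = "X-linked", x = "X-linked", xy = "X-linked",
    xhemizygous  = "X-hemizygous", hemizygous = "X-hemizygous",
    xhemi        = "X-hemizygous"
  )
  out <- unname(map[key])
  out
}

.validate_gene_table <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("gene_id", "set_label", "annotated", "go_terms")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("annotation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("annotation table contains no gene records", call. = FALSE)
  }
  if (any(!nzchar(records$gene_id))) {
    stop("empty gene_id at row(s): ",
         paste(which(!nzchar(records$gene_id)), collapse = ", "), call. = FALSE)
  }
  dup <- unique(records$gene_id[duplicated(records$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene_id value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_set <- which(!(records$set_label %in% GENE_SETS))
  if (length(bad_set) > 0L) {
    stop("unrecognized set_label at row(s) ",
         paste(bad_set, collapse = ", "), ": expected one of ",
         paste(GENE_SETS, collapse = ", "), call. = FALSE)
  }
  terms <- records$go_terms
  n_terms <- lengths(terms)
  orphan <- which(n_terms > 0L & !records$annotated)
  if (length(orphan) > 0L) {
    stop("GO terms present for unannotated gene(s) at row(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  all_terms <- unlist(terms, use.names = FALSE)
  bad_go <- unique(all_terms[!grepl(GO_PATTERN, all_terms)])
  if (length(bad_go) > 0L) {
    stop("malformed GO identifier(s): ", paste(bad_go, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Read a per-gene annotation table
#'
#' Reads a delimited per-gene annotation table in the style of a Blast2GO
#' export: one row per gene with its gene-set label (autosomal, X-linked or
#' X-hemizygous), whether any functional annotation was obtained, and the GO
#' identifiers assigned to it (several per gene, packed into one column).
#'
#' Gene-set labels are matched case-insensitively and tolerate common
#' separator variants (`"x_linked"`, `"hemizygous"`, ...). The `annotated`
#' column accepts `TRUE`/`FALSE`, `T`/`F`, `1`/`0`, `yes`/`no`. Rows with an
#' empty GO field but `annotated = TRUE` are legitimate: the gene was
#' annotated, just not with any retained term.
#'
#' @param path Path to the table.
#' @param sep Field separator (default tab).
#' @param go_sep Separator between GO identifiers within the `go_terms`
#'   field (default `";"`).
#' @return A `data.frame` with columns `gene_id` (character), `set_label`
#'   (factor over the three gene sets), `annotated` (logical) and `go_terms`
#'   (list of character vectors), one row per gene, in file order.
#' @seealso [write_annotation_table()], [summarize_counts()]
#' @examples
#' path <- system.file("extdata", "example_annotations.tsv",
#'                     package = "cytonuclear")
#' head(read_annotation_table(path))
#' @export
read_annotation_table <- function(path, sep = "\t", go_sep = ";") {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE, quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, strip.white = TRUE)
  required <- c("gene_id", "set_label", "annotated", "go_terms")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("annotation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  set_label <- .norm_set_label(raw$set_label)
  bad_set <- which(is.na(set_label))
  if (length(bad_set) > 0L) {
    stop("unrecognized set_label at row(s) ", paste(bad_set, collapse = ", "),
         ": ", paste(unique(raw$set_label[bad_set]), collapse = ", "),
         call. = FALSE)
  }

  ann_key <- tolower(raw$annotated)
  annotated <- ann_key %in% c("true", "t", "1", "yes", "y")
  bad_ann <- which(!(ann_key %in% c("true", "t", "1", "yes", "y",
                                    "false", "f", "0", "no", "n")))
  if (length(bad_ann) > 0L) {
    stop("unparseable annotated flag at row(s): ",
         paste(bad_ann, collapse = ", "), call. = FALSE)
  }

  go_terms <- lapply(strsplit(raw$go_terms, go_sep, fixed = TRUE),
                     function(x) {
                       x <- trimws(x)
                       unique(x[nzchar(x)])
                     })

  records <- data.frame(
    gene_id = raw$gene_id,
    set_label = factor(set_label, levels = GENE_SETS),
    annotated = annotated,
    stringsAsFactors = FALSE
  )
  records$go_terms <- go_terms
  .validate_gene_table(records)
  records
}

#' Write a per-gene annotation table
#'
#' Inverse of [read_annotation_table()]: GO identifiers are joined with
#' `go_sep` into a single column and the table is written without quoting.
#'
#' @param records Gene table as returned by [read_annotation_table()] or
#'   [generate_annotation_table()].
#' @inheritParams read_annotation_table
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(records, path, sep = "\t", go_sep = ";") {
  .validate_gene_table(records)
  out <- data.frame(
    gene_id = records$gene_id,
    set_label = as.character(records$set_label),
    annotated = records$annotated,
    go_terms = vapply(records$go_terms, paste, character(1), collapse = go_sep),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag genes belonging to GO categories
#'
#' A gene is flagged for a category if and only if the category's exact GO
#' identifier is among the gene's terms. No ontology-ancestor propagation is
#' applied: Blast2GO-style annotation sets conventionally already carry the
#' cellular-component assignment itself, so membership is tested against the
#' literal identifier (mitochondrion GO:0005739, chloroplast GO:0009507 by
#' default).
#'
#' @param records Gene table.
#' @param target_terms Named character vector mapping category names to GO
#'   identifiers. Defaults to `c("N-mt" = "GO:0005739", "N-cp" = "GO:0009507")`.
#' @return A `data.frame` of logicals, one column per category, one row per
#'   gene (same order as `records`).
#' @examples
#' tab <- generate_table1_fixture()
#' flags <- assign_category_flags(tab)
#' colSums(flags)
#' @export
assign_category_flags <- function(records,
                                  target_terms = DEFAULT_TARGET_TERMS) {
  .validate_gene_table(records)
  if (is.null(names(target_terms)) || any(!nzchar(names(target_terms)))) {
    stop("target_terms must be a named character vector", call. = FALSE)
  }
  bad <- target_terms[!grepl(GO_PATTERN, target_terms)]
  if (length(bad) > 0L) {
    stop("malformed target GO identifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  flags <- lapply(target_terms, function(term) {
    vapply(records$go_terms, function(g) term %in% g, logical(1))
  })
  as.data.frame(flags, check.names = FALSE, optional = TRUE)
}

.count_column <- function(category) {
  key <- gsub("^n[-_ ]", "", tolower(category))
  paste0("n_", gsub("[^a-z0-9]+", "_", key))
}

#' Tabulate gene counts by gene set and category
#'
#' Produces the per-set count table that all downstream statistics consume:
#' total genes, annotated genes, and genes in each GO category.
#'
#' @param records Gene table.
#' @param flags Per-gene category flags from [assign_category_flags()];
#'   recomputed with the default target terms when omitted.
#' @return A `count_summary`: a `data.frame` with one row per gene set and
#'   columns `gene_set`, `n_total`, `n_annotated`, plus one count column per
#'   flagged category (`n_mt`, `n_cp` for the defaults). The category names
#'   are kept in `attr(x, "categories")`.
#' @examples
#' summarize_counts(generate_table1_fixture())
#' @export
summarize_counts <- function(records, flags = assign_category_flags(records)) {
  .validate_gene_table(records)
  if (nrow(flags) != nrow(records)) {
    stop("flags must have one row per gene record", call. = FALSE)
  }
  sets <- factor(records$set_label, levels = GENE_SETS)
  out <- data.frame(
    gene_set = GENE_SETS,
    n_total = as.integer(tabulate(sets, nbins = length(GENE_SETS))),
    n_annotated = as.integer(tapply0(records$annotated, sets)),
    stringsAsFactors = FALSE
  )
  categories <- names(flags)
  for (cat in categories) {
    out[[.count_column(cat)]] <- as.integer(tapply0(flags[[cat]], sets))
  }
  attr(out, "categories") <- stats::setNames(.count_column(categories),
                                             categories)
  class(out) <- c("count_summary", "data.frame")
  out
}

## sum of a logical by factor level, zero-filled over empty levels
tapply0 <- function(x, f) {
  s <- tapply(x, f, sum, default = 0L)
  s[is.na(s)] <- 0L
  s
}

#' @export
print.count_summary <- function(x, ...) {
  cat("Gene counts by set\n")
  m <- t(as.matrix(x[, -1, drop = FALSE]))
  colnames(m) <- x$gene_set
  rownames(m) <- c("total", "annotated",
                   names(attr(x, "categories")))[seq_len(nrow(m))]
  print(m)
  invisible(x)
}

## Resolve a category name ("N-mt", "n_mt", "mt", ...) to its count column.
.category_col <- function(summary, category) {
  cats <- attr(summary, "categories")
  if (category %in% names(cats)) return(unname(cats[category]))
  if (category %in% cats) return(category)
  col <- .count_column(category)
  if (col %in% cats) return(col)
  stop("unknown category '", category, "'; expected one of: ",
       paste(names(cats), collapse = ", "), call. = FALSE)
}

.check_summary <- function(summary) {
  if (!inherits(summary, "count_summary")) {
    stop("expected a count_summary from summarize_counts()", call. = FALSE)
  }
  invisible(summary)
}
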