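## Published per-set gene counts for the Rumex hastatulus transcriptome
## data set: total genes, genes with any functional annotation, and genes
## carrying the mitochondrion / chloroplast GO identifiers.
.table1_counts <- function() {
  data.frame(
    gene_set = GENE_SETS,
    n_total = c(1167L, 624L, 107L),
    n_annotated = c(1073L, 567L, 95L),
    n_mt = c(194L, 94L, 13L),
    n_cp = c(222L, 102L, 22L),
    stringsAsFactors = FALSE
  )
}

## Decoy cellular-component/process terms: syntactically valid GO ids that
## are never the mitochondrion or chloroplast target, so matching logic is
## exercised against near-misses.
.decoy_pool <- c(
  "GO:0003674", "GO:0005575", "GO:0008150", "GO:0005634", "GO:0005737",
  "GO:0016020", "GO:0005886", "GO:0005829", "GO:0009536", "GO:0005740",
  "GO:0005773", "GO:0042651"
)

#' Configuration for the synthetic annotation-table generator
#'
#' Describes the generative model the analysis assumes: three gene sets of
#' fixed sizes; each gene annotated with a per-set Bernoulli probability;
#' each annotated gene independently a member of each GO category with
#' probability `effect * base_prop` for its set. Effects of 1 give the
#' homogeneous null under which observed/expected ratios are 1.
#'
#' Defaults reproduce the scale of the *Rumex hastatulus* study data:
#' set sizes 1167/624/107, a 90% annotation rate, and baseline category
#' proportions equal to the study-wide pooled proportions (0.1735 for the
#' mitochondrion category, 0.1994 for the chloroplast category).
#'
#' @param set_sizes Named integer vector of gene counts per set.
#' @param annotation_rate Probability a gene receives any annotation, per
#'   set (recycled from a scalar).
#' @param base_props Named vector of baseline category proportions among
#'   annotated genes.
#' @param effects Matrix of multiplicative effects, sets x categories
#'   (dimnames optional; defaults to all 1 = null). An effect pushing any
#'   probability outside \[0, 1\] is rejected, not clamped.
#' @param target_terms Category-to-GO-identifier map.
#' @param correlation Within-gene correlation between category memberships
#'   on the latent Gaussian scale (default 0 = independent).
#' @param max_decoys Maximum number of decoy GO terms per annotated gene
#'   (uniform on 0..max_decoys; default 3).
#' @param seed Optional integer seed consumed by
#'   [generate_annotation_table()].
#' @return A `synthetic_config` list.
#' @examples
#' synthetic_config(effects = matrix(c(1, 1.5, 1, 1, 1, 1), nrow = 3))
#' @export
synthetic_config <- function(set_sizes = c("autosomal" = 1167L,
                                           "X-linked" = 624L,
                                           "X-hemizygous" = 107L),
                             annotation_rate = 0.9,
                             base_props = c("N-mt" = 301 / 1735,
                                            "N-cp" = 346 / 1735),
                             effects = NULL,
                             target_terms = DEFAULT_TARGET_TERMS,
                             correlation = 0,
                             max_decoys = 3L,
                             seed = NULL) {
  if (is.null(names(set_sizes)) ||
      !all(names(set_sizes) %in% GENE_SETS)) {
    stop("set_sizes must be named with gene sets: ",
         paste(GENE_SETS, collapse = ", "), call. = FALSE)
  }
  if (any(set_sizes < 0) || any(set_sizes != round(set_sizes))) {
    stop("set_sizes must be non-negative integers", call. = FALSE)
  }
  annotation_rate <- rep_len(annotation_rate, length(set_sizes))
  if (any(annotation_rate < 0) || any(annotation_rate > 1)) {
    stop("annotation_rate must be in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(base_props), names(target_terms))) {
    stop("base_props and target_terms must name the same categories",
         call. = FALSE)
  }
  if (is.null(effects)) {
    effects <- matrix(1, length(set_sizes), length(base_props))
  }
  effects <- as.matrix(effects)
  if (nrow(effects) != length(set_sizes) ||
      ncol(effects) != length(base_props)) {
    stop("effects must be a ", length(set_sizes), " x ", length(base_props),
         " matrix (sets x categories)", call. = FALSE)
  }
  dimnames(effects) <- list(names(set_sizes), names(base_props))
  probs <- sweep(effects, 2L, base_props[colnames(effects)], `*`)
  if (any(probs < 0) || any(probs > 1)) {
    bad <- which(probs < 0 | probs > 1, arr.ind = TRUE)
    stop("effects push membership probability outside [0, 1] for: ",
         paste(rownames(probs)[bad[, 1]], colnames(probs)[bad[, 2]],
               sep = "/", collapse = ", "), call. = FALSE)
  }
  if (abs(correlation) > 1) {
    stop("correlation must be in [-1, 1]", call. = FALSE)
  }
  structure(
    list(set_sizes = set_sizes, annotation_rate = annotation_rate,
         base_props = base_props, effects = effects, probs = probs,
         target_terms = target_terms[names(base_props)],
         correlation = correlation, max_decoys = as.integer(max_decoys),
         seed = seed),
    class = "synthetic_config"
  )
}

## Correlated Bernoulli pair via a Gaussian copula: latent z2 is a mix of
## z1 and fresh noise; each flag thresholds its own latent at qnorm(p).
.correlated_flags <- function(n, probs, correlation) {
  k <- ncol(probs)
  z <- matrix(stats::rnorm(n * k), n, k)
  if (correlation != 0 && k >= 2L) {
    for (j in 2:k) {
      z[, j] <- correlation * z[, 1L] +
        sqrt(1 - correlation^2) * z[, j]
    }
  }
  flags <- matrix(FALSE, n, k)
  for (j in seq_len(k)) flags[, j] <- z[, j] < stats::qnorm(probs[j])
  flags
}

#' Generate a synthetic per-gene annotation table
#'
#' Draws a gene table from the generative model in a [synthetic_config()]:
#' genes are annotated at the configured rate; annotated genes join each GO
#' category with probability `effect * base_prop` for their set. Flagged
#' genes carry the category's GO identifier plus 0-3 decoy terms; annotated
#' but unflagged genes carry decoys only (possibly none).
#'
#' @param config A `synthetic_config`.
#' @return A gene table (same shape as [read_annotation_table()] output).
#' @examples
#' cfg <- synthetic_config(set_sizes = c("autosomal" = 50, "X-linked" = 30,
#'                                       "X-hemizygous" = 10), seed = 1)
#' summarize_counts(generate_annotation_table(cfg))
#' @export
generate_annotation_table <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must come from synthetic_config()", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  sets <- names(config$set_sizes)
  prefix <- c("autosomal" = "aut", "X-linked" = "xl", "X-hemizygous" = "xh")
  pieces <- vector("list", length(sets))

  for (si in seq_along(sets)) {
    s <- sets[si]
    n <- config$set_sizes[[s]]
    if (n == 0L) next
    annotated <- stats::runif(n) < config$annotation_rate[si]
    n_ann <- sum(annotated)
    go <- rep(list(character(0)), n)
    if (n_ann > 0L) {
      flags <- .correlated_flags(n_ann, config$probs[s, , drop = FALSE],
                                 config$correlation)
      n_dec <- sample.int(config$max_decoys + 1L, n_ann, replace = TRUE) - 1L
      terms <- unname(config$target_terms)
      pool <- unname(.decoy_pool)
      go[annotated] <- lapply(seq_len(n_ann), function(i) {
        c(terms[flags[i, ]],
          if (n_dec[i] > 0L) sample(pool, n_dec[i]) else character(0))
      })
    }
    df <- data.frame(
      gene_id = sprintf("%s_g%05d", prefix[[s]], seq_len(n)),
      set_label = factor(s, levels = GENE_SETS),
      annotated = annotated,
      stringsAsFactors = FALSE
    )
    df$go_terms <- go
    pieces[[si]] <- df
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  .validate_gene_table(out)
  out
}

#' Deterministic gene table reproducing the study count summary
#'
#' Builds an annotation table whose [summarize_counts()] output equals,
#' cell for cell, the published per-set counts of the *Rumex hastatulus*
#' data set (1167/624/107 genes; 1073/567/95 annotated; 194/94/13 with the
#' mitochondrion term; 222/102/22 with the chloroplast term). Gene
#' identifiers are synthetic; within each set the first genes carry the
#' category terms (a gene may carry both -- the two category analyses are
#' independent).
#'
#' @return A gene table.
#' @examples
#' summarize_counts(generate_table1_fixture())
#' @export
generate_table1_fixture <- function() {
  counts <- .table1_counts()
  prefix <- c("aut", "xl", "xh")
  pieces <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    n <- counts$n_total[i]
    idx <- seq_len(n)
    go <- rep(list(character(0)), n)
    has_mt <- idx <= counts$n_mt[i]
    has_cp <- idx <= counts$n_cp[i]
    both <- has_mt | has_cp
    go[both] <- Map(function(mt, cp) {
      c(if (mt) DEFAULT_TARGET_TERMS[["N-mt"]],
        if (cp) DEFAULT_TARGET_TERMS[["N-cp"]])
    }, has_mt[both], has_cp[both])
    df <- data.frame(
      gene_id = sprintf("%s_g%05d", prefix[i], idx),
      set_label = factor(counts$gene_set[i], levels = GENE_SETS),
      annotated = idx <= counts$n_annotated[i],
      stringsAsFactors = FALSE
    )
    df$go_terms <- go
    pieces[[i]] <- df
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
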