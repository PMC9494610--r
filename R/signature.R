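# TAT transcriptional signature: per-dataset differential expression
# between CD8+ TATs and non-clonal T cells, recurrence filtering across
# datasets, bulk-sample scoring, TIGS, and leave-one-dataset-out
# validation.

#' Construct a labelled single-cell expression object
#'
#' @param expr genes x cells numeric matrix, log-scale normalized
#'   expression, with gene row names and cell column names.
#' @param cells data.frame with one row per cell (same order as columns of
#'   \code{expr}): \code{clonotype_id}, \code{clone_frequency} (cells per
#'   clonotype), \code{tat_flag} (clonotype shared with the paired TIL
#'   repertoire), \code{cd8_flag}.
#' @param dataset_id Dataset identifier.
#' @return An object of class \code{labelled_expression}.
#' @export
labelled_expression <- function(expr, cells, dataset_id = "dataset") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  required <- c("clonotype_id", "clone_frequency", "tat_flag", "cd8_flag")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cell metadata missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cells) != ncol(expr)) {
    stop("cell metadata rows must match expression columns", call. = FALSE)
  }
  structure(list(expr = expr, cells = cells, dataset_id = dataset_id),
            class = "labelled_expression")
}

#' @export
print.labelled_expression <- function(x, ...) {
  cat(sprintf(
    "Labelled expression '%s': %d genes x %d cells (%d TAT, %d non-clonal)\n",
    x$dataset_id, nrow(x$expr), ncol(x$expr), sum(x$cells$tat_flag),
    sum(x$cells$clone_frequency == 1)))
  invisible(x)
}

# Default group selectors. Non-clonal cells are clonotypes seen exactly
# once; cells with clone_frequency == 2 fall in neither the clonal (> 2)
# nor the non-clonal (= 1) group and are excluded from both. TAT cells
# that happen to have frequency 1 are kept out of the non-clonal group.
.group_tat_cd8 <- function(cells) cells$tat_flag & cells$cd8_flag
.group_non_clonal <- function(cells) {
  cells$clone_frequency == 1 & !cells$tat_flag
}

#' Per-gene differential expression between cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene with Benjamini-Hochberg
#' adjustment; a gene is called differentially expressed when the adjusted
#' p-value is below \code{alpha} and the absolute log2 fold change (mean
#' difference on the log2 expression scale) is at least
#' \code{lfc_threshold}. Default groups are CD8+ TATs versus non-clonal
#' T cells.
#'
#' @param x A \code{labelled_expression}.
#' @param group_a,group_b Logical vectors over cells, or NULL for the
#'   defaults (TAT & CD8 vs non-clonal).
#' @param min_cells Minimum cells per group (default 20); smaller groups
#'   return NULL with a warning so the dataset is skipped.
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 0.25).
#' @return data.frame of class \code{de_table}: \code{gene},
#'   \code{log2fc}, \code{p}, \code{p_adj}, \code{de}, \code{direction},
#'   \code{dataset_id}; or NULL when a group is too small.
#' @export
de_genes <- function(x, group_a = NULL, group_b = NULL, min_cells = 20L,
                     alpha = 0.05, lfc_threshold = 0.25) {
  stopifnot(inherits(x, "labelled_expression"))
  if (is.null(group_a)) group_a <- .group_tat_cd8(x$cells)
  if (is.null(group_b)) group_b <- .group_non_clonal(x$cells)
  if (sum(group_a) < min_cells || sum(group_b) < min_cells) {
    warning(sprintf(
      "dataset %s skipped: group sizes %d and %d below min_cells = %d",
      x$dataset_id, sum(group_a), sum(group_b), min_cells), call. = FALSE)
    return(NULL)
  }
  A <- x$expr[, group_a, drop = FALSE]
  B <- x$expr[, group_b, drop = FALSE]
  lfc <- rowMeans(A) - rowMeans(B)
  p <- vapply(seq_len(nrow(A)), function(g) {
    a <- A[g, ]; b <- B[g, ]
    if (stats::var(c(a, b)) == 0) return(1)
    suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(x$expr), log2fc = lfc, p = p,
                    p_adj = p_adj,
                    de = p_adj < alpha & abs(lfc) >= lfc_threshold,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    dataset_id = x$dataset_id,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Recurrently differentially expressed signature genes
#'
#' A gene enters the signature when it is differentially expressed in
#' strictly more than \code{min_datasets} of the supplied datasets (e.g.
#' more than 10 of 14) and its direction is consistent by majority across
#' its DE calls; an exact direction tie excludes the gene.
#'
#' @param tables List of \code{de_table} objects (NULL entries from
#'   skipped datasets are dropped).
#' @param min_datasets Strict lower bound on the DE support count
#'   (default 10: support must be >= min_datasets + 1).
#' @return An object of class \code{signature_genes}: data.frame with
#'   \code{gene}, \code{direction}, \code{support}.
#' @export
recurrent_signature <- function(tables, min_datasets = 10L) {
  tables <- Filter(Negate(is.null), tables)
  if (length(tables) < 2L) stop("need at least 2 DE tables", call. = FALSE)
  de <- do.call(rbind, lapply(tables, function(t) {
    t[t$de, c("gene", "direction"), drop = FALSE]
  }))
  if (nrow(de) == 0L) {
    return(structure(data.frame(gene = character(), direction = character(),
                                support = integer()),
                     class = c("signature_genes", "data.frame"),
                     n_datasets = length(tables),
                     min_datasets = min_datasets))
  }
  n_up <- tapply(de$direction == "up", de$gene, sum)
  n_total <- tapply(rep(1L, nrow(de)), de$gene, sum)
  n_down <- n_total - n_up
  keep <- n_total > min_datasets & n_up != n_down
  out <- data.frame(gene = names(n_total)[keep],
                    direction = ifelse(n_up[keep] > n_down[keep],
                                       "up", "down"),
                    support = as.integer(n_total[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("signature_genes", "data.frame"),
            n_datasets = length(tables), min_datasets = min_datasets)
}

#' Score bulk samples with a TAT signature
#'
#' Each gene is z-scored across samples; a sample's score is the mean
#' z-score of the up-regulated signature genes minus the mean z-score of
#' the down-regulated ones. At least half the signature genes must be
#' present in the matrix.
#'
#' @param bulk genes x samples numeric matrix with gene row names.
#' @param sig A \code{signature_genes} object (or data.frame with
#'   \code{gene} and \code{direction}).
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(bulk, sig) {
  stopifnot(is.matrix(bulk), !is.null(rownames(bulk)), nrow(sig) > 0L)
  present <- sig$gene %in% rownames(bulk)
  if (mean(present) < 0.5) {
    stop("fewer than 50% of signature genes present in matrix; missing: ",
         paste(utils::head(sig$gene[!present], 10L), collapse = ", "),
         call. = FALSE)
  }
  sig <- sig[present, , drop = FALSE]
  z <- t(scale(t(bulk[sig$gene, , drop = FALSE])))
  z[is.nan(z)] <- 0  # zero-variance genes contribute nothing
  up <- sig$direction == "up"
  score <- numeric(ncol(bulk))
  if (any(up)) score <- score + colMeans(z[up, , drop = FALSE])
  if (any(!up)) score <- score - colMeans(z[!up, , drop = FALSE])
  stats::setNames(score, colnames(bulk))
}

#' Tumour immunogenicity score (TIGS)
#'
#' TIGS of a sample is its tumour mutation burden multiplied by the mean
#' expression of a set of antigen-presenting machinery genes in that
#' sample.
#'
#' @param tmb Named numeric vector of tumour mutation burden
#'   (mutations/Mb) per sample; NA gives an NA score.
#' @param expr genes x samples expression matrix covering the samples in
#'   \code{tmb}.
#' @param apm_genes Character vector of antigen-presenting genes; all must
#'   be present in \code{expr}.
#' @return Named numeric vector of TIGS values.
#' @export
tigs <- function(tmb, expr, apm_genes) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  missing_genes <- setdiff(apm_genes, rownames(expr))
  if (length(missing_genes) > 0L) {
    stop("antigen-presenting gene(s) absent from matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  samples <- if (!is.null(names(tmb))) names(tmb) else colnames(expr)
  apm_mean <- colMeans(expr[apm_genes, samples, drop = FALSE])
  stats::setNames(as.numeric(tmb) * apm_mean, samples)
}

#' Leave-one-dataset-out validation of the TAT signature
#'
#' For each held-out dataset, the signature is re-derived from the
#' remaining datasets' DE tables, a logistic regression on the
#' signature-gene expression is fitted to the remaining datasets' cells
#' (CD8+ TAT vs non-clonal), and the TAT-vs-non-clonal ROC-AUC is
#' evaluated on the held-out cells. Signature genes absent from the
#' held-out matrix are imputed as zero with a warning.
#'
#' @param datasets List of \code{labelled_expression} objects (>= 3).
#' @param min_datasets Recurrence bound passed to
#'   \code{\link{recurrent_signature}}, applied to the reduced dataset
#'   list; defaults to ceiling(0.75 * (n - 1)) so the strictness of the
#'   full-data rule is preserved.
#' @param ... Passed to \code{\link{de_genes}}.
#' @return data.frame of class \code{lodo_result}: \code{dataset_id},
#'   \code{auc}, \code{n_signature}.
#' @export
loo_dataset_validation <- function(datasets, min_datasets = NULL, ...) {
  if (length(datasets) < 3L) stop("need at least 3 datasets", call. = FALSE)
  if (is.null(min_datasets)) {
    min_datasets <- ceiling(0.75 * (length(datasets) - 1L)) - 1L
  }
  tables <- lapply(datasets, de_genes, ...)
  out <- data.frame(dataset_id = character(), auc = numeric(),
                    n_signature = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(datasets)) {
    held <- datasets[[i]]
    sig <- recurrent_signature(tables[-i], min_datasets = min_datasets)
    if (nrow(sig) == 0L) {
      warning("no signature genes for held-out dataset ", held$dataset_id,
              call. = FALSE)
      out[nrow(out) + 1L, ] <- list(held$dataset_id, NA_real_, 0L)
      next
    }
    train_x <- list(); train_y <- list()
    for (d in datasets[-i]) {
      ga <- .group_tat_cd8(d$cells); gb <- .group_non_clonal(d$cells)
      sel <- ga | gb
      feats <- .signature_features(d$expr, sig$gene)
      train_x[[length(train_x) + 1L]] <- t(feats[, sel, drop = FALSE])
      train_y[[length(train_y) + 1L]] <- as.integer(ga[sel])
    }
    fit_df <- as.data.frame(do.call(rbind, train_x))
    names(fit_df) <- paste0("g", seq_len(ncol(fit_df)))
    fit_df$y <- unlist(train_y)
    fit <- suppressWarnings(
      stats::glm(y ~ ., family = stats::binomial(), data = fit_df))
    ga <- .group_tat_cd8(held$cells); gb <- .group_non_clonal(held$cells)
    sel <- ga | gb
    test_feats <- .signature_features(held$expr, sig$gene, warn_id =
                                        held$dataset_id)
    test_df <- as.data.frame(t(test_feats[, sel, drop = FALSE]))
    names(test_df) <- paste0("g", seq_len(nrow(test_feats)))
    p <- stats::predict(fit, newdata = test_df, type = "response")
    y <- as.integer(ga[sel])
    out[nrow(out) + 1L, ] <- list(held$dataset_id, roc_auc(y, p),
                                  nrow(sig))
  }
  class(out) <- c("lodo_result", "data.frame")
  out
}

# Extract signature-gene rows, zero-imputing absent genes.
.signature_features <- function(expr, genes, warn_id = NULL) {
  present <- genes %in% rownames(expr)
  if (!all(present) && !is.null(warn_id)) {
    warning(sprintf("dataset %s missing %d signature gene(s); imputed as 0",
                    warn_id, sum(!present)), call. = FALSE)
  }
  m <- matrix(0, length(genes), ncol(expr),
              dimnames = list(genes, colnames(expr)))
  m[present, ] <- expr[genes[present], , drop = FALSE]
  m
}

#' Permutation test of a discrimination AUC
#'
#' Compares an observed ROC-AUC with its null distribution obtained by
#' permuting the class labels.
#'
#' @param labels Binary labels.
#' @param scores Numeric scores.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return List: \code{auc}, \code{perm_auc} (vector), \code{p_value}
#'   (one-sided, with the +1 correction), \code{q95} (95th percentile of
#'   the null).
#' @export
permutation_auc_test <- function(labels, scores, n_perm = 1000L, seed = 1L) {
  labels <- as.integer(labels == 1 | labels == TRUE)
  observed <- .auc_rank(labels, scores)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    .auc_rank(sample(labels), scores)
  }, numeric(1))
  list(auc = observed, perm_auc = perm,
       p_value = (sum(perm >= observed) + 1) / (n_perm + 1),
       q95 = stats::quantile(perm, 0.95, names = FALSE))
}
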