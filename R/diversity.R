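# Clone-size diversity statistics: Shannon entropy, clonality, Gini.
#
# Clonality is 1 - H / ln(richness) (normalized Shannon entropy), the
# standard repertoire definition: 0 for a perfectly even repertoire,
# approaching 1 when a single clone dominates. The Gini coefficient is the
# mean absolute difference form G = sum_ij |c_i - c_j| / (2 n sum(c)),
# without small-sample correction (the n/(n-1) factor is exposed as an
# option).

#' Shannon entropy of a clone-count vector
#'
#' @param counts Vector of positive counts, length >= 1.
#' @return Entropy in nats: \eqn{H = -\sum p_i \log p_i}.
#' @export
shannon_entropy <- function(counts) {
  if (!.is_count_vector(counts) || any(counts < 1)) {
    stop("counts must be a non-empty vector of positive values",
         call. = FALSE)
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Repertoire clonality
#'
#' \code{1 - H / log(richness)}. Undefined (NA with a warning) for a
#' single-clone repertoire, where both entropy and its maximum are zero.
#'
#' @param counts Vector of positive clone counts.
#' @return Clonality in [0, 1], or NA for richness 1.
#' @export
clonality <- function(counts) {
  if (!.is_count_vector(counts) || any(counts < 1)) {
    stop("counts must be a non-empty vector of positive values",
         call. = FALSE)
  }
  if (length(counts) == 1L) {
    warning("clonality is undefined for a single clone (0/0); returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  1 - shannon_entropy(counts) / log(length(counts))
}

#' Gini coefficient of clone sizes
#'
#' Mean-absolute-difference form over all clone pairs:
#' \eqn{G = \sum_i \sum_j |c_i - c_j| / (2 n \sum c)}. Computed via the
#' equivalent sorted form in O(n log n).
#'
#' @param counts Vector of non-negative counts with positive sum.
#' @param corrected If TRUE, apply the small-sample factor n/(n-1).
#' @return Gini coefficient in [0, 1).
#' @export
gini <- function(counts, corrected = FALSE) {
  if (!.is_count_vector(counts) || any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be non-negative with a positive sum", call. = FALSE)
  }
  n <- length(counts)
  x <- sort(counts)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i), for sorted x
  g <- sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  if (corrected && n > 1L) g <- g * n / (n - 1)
  g
}

#' Diversity summary of a repertoire
#'
#' @param rep A \code{tcr_repertoire}.
#' @return One-row data.frame: \code{sample_id}, \code{richness},
#'   \code{shannon_entropy}, \code{clonality}, \code{gini}.
#' @export
repertoire_diversity <- function(rep) {
  .stop_if_not_repertoire(rep)
  counts <- rep$clones$count
  if (length(counts) == 0L) {
    return(data.frame(sample_id = rep$sample_id, richness = 0L,
                      shannon_entropy = NA_real_, clonality = NA_real_,
                      gini = NA_real_, stringsAsFactors = FALSE))
  }
  data.frame(sample_id = rep$sample_id,
             richness = length(counts),
             shannon_entropy = shannon_entropy(counts),
             clonality = if (length(counts) > 1L) clonality(counts)
                         else NA_real_,
             gini = gini(counts),
             stringsAsFactors = FALSE)
}

#' Correlate shared-TCR proportion with overall diversity
#'
#' Spearman rank correlation between the per-subject shared proportion in a
#' tissue and that tissue's overall clonality and Gini coefficient. The
#' shared proportion is observable only when tumour tissue is sequenced,
#' while PBMC clonality/Gini are obtained non-invasively, so a strong
#' correlation in PBMCs supports their use as indicators.
#'
#' @param summaries data.frame of rows from \code{\link{overlap_proportion}}.
#' @param diversities data.frame of rows from
#'   \code{\link{repertoire_diversity}}, matched to \code{summaries} by
#'   position.
#' @param tissue \code{"PBMC"} or \code{"TIL"}: which tissue's shared
#'   proportion to use.
#' @return data.frame with one row per metric (clonality, gini): columns
#'   \code{metric}, \code{rho}, \code{p_value}.
#' @export
correlate_overlap_diversity <- function(summaries, diversities,
                                        tissue = c("PBMC", "TIL")) {
  tissue <- match.arg(tissue)
  if (nrow(summaries) < 3L || nrow(summaries) != nrow(diversities)) {
    stop("need >= 3 paired samples with matching diversity rows",
         call. = FALSE)
  }
  prop <- if (tissue == "PBMC") summaries$pbmc_shared_prop_seq
          else summaries$til_shared_prop_seq
  out <- lapply(c("clonality", "gini"), function(metric) {
    ct <- suppressWarnings(
      stats::cor.test(prop, diversities[[metric]], method = "spearman"))
    data.frame(metric = metric, rho = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-group comparison of diversity or score values
#'
#' Two-sided Mann-Whitney U test (Wilcoxon rank-sum), the test used for
#' all between-compartment and between-risk-group comparisons. No
#' multiple-testing correction is applied.
#'
#' @param values_a,values_b Numeric vectors, each non-empty.
#' @param test Currently only \code{"mann_whitney"}.
#' @return List with \code{statistic} (U for the first group) and
#'   \code{p_value}.
#' @export
group_compare <- function(values_a, values_b, test = "mann_whitney") {
  test <- match.arg(test, "mann_whitney")
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
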