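# Shared internal helpers.

#' @importFrom pROC roc auc
#' @importFrom stats predict
NULL

# The 20 standard amino acids, fixed ordering used by the one-hot encoder
# and all positional frequency matrices.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Area under the ROC curve
#'
#' Thin wrapper around \code{pROC::auc} with the orientation fixed so that
#' higher scores for the positive class give AUC > 0.5.
#'
#' @param labels Binary vector (0/1, logical, or two-level factor); 1/TRUE is
#'   the positive class.
#' @param scores Numeric scores, higher meaning more positive-like.
#' @return AUC as a plain numeric scalar in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  keep <- !is.na(scores) & !is.na(labels)
  labels <- labels[keep]; scores <- scores[keep]
  if (length(unique(labels)) < 2L) {
    stop("roc_auc() needs both classes present")
  }
  as.numeric(pROC::auc(pROC::roc(labels, scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

# Fast rank-based AUC used in tight permutation loops; equals the
# Mann-Whitney U statistic scaled to [0,1]. pROC remains the user-facing path.
.auc_rank <- function(labels, scores) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.is_count_vector <- function(x) {
  is.numeric(x) && length(x) >= 1L && all(is.finite(x))
}

.stop_if_not_repertoire <- function(x, arg = "rep") {
  if (!inherits(x, "tcr_repertoire")) {
    stop(sprintf("`%s` must be a tcr_repertoire object", arg), call. = FALSE)
  }
}
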