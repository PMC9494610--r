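# TCR repertoire risk score (TRRS).
#
# For one PBMC sample, the TRRS is the number of distinct CDR3 sequences
# the classifier calls TAT-like (probability above a cutoff, default .66)
# divided by the number of distinct sequences that overlap the healthy
# reference pool. Both counts are over unique CDR3 sequences, not
# count-weighted clones, and a sequence may contribute to both counts (a
# mutually-exclusive variant is available).

.trrs_from_probs <- function(seqs, probs, pool, prob_threshold,
                             count_weights = NULL, exclusive = FALSE) {
  in_pool <- seqs %in% pool$sequences
  above <- !is.na(probs) & probs > prob_threshold
  if (exclusive) above <- above & !in_pool
  w <- if (is.null(count_weights)) rep(1, length(seqs)) else count_weights
  n_tat <- sum(w[above])
  n_overlap <- sum(w[in_pool])
  trrs <- if (n_overlap > 0) n_tat / n_overlap else NA_real_
  list(n_predicted_tats = n_tat, n_healthy_overlap = n_overlap, trrs = trrs)
}

#' Compute the TCR repertoire risk score for one sample
#'
#' @param rep A \code{tcr_repertoire}, already functional- and
#'   length-filtered (see \code{\link{filter_functional}},
#'   \code{\link{filter_length}}).
#' @param model A fitted \code{\link{tat_cnn}}.
#' @param pool The healthy reference \code{tcr_pool} (TRRS denominator).
#' @param prob_threshold Per-sequence probability cutoff above which a
#'   sequence counts as a predicted TAT (default 0.66).
#' @param count_weighted If TRUE, weight both counts by clone template
#'   counts instead of unique sequences.
#' @param exclusive If TRUE, pool-overlapping sequences are excluded from
#'   the numerator.
#' @return One-row data.frame: \code{sample_id}, \code{n_predicted_tats},
#'   \code{n_healthy_overlap}, \code{trrs}, \code{prob_threshold}. A
#'   sample with zero pool overlap gets NA with a warning.
#' @export
compute_trrs <- function(rep, model, pool, prob_threshold = 0.66,
                         count_weighted = FALSE, exclusive = FALSE) {
  .stop_if_not_repertoire(rep)
  stopifnot(inherits(model, "tat_cnn"), inherits(pool, "tcr_pool"))
  seqs <- unique(rep$clones$cdr3_aa)
  probs <- predict(model, seqs)
  w <- NULL
  if (count_weighted) {
    w <- as.numeric(tapply(rep$clones$count,
                           factor(rep$clones$cdr3_aa, levels = seqs), sum))
  }
  r <- .trrs_from_probs(seqs, probs, pool, prob_threshold,
                        count_weights = w, exclusive = exclusive)
  if (is.na(r$trrs)) {
    warning("sample ", rep$sample_id,
            " has no overlap with the healthy pool; TRRS undefined",
            call. = FALSE)
  }
  data.frame(sample_id = rep$sample_id,
             n_predicted_tats = r$n_predicted_tats,
             n_healthy_overlap = r$n_healthy_overlap,
             trrs = r$trrs, prob_threshold = prob_threshold,
             stringsAsFactors = FALSE)
}

#' Score a cohort of PBMC samples and evaluate discrimination
#'
#' @param reps List of filtered \code{tcr_repertoire} objects.
#' @param model,pool,prob_threshold As in \code{\link{compute_trrs}}.
#' @param labels Optional binary vector (1 = tumour) aligned with
#'   \code{reps}; when both classes are present the TRRS ROC-AUC is
#'   reported.
#' @return An object of class \code{trrs_cohort}: list with
#'   \code{results} (per-sample TRRS table, including \code{label} when
#'   given) and \code{auc} (NA when labels are absent or single-class).
#' @export
score_cohort <- function(reps, model, pool, labels = NULL,
                         prob_threshold = 0.66) {
  res <- do.call(rbind, lapply(reps, compute_trrs, model = model,
                               pool = pool,
                               prob_threshold = prob_threshold))
  auc <- NA_real_
  if (!is.null(labels)) {
    res$label <- labels
    if (length(unique(labels)) >= 2L) {
      auc <- roc_auc(labels, res$trrs)
    }
  }
  structure(list(results = res, auc = auc,
                 prob_threshold = prob_threshold),
            class = "trrs_cohort")
}

#' @export
print.trrs_cohort <- function(x, ...) {
  cat(sprintf("TRRS cohort: %d samples, threshold %.2f\n",
              nrow(x$results), x$prob_threshold))
  if (!is.na(x$auc)) cat(sprintf("  tumour-vs-healthy ROC-AUC: %.3f\n",
                                 x$auc))
  invisible(x)
}

#' Robustness of cohort discrimination to the probability cutoff
#'
#' Recomputes the cohort TRRS ROC-AUC over a grid of per-sequence
#' probability cutoffs. Predictions are computed once per sample and
#' reused across the grid.
#'
#' @param reps,model,pool,labels As in \code{\link{score_cohort}}.
#' @param thresholds Numeric grid of cutoffs in (0, 1]; values of 1 or
#'   above give all-zero scores and a degenerate AUC of 0.5.
#' @return data.frame with columns \code{threshold} and \code{auc}.
#' @export
threshold_sensitivity <- function(reps, model, pool, labels,
                                  thresholds = c(0.5, 0.6, 0.66, 0.7, 0.8)) {
  stopifnot(length(unique(labels)) >= 2L)
  per_sample <- lapply(reps, function(r) {
    seqs <- unique(r$clones$cdr3_aa)
    list(seqs = seqs, probs = predict(model, seqs))
  })
  auc <- vapply(thresholds, function(th) {
    scores <- vapply(per_sample, function(s) {
      .trrs_from_probs(s$seqs, s$probs, pool, th)$trrs
    }, numeric(1))
    if (all(is.na(scores)) || length(unique(scores[!is.na(scores)])) < 2L) {
      return(0.5)
    }
    roc_auc(labels, scores)
  }, numeric(1))
  data.frame(threshold = thresholds, auc = auc)
}

#' Split samples into high- and low-risk groups
#'
#' Samples at or above the TRRS quantile cutoff (median by default) are
#' labelled high risk; ties at the cutoff go to the high group.
#'
#' @param results data.frame of TRRS results (from
#'   \code{\link{compute_trrs}} rows or \code{\link{score_cohort}}).
#' @param quantile Quantile cutoff in (0, 1); default 0.5.
#' @return Character vector ("high"/"low") aligned with the rows of
#'   \code{results}; NA scores give NA labels.
#' @export
risk_groups <- function(results, quantile = 0.5) {
  trrs <- results$trrs
  if (all(is.na(trrs))) stop("all TRRS values are missing", call. = FALSE)
  if (length(trrs) < 2L) stop("need at least 2 samples", call. = FALSE)
  cut <- stats::quantile(trrs, quantile, na.rm = TRUE, names = FALSE)
  ifelse(is.na(trrs), NA_character_, ifelse(trrs >= cut, "high", "low"))
}
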