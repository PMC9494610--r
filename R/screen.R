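# Combined screening model: logistic regression on the TRRS and the TAT
# signature score, giving the final cancer risk score as the predicted
# probability.

#' Fit the combined cancer screening model
#'
#' Maximum-likelihood logistic regression of tumour status on the
#' z-standardized TRRS and TAT signature score. Under complete separation
#' (or non-convergence) the fit falls back to a small fixed ridge penalty
#' (1e-4 on the slopes) with a warning, which keeps coefficients finite
#' while leaving well-posed fits untouched.
#'
#' @param trrs_scores,sig_scores Numeric feature vectors.
#' @param labels Binary outcome (1 = tumour).
#' @param standardize Z-standardize features before fitting (default TRUE;
#'   the standardization constants are stored so prediction is on the
#'   original feature scale).
#' @param ridge_penalty Fallback L2 penalty.
#' @return An object of class \code{screen_model} with coefficients,
#'   standardization parameters, and fit metadata.
#' @export
fit_screen <- function(trrs_scores, sig_scores, labels, standardize = TRUE,
                       ridge_penalty = 1e-4) {
  y <- as.integer(labels == 1 | labels == TRUE)
  ok <- !is.na(trrs_scores) & !is.na(sig_scores) & !is.na(y)
  x1 <- trrs_scores[ok]; x2 <- sig_scores[ok]; y <- y[ok]
  if (length(y) < 6L || length(unique(y)) < 2L) {
    stop("need >= 6 samples with both classes present", call. = FALSE)
  }
  center <- c(trrs = 0, sig = 0); scale_ <- c(trrs = 1, sig = 1)
  if (standardize) {
    center <- c(trrs = mean(x1), sig = mean(x2))
    scale_ <- c(trrs = stats::sd(x1), sig = stats::sd(x2))
    scale_[scale_ == 0] <- 1  # constant feature: leave unscaled
    x1 <- (x1 - center["trrs"]) / scale_["trrs"]
    x2 <- (x2 - center["sig"]) / scale_["sig"]
  }
  X <- cbind(`(Intercept)` = 1, trrs = x1, sig = x2)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- fit$coefficients
  method <- "ml"
  if (separated || !fit$converged || any(!is.finite(coefs)) ||
      any(abs(coefs[-1]) > 1e3)) {
    warning("complete separation detected; refitting with ridge penalty ",
            ridge_penalty, call. = FALSE)
    coefs <- .ridge_logistic(X, y, lambda = ridge_penalty)
    method <- "ridge"
  }
  structure(list(coefficients = coefs, center = center, scale = scale_,
                 standardize = standardize, method = method,
                 n = length(y), n_pos = sum(y)),
            class = "screen_model")
}

# Penalized Newton (IRLS) logistic fit; intercept unpenalized.
.ridge_logistic <- function(X, y, lambda, max_iter = 200L, tol = 1e-10) {
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    grad <- crossprod(X, y - p) - pen %*% beta
    H <- crossprod(X, X * W) + pen
    step <- solve(H + diag(1e-12, ncol(X)), grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  stats::setNames(drop(beta), colnames(X))
}

#' @export
print.screen_model <- function(x, ...) {
  cat(sprintf(
    "Combined screening model (%s fit, %d samples, %d tumour)\n",
    ifelse(x$method == "ridge", "ridge-penalized", "maximum-likelihood"),
    x$n, x$n_pos))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.screen_model <- function(object, ...) object$coefficients

#' @export
summary.screen_model <- function(object, ...) {
  print(object)
  if (object$standardize) {
    cat("feature standardization (mean / sd):\n")
    print(rbind(center = object$center, scale = object$scale))
  }
  invisible(object)
}

#' Final cancer risk score
#'
#' The risk score of a sample is the predicted probability of the combined
#' logistic model given its TRRS and signature score.
#'
#' @param model A fitted \code{screen_model}.
#' @param trrs,sig Feature values (vectors of equal length); NA in either
#'   gives an NA risk.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
cancer_risk <- function(model, trrs, sig) {
  stopifnot(inherits(model, "screen_model"))
  x1 <- (trrs - model$center["trrs"]) / model$scale["trrs"]
  x2 <- (sig - model$center["sig"]) / model$scale["sig"]
  eta <- model$coefficients["(Intercept)"] +
    model$coefficients["trrs"] * x1 + model$coefficients["sig"] * x2
  unname(1 / (1 + exp(-eta)))
}

#' @export
predict.screen_model <- function(object, trrs, sig, ...) {
  cancer_risk(object, trrs, sig)
}

#' Cross-validated comparison of TRRS, signature, and combined models
#'
#' Fits single-feature and combined logistic models on the same
#' cross-validation folds (leave-one-out by default, suited to small
#' validation cohorts) and reports both cross-validated and in-sample
#' ROC-AUC for each feature set.
#'
#' @param trrs,sig,labels As in \code{\link{fit_screen}}.
#' @param k Number of folds; default \code{length(labels)} (leave-one-out).
#' @param seed Seed for fold assignment when k < n.
#' @return data.frame with one row per feature set (\code{trrs_only},
#'   \code{signature_only}, \code{combined}): \code{auc_cv},
#'   \code{auc_insample}.
#' @export
compare_components <- function(trrs, sig, labels, k = length(labels),
                               seed = 1L) {
  y <- as.integer(labels == 1 | labels == TRUE)
  n <- length(y)
  stopifnot(length(trrs) == n, length(sig) == n, min(table(y)) >= 2L)
  k <- min(k, n)
  set.seed(seed)
  fold <- if (k == n) seq_len(n) else sample(rep_len(seq_len(k), n))
  feature_sets <- list(trrs_only = cbind(trrs),
                       signature_only = cbind(sig),
                       combined = cbind(trrs, sig))
  one_set <- function(X) {
    Xs <- scale(X)
    Xs[, apply(X, 2, stats::sd) == 0] <- 0
    cv_pred <- rep(NA_real_, n)
    for (f in unique(fold)) {
      test <- fold == f
      if (length(unique(y[!test])) < 2L) next
      beta <- .ridge_logistic(cbind(1, Xs[!test, , drop = FALSE]), y[!test],
                              lambda = 1e-4)
      cv_pred[test] <- drop(cbind(1, Xs[test, , drop = FALSE]) %*% beta)
    }
    beta_full <- .ridge_logistic(cbind(1, Xs), y, lambda = 1e-4)
    c(auc_cv = roc_auc(y[!is.na(cv_pred)], cv_pred[!is.na(cv_pred)]),
      auc_insample = roc_auc(y, drop(cbind(1, Xs) %*% beta_full)))
  }
  res <- t(vapply(feature_sets, one_set, numeric(2)))
  data.frame(feature_set = rownames(res), auc_cv = res[, "auc_cv"],
             auc_insample = res[, "auc_insample"], row.names = NULL,
             stringsAsFactors = FALSE)
}
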