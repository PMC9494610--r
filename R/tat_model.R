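# TAT CDR3 classifier: training-set assembly, one-hot encoding, the
# convolutional model fit, patient-level cross-validation and positional
# motif enrichment.

#' One-hot encode a CDR3 amino-acid sequence
#'
#' Encodes a CDR3 beta-chain sequence as a \code{max_len} x 21 matrix: one
#' row per position, 20 amino-acid channels plus a dedicated padding
#' channel (column 21) marking rows beyond the sequence end. Every row is
#' exactly one-hot. Sequences outside the accepted length range or with
#' non-standard letters raise an error.
#'
#' @param seq Amino-acid string using the 20 standard letters.
#' @param max_len Padded length (default 17).
#' @param min_len Minimum accepted length (default 12).
#' @return A \code{max_len} x 21 numeric matrix with the source sequence
#'   attached as attribute \code{"sequence"}.
#' @export
encode_cdr3 <- function(seq, max_len = 17L, min_len = 12L) {
  n <- nchar(seq)
  if (is.na(seq) || n < min_len || n > max_len) {
    stop(sprintf("sequence length %d outside [%d, %d]: %s", n, min_len,
                 max_len, seq), call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    stop("invalid amino-acid letter(s) in sequence: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, max_len, 21L,
              dimnames = list(NULL, c(AA_ALPHABET, "pad")))
  m[cbind(seq_len(n), idx)] <- 1
  if (n < max_len) m[(n + 1):max_len, 21L] <- 1
  attr(m, "sequence") <- seq
  m
}

#' Decode a one-hot CDR3 matrix back to its sequence
#'
#' @param mat A matrix produced by \code{\link{encode_cdr3}}.
#' @return The amino-acid string (padding rows dropped).
#' @export
decode_cdr3 <- function(mat) {
  idx <- max.col(mat, ties.method = "first")
  idx <- idx[idx <= 20L]
  paste(AA_ALPHABET[idx], collapse = "")
}

# Batch encoder: returns the position-major (N*L) x 21 matrix the conv
# engine consumes, or NULL rows marked in `bad` for unencodable input.
.encode_batch <- function(seqs, max_len = 17L, min_len = 12L) {
  n <- length(seqs)
  len <- nchar(seqs)
  bad <- is.na(seqs) | len < min_len | len > max_len
  chan <- matrix(21L, n, max_len)
  ok <- which(!bad)
  if (length(ok) > 0L) {
    split_chars <- strsplit(seqs[ok], "")
    for (j in seq_along(ok)) {
      idx <- match(split_chars[[j]], AA_ALPHABET)
      if (anyNA(idx)) {
        bad[ok[j]] <- TRUE
      } else {
        chan[ok[j], seq_along(idx)] <- idx
      }
    }
  }
  X <- matrix(0, n * max_len, 21L)
  rows <- rep(seq_len(n), max_len) + (rep(seq_len(max_len), each = n) - 1L) * n
  X[cbind(rows, as.vector(chan))] <- 1
  list(X = X, bad = bad)
}

#' Assemble the TAT-vs-healthy training set
#'
#' Positives are the distinct CDR3 sequences of the circulating
#' tumour-associated T cells (PBMCs_Shared clones), minus any sequence
#' present in the healthy pool and minus any sequence in the optional
#' virus/bacteria exclusion list. Negatives are drawn uniformly without
#' replacement from the (exclusion-filtered) healthy pool, one per
#' positive. Sequences are deduplicated globally; a sequence seen in
#' several subjects keeps its first subject for the patient-level split.
#' Only sequences encodable at the configured lengths are retained.
#'
#' @param tat_reps List of \code{tcr_repertoire} objects already restricted
#'   to their PBMCs_Shared compartment (see \code{\link{extract_tats}}).
#' @param healthy_pool A \code{tcr_pool} of healthy CDR3 sequences.
#' @param exclusion Optional \code{tcr_pool} of virus/bacteria-associated
#'   sequences removed from both classes.
#' @param seed Integer seed for negative sampling.
#' @param min_len,max_len Encodable length range (defaults 12, 17).
#' @return An object of class \code{tat_training_set}: data.frame with
#'   columns \code{cdr3_aa}, \code{label} (1 = TAT, 0 = healthy),
#'   \code{subject_id}, plus a provenance attribute.
#' @export
build_training_set <- function(tat_reps, healthy_pool, exclusion = NULL,
                               seed = 1L, min_len = 12L, max_len = 17L) {
  stopifnot(inherits(healthy_pool, "tcr_pool"))
  if (inherits(tat_reps, "tcr_repertoire")) tat_reps <- list(tat_reps)
  pos <- do.call(rbind, lapply(tat_reps, function(r) {
    data.frame(cdr3_aa = r$clones$cdr3_aa, subject_id = r$subject_id,
               stringsAsFactors = FALSE)
  }))
  pos <- pos[!duplicated(pos$cdr3_aa), , drop = FALSE]
  len <- nchar(pos$cdr3_aa)
  pos <- pos[len >= min_len & len <= max_len &
             !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                    pos$cdr3_aa), , drop = FALSE]
  excl <- if (is.null(exclusion)) character() else exclusion$sequences
  pool_seqs <- setdiff(healthy_pool$sequences, excl)
  plen <- nchar(pool_seqs)
  pool_seqs <- pool_seqs[plen >= min_len & plen <= max_len]
  pos <- pos[!(pos$cdr3_aa %in% healthy_pool$sequences) &
             !(pos$cdr3_aa %in% excl), , drop = FALSE]
  if (nrow(pos) == 0L) {
    warning("no positive sequences remain after pool/exclusion filtering",
            call. = FALSE)
  }
  if (length(pool_seqs) < nrow(pos)) {
    stop(sprintf(
      "healthy pool (%d usable sequences) smaller than positive set (%d)",
      length(pool_seqs), nrow(pos)), call. = FALSE)
  }
  set.seed(seed)
  neg <- sample(pool_seqs, nrow(pos), replace = FALSE)
  ts <- data.frame(
    cdr3_aa = c(pos$cdr3_aa, neg),
    label = rep(c(1L, 0L), c(nrow(pos), length(neg))),
    subject_id = c(pos$subject_id, rep(healthy_pool$label, length(neg))),
    stringsAsFactors = FALSE)
  rownames(ts) <- NULL
  structure(ts, class = c("tat_training_set", "data.frame"),
            provenance = list(seed = seed, min_len = min_len,
                              max_len = max_len,
                              pool = healthy_pool$label,
                              n_excluded = length(excl)))
}

#' Fit the TAT convolutional classifier
#'
#' Trains a three-layer 1-D convolutional network on one-hot encoded CDR3
#' beta sequences to output the probability that a sequence comes from a
#' tumour-associated T cell. Variable lengths are handled by padding to
#' \code{max_len} with a dedicated 21st channel in a single model. The
#' default architecture is three convolution layers (kernel width 3,
#' same-padding, ReLU; 32/64/128 channels), global max-pooling over
#' positions, and one dense sigmoid unit, trained with binary
#' cross-entropy and Adam.
#'
#' @param ts A \code{tat_training_set} (or any data.frame with columns
#'   \code{cdr3_aa} and binary \code{label}).
#' @param epochs Training epochs (default 60, where loss and accuracy
#'   typically plateau).
#' @param batch_size Minibatch size (default 256).
#' @param lr Adam learning rate (default 1e-3).
#' @param channels Convolution channel widths (default c(32, 64, 128)).
#' @param max_len,min_len Encodable length range.
#' @param seed Integer seed controlling initialization and batch shuffling;
#'   mandatory for reproducibility.
#' @param verbose Print per-epoch loss/accuracy.
#' @return An object of class \code{tat_cnn} with elements \code{params}
#'   (network weights), \code{config}, and \code{history} (per-epoch loss
#'   and accuracy).
#' @export
tat_cnn <- function(ts, epochs = 60L, batch_size = 256L, lr = 1e-3,
                    channels = c(32L, 64L, 128L), max_len = 17L,
                    min_len = 12L, seed = 1L, verbose = FALSE) {
  stopifnot(is.data.frame(ts), all(c("cdr3_aa", "label") %in% names(ts)))
  y_all <- as.integer(ts$label)
  if (length(unique(y_all)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  enc <- .encode_batch(ts$cdr3_aa, max_len, min_len)
  if (any(enc$bad)) {
    stop(sum(enc$bad), " training sequence(s) not encodable", call. = FALSE)
  }
  n <- length(y_all)
  L <- max_len
  set.seed(seed)
  params <- .cnn_init(21L, channels)
  state <- .adam_state(params)
  history <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                        accuracy = NA_real_)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n, by = batch_size)) {
      b <- ord[start:min(start + batch_size - 1L, n)]
      N <- length(b)
      rows <- rep(b, L) + (rep(seq_len(L), each = N) - 1L) * n
      Xb <- enc$X[rows, , drop = FALSE]
      yb <- y_all[b]
      fwd <- .cnn_forward(params, Xb, N, L, keep = TRUE)
      g <- .cnn_backward(params, fwd, yb, N, L)
      upd <- .adam_step(params, g, state, lr = lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + .bce_loss(fwd$p, yb) * N
      ep_correct <- ep_correct + sum((fwd$p > 0.5) == (yb == 1L))
    }
    history$loss[e] <- ep_loss / n
    history$accuracy[e] <- ep_correct / n
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.4f", e,
                      history$loss[e], history$accuracy[e]))
    }
  }
  structure(list(params = params,
                 config = list(epochs = epochs, batch_size = batch_size,
                               lr = lr, channels = channels,
                               kernel = 3L, max_len = max_len,
                               min_len = min_len, seed = seed,
                               n_train = n),
                 history = history,
                 version = "tat_cnn/1"),
            class = "tat_cnn")
}

#' @export
print.tat_cnn <- function(x, ...) {
  cat("TAT CDR3 convolutional classifier\n")
  cat(sprintf("  conv layers: %s channels, kernel %d, padded length %d\n",
              paste(x$config$channels, collapse = "/"), x$config$kernel,
              x$config$max_len))
  cat(sprintf("  trained %d epochs on %d sequences (seed %d)\n",
              x$config$epochs, x$config$n_train, x$config$seed))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final training loss %.4f, accuracy %.4f\n",
              h$loss, h$accuracy))
  invisible(x)
}

#' @export
summary.tat_cnn <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$params$conv,
                      function(l) length(l$W) + length(l$b), numeric(1))) +
    length(object$params$dense$W) + 1L
  cat(sprintf("  %d trainable parameters\n", n_par))
  invisible(object$history)
}

#' Plot the training trace of a TAT classifier
#'
#' Loss and accuracy per epoch; the curves should plateau well before the
#' final epoch under the defaults.
#'
#' @param x A \code{tat_cnn}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.tat_cnn <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$loss, x$history$accuracy),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "value", ...)
  graphics::legend("right", legend = c("loss", "accuracy"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Predict TAT probabilities for CDR3 sequences
#'
#' @param object A fitted \code{tat_cnn}.
#' @param seqs Character vector of CDR3 amino-acid sequences.
#' @param batch_size Sequences scored per internal batch.
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1], order preserved;
#'   unencodable sequences yield NA with one warning.
#' @export
predict.tat_cnn <- function(object, seqs, batch_size = 4096L, ...) {
  L <- object$config$max_len
  out <- rep(NA_real_, length(seqs))
  enc <- .encode_batch(seqs, L, object$config$min_len)
  if (any(enc$bad)) {
    warning(sum(enc$bad),
            " sequence(s) not encodable; returning NA for them",
            call. = FALSE)
  }
  ok <- which(!enc$bad)
  n_all <- length(seqs)
  for (start in seq(1L, length(ok), by = batch_size)) {
    b <- ok[start:min(start + batch_size - 1L, length(ok))]
    N <- length(b)
    rows <- rep(b, L) + (rep(seq_len(L), each = N) - 1L) * n_all
    fwd <- .cnn_forward(object$params, enc$X[rows, , drop = FALSE], N, L)
    out[b] <- fwd$p
  }
  out
}

#' Save / load a fitted TAT classifier
#'
#' The archive contains the architecture and training configuration with
#' the network parameters, version-stamped; loading restores an object
#' whose predictions are bit-identical to the saved model's.
#'
#' @param model A \code{tat_cnn}.
#' @param path File path.
#' @return \code{save_tat_cnn}: \code{path} invisibly;
#'   \code{load_tat_cnn}: the restored \code{tat_cnn}.
#' @export
save_tat_cnn <- function(model, path) {
  stopifnot(inherits(model, "tat_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tat_cnn
#' @export
load_tat_cnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tat_cnn") || !identical(model$version, "tat_cnn/1")) {
    stop("file does not contain a compatible tat_cnn archive", call. = FALSE)
  }
  model
}

# Average precision (step-wise area under the precision-recall curve).
.prc_auc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(labels[ord] == 1L)
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision * y) / sum(y)
}

#' Patient-level k-fold cross-validation of the TAT classifier
#'
#' Positive sequences are split by subject (patient), never by sequence,
#' so that no patient contributes to both the training and test side of a
#' fold; negatives are split randomly. Reports per-fold ROC and
#' precision-recall AUC.
#'
#' @param ts A \code{tat_training_set}.
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment (training seeds derive from it).
#' @param ... Passed to \code{\link{tat_cnn}} (e.g. \code{epochs}).
#' @return An object of class \code{tat_cv}: data.frame of per-fold
#'   metrics plus a \code{folds} attribute mapping fold -> held-out
#'   subjects.
#' @export
cross_validate <- function(ts, k = 5L, seed = 1L, ...) {
  stopifnot(is.data.frame(ts), all(c("cdr3_aa", "label",
                                     "subject_id") %in% names(ts)))
  pos_subjects <- unique(ts$subject_id[ts$label == 1L])
  if (length(pos_subjects) < k) {
    stop(sprintf("only %d positive subjects for %d folds",
                 length(pos_subjects), k), call. = FALSE)
  }
  set.seed(seed)
  subj_fold <- sample(rep_len(seq_len(k), length(pos_subjects)))
  names(subj_fold) <- pos_subjects
  neg_idx <- which(ts$label == 0L)
  neg_fold <- sample(rep_len(seq_len(k), length(neg_idx)))
  res <- data.frame(fold = seq_len(k), roc_auc = NA_real_,
                    prc_auc = NA_real_, n_test = NA_integer_)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_subjects <- pos_subjects[subj_fold == f]
    folds[[f]] <- test_subjects
    is_test <- (ts$label == 1L & ts$subject_id %in% test_subjects)
    is_test[neg_idx[neg_fold == f]] <- TRUE
    train <- ts[!is_test, , drop = FALSE]
    test <- ts[is_test, , drop = FALSE]
    fit <- tat_cnn(train, seed = seed + f, ...)
    p <- predict(fit, test$cdr3_aa)
    res$roc_auc[f] <- roc_auc(test$label, p)
    res$prc_auc[f] <- .prc_auc(test$label, p)
    res$n_test[f] <- nrow(test)
  }
  structure(res, class = c("tat_cv", "data.frame"), folds = folds,
            seed = seed)
}

#' Positional amino-acid motif enrichment
#'
#' Compares positional amino-acid frequencies between the sequences with
#' the highest and lowest predicted TAT probabilities (top and bottom
#' quartiles by default). Frequencies are computed per CDR3 length stratum
#' (columns sum to 1 per position) and aggregated left-aligned across
#' strata; log-odds are log2((f_high + pc) / (f_low + pc)).
#'
#' @param seqs Character vector of CDR3 sequences.
#' @param probs Predicted probabilities, same length as \code{seqs}.
#' @param top_q,bottom_q Quantile fractions defining the high and low
#'   groups (defaults 0.25).
#' @param pseudocount Added to both frequencies before the log-ratio.
#' @return An object of class \code{motif_enrichment}: list with
#'   \code{per_length} (length -> list(high, low, log_odds) of 20 x L
#'   matrices) and \code{aggregate} (same over positions shared by all
#'   strata).
#' @export
motif_enrichment <- function(seqs, probs, top_q = 0.25, bottom_q = 0.25,
                             pseudocount = 1e-3) {
  stopifnot(length(seqs) == length(probs))
  keep <- !is.na(probs)
  seqs <- seqs[keep]; probs <- probs[keep]
  if (length(seqs) < 4L) stop("need at least 4 scored sequences",
                              call. = FALSE)
  hi_cut <- stats::quantile(probs, 1 - top_q, names = FALSE)
  lo_cut <- stats::quantile(probs, bottom_q, names = FALSE)
  high <- seqs[probs >= hi_cut]
  low <- seqs[probs <= lo_cut]
  freq_matrix <- function(ss, L) {
    m <- matrix(0, 20L, L, dimnames = list(AA_ALPHABET, seq_len(L)))
    if (length(ss) == 0L) return(m)
    ch <- do.call(rbind, strsplit(substr(ss, 1L, L), ""))
    for (pos in seq_len(L)) {
      tab <- table(factor(ch[, pos], levels = AA_ALPHABET))
      m[, pos] <- as.numeric(tab) / length(ss)
    }
    m
  }
  lens <- sort(unique(nchar(c(high, low))))
  per_length <- list()
  for (L in lens) {
    h <- high[nchar(high) == L]
    l <- low[nchar(low) == L]
    if (length(h) == 0L || length(l) == 0L) {
      warning("length ", L, " stratum empty in one group; skipped",
              call. = FALSE)
      next
    }
    fh <- freq_matrix(h, L); fl <- freq_matrix(l, L)
    per_length[[as.character(L)]] <-
      list(high = fh, low = fl,
           log_odds = log2((fh + pseudocount) / (fl + pseudocount)))
  }
  Lmin <- min(nchar(c(high, low)))
  fh <- freq_matrix(high, Lmin); fl <- freq_matrix(low, Lmin)
  structure(list(per_length = per_length,
                 aggregate = list(
                   high = fh, low = fl,
                   log_odds = log2((fh + pseudocount) / (fl + pseudocount))),
                 n_high = length(high), n_low = length(low)),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  lo <- x$aggregate$log_odds
  top <- arrayInd(which.max(lo), dim(lo))
  cat(sprintf(
    "Motif enrichment: %d high vs %d low sequences, %d length strata\n",
    x$n_high, x$n_low, length(x$per_length)))
  cat(sprintf("  strongest enrichment: %s at position %d (log2 odds %.2f)\n",
              rownames(lo)[top[1]], top[2], max(lo)))
  invisible(x)
}
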