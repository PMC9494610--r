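test_that("training-set assembly subtracts pool and exclusion sequences", {
  tat_seqs <- random_seqs(10)
  pool <- tcr_pool(c(tat_seqs[1:2], random_seqs(50)), label = "H")
  tats <- make_rep(tat_seqs, subject_id = "p1")
  ts <- build_training_set(list(tats), pool, seed = 4L)
  expect_equal(sum(ts$label == 1L), 8L)
  expect_equal(sum(ts$label == 0L), 8L)
  expect_false(any(ts$cdr3_aa[ts$label == 1L] %in% pool$sequences))
  expect_false(any(duplicated(ts$cdr3_aa)))
  # exclusion list removes from both classes
  excl <- tcr_pool(tat_seqs[3])
  ts2 <- build_training_set(list(tats), pool, exclusion = excl, seed = 4L)
  expect_equal(sum(ts2$label == 1L), 7L)
  expect_false(excl$sequences %in% ts2$cdr3_aa)
})

test_that("degenerate training sets are flagged", {
  seqs <- random_seqs(6)
  pool <- tcr_pool(c(seqs, random_seqs(20)))
  expect_warning(ts <- build_training_set(make_rep(seqs), pool, seed = 1L),
                 "no positive")
  expect_equal(sum(ts$label == 1L), 0L)
  small_pool <- tcr_pool(random_seqs(3))
  expect_error(build_training_set(make_rep(random_seqs(10)), small_pool),
               "smaller")
})

test_that("negative sampling is reproducible under a fixed seed", {
  tats <- make_rep(random_seqs(15), subject_id = "p1")
  pool <- tcr_pool(random_seqs(200))
  a <- build_training_set(list(tats), pool, seed = 99L)
  b <- build_training_set(list(tats), pool, seed = 99L)
  expect_identical(a$cdr3_aa, b$cdr3_aa)
  c <- build_training_set(list(tats), pool, seed = 100L)
  expect_false(identical(sort(c$cdr3_aa[c$label == 0]),
                         sort(a$cdr3_aa[a$label == 0])))
})

test_that("the classifier recovers a planted positional motif", {
  bundle <- test_model_bundle()
  held_cfg <- repertoire_sim_config(n_clones = 400L, shared_fraction = 1,
                                    seed = 202L)
  pos <- gen_paired_repertoires(held_cfg)$truth$motif_sequences
  neg_cfg <- repertoire_sim_config(n_clones = 400L, shared_fraction = 0,
                                   motif = NULL, seed = 203L)
  neg <- gen_paired_repertoires(neg_cfg)$pbmc$clones$cdr3_aa
  p <- predict(bundle$fit, c(pos, neg))
  auc <- roc_auc(rep(1:0, c(length(pos), length(neg))), p)
  expect_gte(auc, 0.85)
  expect_gt(mean(p[seq_along(pos)]), mean(p[-seq_along(pos)]))
})

test_that("the training loss decreases to a plateau", {
  bundle <- test_model_bundle()
  loss <- bundle$fit$history$loss
  smooth <- stats::filter(loss, rep(1 / 5, 5), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_lt(tail(smooth, 1), smooth[1])
  # non-increasing within the smoothing window (small tolerance for noise)
  expect_true(all(diff(smooth) < 0.02))
})

test_that("patient-level folds partition subjects without leakage", {
  set.seed(41)
  per_subject <- 30L
  pos <- data.frame(
    cdr3_aa = random_seqs(10L * per_subject), label = 1L,
    subject_id = rep(sprintf("p%02d", 1:10), each = per_subject))
  neg <- data.frame(cdr3_aa = random_seqs(10L * per_subject), label = 0L,
                    subject_id = "pool")
  ts <- structure(rbind(pos, neg),
                  class = c("tat_training_set", "data.frame"))
  cv <- cross_validate(ts, k = 5L, seed = 6L, epochs = 2L)
  folds <- attr(cv, "folds")
  expect_equal(sort(unlist(folds)), sort(sprintf("p%02d", 1:10)))
  expect_true(all(lengths(folds) == 2L))          # 10 subjects over 5 folds
  for (f in seq_along(folds)) {
    expect_equal(length(intersect(folds[[f]], unlist(folds[-f]))), 0L)
  }
  expect_true(all(cv$roc_auc >= 0 & cv$roc_auc <= 1))
  expect_true(all(cv$prc_auc >= 0 & cv$prc_auc <= 1))
  expect_error(cross_validate(ts[ts$subject_id %in%
                                 c("p01", "p02", "pool"), ], k = 5L),
               "subjects")
})

test_that("motif enrichment contrasts top and bottom probability groups", {
  high <- vapply(1:20, function(i) {
    s <- random_seqs(1, 12, 12); substr(s, 2, 2) <- "S"; s
  }, character(1))
  low <- vapply(1:20, function(i) {
    s <- random_seqs(1, 12, 12); substr(s, 2, 2) <- "A"; s
  }, character(1))
  me <- motif_enrichment(c(high, low), c(rep(0.9, 20), rep(0.1, 20)))
  expect_equal(me$aggregate$high["S", 2], 1.0)
  expect_equal(me$aggregate$low["A", 2], 1.0)
  lo12 <- me$per_length[["12"]]
  expect_equal(colSums(lo12$high), rep(1, 12), ignore_attr = TRUE)
  expect_equal(colSums(lo12$low), rep(1, 12), ignore_attr = TRUE)
  top <- arrayInd(which.max(me$aggregate$log_odds),
                  dim(me$aggregate$log_odds))
  expect_equal(rownames(me$aggregate$log_odds)[top[1]], "S")
  expect_equal(top[2], 2L)
})

test_that("motif enrichment is flat under random probabilities", {
  set.seed(51)
  seqs <- random_seqs(3000, 14, 14)
  me <- motif_enrichment(seqs, runif(3000))
  # multinomial noise bound: frequencies ~ p = 1/20 over ~750 sequences
  noise_sd <- sqrt(0.05 * 0.95 / 750)
  max_ratio <- max(abs(me$aggregate$high - me$aggregate$low))
  expect_lt(max_ratio, 6 * noise_sd)
  expect_error(motif_enrichment(seqs[1:3], runif(3)), "at least 4")
})
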