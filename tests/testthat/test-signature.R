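make_de_table <- function(genes, de_genes_up = character(),
                          de_genes_down = character(), id = "d") {
  data.frame(gene = genes,
             log2fc = ifelse(genes %in% de_genes_down, -1,
                             ifelse(genes %in% de_genes_up, 1, 0)),
             p = 0.5, p_adj = ifelse(genes %in% c(de_genes_up,
                                                  de_genes_down),
                                     0.001, 0.9),
             de = genes %in% c(de_genes_up, de_genes_down),
             direction = ifelse(genes %in% de_genes_down, "down", "up"),
             dataset_id = id, stringsAsFactors = FALSE)
}

test_that("planted differentially expressed genes are recovered", {
  cfg <- expression_sim_config(n_genes = 800L, n_cells = 500L,
                               sig_genes = sprintf("SIG%02d", 1:25),
                               sig_effects = 1, seed = 61L)
  le <- gen_expression(cfg, "single_cell")
  de <- de_genes(le)
  called <- de$gene[de$de]
  expect_gte(sum(cfg$sig_genes %in% called), 23L)   # >= ~90% recall
  # BH controls the false-discovery rate in expectation; allow a loose
  # high-probability bound on one realization
  false_calls <- setdiff(called, cfg$sig_genes)
  expect_lte(length(false_calls), 10L)
  expect_true(all(de$p_adj >= de$p))
})

test_that("label permutation yields alpha-controlled false calls", {
  cfg <- expression_sim_config(n_genes = 500L, n_cells = 400L,
                               sig_genes = character(0), seed = 62L)
  le <- gen_expression(cfg, "single_cell")
  de <- de_genes(le)
  # no planted signal: BH at .05 controls expected false discoveries
  expect_lte(sum(de$de), 10L)
  expect_gte(mean(de$p < 0.05), 0.02)  # raw p uniform-ish
  expect_lte(mean(de$p < 0.05), 0.09)
})

test_that("degenerate genes and small groups are handled", {
  cfg <- expression_sim_config(n_genes = 60L, n_cells = 200L,
                               sig_genes = character(0), seed = 63L)
  le <- gen_expression(cfg, "single_cell")
  le$expr[1, ] <- 5                                  # zero variance
  de <- de_genes(le)
  expect_false(de$de[1])
  expect_equal(de$p[1], 1)
  tiny <- le
  tiny$cells$tat_flag[] <- FALSE
  tiny$cells$tat_flag[1:3] <- TRUE
  expect_warning(res <- de_genes(tiny), "skipped")
  expect_null(res)
})

test_that("recurrence rule is strict and direction ties exclude", {
  genes <- sprintf("G%02d", 1:5)
  tabs <- c(
    lapply(1:11, function(i) make_de_table(genes, de_genes_up = "G01",
                                           id = paste0("d", i))),
    lapply(12:14, function(i) make_de_table(genes, id = paste0("d", i))))
  # G01 up in 11/14 -> included
  sig <- recurrent_signature(tabs, min_datasets = 10L)
  expect_equal(sig$gene, "G01")
  expect_equal(sig$direction, "up")
  expect_equal(sig$support, 11L)
  # DE in 10/14 -> excluded (strict inequality)
  tabs10 <- c(lapply(1:10, function(i) {
    make_de_table(genes, de_genes_up = "G02", id = paste0("d", i))
  }), lapply(11:14, function(i) make_de_table(genes, id = paste0("d", i))))
  expect_equal(nrow(recurrent_signature(tabs10, min_datasets = 10L)), 0L)
  # 6 up / 6 down is a direction tie -> excluded even though 12 > 10
  tabs_tie <- c(
    lapply(1:6, function(i) make_de_table(genes, de_genes_up = "G03",
                                          id = paste0("u", i))),
    lapply(1:6, function(i) make_de_table(genes, de_genes_down = "G03",
                                          id = paste0("w", i))),
    lapply(1:2, function(i) make_de_table(genes, id = paste0("n", i))))
  expect_equal(nrow(recurrent_signature(tabs_tie, min_datasets = 10L)), 0L)
  expect_error(recurrent_signature(tabs[1], min_datasets = 10L),
               "at least 2")
})

test_that("recurrent signature ignores dataset order", {
  genes <- sprintf("G%02d", 1:6)
  tabs <- lapply(1:5, function(i) {
    make_de_table(genes, de_genes_up = c("G01", "G02"),
                  de_genes_down = "G05", id = paste0("d", i))
  })
  a <- recurrent_signature(tabs, min_datasets = 3L)
  b <- recurrent_signature(rev(tabs), min_datasets = 3L)
  expect_equal(a, b, ignore_attr = TRUE)
  expect_setequal(a$gene, c("G01", "G02", "G05"))
  expect_equal(a$direction[a$gene == "G05"], "down")
})

test_that("signature scoring is the up-minus-down mean z-score", {
  genes <- c("U1", "U2", "D1", "D2", sprintf("X%d", 1:6))
  n <- 10L
  set.seed(64)
  base <- matrix(rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, paste0("s", 1:n)))
  # centre and unit-scale each gene, then push one sample to +/-2 SD
  base <- t(scale(t(base)))
  base["U1", 1] <- 2; base["U2", 1] <- 2
  base["D1", 1] <- -2; base["D2", 1] <- -2
  z <- t(scale(t(base)))
  sig <- data.frame(gene = c("U1", "U2", "D1", "D2"),
                    direction = c("up", "up", "down", "down"))
  s <- signature_score(base, sig)
  manual <- colMeans(z[c("U1", "U2"), ]) - colMeans(z[c("D1", "D2"), ])
  expect_equal(s, manual)
  # exact arithmetic on an already-standardized toy matrix
  toy <- matrix(c(2, 2, -2, -2, 0, 0, 0, 0, -2, -2, 2, 2), 4, 3,
                dimnames = list(c("U1", "U2", "D1", "D2"), c("a", "b", "c")))
  toy_z <- t(scale(t(toy)))
  s_toy <- signature_score(toy, sig)
  expect_equal(unname(s_toy["b"]), 0)              # cohort-mean sample
  expect_gt(s_toy["a"], s_toy["c"])
  # exactly 50% coverage is accepted; below 50% errors
  expect_silent(signature_score(base[1:2, ], sig))
  expect_error(signature_score(base[1, , drop = FALSE], sig), "50%")
})

test_that("signature scoring is invariant to gene-wise affine rescaling", {
  cfg <- expression_sim_config(n_genes = 100L, n_samples = 20L,
                               sig_genes = sprintf("SIG%02d", 1:10),
                               seed = 65L)
  bk <- gen_expression(cfg, "bulk")
  sig <- data.frame(gene = cfg$sig_genes, direction = "up")
  s1 <- signature_score(bk$expr, sig)
  rescaled <- bk$expr * runif(100, 0.5, 3) + rnorm(100)
  expect_equal(signature_score(rescaled, sig), s1)
})

test_that("TIGS is mutation burden times mean antigen-presenting expression", {
  expr <- matrix(c(2, 4, 6), 3, 1,
                 dimnames = list(c("HLA-A", "B2M", "TAP1"), "s1"))
  expect_equal(unname(tigs(c(s1 = 10), expr, rownames(expr))), 40)
  expect_equal(unname(tigs(c(s1 = 0), expr, rownames(expr))), 0)
  expect_equal(unname(tigs(c(s1 = 10), expr * 2, rownames(expr))), 80)
  expect_true(is.na(tigs(c(s1 = NA), expr, rownames(expr))))
  expect_error(tigs(c(s1 = 1), expr, c("HLA-A", "MISSING")), "MISSING")
})

test_that("the signature generalizes across held-out synthetic datasets", {
  datasets <- lapply(1:4, function(i) {
    gen_expression(expression_sim_config(
      n_genes = 300L, n_cells = 250L,
      sig_genes = sprintf("SIG%02d", 1:15), sig_effects = 1,
      seed = 70L + i), "single_cell", dataset_id = paste0("d", i))
  })
  res <- loo_dataset_validation(datasets, min_datasets = 2L)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$auc >= 0.8))
  # permutation places the true separation far above the null
  held <- datasets[[1]]
  sel <- held$cells$tat_flag | held$cells$clone_frequency == 1
  y <- as.integer(held$cells$tat_flag[sel])
  score <- colMeans(held$expr[sprintf("SIG%02d", 1:15), sel])
  pt <- permutation_auc_test(y, score, n_perm = 300L, seed = 71L)
  expect_gt(pt$auc, pt$q95)
  expect_lt(pt$p_value, 0.01)
})
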