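test_that("reading an AIRR table merges identical clones additively", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "junction_aa\tv_call\tj_call\tproductive\tduplicate_count",
    "CASSLGFDEQFFREW\tTRBV20-1\tTRBJ2-1\tT\t2",
    "CASSLGFDEQFFREW\tTRBV20-1\tTRBJ2-1\tT\t3",
    "CASSPDRGEQYFREW\tTRBV6-2/6-3\tTRBJ2-7\tT\t1"), path)
  rep <- read_repertoire(path, "airr", subject_id = "p1", tissue = "PBMC")
  expect_equal(nrow(rep$clones), 2L)
  merged <- rep$clones[rep$clones$cdr3_aa == "CASSLGFDEQFFREW", ]
  expect_equal(merged$count, 5L)
  expect_equal(rep$total_count, 6L)
  # ambiguous gene calls kept verbatim
  expect_true("TRBV6-2/6-3" %in% rep$clones$v_gene)
})

test_that("non-productive rows are retained until filtering", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "junction_aa\tv_call\tj_call\tproductive\tduplicate_count",
    "CASSLGFDEQFFREW\tTRBV1\tTRBJ1\tT\t4",
    "CASS*GFDEQFFREW\tTRBV1\tTRBJ1\tF\t2"), path)
  rep <- read_repertoire(path, "airr")
  expect_equal(nrow(rep$clones), 2L)
  expect_equal(sum(rep$clones$productive), 1L)
  expect_equal(nrow(filter_functional(rep)$clones), 1L)
})

test_that("a missing required column is a named format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("v_call\tj_call\tproductive\tduplicate_count",
               "TRBV1\tTRBJ1\tT\t2"), path)
  expect_error(read_repertoire(path, "airr"), "junction_aa")
})

test_that("a file with zero productive rows warns instead of failing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tproductive\tduplicate_count",
               "CASSLGFDEQFFREW\tTRBV1\tTRBJ1\tF\t2"), path)
  expect_warning(rep <- read_repertoire(path, "airr"), "productive")
  expect_s3_class(rep, "tcr_repertoire")
})

test_that("the immuneACCESS v2 dialect maps its headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "amino_acid\tv_resolved\tj_resolved\tframe_type\ttemplates",
    "CASSLGFDEQFFREW\tTRBV20-1\tTRBJ2-1\tIn\t7",
    "CASSXGFDEQFFREW\tTRBV20-1\tTRBJ2-1\tOut\t2"), path)
  rep <- read_repertoire(path, "immuneaccess_v2")
  expect_equal(rep$clones$count[rep$clones$productive], 7L)
  expect_false(rep$clones$productive[rep$clones$cdr3_aa ==
                                     "CASSXGFDEQFFREW"])
})

test_that("write/read round-trips clone sets and counts exactly", {
  set.seed(7)
  rep <- make_rep(random_seqs(40), count = sample(1:50, 40, TRUE),
                  v = sample(paste0("TRBV", 1:8), 40, TRUE),
                  j = sample(paste0("TRBJ", 1:3), 40, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(rep, path)
  back <- read_repertoire(path, "airr", subject_id = "sub")
  ord <- function(df) df[order(df$v_gene, df$cdr3_aa, df$j_gene), ]
  expect_equal(ord(back$clones)[c("cdr3_aa", "v_gene", "j_gene", "count")],
               ord(rep$clones)[c("cdr3_aa", "v_gene", "j_gene", "count")],
               ignore_attr = TRUE)
})

test_that("length filter keeps the 12-17 window inclusively", {
  lens <- c(11L, 12L, 17L, 18L)
  rep <- make_rep(vapply(lens, function(l) {
    paste(rep("A", l), collapse = "")
  }, character(1)))
  kept <- filter_length(rep)
  expect_setequal(nchar(kept$clones$cdr3_aa), c(12L, 17L))
  only14 <- filter_length(make_rep(c(strrep("A", 14), strrep("A", 15))),
                          min_len = 14, max_len = 14)
  expect_equal(nchar(only14$clones$cdr3_aa), 14L)
  all13 <- make_rep(rep(strrep("G", 13), 1))
  expect_equal(filter_length(all13)$clones, all13$clones)
})

test_that("functional and length filters commute", {
  set.seed(42)
  for (i in 1:20) {
    n <- 30L
    seqs <- random_seqs(n, min_len = 9, max_len = 20)
    bad <- sample(n, 5)
    substr(seqs[bad[1:2]], 3, 3) <- "*"
    rep <- make_rep(seqs, count = sample(1:9, n, TRUE),
                    productive = !(seq_len(n) %in% bad[3:5]))
    a <- filter_length(filter_functional(rep))
    b <- filter_functional(filter_length(rep))
    expect_equal(a$clones, b$clones)
  }
})

test_that("length distribution reports unique-sequence proportions", {
  rep <- make_rep(c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "DDDDDDDDDDDDD",
                    "EEEEEEEEEEEEEE"),
                  v = paste0("TRBV", 1:4))
  ld <- length_distribution(rep)
  expect_equal(ld$proportion[ld$length == 12], 0.5)
  expect_equal(ld$proportion[ld$length == 13], 0.25)
  expect_equal(sum(ld$proportion), 1)
  one <- length_distribution(make_rep("AAAAAAAAAAAA"))
  expect_equal(one$proportion, 1)
  empty <- filter_functional(make_rep("AAAAAAAAAAAA", productive = FALSE))
  expect_equal(nrow(length_distribution(empty)), 0L)
})

test_that("generated repertoires match the configured length distribution", {
  cfg <- repertoire_sim_config(n_clones = 4000L, shared_fraction = 0,
                               seed = 9L)
  pr <- gen_paired_repertoires(cfg)
  ld <- length_distribution(pr$pbmc)
  expected <- cfg$len_probs[as.character(ld$length)]
  # multinomial sampling error: 4 SDs per length bin
  tol <- 4 * sqrt(expected * (1 - expected) / 4000)
  expect_true(all(abs(ld$proportion - expected) < tol))
})

test_that("V-gene usage weights by sequence or by clone count", {
  rep <- make_rep(c("AAAAAAAAAAAA", "CCCCCCCCCCCC"), count = c(9L, 1L),
                  v = c("TRBV1", "TRBV2"))
  seq_level <- vgene_usage(rep, "sequence")
  expect_equal(seq_level$frequency[seq_level$v_gene == "TRBV1"], 0.5)
  clone_level <- vgene_usage(rep, "clone")
  expect_equal(clone_level$frequency[clone_level$v_gene == "TRBV1"], 0.9)
  expect_equal(sum(clone_level$frequency), 1)
  empty <- filter_functional(make_rep("AAAAAAAAAAAA", productive = FALSE))
  expect_equal(nrow(vgene_usage(empty)), 0L)
})
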