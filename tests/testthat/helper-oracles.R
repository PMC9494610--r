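# Independent oracles used to check the package's diversity statistics.

# Gini by the literal pairwise mean-absolute-difference double sum.
oracle_gini_pairwise <- function(counts) {
  n <- length(counts)
  sum(abs(outer(counts, counts, "-"))) / (2 * n * sum(counts))
}

# Gini from the trapezoid area under the Lorenz curve.
oracle_gini_lorenz <- function(counts) {
  x <- sort(counts)
  n <- length(x)
  cum <- cumsum(x) / sum(x)
  1 - (2 * sum(cum) - 1) / n
}

# Entropy by direct summation over the empirical distribution.
oracle_entropy <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# Quick builder for repertoires in tests.
make_rep <- function(cdr3, count = rep(1L, length(cdr3)),
                     v = rep("TRBV01", length(cdr3)),
                     j = rep("TRBJ01", length(cdr3)),
                     productive = rep(TRUE, length(cdr3)),
                     sample_id = "s", subject_id = "sub",
                     tissue = "PBMC") {
  tcr_repertoire(data.frame(cdr3_aa = cdr3, v_gene = v, j_gene = j,
                            count = count, productive = productive,
                            stringsAsFactors = FALSE),
                 sample_id = sample_id, subject_id = subject_id,
                 tissue = tissue)
}

# Random amino-acid sequences of lengths 12-17.
random_seqs <- function(n, min_len = 12L, max_len = 17L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  lens <- if (min_len == max_len) rep(min_len, n) else
    sample(seq(min_len, max_len), n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(aa, l, replace = TRUE), collapse = "")
  }, character(1))
}
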