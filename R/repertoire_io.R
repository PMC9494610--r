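# Reading, validating, filtering and summarizing TCR beta-chain repertoires.
#
# A repertoire is the set of clones observed in one sample of one tissue
# (PBMC or TIL). Clone identity is the triple (v_gene, cdr3_aa, j_gene);
# "sequence level" statistics elsewhere in the package count distinct
# cdr3_aa strings only.

#' Construct a TCR repertoire object
#'
#' @param clones data.frame with columns \code{cdr3_aa}, \code{v_gene},
#'   \code{j_gene}, \code{count}, \code{productive}. Rows with identical
#'   clone identity (v_gene, cdr3_aa, j_gene) are merged and their counts
#'   summed.
#' @param sample_id,subject_id Sample and subject identifiers.
#' @param tissue One of \code{"PBMC"} or \code{"TIL"}.
#' @return An object of class \code{tcr_repertoire}: a list with the merged
#'   clone table, identifiers and \code{total_count}.
#' @export
tcr_repertoire <- function(clones, sample_id = NA_character_,
                           subject_id = NA_character_,
                           tissue = c("PBMC", "TIL")) {
  tissue <- match.arg(tissue)
  required <- c("cdr3_aa", "v_gene", "j_gene", "count", "productive")
  missing_cols <- setdiff(required, names(clones))
  if (length(missing_cols) > 0L) {
    stop("clone table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  clones <- as.data.frame(clones)[required]
  clones$cdr3_aa <- as.character(clones$cdr3_aa)
  clones$v_gene <- as.character(clones$v_gene)
  clones$j_gene <- as.character(clones$j_gene)
  clones$count <- as.integer(clones$count)
  clones$productive <- as.logical(clones$productive)
  if (nrow(clones) > 0L) {
    if (any(is.na(clones$cdr3_aa) | clones$cdr3_aa == "")) {
      stop("cdr3_aa must be non-empty for every clone", call. = FALSE)
    }
    if (any(is.na(clones$count) | clones$count < 1L)) {
      stop("clone counts must be positive integers", call. = FALSE)
    }
    key <- paste(clones$v_gene, clones$cdr3_aa, clones$j_gene, sep = "|")
    if (anyDuplicated(key)) {
      count <- tapply(clones$count, key, sum)
      first <- clones[!duplicated(key), , drop = FALSE]
      first$count <- as.integer(count[paste(first$v_gene, first$cdr3_aa,
                                            first$j_gene, sep = "|")])
      clones <- first
    }
    rownames(clones) <- NULL
  }
  structure(
    list(sample_id = sample_id, subject_id = subject_id, tissue = tissue,
         clones = clones, total_count = sum(clones$count)),
    class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire '%s' (subject %s, %s)\n",
              x$sample_id, x$subject_id, x$tissue))
  cat(sprintf("  %d clones, %d total templates, %d unique CDR3 sequences\n",
              nrow(x$clones), x$total_count, length(unique(x$clones$cdr3_aa))))
  invisible(x)
}

#' @export
summary.tcr_repertoire <- function(object, ...) {
  d <- repertoire_diversity(object)
  cat(sprintf(
    "TCR repertoire '%s' (%s): richness %d, entropy %.3f nats, clonality %s, Gini %.3f\n",
    object$sample_id, object$tissue, d$richness, d$shannon_entropy,
    ifelse(is.na(d$clonality), "NA", sprintf("%.3f", d$clonality)), d$gini))
  invisible(d)
}

# Column maps for the two supported table dialects.
.dialect_columns <- list(
  airr = c(cdr3_aa = "junction_aa", v_gene = "v_call", j_gene = "j_call",
           count = "duplicate_count", productive = "productive"),
  immuneaccess_v2 = c(cdr3_aa = "amino_acid", v_gene = "v_resolved",
                      j_gene = "j_resolved", count = "templates",
                      productive = "frame_type")
)

#' Read a TCR repertoire table
#'
#' Supports the AIRR rearrangement TSV dialect (columns \code{junction_aa},
#' \code{v_call}, \code{j_call}, \code{productive}, \code{duplicate_count})
#' and the immuneACCESS v2 export dialect (\code{amino_acid},
#' \code{v_resolved}, \code{j_resolved}, \code{frame_type},
#' \code{templates}). Rows with identical clone identity are merged with
#' counts summed. A file with zero productive rows yields an empty
#' repertoire with a warning, not an error.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect \code{"airr"} or \code{"immuneaccess_v2"}.
#' @inheritParams tcr_repertoire
#' @return A \code{tcr_repertoire}.
#' @examples
#' path <- system.file("extdata", "example_airr_synthetic.tsv",
#'                     package = "tatscreen")
#' rep <- read_repertoire(path, "airr", subject_id = "p1", tissue = "PBMC")
#' filter_length(filter_functional(rep))
#' @export
read_repertoire <- function(path, dialect = c("airr", "immuneaccess_v2"),
                            sample_id = NA_character_,
                            subject_id = NA_character_,
                            tissue = c("PBMC", "TIL")) {
  dialect <- match.arg(dialect)
  tissue <- match.arg(tissue)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  map <- .dialect_columns[[dialect]]
  missing_cols <- setdiff(unname(map), names(tab))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s table is missing required column(s): %s",
                 dialect, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  clones <- data.frame(
    cdr3_aa = as.character(tab[[map[["cdr3_aa"]]]]),
    v_gene = as.character(tab[[map[["v_gene"]]]]),
    j_gene = as.character(tab[[map[["j_gene"]]]]),
    count = tab[[map[["count"]]]],
    stringsAsFactors = FALSE)
  clones$productive <- if (dialect == "airr") {
    toupper(as.character(tab$productive)) %in% c("T", "TRUE", "YES", "1")
  } else {
    tab$frame_type == "In"
  }
  if (is.na(sample_id)) {
    sample_id <- sub("\\.(tsv|txt)$", "", basename(path))
  }
  if (!any(clones$productive)) {
    warning("no productive rows in ", path, "; returning empty repertoire",
            call. = FALSE)
  }
  tcr_repertoire(clones, sample_id = sample_id, subject_id = subject_id,
                 tissue = tissue)
}

#' Write a repertoire as an AIRR-subset TSV
#'
#' Writes the canonical column subset (\code{junction_aa}, \code{v_call},
#' \code{j_call}, \code{productive}, \code{duplicate_count}) so that
#' \code{read_repertoire(..., dialect = "airr")} round-trips the clone set
#' and counts exactly.
#'
#' @param rep A \code{tcr_repertoire}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  .stop_if_not_repertoire(rep)
  out <- data.frame(
    junction_aa = rep$clones$cdr3_aa,
    v_call = rep$clones$v_gene,
    j_call = rep$clones$j_gene,
    productive = ifelse(rep$clones$productive, "T", "F"),
    duplicate_count = rep$clones$count,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep only functional clones
#'
#' Retains clones flagged productive whose CDR3 amino-acid sequence is free
#' of stop/frameshift symbols (\code{*}, \code{_}, \code{X}).
#'
#' @param rep A \code{tcr_repertoire}.
#' @return The filtered repertoire.
#' @export
filter_functional <- function(rep) {
  .stop_if_not_repertoire(rep)
  keep <- rep$clones$productive &
    !grepl("[*_X]", rep$clones$cdr3_aa, perl = TRUE)
  rep$clones <- rep$clones[keep, , drop = FALSE]
  rownames(rep$clones) <- NULL
  rep$total_count <- sum(rep$clones$count)
  rep
}

#' Filter clones by CDR3 length
#'
#' Most CDR3 beta sequences fall in the 12-17 amino-acid range; clones with
#' excessively short or long CDR3 regions are removed before downstream
#' analysis. Bounds are inclusive.
#'
#' @param rep A \code{tcr_repertoire}.
#' @param min_len,max_len Inclusive length bounds (defaults 12 and 17).
#' @return The filtered repertoire.
#' @export
filter_length <- function(rep, min_len = 12L, max_len = 17L) {
  .stop_if_not_repertoire(rep)
  stopifnot(min_len <= max_len)
  len <- nchar(rep$clones$cdr3_aa)
  rep$clones <- rep$clones[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(rep$clones) <- NULL
  rep$total_count <- sum(rep$clones$count)
  rep
}

#' CDR3 length distribution
#'
#' @param rep A \code{tcr_repertoire}.
#' @return data.frame with columns \code{length}, \code{n_sequences}
#'   (unique CDR3 sequences of that length) and \code{proportion} (summing
#'   to 1 over observed lengths). Empty repertoire gives zero rows.
#' @export
length_distribution <- function(rep) {
  .stop_if_not_repertoire(rep)
  seqs <- unique(rep$clones$cdr3_aa)
  if (length(seqs) == 0L) {
    return(data.frame(length = integer(), n_sequences = integer(),
                      proportion = numeric()))
  }
  tab <- table(nchar(seqs))
  data.frame(length = as.integer(names(tab)),
             n_sequences = as.integer(tab),
             proportion = as.numeric(tab) / length(seqs))
}

#' V-gene usage frequencies
#'
#' @param rep A \code{tcr_repertoire}.
#' @param level \code{"sequence"} weights each distinct clone once;
#'   \code{"clone"} weights clones by their template count.
#' @return data.frame with columns \code{v_gene} and \code{frequency}
#'   (summing to 1). Empty repertoire gives zero rows.
#' @export
vgene_usage <- function(rep, level = c("sequence", "clone")) {
  .stop_if_not_repertoire(rep)
  level <- match.arg(level)
  if (nrow(rep$clones) == 0L) {
    return(data.frame(v_gene = character(), frequency = numeric()))
  }
  w <- if (level == "sequence") rep(1, nrow(rep$clones)) else rep$clones$count
  tot <- tapply(w, rep$clones$v_gene, sum)
  data.frame(v_gene = names(tot),
             frequency = as.numeric(tot) / sum(w),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a healthy TCR sequence pool
#'
#' A pool is a deduplicated set of CDR3 amino-acid sequences aggregated
#' across donors (e.g. an HCMV-negative healthy cohort); membership queries
#' are exact string matches.
#'
#' @param sequences Character vector of CDR3 amino-acid sequences.
#' @param label Pool label.
#' @param n_donors Number of donors contributing to the pool.
#' @param serostatus Optional per-donor metadata retained for filtering.
#' @return An object of class \code{tcr_pool}.
#' @export
tcr_pool <- function(sequences, label = "pool", n_donors = NA_integer_,
                     serostatus = NULL) {
  structure(list(label = label,
                 sequences = unique(as.character(sequences)),
                 n_donors = n_donors, serostatus = serostatus),
            class = "tcr_pool")
}

#' @export
print.tcr_pool <- function(x, ...) {
  cat(sprintf("TCR pool '%s': %d unique sequences (%s donors)\n",
              x$label, length(x$sequences),
              ifelse(is.na(x$n_donors), "?", x$n_donors)))
  invisible(x)
}
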