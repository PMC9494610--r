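# Four-compartment PBMC/TIL sharing analysis.
#
# Clones of a paired PBMC/TIL sample are partitioned by whether their TCR
# is observed in the other tissue: PBMCs_Shared (the circulating
# tumour-associated T cells, cTATs), PBMCs_Only, TILs_Shared and
# TILs_Only. Sharing defaults to exact CDR3 amino-acid identity; matching
# on the full (V, CDR3, J) clone key is available for sensitivity
# analysis.

.clone_keys <- function(rep, match_on) {
  if (match_on == "cdr3_aa") rep$clones$cdr3_aa
  else paste(rep$clones$v_gene, rep$clones$cdr3_aa, rep$clones$j_gene,
             sep = "|")
}

#' Assign clones to the four TCR-sharing compartments
#'
#' @param pbmc,til Paired \code{tcr_repertoire} objects from the same
#'   subject.
#' @param match_on Sharing key: \code{"cdr3_aa"} (default; exact amino-acid
#'   identity) or \code{"clone_key"} (V gene + CDR3 + J gene).
#' @return An object of class \code{compartment_assignment} with a
#'   per-clone table (\code{clone_key}, \code{cdr3_aa}, \code{tissue},
#'   \code{compartment}, \code{count}) and the set of shared CDR3
#'   sequences.
#' @export
assign_compartments <- function(pbmc, til,
                                match_on = c("cdr3_aa", "clone_key")) {
  .stop_if_not_repertoire(pbmc, "pbmc"); .stop_if_not_repertoire(til, "til")
  match_on <- match.arg(match_on)
  if (!is.na(pbmc$subject_id) && !is.na(til$subject_id) &&
      pbmc$subject_id != til$subject_id) {
    stop("pbmc and til repertoires come from different subjects: ",
         pbmc$subject_id, " vs ", til$subject_id, call. = FALSE)
  }
  kp <- .clone_keys(pbmc, match_on)
  kt <- .clone_keys(til, match_on)
  shared_keys <- intersect(kp, kt)
  labels <- rbind(
    data.frame(clone_key = kp, cdr3_aa = pbmc$clones$cdr3_aa,
               tissue = "PBMC",
               compartment = ifelse(kp %in% shared_keys,
                                    "PBMCs_Shared", "PBMCs_Only"),
               count = pbmc$clones$count, stringsAsFactors = FALSE),
    data.frame(clone_key = kt, cdr3_aa = til$clones$cdr3_aa,
               tissue = "TIL",
               compartment = ifelse(kt %in% shared_keys,
                                    "TILs_Shared", "TILs_Only"),
               count = til$clones$count, stringsAsFactors = FALSE))
  shared_sequences <- intersect(pbmc$clones$cdr3_aa, til$clones$cdr3_aa)
  structure(list(subject_id = pbmc$subject_id, match_on = match_on,
                 labels = labels, shared_sequences = shared_sequences),
            class = "compartment_assignment")
}

#' @export
print.compartment_assignment <- function(x, ...) {
  tab <- table(x$labels$compartment)
  cat(sprintf("Compartment assignment for subject %s (match on %s)\n",
              x$subject_id, x$match_on))
  for (cmp in c("PBMCs_Shared", "PBMCs_Only", "TILs_Shared", "TILs_Only")) {
    cat(sprintf("  %-13s %d clones\n", cmp,
                if (cmp %in% names(tab)) tab[[cmp]] else 0L))
  }
  invisible(x)
}

#' Proportion of shared TCRs per tissue
#'
#' Sequence-level proportion = shared unique sequences / unique sequences
#' in the tissue; clone-level proportion = summed counts of shared clones /
#' total count of the tissue.
#'
#' @param assignment A \code{compartment_assignment} built from \code{pbmc}
#'   and \code{til}.
#' @param pbmc,til The repertoires the assignment was built from.
#' @return One-row data.frame with \code{subject_id},
#'   \code{pbmc_shared_prop_seq}, \code{pbmc_shared_prop_clone},
#'   \code{til_shared_prop_seq}, \code{til_shared_prop_clone}. Empty
#'   repertoires yield NA proportions.
#' @export
overlap_proportion <- function(assignment, pbmc, til) {
  stopifnot(inherits(assignment, "compartment_assignment"))
  one_side <- function(tissue) {
    lab <- assignment$labels[assignment$labels$tissue == tissue, ,
                            drop = FALSE]
    if (nrow(lab) == 0L) return(c(seq = NA_real_, clone = NA_real_))
    shared <- grepl("_Shared$", lab$compartment)
    c(seq = length(unique(lab$cdr3_aa[shared])) /
        length(unique(lab$cdr3_aa)),
      clone = sum(lab$count[shared]) / sum(lab$count))
  }
  p <- one_side("PBMC"); t <- one_side("TIL")
  data.frame(subject_id = assignment$subject_id,
             pbmc_shared_prop_seq = unname(p["seq"]),
             pbmc_shared_prop_clone = unname(p["clone"]),
             til_shared_prop_seq = unname(t["seq"]),
             til_shared_prop_clone = unname(t["clone"]),
             stringsAsFactors = FALSE)
}

#' Extract the circulating tumour-associated T cells (cTATs)
#'
#' Restricts the PBMC repertoire to its PBMCs_Shared compartment: the
#' clones whose TCR is also observed among the paired TILs. Counts are the
#' PBMC counts.
#'
#' @inheritParams overlap_proportion
#' @return A \code{tcr_repertoire} containing only the shared PBMC clones.
#' @export
extract_tats <- function(assignment, pbmc) {
  stopifnot(inherits(assignment, "compartment_assignment"))
  .stop_if_not_repertoire(pbmc, "pbmc")
  lab <- assignment$labels
  shared_keys <- lab$clone_key[lab$tissue == "PBMC" &
                               lab$compartment == "PBMCs_Shared"]
  keys <- .clone_keys(pbmc, assignment$match_on)
  out <- pbmc
  out$clones <- pbmc$clones[keys %in% shared_keys, , drop = FALSE]
  rownames(out$clones) <- NULL
  out$total_count <- sum(out$clones$count)
  out
}

#' Overlap of a repertoire with a reference sequence pool
#'
#' Counts the distinct CDR3 amino-acid sequences of the repertoire that are
#' present (exact match) in the pool; this is the denominator of the TCR
#' repertoire risk score when the pool is the healthy reference.
#'
#' @param rep A \code{tcr_repertoire}.
#' @param pool A \code{tcr_pool}.
#' @return List with \code{n_overlap} and \code{overlapping_sequences}.
#' @export
pool_overlap <- function(rep, pool) {
  .stop_if_not_repertoire(rep)
  stopifnot(inherits(pool, "tcr_pool"))
  seqs <- unique(rep$clones$cdr3_aa)
  hit <- seqs[seqs %in% pool$sequences]
  list(n_overlap = length(hit), overlapping_sequences = hit)
}
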