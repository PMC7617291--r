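.require_tissues <- function(samples) {
  for (t in c("blood", "kidney", "tumour")) {
    if (!any(samples$tissue == t)) {
      stopf("clonal expansion analysis requires at least one %s sample", t)
    }
  }
}

.kidney_present <- function(calls, counts, kidney, method, min_reads) {
  if (method == "call") {
    apply(calls$call[, kidney, drop = FALSE], 1, any)
  } else {
    apply(counts$alt[, kidney, drop = FALSE] >= min_reads, 1, any)
  }
}

#' Mutations shared between tumour and normal kidney but absent from blood
#'
#' Identifies putative clonal precursors of the tumour: variants called
#' present in at least one tumour sample and in normal kidney, with fewer
#' than two supporting reads in every blood sample. Kidney presence uses
#' the beta-binomial call by default (the statistical stand-in for manual
#' inspection); `kidney_presence = "reads"` switches to a minimum-read
#' threshold.
#'
#' @param calls result of [call_true_somatic()] over the somatic variants
#' @param counts the matching [variant_counts()]
#' @param samples sample metadata (needs blood, kidney and tumour samples)
#' @param blood_max_alt exclusive blood read threshold (default: fewer than
#'   2 supporting reads)
#' @param kidney_presence `"call"` or `"reads"`
#' @param min_reads read threshold used when `kidney_presence = "reads"`
#' @return character vector of variant ids
#' @export
find_shared_precursor_mutations <- function(calls, counts, samples,
                                            blood_max_alt = 2,
                                            kidney_presence = c("call", "reads"),
                                            min_reads = 4) {
  kidney_presence <- match.arg(kidney_presence)
  .require_tissues(samples)
  blood <- samples$sample_id[samples$tissue == "blood"]
  kidney <- samples$sample_id[samples$tissue == "kidney"]
  tumour <- samples$sample_id[samples$tissue == "tumour"]
  in_tumour <- apply(calls$call[, tumour, drop = FALSE], 1, any)
  in_kidney <- .kidney_present(calls, counts, kidney, kidney_presence, min_reads)
  blood_clean <- apply(counts$alt[, blood, drop = FALSE] < blood_max_alt, 1, all)
  counts$variants$variant_id[in_tumour & in_kidney & blood_clean]
}

#' Kidney-restricted mutations absent from blood and tumour
#'
#' The complement of the precursor set within kidney clonal expansions:
#' variants called present in normal kidney, with fewer than two blood
#' reads, and not called in any tumour sample. Precursor and private sets
#' are disjoint by construction.
#'
#' @inheritParams find_shared_precursor_mutations
#' @return character vector of variant ids
#' @export
find_kidney_private_mutations <- function(calls, counts, samples,
                                          blood_max_alt = 2,
                                          kidney_presence = c("call", "reads"),
                                          min_reads = 4) {
  kidney_presence <- match.arg(kidney_presence)
  .require_tissues(samples)
  blood <- samples$sample_id[samples$tissue == "blood"]
  kidney <- samples$sample_id[samples$tissue == "kidney"]
  tumour <- samples$sample_id[samples$tissue == "tumour"]
  in_tumour <- apply(calls$call[, tumour, drop = FALSE], 1, any)
  in_kidney <- .kidney_present(calls, counts, kidney, kidney_presence, min_reads)
  blood_clean <- apply(counts$alt[, blood, drop = FALSE] < blood_max_alt, 1, all)
  counts$variants$variant_id[!in_tumour & in_kidney & blood_clean]
}

#' Summarise a kidney clone
#'
#' Reports the number of mutations defining the clone, the largest kidney
#' VAF over the set, and the clone cell fraction estimated as twice the
#' median kidney VAF at diploid sites.
#'
#' @param variant_ids the clone's variant ids (may be empty)
#' @param counts a [variant_counts()]
#' @param samples sample metadata
#' @param segments optional segment table (non-diploid kidney sites are
#'   excluded from the cell fraction estimate)
#' @return data.frame with `n_mutations`, `max_vaf`, `est_cell_fraction`
#' @export
summarise_clone <- function(variant_ids, counts, samples, segments = NULL) {
  if (!length(variant_ids)) {
    return(data.frame(n_mutations = 0L, max_vaf = 0, est_cell_fraction = 0))
  }
  kidney <- samples$sample_id[samples$tissue == "kidney"][1]
  i <- match(variant_ids, counts$variants$variant_id)
  vaf <- counts$alt[i, kidney] / pmax(counts$depth[i, kidney], 1)
  diploid <- rep(TRUE, length(i))
  if (!is.null(segments)) {
    cn <- .cn_lookup(segments, kidney, counts$variants$chrom[i],
                     counts$variants$pos[i])
    diploid <- is.na(cn) | cn == 2
  }
  est <- if (any(diploid)) 2 * stats::median(vaf[diploid]) else NA_real_
  data.frame(n_mutations = length(i), max_vaf = max(vaf),
             est_cell_fraction = min(est, 1))
}

#' Per-patient clone report
#'
#' Runs precursor and private detection and summarises both sets; also
#' returns a per-variant review table with all counts, mirroring the
#' manual-curation step of browser-based inspection.
#'
#' @inheritParams find_shared_precursor_mutations
#' @param segments optional segment table
#' @return list with `summary` (one row per set) and `detail` (per-variant
#'   counts flagged by set)
#' @export
clone_report <- function(calls, counts, samples, segments = NULL, ...) {
  prec <- find_shared_precursor_mutations(calls, counts, samples, ...)
  priv <- find_kidney_private_mutations(calls, counts, samples, ...)
  summary <- rbind(
    cbind(set = "precursor", summarise_clone(prec, counts, samples, segments)),
    cbind(set = "private", summarise_clone(priv, counts, samples, segments)))
  summary$patient_id <- samples$patient_id[1]
  ids <- c(prec, priv)
  detail <- if (length(ids)) {
    i <- match(ids, counts$variants$variant_id)
    data.frame(counts$variants[i, c("variant_id", "chrom", "pos", "ref", "alt")],
               set = rep(c("precursor", "private"), c(length(prec), length(priv))),
               counts$alt[i, , drop = FALSE], check.names = FALSE,
               stringsAsFactors = FALSE)
  } else data.frame()
  list(summary = summary, detail = detail)
}
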