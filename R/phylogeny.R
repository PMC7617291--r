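# Two presence patterns are compatible on a rooted tree iff they are
# nested or disjoint (the four-gamete condition with an all-absent root).
.compatible <- function(a, b) {
  ab <- sum(a & b)
  ab == 0 || ab == sum(a) || ab == sum(b)
}

#' Build a rooted tree from presence patterns
#'
#' Maximum-compatibility perfect phylogeny: variants are grouped by
#' identical presence pattern; patterns are accepted greedily in order of
#' decreasing variant support (ties broken towards the lexicographically
#' earlier pattern), discarding any pattern incompatible with an already
#' accepted one; the accepted laminar family is assembled into a rooted
#' tree whose edges carry mutation counts. A fully incompatible matrix
#' degrades to a star tree with every conflict logged.
#'
#' Internal-edge patterns (more than one sample, fewer than all) carried
#' by fewer than `min_internal_support` variants are discarded as
#' noise-level evidence - a single miscalled read pattern must not
#' restructure the tree - and logged. Singleton and full-set patterns are
#' exempt: leaf and root edges exist structurally. At typical error rates
#' (~1e-3) and depths (~80x), chance co-patterns of one or two misread
#' variants recur often enough across thousands of sites that internal
#' edges supported by fewer than 3 variants sit below the noise floor.
#'
#' @param presence logical matrix (variants x samples) with dimnames;
#'   all-absent rows are dropped and reported
#' @param min_internal_support minimum variant support for an internal
#'   edge (default 3)
#' @return list with `newick` (canonical: children sorted by smallest leaf
#'   label; branch lengths are mutation counts, the root edge carries
#'   mutations shared by every sample), `edges`, `dropped`, `assignments`,
#'   `leaves`, `n_retained`
#' @keywords internal
build_tree_from_patterns <- function(presence, min_internal_support = 3) {
  leaves <- colnames(presence)
  if (is.null(leaves)) stopf("presence matrix needs sample column names")
  storage.mode(presence) <- "logical"
  if (is.null(rownames(presence))) {
    rownames(presence) <- sprintf("v%05d", seq_len(nrow(presence)))
  }
  absent <- rowSums(presence) == 0
  dropped_absent <- rownames(presence)[absent]
  presence <- presence[!absent, , drop = FALSE]
  pat_key <- apply(presence, 1, function(z) paste(as.integer(z), collapse = ""))
  tab <- table(pat_key)
  ord <- order(-as.vector(tab), names(tab))
  keys <- names(tab)[ord]
  support <- as.vector(tab)[ord]
  key_to_set <- function(k) as.logical(as.integer(strsplit(k, "")[[1]]))

  accepted <- list()
  acc_keys <- character(0)
  acc_n <- integer(0)
  dropped <- data.frame(pattern = character(0), n_mut = integer(0),
                        conflict_with = character(0), stringsAsFactors = FALSE)
  n_leaf <- ncol(presence)
  for (i in seq_along(keys)) {
    set <- key_to_set(keys[i])
    if (sum(set) > 1 && sum(set) < n_leaf &&
        support[i] < min_internal_support) {
      dropped <- rbind(dropped, data.frame(
        pattern = keys[i], n_mut = support[i], conflict_with = "low_support",
        stringsAsFactors = FALSE))
      next
    }
    clash <- NULL
    for (j in seq_along(accepted)) {
      if (!.compatible(set, accepted[[j]])) { clash <- acc_keys[j]; break }
    }
    if (is.null(clash)) {
      accepted[[length(accepted) + 1]] <- set
      acc_keys <- c(acc_keys, keys[i])
      acc_n <- c(acc_n, support[i])
    } else {
      dropped <- rbind(dropped, data.frame(
        pattern = keys[i], n_mut = support[i], conflict_with = clash,
        stringsAsFactors = FALSE))
    }
  }

  # Laminar family -> tree. Nodes: accepted patterns plus the full set
  # (root) and every leaf singleton; duplicates merge.
  full_key <- paste(rep(1L, length(leaves)), collapse = "")
  node_keys <- acc_keys
  counts <- stats::setNames(acc_n, acc_keys)
  for (k in c(full_key, vapply(seq_along(leaves), function(i) {
    z <- integer(length(leaves)); z[i] <- 1L; paste(z, collapse = "")
  }, character(1)))) {
    if (!k %in% node_keys) {
      node_keys <- c(node_keys, k)
      counts[k] <- 0L
    }
  }
  sets <- lapply(node_keys, key_to_set)
  names(sets) <- node_keys
  sizes <- vapply(sets, sum, numeric(1))
  parent <- stats::setNames(rep(NA_character_, length(node_keys)), node_keys)
  for (k in node_keys) {
    if (k == full_key) next
    sup <- node_keys[vapply(node_keys, function(q) {
      sizes[q] > sizes[k] && all(sets[[k]] <= sets[[q]])
    }, logical(1))]
    parent[k] <- sup[which.min(sizes[sup])]
  }
  min_leaf <- vapply(node_keys, function(k) min(leaves[sets[[k]]]), character(1))
  newick_of <- function(k) {
    kids <- node_keys[!is.na(parent) & parent == k]
    kids <- kids[order(min_leaf[kids])]
    lab <- if (sizes[k] == 1) leaves[sets[[k]]] else ""
    inner <- if (length(kids)) {
      paste0("(", paste(vapply(kids, newick_of, character(1)), collapse = ","),
             ")")
    } else ""
    paste0(inner, lab, ":", counts[k])
  }
  newick <- paste0(newick_of(full_key), ";")
  if (!startsWith(newick, "(")) newick <- paste0("(", sub(";$", "", newick), ");")

  acc_idx <- match(pat_key, acc_keys)
  assignments <- data.frame(
    variant_id = rownames(presence),
    pattern = ifelse(is.na(acc_idx), NA_character_, pat_key),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    pattern = node_keys,
    samples = vapply(node_keys, function(k)
      paste(leaves[sets[[k]]], collapse = ","), character(1)),
    n_mut = as.integer(counts[node_keys]), stringsAsFactors = FALSE)
  structure(list(newick = newick, edges = edges, dropped = dropped,
                 dropped_absent = dropped_absent, assignments = assignments,
                 leaves = leaves, n_retained = sum(acc_n)),
            class = "somafoot_tree")
}

#' @export
print.somafoot_tree <- function(x, ...) {
  cat("<somafoot_tree>", length(x$leaves), "leaves,",
      x$n_retained, "assigned mutations\n")
  cat(x$newick, "\n")
  if (nrow(x$dropped)) {
    cat(sprintf("conflicts: %d pattern(s) (%d mutations) discarded\n",
                nrow(x$dropped), sum(x$dropped$n_mut)))
  }
  invisible(x)
}

#' Convert a reconstructed tree to an ape phylo
#' @param tree a `somafoot_tree`
#' @return an `ape::phylo` (branch lengths are mutation counts)
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = tree$newick)
}

#' Build the variant x sample presence matrix for phylogeny reconstruction
#'
#' A variant is present in a sample when it is called by the beta-binomial
#' model and its VAF clears a presence floor scaled by tumour purity
#' (`tumour_floor * purity` in tumours, `normal_floor` in normals).
#' Variants in regions where every tumour sample is non-diploid are
#' excluded (their VAFs are not comparable across samples), with reasons
#' listed.
#'
#' The tumour floor must clear the VAF that contaminating normal cells can
#' contribute on their own: a kidney clonal expansion at cell fraction f
#' adds up to `(1 - purity) f / 2` to a tumour sample's VAF without the
#' tumour lineage carrying the mutation at all, so the default floor of
#' `0.2 * purity` keeps large normal-tissue clones from masquerading as
#' tumour mutations while remaining far below the clonal expectation
#' `purity / 2`.
#'
#' @param calls result of [call_true_somatic()]
#' @param counts the matching [variant_counts()]
#' @param samples sample metadata (purity required for tumour samples)
#' @param segments optional segment table for the non-diploid exclusion
#' @param tumour_floor,normal_floor presence floors on VAF
#' @return list with `presence` (logical matrix) and `excluded`
#'   (data.frame of variant ids and reasons)
#' @export
build_presence_matrix <- function(calls, counts, samples, segments = NULL,
                                  tumour_floor = 0.2, normal_floor = 0.03) {
  v <- counts$variants
  vaf <- vaf_matrix(counts)
  pres <- calls$call
  for (s in colnames(pres)) {
    ti <- samples$tissue[samples$sample_id == s]
    if (ti == "tumour") {
      pu <- samples$purity[samples$sample_id == s]
      if (is.na(pu)) stopf("missing purity for tumour sample %s", s)
      floor_s <- tumour_floor * pu
    } else floor_s <- normal_floor
    pres[, s] <- pres[, s] & !is.na(vaf[, s]) & vaf[, s] >= floor_s
  }
  excluded <- data.frame(variant_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(segments)) {
    tumours <- samples$sample_id[samples$tissue == "tumour"]
    if (length(tumours)) {
      nondip <- sapply(tumours, function(s) {
        cn <- .cn_lookup(segments, s, v$chrom, v$pos)
        !is.na(cn) & cn != 2
      })
      if (is.null(dim(nondip))) nondip <- matrix(nondip, nrow = nrow(v))
      all_nondip <- rowSums(nondip) == length(tumours)
      if (any(all_nondip)) {
        excluded <- data.frame(variant_id = v$variant_id[all_nondip],
                               reason = "all_tumours_non_diploid",
                               stringsAsFactors = FALSE)
        pres <- pres[!all_nondip, , drop = FALSE]
      }
    }
  }
  list(presence = pres, excluded = excluded)
}

#' Reconstruct the developmental and tumour phylogeny of one patient
#'
#' Wraps [build_tree_from_patterns()] with an optional developmental
#' constraint: when timing labels and sample tissues are supplied,
#' early-mosaic variants (which by definition pervade blood and kidney)
#' that are called in at least one normal sample have their presence
#' expanded to every blood and kidney sample before pattern grouping,
#' pinning them to edges above the blood/kidney split and healing
#' sporadic dropout in the shallower normal samples. Variants with an
#' early label but no normal-sample call are left with their observed
#' pattern - there is no call-level evidence to anchor the expansion, and
#' an inconsistent pattern is better surfaced as a logged conflict than
#' silently rewritten.
#'
#' @param presence logical variant x sample matrix (see
#'   [build_presence_matrix()])
#' @param timing optional named timing vector (names = variant ids)
#' @param samples optional sample metadata (required with `timing`)
#' @param min_internal_support minimum variant support for an internal
#'   edge (see [build_tree_from_patterns()])
#' @return a `somafoot_tree`
#' @export
reconstruct_phylogeny <- function(presence, timing = NULL, samples = NULL,
                                  min_internal_support = 3) {
  if (!is.null(timing)) {
    if (is.null(samples)) stopf("samples metadata required with timing labels")
    normals <- samples$sample_id[samples$tissue %in% c("blood", "kidney")]
    normals <- intersect(normals, colnames(presence))
    early <- names(timing)[timing == "early_mosaic" & !is.na(timing)]
    early <- intersect(early, rownames(presence))
    if (length(early) && length(normals)) {
      anchored <- rowSums(presence[early, normals, drop = FALSE]) > 0
      presence[early[anchored], normals] <- TRUE
    }
  }
  build_tree_from_patterns(presence, min_internal_support)
}

#' Relatedness of a secondary neoplasm to a primary tumour
#'
#' Counts mutations present in at least one primary and one secondary
#' sample, excluding mutations with normal-tissue timing: the shared
#' embryonic background of two independent neoplasms must not count as
#' tumour-lineage sharing, and mutations attributable to a clonal
#' expansion of normal kidney (late mosaic) are precursor-tissue, not
#' tumour-lineage, evidence - a high-fraction kidney clone contaminates
#' every biopsy taken through that kidney. Any remaining shared mutation
#' above the threshold implies a shared mutational trunk; otherwise the
#' neoplasms evolved independently (parallel evolution of the same driver
#' with zero shared passengers still reads as independent).
#'
#' @param presence logical variant x sample matrix
#' @param primary,secondary disjoint sample id sets
#' @param timing optional named timing vector (variant ids)
#' @param exclude_timing timing labels excluded from the shared count
#' @param threshold shared-mutation count above which the verdict is
#'   `shared_trunk` (default 0: any shared mutation)
#' @return list with `verdict` (`"shared_trunk"`/`"independent"`),
#'   `n_shared_somatic`, `shared_ids`
#' @export
relatedness <- function(presence, primary, secondary, timing = NULL,
                        exclude_timing = c("early_mosaic", "late_mosaic",
                                           "germline"),
                        threshold = 0) {
  if (length(intersect(primary, secondary))) {
    stopf("primary and secondary sample sets overlap")
  }
  if (!length(primary) || !length(secondary)) {
    stopf("both sample sets must be non-empty")
  }
  keep <- rep(TRUE, nrow(presence))
  if (!is.null(timing)) {
    tm <- timing[rownames(presence)]
    keep <- is.na(tm) | !tm %in% exclude_timing
  }
  in_p <- rowSums(presence[, primary, drop = FALSE]) > 0
  in_s <- rowSums(presence[, secondary, drop = FALSE]) > 0
  shared <- keep & in_p & in_s
  list(verdict = if (sum(shared) > threshold) "shared_trunk" else "independent",
       n_shared_somatic = sum(shared),
       shared_ids = rownames(presence)[shared])
}

#' VAF heatmap matrix
#'
#' VAF of each variant in each sample (NA at zero depth), with rows
#' ordered by timing class and then by presence pattern, mirroring the
#' embryonic-to-tumour VAF inflation display.
#'
#' @param counts a [variant_counts()]
#' @param variant_ids,sample_ids rows and columns to include
#' @param timing optional named timing vector used for row ordering
#' @return numeric matrix
#' @export
vaf_heatmap <- function(counts, variant_ids = counts$variants$variant_id,
                        sample_ids = counts$sample_ids, timing = NULL) {
  if (!length(variant_ids) || !length(sample_ids)) {
    stopf("variant and sample lists must be non-empty")
  }
  vaf <- vaf_matrix(counts)[variant_ids, sample_ids, drop = FALSE]
  pattern <- apply(!is.na(vaf) & vaf > 0, 1, function(z)
    paste(as.integer(z), collapse = ""))
  if (!is.null(timing)) {
    lev <- c("germline", "early_mosaic", "late_mosaic", "tumour_only")
    tm <- factor(timing[variant_ids], levels = lev)
    ord <- order(tm, pattern, decreasing = c(FALSE, TRUE), method = "radix")
  } else {
    ord <- order(pattern, decreasing = TRUE)
  }
  vaf[ord, , drop = FALSE]
}
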