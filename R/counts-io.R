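#' Multi-sample variant count container
#'
#' Holds one substitution/indel table together with per-sample read counts:
#' raw alt and total depth, plus high-quality recounts (reads surviving
#' mapping/base-quality thresholds upstream). Count invariants
#' (`alt <= depth`, `hq_alt <= alt`, `hq_depth <= depth`) are enforced.
#'
#' @param variants data.frame with at least `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`; optional `channel`, `near_indel_bp`, `gene`,
#'   `consequence`, `protein_pos`
#' @param alt,depth,hq_alt,hq_depth integer matrices, variants x samples,
#'   with identical dimnames
#' @return object of class `variant_counts`
#' @export
variant_counts <- function(variants, alt, depth, hq_alt, hq_depth) {
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stopf("variants table must have columns: %s", paste(need, collapse = ", "))
  }
  mats <- list(alt = alt, depth = depth, hq_alt = hq_alt, hq_depth = hq_depth)
  for (nm in names(mats)) {
    if (!is.matrix(mats[[nm]]) || nrow(mats[[nm]]) != nrow(variants)) {
      stopf("'%s' must be a matrix with one row per variant", nm)
    }
  }
  if (!identical(colnames(alt), colnames(depth)) ||
      !identical(colnames(alt), colnames(hq_alt)) ||
      !identical(colnames(alt), colnames(hq_depth))) {
    stopf("count matrices must share identical sample columns")
  }
  if (any(alt > depth)) stopf("alt counts exceed depth")
  if (any(hq_alt > alt)) stopf("hq_alt counts exceed alt")
  if (any(hq_depth > depth)) stopf("hq_depth counts exceed depth")
  for (nm in names(mats)) storage.mode(mats[[nm]]) <- "integer"
  alt <- mats$alt; depth <- mats$depth
  hq_alt <- mats$hq_alt; hq_depth <- mats$hq_depth
  structure(list(variants = variants, alt = alt, depth = depth,
                 hq_alt = hq_alt, hq_depth = hq_depth,
                 sample_ids = colnames(alt)),
            class = "variant_counts")
}

#' @export
print.variant_counts <- function(x, ...) {
  cat(sprintf("<variant_counts> %d variants x %d samples\n",
              nrow(x$variants), length(x$sample_ids)))
  cat("samples:", paste(x$sample_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Variant allele fractions
#'
#' @param counts a [variant_counts()] object
#' @param high_quality use the high-quality recounts instead of raw counts
#' @return numeric matrix of alt/depth; `NA` where depth is zero
#' @export
vaf_matrix <- function(counts, high_quality = FALSE) {
  a <- if (high_quality) counts$hq_alt else counts$alt
  d <- if (high_quality) counts$hq_depth else counts$depth
  out <- a / d
  out[d == 0] <- NA_real_
  out
}

#' Write/read a variant count table as TSV
#'
#' Wide dialect: `chrom`, `pos` (1-based), `ref`, `alt`, `channel` and
#' per-sample columns `<sample>.alt`, `<sample>.depth`, `<sample>.hq_alt`,
#' `<sample>.hq_depth`.
#'
#' @param counts a [variant_counts()]
#' @param path TSV path
#' @return the path (write) or a `variant_counts` (read)
#' @export
write_counts <- function(counts, path) {
  per <- lapply(counts$sample_ids, function(s) {
    stats::setNames(
      data.frame(counts$alt[, s], counts$depth[, s], counts$hq_alt[, s],
                 counts$hq_depth[, s]),
      paste0(s, c(".alt", ".depth", ".hq_alt", ".hq_depth")))
  })
  tab <- do.call(cbind, c(list(counts$variants), per))
  write_tsv(tab, path, comment = "variant positions are 1-based")
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  tab <- read_tsv(path)
  cc <- grep("\\.(alt|depth|hq_alt|hq_depth)$", names(tab), value = TRUE)
  sample_ids <- unique(sub("\\.(alt|depth|hq_alt|hq_depth)$", "", cc))
  pull <- function(suffix) {
    m <- as.matrix(tab[, paste0(sample_ids, suffix), drop = FALSE])
    dimnames(m) <- list(tab$variant_id, sample_ids)
    storage.mode(m) <- "integer"
    m
  }
  variants <- tab[, setdiff(names(tab), cc), drop = FALSE]
  variant_counts(variants, pull(".alt"), pull(".depth"), pull(".hq_alt"),
                 pull(".hq_depth"))
}

#' Export counts as a minimal VCF
#'
#' One genotype column per sample with `AD` (ref,alt) and `DP` FORMAT
#' fields; genotypes are left unstated (`./.`) since calling is the
#' pipeline's job, not the container's.
#'
#' @param counts a [variant_counts()]
#' @param path output path (plain text VCF)
#' @return the path, invisibly
#' @export
write_vcf <- function(counts, path) {
  v <- counts$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", counts$sample_ids), collapse = "\t"))
  gt <- sapply(counts$sample_ids, function(s) {
    sprintf("./.:%d,%d:%d", counts$depth[, s] - counts$alt[, s],
            counts$alt[, s], counts$depth[, s])
  })
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(v))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", ".", ".",
                "GT:AD:DP", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
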