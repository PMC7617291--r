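# Local copy number lookup: the most specific (shortest) overlapping segment
# wins, so focal events override whole-chromosome baselines.
.cn_lookup <- function(segments, sample_id, chrom, pos) {
  out <- rep(NA_integer_, length(chrom))
  best_len <- rep(Inf, length(chrom))
  seg <- segments[segments$sample_id == sample_id, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    hit <- chrom == seg$chrom[i] & pos > seg$start[i] & pos <= seg$end[i]
    len <- seg$end[i] - seg$start[i]
    take <- hit & len < best_len
    out[take] <- seg$cn_total[i]
    best_len[take] <- len
  }
  out
}

.expected_normal_cn <- function(chrom, sex) {
  ifelse(chrom %in% c("chrX", "chrY", "X", "Y") & sex == "M", 1L, 2L)
}

#' Pool read counts across the normal samples of one patient
#'
#' Sums alt and depth over blood and kidney samples, restricted to samples
#' whose local copy number at the site equals the expected normal ploidy
#' (2 on autosomes, 1 on male sex chromosomes). With no segment table all
#' normals are assumed diploid and pooled.
#'
#' @param counts a [variant_counts()]
#' @param samples sample metadata (`sample_id`, `tissue`, `sex`)
#' @param segments optional copy-number segment table
#' @return data.frame with `variant_id`, `pooled_alt`, `pooled_depth`,
#'   `n_pooled` and a comma-separated `pooled_samples` audit column
#' @export
pool_normal_counts <- function(counts, samples, segments = NULL) {
  normals <- samples$sample_id[samples$tissue %in% c("blood", "kidney")]
  if (!length(normals)) stopf("no normal (blood/kidney) samples to pool")
  v <- counts$variants
  sex <- samples$sex[1]
  expected <- .expected_normal_cn(v$chrom, sex)
  n_var <- nrow(v)
  pooled_alt <- pooled_depth <- rep(0L, n_var)
  n_pooled <- rep(0L, n_var)
  who <- matrix(FALSE, n_var, length(normals), dimnames = list(NULL, normals))
  for (s in normals) {
    eligible <- if (is.null(segments)) rep(TRUE, n_var) else {
      cn <- .cn_lookup(segments, s, v$chrom, v$pos)
      ifelse(is.na(cn), TRUE, cn == expected)
    }
    pooled_alt <- pooled_alt + ifelse(eligible, counts$alt[, s], 0L)
    pooled_depth <- pooled_depth + ifelse(eligible, counts$depth[, s], 0L)
    n_pooled <- n_pooled + eligible
    who[, s] <- eligible
  }
  data.frame(variant_id = v$variant_id, pooled_alt = pooled_alt,
             pooled_depth = pooled_depth, n_pooled = n_pooled,
             pooled_samples = apply(who, 1, function(z)
               paste(normals[z], collapse = ",")),
             stringsAsFactors = FALSE)
}

#' Germline versus somatic classification by exact binomial test
#'
#' One-sided exact binomial test of pooled normal counts against the
#' germline heterozygous null: the p-value is the lower-tail probability
#' `P(X <= pooled_alt | pooled_depth, null_vaf)`. The null VAF is 0.5, or
#' 0.95 on sex chromosomes of males (hemizygous sites, allowing for error).
#' The null is rejected - the variant called somatic - when the p-value
#' falls below `alpha` (default the stringency constant 1e-5 of the
#' alternative hypothesis rate).
#'
#' @param pooled_alt,pooled_depth pooled normal counts (vectorised)
#' @param null_vaf 0.5 or 0.95 per variant
#' @param alpha rejection threshold for the one-sided p-value
#' @return data.frame with `p_value` and `class` in
#'   `{germline, somatic, unresolved}` (unresolved when pooled depth is 0)
#' @export
classify_germline_somatic <- function(pooled_alt, pooled_depth,
                                      null_vaf = 0.5, alpha = 1e-5) {
  if (any(pooled_alt > pooled_depth)) stopf("pooled_alt exceeds pooled_depth")
  p <- stats::pbinom(pooled_alt, pooled_depth, null_vaf)
  cls <- ifelse(p < alpha, "somatic", "germline")
  unres <- is.na(pooled_depth) | pooled_depth == 0
  p[unres] <- NA_real_
  cls[unres] <- "unresolved"
  data.frame(p_value = p, class = cls, stringsAsFactors = FALSE)
}

#' Classify every variant of a patient as germline or somatic
#'
#' Pools normal counts ([pool_normal_counts()]), selects the null VAF by
#' contig and sex, and applies [classify_germline_somatic()]. Sites where
#' no normal sample is copy-number eligible are reported unresolved.
#'
#' @inheritParams pool_normal_counts
#' @param alpha rejection threshold
#' @return data.frame keyed by `variant_id` with pooled counts, `null_vaf`,
#'   `p_value` and `class`
#' @export
classify_variants <- function(counts, samples, segments = NULL, alpha = 1e-5) {
  pooled <- pool_normal_counts(counts, samples, segments)
  v <- counts$variants
  sex <- samples$sex[1]
  null_vaf <- ifelse(v$chrom %in% c("chrX", "chrY", "X", "Y") & sex == "M",
                     0.95, 0.5)
  cls <- classify_germline_somatic(pooled$pooled_alt, pooled$pooled_depth,
                                   null_vaf, alpha)
  cls$class[pooled$n_pooled == 0] <- "unresolved"
  cbind(pooled, null_vaf = null_vaf, cls)
}

#' Read-level site filters
#'
#' Flags variants failing any of the burden filters: proximity to an indel
#' (within 10 bp), at least `blood_min_alt` supporting reads in any blood
#' sample (a germline/contamination guard used when counting somatic
#' burdens), a consistently low-depth site (below `low_depth` in every
#' sample of the patient), or a high-quality read fraction `hq_alt/alt` at
#' or below `hq_min` in any sample with supporting reads (strict: 0.76
#' passes, 0.75 fails).
#'
#' @param counts a [variant_counts()]
#' @param samples sample metadata
#' @param indel_bp proximity threshold in bp (fail when `near_indel_bp` <= it)
#' @param blood_min_alt blood read threshold (fail when any blood sample has
#'   at least this many alt reads); skipped with a warning when the patient
#'   has no blood sample
#' @param hq_min minimum high-quality read fraction (strict >)
#' @param low_depth depth below which a site counts as low-depth
#' @return data.frame with `variant_id`, `pass` and a comma-separated
#'   `reasons` column (empty string when passing); filters commute, so the
#'   reason set is order-independent
#' @export
apply_site_filters <- function(counts, samples, indel_bp = 10,
                               blood_min_alt = 3, hq_min = 0.75,
                               low_depth = 10) {
  v <- counts$variants
  n <- nrow(v)
  reasons <- vector("list", n)
  add <- function(idx, code) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  if (!is.null(v$near_indel_bp)) {
    add(!is.na(v$near_indel_bp) & v$near_indel_bp <= indel_bp, "near_indel")
  }
  blood <- samples$sample_id[samples$tissue == "blood"]
  if (!length(blood)) {
    warnf("no blood sample: blood read filter skipped")
  } else {
    bl <- counts$alt[, blood, drop = FALSE]
    add(apply(bl >= blood_min_alt, 1, any), "blood_reads")
  }
  add(apply(counts$depth < low_depth, 1, all), "low_depth")
  frac_ok <- counts$hq_alt / counts$alt > hq_min
  frac_ok[counts$alt == 0] <- TRUE
  add(apply(!frac_ok, 1, any), "low_hq_fraction")
  out <- data.frame(
    variant_id = v$variant_id,
    pass = vapply(reasons, function(r) is.null(r), logical(1)),
    reasons = vapply(reasons, function(r) paste(r, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  out
}

#' Developmental-timing classification of somatic variants
#'
#' Maps per-tissue presence of each somatic variant to its developmental
#' timing: `early_mosaic` when the variant pervades both blood and kidney
#' (it arose before blood and kidney lineages diverged within the
#' mesoderm), `late_mosaic` when confined to normal kidney, `tumour_only`
#' when seen in tumour samples alone. Germline-classified variants map to
#' `germline` timing. A somatic variant present in blood but not in sampled
#' kidney is still labelled `early_mosaic` - blood plus any kidney-lineage
#' descendant (tumour) implies a pre-split origin - and flagged
#' `blood_restricted` for review.
#'
#' @param class classification vector (`germline`/`somatic`/`unresolved`)
#' @param present_blood,present_kidney,present_tumour logical vectors of
#'   per-tissue presence calls
#' @return data.frame with `timing` and `flag` columns
#' @export
classify_timing <- function(class, present_blood, present_kidney,
                            present_tumour) {
  n <- length(class)
  timing <- rep(NA_character_, n)
  flag <- rep("", n)
  timing[class == "germline"] <- "germline"
  som <- class == "somatic"
  timing[som & present_blood & present_kidney] <- "early_mosaic"
  timing[som & !present_blood & present_kidney] <- "late_mosaic"
  timing[som & !present_blood & !present_kidney & present_tumour] <- "tumour_only"
  bres <- som & present_blood & !present_kidney
  timing[bres] <- "early_mosaic"
  flag[bres] <- "blood_restricted"
  data.frame(timing = timing, flag = flag, stringsAsFactors = FALSE)
}
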