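#' Select informative sites for an LOH screen
#'
#' Within a tumour-defined LOH region, informative sites are candidate
#' germline heterozygous positions at which the tumour is effectively
#' homozygous: pooled tumour VAF at or above `hom_cutoff` (retained allele
#' = alt) or at or below `1 - hom_cutoff` (retained allele = ref), at
#' pooled depth of at least `depth_min`. Candidate heterozygosity is taken
#' from pooled normal VAF in `het_range` when normal samples are supplied
#' and assumed otherwise (or supplied via `known_het` when the normals
#' themselves may carry the LOH, e.g. a germline event).
#'
#' @param counts a [variant_counts()]
#' @param tumour_samples tumour sample ids whose pooled counts define
#'   homozygosity
#' @param region list with `chrom`, `start`, `end` (0-based half-open)
#' @param depth_min pooled tumour depth floor (default 10)
#' @param hom_cutoff tumour homozygosity VAF cutoff (default 0.9)
#' @param normal_samples optional normal sample ids for the heterozygosity
#'   check
#' @param het_range pooled normal VAF window defining heterozygous
#'   candidates
#' @param known_het optional variant ids asserted heterozygous (overrides
#'   the pooled-normal check)
#' @return data.frame with `variant_id` and `retained` (`"alt"`/`"ref"`);
#'   errors with "uninformative region" when empty
#' @export
select_informative_sites <- function(counts, tumour_samples, region,
                                     depth_min = 10, hom_cutoff = 0.9,
                                     normal_samples = NULL,
                                     het_range = c(0.3, 0.7),
                                     known_het = NULL) {
  v <- counts$variants
  in_region <- v$chrom == region$chrom & v$pos > region$start &
    v$pos <= region$end
  t_alt <- rowSums(counts$alt[, tumour_samples, drop = FALSE])
  t_depth <- rowSums(counts$depth[, tumour_samples, drop = FALSE])
  t_vaf <- t_alt / pmax(t_depth, 1)
  het <- if (!is.null(known_het)) {
    v$variant_id %in% known_het
  } else if (!is.null(normal_samples)) {
    n_alt <- rowSums(counts$alt[, normal_samples, drop = FALSE])
    n_depth <- rowSums(counts$depth[, normal_samples, drop = FALSE])
    n_vaf <- n_alt / pmax(n_depth, 1)
    n_vaf >= het_range[1] & n_vaf <= het_range[2]
  } else rep(TRUE, nrow(v))
  hom_alt <- t_vaf >= hom_cutoff
  hom_ref <- t_vaf <= 1 - hom_cutoff
  keep <- in_region & het & t_depth >= depth_min & (hom_alt | hom_ref)
  if (!any(keep)) stopf("uninformative region: no qualifying homozygous sites")
  data.frame(variant_id = v$variant_id[keep],
             retained = ifelse(hom_alt[keep], "alt", "ref"),
             stringsAsFactors = FALSE)
}

#' Retained-allele VAF profile of a normal sample
#'
#' Converts counts at informative sites to the VAF of the tumour-retained
#' allele (alt/depth where alt is retained, (depth-alt)/depth where ref
#' is) and averages across sites. Zero-depth sites are dropped with a
#' warning; all-zero depth is an error.
#'
#' @param counts a [variant_counts()]
#' @param sample_id the normal sample to profile
#' @param sites data.frame from [select_informative_sites()]
#' @return list with `vaf` (per-site data.frame), `mean_vaf`,
#'   `pooled_alt`, `pooled_depth` (pooled retained-allele counts)
#' @export
normal_vaf_profile <- function(counts, sample_id, sites) {
  i <- match(sites$variant_id, counts$variants$variant_id)
  if (anyNA(i)) stopf("unknown site id(s) in profile request")
  a <- counts$alt[i, sample_id]
  d <- counts$depth[i, sample_id]
  ret <- ifelse(sites$retained == "alt", a, d - a)
  keep <- d > 0
  if (!any(keep)) stopf("all informative sites have zero depth in %s", sample_id)
  if (any(!keep)) warnf("dropping %d zero-depth site(s)", sum(!keep))
  vaf <- ret[keep] / d[keep]
  list(vaf = data.frame(variant_id = sites$variant_id[keep],
                        retained = sites$retained[keep],
                        retained_reads = ret[keep], depth = d[keep],
                        vaf = vaf, stringsAsFactors = FALSE),
       mean_vaf = mean(vaf),
       pooled_alt = sum(ret[keep]), pooled_depth = sum(d[keep]))
}

#' Flag mosaic LOH and invert the cell fraction
#'
#' A normal sample is flagged when its mean retained-allele VAF strictly
#' exceeds 0.5. The LOH cell fraction is solved from the mean VAF under
#' each mode: copy-neutral `f = 2 (mean - 0.5)`; deletion
#' `f = 2 - 1/mean`; both clipped to \[0, 1\]. Because a mean of 0.5 is
#' the no-LOH expectation, the flag is advisory - a one-sided exact
#' binomial test of the pooled retained counts against 0.5 is reported
#' alongside, and the per-site B-allele-frequency table is returned for
#' inspection.
#'
#' @param profile result of [normal_vaf_profile()]
#' @param mode declared mode hypothesis, `"copy_neutral"` or `"deletion"`
#' @return list with `flag`, `mean_vaf`, `n_sites`, `f_hat` (declared
#'   mode), `f_hat_copy_neutral`, `f_hat_deletion`, `p_pooled`, `baf`
#' @export
flag_mosaic_loh <- function(profile, mode = c("copy_neutral", "deletion")) {
  mode <- match.arg(mode)
  m <- profile$mean_vaf
  f_cn <- min(1, max(0, 2 * (m - 0.5)))
  f_del <- if (m > 0.5) min(1, max(0, 2 - 1 / m)) else 0
  p <- stats::binom.test(profile$pooled_alt, profile$pooled_depth, 0.5,
                         alternative = "greater")$p.value
  list(flag = m > 0.5, mean_vaf = m, n_sites = nrow(profile$vaf),
       f_hat = if (mode == "deletion") f_del else f_cn,
       f_hat_copy_neutral = f_cn, f_hat_deletion = f_del,
       p_pooled = p, baf = profile$vaf)
}

#' Screen all normal samples of a patient for LOH in a region
#'
#' Convenience wrapper: derives the tumour LOH region from the segment
#' table (the widest tumour segment with `cn_minor = 0`) when `region` is
#' `NULL`, selects informative sites, and profiles every blood and kidney
#' sample.
#'
#' @param counts a [variant_counts()]
#' @param samples sample metadata
#' @param segments segment table (used to find the tumour LOH region)
#' @param region optional explicit region `list(chrom, start, end)`
#' @param mode mode hypothesis passed to [flag_mosaic_loh()]
#' @param ... further arguments to [select_informative_sites()]
#' @return data.frame, one row per normal sample, with screen results;
#'   `NULL` when no tumour LOH region exists
#' @export
screen_loh <- function(counts, samples, segments, region = NULL,
                       mode = c("copy_neutral", "deletion"), ...) {
  mode <- match.arg(mode)
  tumour <- samples$sample_id[samples$tissue == "tumour"]
  if (is.null(region)) {
    seg <- segments[segments$sample_id %in% tumour & segments$cn_minor == 0 &
                      !segments$chrom %in% c("chrX", "chrY"), , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    w <- which.max(seg$end - seg$start)
    region <- list(chrom = seg$chrom[w], start = seg$start[w], end = seg$end[w])
    mode <- if (seg$cn_total[w] < 2) "deletion" else "copy_neutral"
  }
  sites <- select_informative_sites(counts, tumour, region, ...)
  normals <- samples$sample_id[samples$tissue %in% c("blood", "kidney")]
  rows <- lapply(normals, function(s) {
    pr <- normal_vaf_profile(counts, s, sites)
    fl <- flag_mosaic_loh(pr, mode)
    data.frame(sample_id = s,
               region = sprintf("%s:%d-%d", region$chrom, region$start,
                                region$end),
               mode = mode, n_sites = fl$n_sites, mean_vaf = fl$mean_vaf,
               flag = fl$flag, f_hat = fl$f_hat,
               f_hat_copy_neutral = fl$f_hat_copy_neutral,
               f_hat_deletion = fl$f_hat_deletion, p_pooled = fl$p_pooled,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
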