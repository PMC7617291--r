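# Hand-built count containers and small simulator configurations shared
# across test files. All fixtures are constructed in code.

# A minimal patient: one blood, one kidney, two tumour biopsies, with
# explicit per-sample counts for a handful of crafted variants.
make_counts <- function(alt, depth, hq_alt = NULL, hq_depth = NULL,
                        chrom = NULL, pos = NULL, near_indel_bp = NULL) {
  n <- nrow(alt)
  variants <- data.frame(
    variant_id = sprintf("v%03d", seq_len(n)),
    chrom = chrom %||% rep("chr1", n),
    pos = pos %||% (seq_len(n) * 1000L),
    ref = "C", alt = "T",
    near_indel_bp = near_indel_bp %||% rep(1000L, n),
    stringsAsFactors = FALSE)
  if (is.null(colnames(alt))) {
    colnames(alt) <- c("B", "K", "T1", "T2")[seq_len(ncol(alt))]
  }
  rn <- list(variants$variant_id, colnames(alt))
  dimnames(alt) <- dimnames(depth) <- rn
  hq_alt <- hq_alt %||% alt
  hq_depth <- hq_depth %||% depth
  dimnames(hq_alt) <- dimnames(hq_depth) <- rn
  variant_counts(variants, alt, depth, hq_alt, hq_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_samples <- function(sample_ids = c("B", "K", "T1", "T2"),
                         tissue = c("blood", "kidney", "tumour", "tumour"),
                         sex = "F", purity = 0.7, tumour = c(NA, NA, 1, 1)) {
  data.frame(sample_id = sample_ids, patient_id = "PT", tissue = tissue,
             sex = sex, age_months = 36,
             purity = ifelse(tissue == "tumour", purity, NA_real_),
             tumour = tumour, stringsAsFactors = FALSE)
}

# small, fast simulator configuration used where the full default size is
# not needed; any field can be overridden
small_config <- function(...) {
  defaults <- list(n_patients = 1, n_germline = 120, n_loh_sites = 20,
                   n_chrx_germline = 5, n_embryonic = 15, n_clone = 10,
                   n_private_clone = 5, n_trunk = 40, n_branch = 10,
                   artifact_sites = 10, n_panel = 20)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# independent lower-tail binomial oracle: direct pmf summation
binom_lower_oracle <- function(k, n, p) sum(stats::dbinom(0:k, n, p))

# independent beta-binomial upper tail in log space (logsumexp), kept
# separate from the package's plain-space summation
betabinom_upper_oracle <- function(alt, depth, mu, rho) {
  if (alt == 0) return(1)
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  k <- alt:depth
  lp <- lchoose(depth, k) + lbeta(k + a, depth - k + b) - lbeta(a, b)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

strip_lengths <- function(newick) gsub(":[0-9.]+", "", newick)
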