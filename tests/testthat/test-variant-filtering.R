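test_that("pooled normal counts sum eligible samples only", {
  alt <- rbind(c(20, 18, 30, 31))
  depth <- rbind(c(40, 42, 60, 60))
  counts <- make_counts(alt, depth)
  colnames(counts$alt)
  samples <- make_samples()
  pooled <- pool_normal_counts(counts, samples)
  expect_identical(pooled$pooled_alt, 38L)
  expect_identical(pooled$pooled_depth, 82L)
  expect_identical(pooled$pooled_samples, "B,K")

  # a normal that is not diploid at the site is left out of the pool
  seg <- data.frame(chrom = "chr1", start = 0L, end = 10^6,
                    sample_id = c("B", "K"), cn_total = c(2L, 1L),
                    cn_minor = c(1L, 0L), purity = NA_real_)
  pooled2 <- pool_normal_counts(counts, samples, seg)
  expect_identical(pooled2$pooled_alt, 20L)
  expect_identical(pooled2$pooled_depth, 40L)
  expect_identical(pooled2$pooled_samples, "B")
  expect_identical(pooled2$n_pooled, 1L)
})

test_that("exact binomial classification matches a brute-force pmf oracle", {
  # frozen oracle values: sum_{k<=alt} C(n,k) p^k (1-p)^(n-k)
  expect_equal(binom_lower_oracle(40, 80, 0.5), 0.5444639, tolerance = 1e-6)
  cls <- classify_germline_somatic(40, 80, 0.5)
  expect_equal(cls$p_value, binom_lower_oracle(40, 80, 0.5), tolerance = 1e-12)
  expect_identical(cls$class, "germline")

  # all-reference reads: closed form 2^-40
  cls0 <- classify_germline_somatic(0, 40, 0.5)
  expect_equal(cls0$p_value, 2^-40, tolerance = 1e-12)
  expect_identical(cls0$class, "somatic")

  # male X null: 2 alt reads of 60 at p = 0.95 is overwhelmingly somatic
  clsx <- classify_germline_somatic(2, 60, 0.95)
  expect_equal(clsx$p_value, binom_lower_oracle(2, 60, 0.95),
               tolerance = 1e-12)
  expect_lt(clsx$p_value, 1e-50)
  expect_identical(clsx$class, "somatic")

  # p-value non-increasing as pooled_alt decreases at fixed depth
  p <- classify_germline_somatic(0:60, 60, 0.5)$p_value
  expect_true(all(diff(p) >= 0))

  # zero depth is unresolved, not a division by zero
  u <- classify_germline_somatic(0, 0, 0.5)
  expect_identical(u$class, "unresolved")
  expect_true(is.na(u$p_value))
  expect_error(classify_germline_somatic(5, 3), "exceeds")
})

test_that("male sex chromosomes use the hemizygous null", {
  alt <- rbind(c(39, 40, 1, 2), c(1, 0, 28, 30))
  depth <- rbind(c(40, 41, 40, 40), c(41, 39, 40, 40))
  counts <- make_counts(alt, depth, chrom = c("chrX", "chrX"))
  samples <- make_samples(sex = "M")
  seg <- do.call(rbind, lapply(samples$sample_id, function(s)
    data.frame(chrom = "chrX", start = 0L, end = 10^8, sample_id = s,
               cn_total = 1L, cn_minor = 0L, purity = NA_real_)))
  cls <- classify_variants(counts, samples, seg)
  expect_identical(cls$null_vaf, c(0.95, 0.95))
  # hemizygous germline (VAF ~ 1 in both normals) accepted as germline
  expect_identical(cls$class, c("germline", "somatic"))
})

test_that("site filters apply the stated thresholds strictly and commute", {
  alt <- rbind(c(0, 0, 30, 28),   # clean somatic
               c(0, 0, 100, 0),   # hq fraction boundary cases below
               c(3, 0, 25, 25),   # 3 blood reads: fails burden filter
               c(2, 0, 25, 25),   # 2 blood reads: passes
               c(0, 0, 30, 30),   # near an indel
               c(0, 0, 5, 4))     # consistently low depth
  depth <- rbind(c(60, 60, 60, 60), c(60, 60, 150, 60), c(60, 60, 60, 60),
                 c(60, 60, 60, 60), c(60, 60, 60, 60), c(8, 9, 9, 8))
  hq_alt <- alt; hq_alt[2, 3] <- 74   # 74/100 = 0.74 <= 0.75 fails
  counts <- make_counts(alt, depth, hq_alt = hq_alt,
                        near_indel_bp = c(1000L, 1000L, 1000L, 1000L, 8L, 1000L))
  samples <- make_samples()
  f <- apply_site_filters(counts, samples)
  expect_identical(f$pass, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(f$reasons[2], "low_hq_fraction")
  expect_identical(f$reasons[3], "blood_reads")
  expect_identical(f$reasons[5], "near_indel")
  expect_identical(f$reasons[6], "low_depth")

  # 0.76 passes the strict > 0.75 rule
  hq_alt2 <- alt; hq_alt2[2, 3] <- 76
  counts2 <- make_counts(alt, depth, hq_alt = hq_alt2,
                         near_indel_bp = counts$variants$near_indel_bp)
  expect_true(apply_site_filters(counts2, samples)$pass[2])

  # permuting variant rows yields the same per-variant verdicts
  perm <- c(4, 2, 6, 1, 5, 3)
  countsp <- make_counts(alt[perm, ], depth[perm, ], hq_alt = hq_alt[perm, ],
                         near_indel_bp = counts$variants$near_indel_bp[perm])
  fp <- apply_site_filters(countsp, samples)
  expect_identical(fp$pass, f$pass[perm])

  # a patient without blood skips the blood filter with a warning
  nb <- make_samples(sample_ids = c("K", "T1"), tissue = c("kidney", "tumour"),
                     tumour = c(NA, 1))
  counts_nb <- make_counts(alt[, c(2, 3)], depth[, c(2, 3)])
  expect_warning(apply_site_filters(counts_nb, nb), "blood")
})

test_that("developmental timing follows tissue presence", {
  cls <- c("somatic", "somatic", "somatic", "germline", "somatic")
  tm <- classify_timing(cls,
                        present_blood = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                        present_kidney = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                        present_tumour = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(tm$timing, c("early_mosaic", "late_mosaic", "tumour_only",
                                "germline", "early_mosaic"))
  expect_identical(tm$flag, c("", "", "", "", "blood_restricted"))
})

test_that("germline/somatic recovery on a small synthetic patient is accurate", {
  cfg <- small_config(seed = 21)
  p <- simulate_patient(cfg, 1)
  cls <- classify_variants(p$counts, p$samples, p$segments)
  tr <- p$truth$variants
  nonart <- tr$class != "artifact"
  truth <- ifelse(tr$class == "germline", "germline", "somatic")
  expect_lt(mean(cls$class[nonart] != truth[nonart]), 0.02)
})
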