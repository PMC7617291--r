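test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(purity = 0), "purity")
  expect_error(sim_config(purity = 1.2), "purity")
  expect_error(sim_config(clone_fraction = 0.3, n_clone = 0), "n_clone")
  expect_error(sim_config(loh = list(mode = "inversion", f = 0.4)), "mode")
  expect_error(sim_config(loh = list(mode = "deletion", f = 1.4)), "f must be")
  expect_error(sim_config(n_germline = 10, n_loh_sites = 8,
                          n_chrx_germline = 5), "exceed")
  expect_error(sim_config(seq_error = -0.1), "seq_error")
  expect_silent(validate_sim_config(sim_config()))
})

test_that("a fixed seed reproduces a patient exactly and seeds separate patients", {
  cfg <- small_config(n_patients = 2, seed = 42)
  p1 <- simulate_patient(cfg, 1)
  p2 <- simulate_patient(cfg, 1)
  expect_identical(p1, p2)
  q <- simulate_patient(cfg, 2)
  expect_false(identical(p1$counts$alt, q$counts$alt))
  expect_error(simulate_patient(cfg, 3), "patient_index")
})

test_that("truth classes partition the emitted variant set", {
  p <- simulate_patient(small_config(seed = 7), 1)
  tr <- p$truth$variants
  expect_identical(sort(tr$variant_id), sort(p$counts$variants$variant_id))
  expect_false(any(duplicated(tr$variant_id)))
  expect_true(all(tr$class %in% c("germline", "embryonic_mosaic",
                                  "kidney_clone", "tumour_trunk",
                                  "tumour_private", "artifact")))
  # count invariants of the container
  expect_true(all(p$counts$alt <= p$counts$depth))
  expect_true(all(p$counts$hq_alt <= p$counts$alt))
  expect_true(all(p$counts$hq_depth <= p$counts$depth))
})

test_that("empirical VAF converges to its configured expectation at saturating depth", {
  cfg <- small_config(depth_mean = 10000, seed = 3,
                      loh = list(mode = "deletion", f = 0.4))
  p <- simulate_patient(cfg, 1)
  tr <- p$truth$variants
  vaf <- vaf_matrix(p$counts)
  kid <- p$samples$sample_id[p$samples$tissue == "kidney"]

  # germline heterozygous variants on diploid autosomes: expectation 0.5
  gl <- tr$class == "germline" & p$counts$variants$chrom == "chr1"
  tol <- 3 * sqrt(0.25 / 10000)
  expect_true(all(abs(vaf[gl, kid] - 0.5) < tol + 0.01))

  # embryonic mutations track their tissue fractions
  em <- tr$class == "embryonic_mosaic"
  expect_true(all(abs(vaf[em, kid] - tr$cf_kidney[em] / 2) < 0.02))

  # deletion-mode LOH at f = 0.4: retained-allele sites at 1/(2-f) = 0.625
  ret <- !is.na(tr$loh_retained) & tr$loh_retained == "alt"
  expect_true(mean(abs(vaf[ret, kid] - 0.625) < 0.02) > 0.95)
  lost <- !is.na(tr$loh_retained) & tr$loh_retained == "ref"
  expect_true(mean(abs(vaf[lost, kid] - 0.375) < 0.02) > 0.95)
})

test_that("trunk burden follows the age model across replicates", {
  ages <- c(6, 36, 60)
  means <- vapply(ages, function(a) {
    burdens <- vapply(1:25, function(s) {
      cfg <- sim_config(n_patients = 1, n_germline = 10, n_loh_sites = 0,
                        n_chrx_germline = 0, n_embryonic = 0, n_clone = 0,
                        clone_fraction = 0, n_private_clone = 0,
                        n_branch = 0, artifact_sites = 0, n_panel = 2,
                        age_months = a, seed = s)
      p <- simulate_patient(cfg, 1)
      sum(p$truth$variants$class == "tumour_trunk")
    }, numeric(1))
    mean(burdens)
  }, numeric(1))
  expected <- 80 + 5 * ages
  # Poisson sample means: 3 sigma around the configured expectation
  expect_true(all(abs(means - expected) < 3 * sqrt(expected / 25)))
  expect_true(all(diff(means) > 0))
})

test_that("truth tree is a perfect phylogeny of the emitted presence at zero error", {
  # purity 1: no contaminating normal cells, so raw presence (alt > 0) at
  # saturating depth coincides with the true presence patterns
  cfg <- small_config(seed = 11, seq_error = 0, artifact_sites = 0,
                      depth_mean = 10000, purity = 1)
  p <- simulate_patient(cfg, 1)
  somatic <- p$truth$variants$class %in%
    c("embryonic_mosaic", "kidney_clone", "tumour_trunk", "tumour_private")
  pres <- p$counts$alt[somatic, , drop = FALSE] > 0
  tree <- somafoot:::build_tree_from_patterns(pres)
  expect_identical(nrow(tree$dropped), 0L)
  expect_identical(tree$newick, p$truth$tree_newick)
})

test_that("cohort writing is manifest-complete, deterministic and seed-sensitive", {
  cfg <- small_config(n_patients = 3, n_germline = 40, n_loh_sites = 5,
                      n_chrx_germline = 0, n_trunk = 10, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  m1 <- simulate_cohort(cfg, d1, overwrite = TRUE)
  expect_length(m1$patients, 3)
  expect_identical(nrow(m1$files), 3L * 6L + 1L)
  expect_true(all(file.exists(file.path(d1, m1$files$path))))

  m2 <- simulate_cohort(cfg, d2, overwrite = TRUE)
  expect_identical(m1$files$md5, m2$files$md5)

  cfg2 <- small_config(n_patients = 3, n_germline = 40, n_loh_sites = 5,
                       n_chrx_germline = 0, n_trunk = 10, seed = 6)
  m3 <- simulate_cohort(cfg2, d3, overwrite = TRUE)
  expect_false(all(m1$files$md5 == m3$files$md5))

  # refuses to clobber a non-empty directory
  expect_error(simulate_cohort(cfg, d1), "non-empty")
})

test_that("count tables round-trip through TSV and export to VCF", {
  p <- simulate_patient(small_config(n_germline = 30, n_loh_sites = 5,
                                     n_chrx_germline = 0, seed = 9), 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(p$counts, path)
  back <- read_counts(path)
  expect_identical(back$alt, p$counts$alt)
  expect_identical(back$depth, p$counts$depth)
  expect_identical(back$variants$pos, p$counts$variants$pos)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(p$counts, vcf)
  lines <- readLines(vcf)
  expect_true(any(startsWith(lines, "##fileformat=VCF")))
  expect_identical(sum(!startsWith(lines, "#")), nrow(p$counts$variants))
})

test_that("spectrum sampling matches its signature mixture", {
  refs <- load_reference_signatures()
  # degenerate mixture: empirical proportions within 3 sigma of the spectrum
  x <- spectrum_sample(c(SYN1 = 1), 1e6, seed = 1)
  expect_identical(sum(x), 1e6L)
  p <- refs[, "SYN1"]
  se <- sqrt(p * (1 - p) / 1e6)
  # 4.5 sigma: simultaneous over 96 channels
  expect_true(all(abs(x / 1e6 - p) <= 4.5 * se + 1e-9))

  # two-spectrum mixture matches 0.6 A + 0.4 B
  y <- spectrum_sample(c(SYN1 = 0.6, SYN2 = 0.4), 1e6, seed = 2)
  pm <- 0.6 * refs[, "SYN1"] + 0.4 * refs[, "SYN2"]
  expect_true(all(abs(y / 1e6 - pm) <= 4.5 * sqrt(pm * (1 - pm) / 1e6) + 1e-9))

  expect_identical(sum(spectrum_sample(c(SYN3 = 1), 0)), 0L)
  expect_error(spectrum_sample(c(SYN1 = 1.2, SYN2 = -0.2), 10), "non-negative")
  expect_error(spectrum_sample(c(SYN1 = 0.7), 10), "sum to 1")
})
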