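pm <- function(rows, samples, times) {
  m <- do.call(rbind, rep(rows, times))
  colnames(m) <- samples
  rownames(m) <- sprintf("v%03d", seq_len(nrow(m)))
  m > 0
}

test_that("shared/private patterns build the expected caterpillar tree", {
  m <- pm(list(c(1, 1), c(1, 0), c(0, 1)), c("A", "B"), c(50, 30, 20))
  tree <- somafoot:::build_tree_from_patterns(m)
  expect_identical(tree$newick, "(A:30,B:20):50;")
  expect_identical(nrow(tree$dropped), 0L)
  expect_identical(sum(tree$edges$n_mut), 100L)
  expect_identical(tree$n_retained, 100L)
  ph <- as_phylo(tree)
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, c("A", "B"))
  expect_identical(ph$root.edge, 50)
})

test_that("samples sharing nothing branch independently from the root", {
  m <- pm(list(c(1, 0), c(0, 1)), c("A", "B"), c(30, 20))
  tree <- somafoot:::build_tree_from_patterns(m)
  expect_identical(tree$newick, "(A:30,B:20):0;")
})

test_that("a single sample yields one edge carrying all its mutations", {
  m <- pm(list(1), "A", 12)
  tree <- somafoot:::build_tree_from_patterns(m)
  expect_identical(tree$newick, "(A:12);")
  expect_identical(tree$n_retained, 12L)
})

test_that("incompatible patterns are resolved by variant support and logged", {
  # {A,B} x5 vs {B,C} x3 violate nested-or-disjoint; the minority loses
  m <- pm(list(c(1, 1, 0), c(0, 1, 1)), c("A", "B", "C"), c(5, 3))
  tree <- somafoot:::build_tree_from_patterns(m)
  expect_identical(tree$dropped$pattern, "011")
  expect_identical(tree$dropped$n_mut, 3L)
  expect_identical(tree$dropped$conflict_with, "110")
  expect_identical(sum(tree$edges$n_mut), 5L)
  # assignments of dropped variants are NA, accepted ones carry patterns
  expect_identical(sum(is.na(tree$assignments$pattern)), 3L)

  # equal support: the lexicographically earlier pattern wins
  m2 <- pm(list(c(1, 1, 0), c(0, 1, 1)), c("A", "B", "C"), c(3, 3))
  tree2 <- somafoot:::build_tree_from_patterns(m2)
  expect_identical(tree2$dropped$pattern, "110")

  # mutually incompatible patterns: the majority survives, the rest is
  # logged
  m3 <- pm(list(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)), c("A", "B", "C"),
           c(4, 3, 3))
  tree3 <- somafoot:::build_tree_from_patterns(m3)
  expect_identical(strip_lengths(tree3$newick), "((A,B),C);")
  expect_identical(nrow(tree3$dropped), 2L)
  expect_identical(sum(tree3$dropped$n_mut), 6L)

  # when no internal pattern clears the support floor the tree is a star
  m4 <- pm(list(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)), c("A", "B", "C"),
           c(2, 2, 2))
  tree4 <- somafoot:::build_tree_from_patterns(m4)
  expect_identical(strip_lengths(tree4$newick), "(A,B,C);")
})

test_that("internal edges below the support floor are pruned as noise", {
  m <- pm(list(c(1, 1, 1, 1), c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0)),
          c("A", "B", "C", "D"), c(10, 2, 5, 5))
  tree <- somafoot:::build_tree_from_patterns(m)
  expect_identical(tree$dropped$conflict_with, "low_support")
  expect_identical(strip_lengths(tree$newick), "(A,B,C,D);")
  # root and leaf patterns are exempt from the floor
  expect_identical(tree$n_retained, 20L)
})

test_that("newick output round-trips and mutation counts are conserved", {
  m <- pm(list(c(1, 1, 1, 1), c(1, 1, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0),
               c(0, 0, 0, 1)),
          c("A", "B", "C", "D"), c(7, 9, 4, 11, 6))
  tree <- somafoot:::build_tree_from_patterns(m)
  expect_identical(nrow(tree$dropped), 0L)
  expect_identical(sum(tree$edges$n_mut), 37L)
  ph <- as_phylo(tree)
  expect_identical(ape::Ntip(ph), 4L)
  # serialising the ape tree and re-reading preserves the topology
  tmp <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(ph, tmp)
  ph2 <- ape::read.tree(tmp)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ph), ape::unroot(ph2))), 0)
})

test_that("presence matrix applies calls, purity-scaled floors and CN exclusion", {
  alt <- rbind(c(0, 0, 20, 22),    # trunk-like, in the all-tumour gain region
               c(0, 0, 21, 20),    # same but one tumour diploid
               c(0, 3, 25, 24),    # kidney + tumours
               c(0, 0, 4, 0))      # called but below the tumour floor
  depth <- matrix(80L, 4, 4, dimnames = list(NULL, c("B", "K", "T1", "T2")))
  counts <- make_counts(alt, depth, pos = c(5000L, 6000L, 7000L, 8000L))
  samples <- make_samples(purity = 0.8)
  call <- alt >= 3
  dimnames(call) <- dimnames(counts$alt)
  calls <- list(p = 1 - call, q = 1 - call, call = call)
  seg <- rbind(
    data.frame(chrom = "chr1", start = 0L, end = 10^6,
               sample_id = c("B", "K", "T1", "T2"), cn_total = 2L,
               cn_minor = 1L, purity = NA_real_),
    data.frame(chrom = "chr1", start = 4500L, end = 5500L,
               sample_id = c("T1", "T2"), cn_total = 3L, cn_minor = 1L,
               purity = 0.8),
    data.frame(chrom = "chr1", start = 5500L, end = 6500L,
               sample_id = "T1", cn_total = 3L, cn_minor = 1L, purity = 0.8))
  res <- build_presence_matrix(calls, counts, samples, seg)
  expect_identical(res$excluded$variant_id, "v001")
  expect_identical(res$excluded$reason, "all_tumours_non_diploid")
  expect_identical(rownames(res$presence), c("v002", "v003", "v004"))
  # VAF 25/80 = 0.31 >= 0.2 * 0.8 floor; 4/80 = 0.05 is below it
  expect_identical(unname(res$presence["v003", ]), c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(unname(res$presence["v004", ]), c(FALSE, FALSE, FALSE, FALSE))

  # tumour purity is required
  samples_np <- samples; samples_np$purity[3] <- NA
  expect_error(build_presence_matrix(calls, counts, samples_np, seg),
               "purity")
})

test_that("the developmental constraint heals anchored early-mosaic dropout", {
  m <- pm(list(c(1, 1, 1, 1), c(0, 1, 1, 1), c(0, 0, 1, 1)),
          c("B", "K", "T1", "T2"), c(5, 3, 6))
  samples <- make_samples(sample_ids = c("B", "K", "T1", "T2"))
  timing <- stats::setNames(rep("tumour_only", nrow(m)), rownames(m))
  timing[6:8] <- "early_mosaic"  # the three {K,T1,T2} variants
  tree <- reconstruct_phylogeny(m, timing = timing, samples = samples)
  # anchored by their kidney call, the early variants join the root edge
  expect_identical(nrow(tree$dropped), 0L)
  expect_identical(strip_lengths(tree$newick), "(B,K,(T1,T2));")
  root <- tree$edges$n_mut[tree$edges$pattern == "1111"]
  expect_identical(root, 8L)

  # without timing the {K,T1,T2} pattern conflicts with nothing here but
  # forms its own internal edge
  tree2 <- reconstruct_phylogeny(m)
  expect_identical(strip_lengths(tree2$newick), "(B,(K,(T1,T2)));")
})

test_that("relatedness counts shared non-developmental mutations only", {
  m <- pm(list(c(0, 0, 1, 1), c(1, 1, 1, 1), c(0, 1, 1, 1), c(0, 0, 1, 0)),
          c("B", "K", "T1", "T2"), c(3, 2, 2, 4))
  timing <- stats::setNames(c(rep("tumour_only", 3),
                              rep("early_mosaic", 2),
                              rep("late_mosaic", 2),
                              rep("tumour_only", 4)), rownames(m))
  r <- relatedness(m, "T1", "T2", timing = timing)
  expect_identical(r$verdict, "shared_trunk")
  expect_identical(r$n_shared_somatic, 3L)

  # only developmental sharing: independent
  r2 <- relatedness(m[4:7, , drop = FALSE], "T1", "T2",
                    timing = timing[4:7])
  expect_identical(r2$verdict, "independent")
  expect_identical(r2$n_shared_somatic, 0L)

  expect_error(relatedness(m, c("T1", "T2"), "T2"), "overlap")
  expect_error(relatedness(m, character(0), "T2"), "non-empty")
})

test_that("VAF heatmaps expose embryonic-to-tumour inflation", {
  alt <- rbind(c(8, 7, 28, 27), c(0, 0, 30, 0))
  depth <- matrix(80L, 2, 4, dimnames = list(NULL, c("B", "K", "T1", "T2")))
  depth2 <- depth; depth2[2, 4] <- 0L
  alt[2, 4] <- 0
  counts <- make_counts(alt, depth2)
  h <- vaf_heatmap(counts)
  expect_true(is.na(h["v002", "T2"]))
  expect_equal(h["v002", "T1"], 30 / 80)
  expect_equal(unname(h["v001", c("B", "T1")]), c(8 / 80, 28 / 80))
  expect_error(vaf_heatmap(counts, variant_ids = character(0)), "non-empty")
})

test_that("reconstruction recovers the true topology across seeded cohorts", {
  ok <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_patients = 1, n_germline = 50, n_loh_sites = 5,
                      n_chrx_germline = 0, n_embryonic = 20, n_clone = 15,
                      n_private_clone = 6, n_tumours = 2,
                      samples_per_tumour = 2, n_trunk = 40, n_branch = 15,
                      artifact_sites = 8, n_panel = 25, seed = 100 + s)
    p <- simulate_patient(cfg, 1)
    panel <- simulate_panel(p, cfg, seed = 200 + s)
    res <- suppressWarnings(
      analyse_patient(p$counts, p$segments, p$samples, panel))
    if (identical(strip_lengths(res$tree$newick),
                  strip_lengths(p$truth$tree_newick))) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
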