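# Toy genome used by the simulator: three contigs are enough to exercise
# autosomal pooling, the chr11p LOH screen and the male sex-chromosome null.
.sim_genome <- list(
  chr_lengths = c(chr1 = 2e8, chr11 = 1.35e8, chrX = 1.5e8),
  loh_region  = list(chrom = "chr11", start = 0, end = 53700000),
  gain_region = list(chrom = "chr1", start = 10000000, end = 20000000),
  wt1_pos     = 32420000
)

.sim_classes <- c("germline", "embryonic_mosaic", "kidney_clone",
                  "tumour_trunk", "tumour_private", "artifact")

.default_signature_weights <- function() {
  list(
    germline  = c(SYN1 = 1),
    embryonic = c(SYN1 = 0.7, SYN2 = 0.3),
    clone     = c(SYN1 = 0.7, SYN2 = 0.3),
    trunk     = c(SYN1 = 0.5, SYN3 = 0.3, SYN5 = 0.2),
    private   = c(SYN1 = 0.5, SYN3 = 0.3, SYN5 = 0.2),
    artifact  = c(SYN6 = 1)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration describing one simulated study: patients
#' with a blood sample, a normal kidney sample and one or more tumours
#' (optionally multi-sampled), carrying germline heterozygous variants,
#' embryonic mosaic mutations shared unevenly between blood and kidney,
#' a kidney clonal expansion preceding the tumour, tumour trunk and private
#' mutations, overdispersed artifact sites, and optionally a mosaic chr11p
#' loss of heterozygosity.
#'
#' Trunk burden follows the age model `burden_intercept + burden_slope *
#' age_months` (Poisson-distributed) unless `n_trunk` pins it. Embryonic
#' per-tissue cell fractions are a shared lineage fraction
#' `Beta(embryonic_shape)` perturbed per tissue by an asymmetry factor
#' `Beta(embryonic_asym_shape)`, so blood and kidney fractions are
#' correlated but unequal.
#'
#' @param n_patients number of patients in the cohort
#' @param depth_mean mean sequencing depth (per-site Poisson mean)
#' @param n_germline heterozygous germline variants per patient (includes
#'   the chr11p and chrX subsets below)
#' @param n_loh_sites germline variants placed on chr11p (informative sites
#'   for the LOH screen)
#' @param n_chrx_germline germline variants placed on chrX
#' @param n_embryonic early mosaic mutations shared by blood and kidney
#' @param embryonic_shape Beta shape pair for the shared lineage fraction
#' @param embryonic_min_fraction lower bound of the lineage fraction: the
#'   generator emulates the mosaic mutations a study can actually detect
#'   and use, i.e. those arising in the first few cell generations; later
#'   mutations with vanishing tissue fractions are below the detection
#'   regime the downstream stages are specified for
#' @param embryonic_asym_shape Beta shape pair for the per-tissue asymmetry
#' @param n_clone mutations private to the kidney clonal expansion that is
#'   the tumour precursor (shared with tumour 1 when `clone_is_precursor`)
#' @param clone_fraction cell fraction of that expansion in kidney
#' @param clone_is_precursor whether the kidney clone is ancestral to
#'   tumour 1 (its mutations then appear clonally in tumour 1)
#' @param n_private_clone mutations of a second, tumour-unrelated kidney clone
#' @param private_clone_fraction cell fraction of the tumour-unrelated clone
#' @param n_tumours independent tumours (bilateral disease when 2)
#' @param samples_per_tumour biopsies per tumour
#' @param n_trunk trunk mutations per tumour; `NULL` draws from the age model
#' @param n_branch private mutations per tumour sample
#' @param burden_intercept,burden_slope age model for expected trunk burden
#' @param age_months patient age at diagnosis in months
#' @param purity tumour cell fraction of tumour samples
#' @param seq_error per-site base error rate
#' @param artifact_sites number of systematically noisy loci
#' @param artifact_mu,artifact_rho beta-binomial mean and overdispersion of
#'   artifact-site noise
#' @param hq_retention probability a read survives high-quality recounting
#' @param artifact_hq_retention same for reads supporting artifact calls
#'   (below 0.75 so the high-quality-fraction filter is exercisable)
#' @param loh optional mosaic chr11p LOH spec:
#'   `list(mode = "deletion"|"copy_neutral", f = <kidney cell fraction>,
#'   in_blood = FALSE)`; `f = 1` with `in_blood = TRUE` emulates germline LOH
#' @param sex `"M"`, `"F"`, or `NULL` to alternate by patient index
#' @param annotate_drivers attach toy gene/consequence annotations to two
#'   trunk mutations (a CTNNB1-like hotspot and a WT1 truncating variant)
#' @param signature_weights named list of signature mixtures per mutation
#'   set (`germline`, `embryonic`, `clone`, `trunk`, `private`, `artifact`)
#'   over the packaged reference signatures
#' @param n_panel blood samples in the simulated reference panel
#' @param seed integer seed; a fixed seed reproduces every output byte
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_patients = 3,
                       depth_mean = 80,
                       n_germline = 1500,
                       n_loh_sites = 200,
                       n_chrx_germline = 20,
                       n_embryonic = 50,
                       embryonic_shape = c(2, 5),
                       embryonic_min_fraction = 0.25,
                       embryonic_asym_shape = c(10, 3),
                       n_clone = 30,
                       clone_fraction = 0.3,
                       clone_is_precursor = TRUE,
                       n_private_clone = 15,
                       private_clone_fraction = 0.15,
                       n_tumours = 1,
                       samples_per_tumour = 2,
                       n_trunk = NULL,
                       n_branch = 50,
                       burden_intercept = 80,
                       burden_slope = 5,
                       age_months = 36,
                       purity = 0.7,
                       seq_error = 1e-3,
                       artifact_sites = 50,
                       artifact_mu = 0.03,
                       artifact_rho = 0.25,
                       hq_retention = 0.97,
                       artifact_hq_retention = 0.6,
                       loh = NULL,
                       sex = NULL,
                       annotate_drivers = TRUE,
                       signature_weights = NULL,
                       n_panel = 50,
                       seed = 1) {
  cfg <- as.list(environment())
  cfg$signature_weights <- signature_weights %||% .default_signature_weights()
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulator configuration
#' @param config a `sim_config`
#' @return the config, invisibly checked; errors on invalid settings
#' @export
validate_sim_config <- function(config) {
  cnt <- c("n_patients", "depth_mean", "n_germline", "n_loh_sites",
           "n_chrx_germline", "n_embryonic", "n_clone", "n_private_clone",
           "n_tumours", "samples_per_tumour", "n_branch", "artifact_sites",
           "n_panel")
  for (f in cnt) {
    if (!is_count(config[[f]])) stopf("config field '%s' must be a non-negative count", f)
  }
  frac <- c("clone_fraction", "private_clone_fraction", "seq_error",
            "hq_retention", "artifact_hq_retention", "artifact_mu",
            "embryonic_min_fraction")
  for (f in frac) {
    if (!is_fraction(config[[f]])) stopf("config field '%s' must be in [0,1]", f)
  }
  if (!is_fraction(config$purity) || config$purity <= 0) {
    stopf("purity must be in (0, 1]")
  }
  if (config$clone_fraction > 0 && config$n_clone == 0) {
    stopf("clone_fraction > 0 requires n_clone > 0")
  }
  if (!is.null(config$n_trunk) && !is_count(config$n_trunk)) {
    stopf("n_trunk must be NULL or a count")
  }
  if (config$n_loh_sites + config$n_chrx_germline > config$n_germline) {
    stopf("n_loh_sites + n_chrx_germline cannot exceed n_germline")
  }
  if (!is.null(config$loh)) {
    if (!config$loh$mode %in% c("deletion", "copy_neutral")) {
      stopf("loh mode must be 'deletion' or 'copy_neutral'")
    }
    if (!is_fraction(config$loh$f)) stopf("loh fraction f must be in [0,1]")
    config$loh$in_blood <- isTRUE(config$loh$in_blood)
  }
  if (!is.null(config$sex) && !config$sex %in% c("M", "F")) {
    stopf("sex must be NULL, 'M' or 'F'")
  }
  invisible(config)
}

#' Read/write a simulator configuration as YAML
#' @param path YAML file path
#' @return `sim_config` (read) or the path invisibly (write)
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$signature_weights)) {
    vals$signature_weights <- lapply(vals$signature_weights, unlist)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config a `sim_config`
#' @export
write_sim_config <- function(config, path) {
  vals <- unclass(config)
  # named numeric vectors survive YAML only as maps
  vals$signature_weights <- lapply(vals$signature_weights, as.list)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Sample a mutation spectrum from a signature mixture
#'
#' Draws `n` mutations whose channel proportions follow the linear mixture
#' of reference signatures given by `weights` (a multinomial draw).
#'
#' @param weights named non-negative weights over reference signatures,
#'   summing to 1 within 1e-9
#' @param n number of mutations
#' @param seed optional seed; `NULL` uses the current RNG state
#' @param references signature matrix (default: packaged synthetic set)
#' @return named integer vector over the 96 channels, totalling `n`
#' @export
spectrum_sample <- function(weights, n, seed = NULL, references = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refs <- references %||% load_reference_signatures()
  if (any(weights < 0)) stopf("signature weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stopf("signature weights must sum to 1")
  if (is.null(names(weights)) || !all(names(weights) %in% colnames(refs))) {
    stopf("weights must be named after reference signatures")
  }
  if (!is_count(n)) stopf("n must be a non-negative count")
  p <- as.vector(refs[, names(weights), drop = FALSE] %*% weights)
  out <- stats::setNames(integer(96), rownames(refs))
  if (n > 0) out[] <- as.integer(stats::rmultinom(1, n, p))
  out
}

.sample_channels <- function(n, weights, refs) {
  if (n == 0) return(character(0))
  p <- as.vector(refs[, names(weights), drop = FALSE] %*% weights)
  sample(rownames(refs), n, replace = TRUE, prob = p)
}

.patient_id <- function(index) sprintf("P%03d", index)

#' Simulate one synthetic patient
#'
#' Generates per-sample read counts, copy-number segments, sample metadata
#' and a truth table for one patient of the configured cohort. Per-sample
#' alt counts at true-variant sites are binomial around the expected VAF
#' implied by tissue cell fraction, tumour purity, local copy number and
#' mutation multiplicity (with the base error rate folded in); artifact
#' sites draw beta-binomial overdispersed noise in every sample.
#' High-quality recounts are binomial thinnings of the raw counts, with a
#' retention below 0.75 for artifact sites.
#'
#' @param config a [sim_config()]
#' @param patient_index 1-based patient index (`<= n_patients`)
#' @return list of class `sim_patient` with elements `counts`
#'   (a `variant_counts` object), `segments`, `samples`, `truth`
#' @export
simulate_patient <- function(config, patient_index = 1) {
  config <- validate_sim_config(config)
  if (patient_index < 1 || patient_index > config$n_patients) {
    stopf("patient_index must be in 1..n_patients")
  }
  set.seed(child_seed(config$seed, patient_index))
  g <- .sim_genome
  pid <- .patient_id(patient_index)
  sex <- config$sex %||% c("M", "F")[1 + patient_index %% 2]
  refs <- load_reference_signatures()
  sw <- config$signature_weights

  ## ---- samples -------------------------------------------------------
  tumour_ids <- unlist(lapply(seq_len(config$n_tumours), function(t) {
    paste0(pid, "_tumour", t, letters[seq_len(config$samples_per_tumour)])
  }))
  tumour_of <- rep(seq_len(config$n_tumours), each = config$samples_per_tumour)
  sample_ids <- c(paste0(pid, "_blood"), paste0(pid, "_kidney"), tumour_ids)
  tissue <- c("blood", "kidney", rep("tumour", length(tumour_ids)))
  samples <- data.frame(
    sample_id = sample_ids, patient_id = pid, tissue = tissue, sex = sex,
    age_months = config$age_months,
    purity = ifelse(tissue == "tumour", config$purity, NA_real_),
    tumour = c(NA, NA, tumour_of), stringsAsFactors = FALSE)

  ## ---- variant classes and positions ---------------------------------
  n_trunk_t <- vapply(seq_len(config$n_tumours), function(t) {
    if (!is.null(config$n_trunk)) config$n_trunk
    else stats::rpois(1, config$burden_intercept +
                        config$burden_slope * config$age_months)
  }, numeric(1))
  n_g <- config$n_germline
  n_g_chr1 <- n_g - config$n_loh_sites - config$n_chrx_germline
  counts_per_class <- c(
    germline = n_g, embryonic_mosaic = config$n_embryonic,
    kidney_clone = config$n_clone + config$n_private_clone,
    tumour_trunk = sum(n_trunk_t),
    tumour_private = config$n_branch * length(tumour_ids),
    artifact = config$artifact_sites)
  class_vec <- rep(names(counts_per_class), counts_per_class)
  n_var <- length(class_vec)

  chrom <- rep("chr1", n_var)
  idx_g <- which(class_vec == "germline")
  chrom[idx_g[seq_len(config$n_loh_sites)]] <- "chr11"
  if (config$n_chrx_germline > 0) {
    chrom[idx_g[config$n_loh_sites + seq_len(config$n_chrx_germline)]] <- "chrX"
  }
  pos <- integer(n_var)
  for (cc in unique(chrom)) {
    i <- chrom == cc
    lim <- if (cc == "chr11") g$loh_region$end else g$chr_lengths[[cc]]
    pos[i] <- as.integer(sort(sample.int(lim, sum(i))))
  }

  edge <- class_vec
  i_clone <- which(class_vec == "kidney_clone")
  edge[i_clone] <- rep(c("clone_precursor", "clone_private"),
                       c(config$n_clone, config$n_private_clone))
  i_trunk <- which(class_vec == "tumour_trunk")
  edge[i_trunk] <- paste0("trunk_t", rep(seq_len(config$n_tumours), n_trunk_t))
  i_priv <- which(class_vec == "tumour_private")
  edge[i_priv] <- paste0("private_", rep(tumour_ids, each = config$n_branch))
  edge[class_vec == "embryonic_mosaic"] <- "embryonic"

  channel <- character(n_var)
  class_sig <- c(germline = "germline", embryonic_mosaic = "embryonic",
                 kidney_clone = "clone", tumour_trunk = "trunk",
                 tumour_private = "private", artifact = "artifact")
  for (cl in names(class_sig)) {
    i <- class_vec == cl
    channel[i] <- .sample_channels(sum(i), sw[[class_sig[[cl]]]], refs)
  }
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)

  near_indel <- rep(1000L, n_var)
  i_art <- which(class_vec == "artifact")
  if (length(i_art)) near_indel[i_art] <- sample(5:500, length(i_art), replace = TRUE)

  gene <- rep(NA_character_, n_var)
  consequence <- rep(NA_character_, n_var)
  protein_pos <- rep(NA_integer_, n_var)
  if (config$annotate_drivers && length(i_trunk) >= 2) {
    t1 <- i_trunk[edge[i_trunk] == "trunk_t1"]
    if (length(t1) >= 2) {
      gene[t1[1]] <- "CTNNB1"; consequence[t1[1]] <- "missense"; protein_pos[t1[1]] <- 45L
      gene[t1[2]] <- "WT1"; consequence[t1[2]] <- "truncating"
      chrom[t1[2]] <- "chr11"; pos[t1[2]] <- as.integer(g$wt1_pos)
    }
  }

  ## ---- true per-tissue cell fractions --------------------------------
  fmin <- config$embryonic_min_fraction
  lin <- fmin + (1 - fmin) *
    stats::rbeta(config$n_embryonic, config$embryonic_shape[1],
                 config$embryonic_shape[2])
  asym_b <- stats::rbeta(config$n_embryonic, config$embryonic_asym_shape[1],
                         config$embryonic_asym_shape[2])
  asym_k <- stats::rbeta(config$n_embryonic, config$embryonic_asym_shape[1],
                         config$embryonic_asym_shape[2])
  cf_blood <- cf_kidney <- numeric(n_var)
  cf_blood[class_vec == "germline"] <- 1
  cf_kidney[class_vec == "germline"] <- 1
  cf_blood[class_vec == "embryonic_mosaic"] <- lin * asym_b
  cf_kidney[class_vec == "embryonic_mosaic"] <- lin * asym_k
  cf_kidney[edge == "clone_precursor"] <- config$clone_fraction
  cf_kidney[edge == "clone_private"] <- config$private_clone_fraction
  # tumour-cell fraction per tumour sample (0/1 at simulation resolution)
  cf_tum <- matrix(0, n_var, length(tumour_ids),
                   dimnames = list(NULL, tumour_ids))
  cf_tum[class_vec %in% c("germline", "embryonic_mosaic"), ] <- 1
  if (config$clone_is_precursor && config$n_tumours >= 1) {
    cf_tum[edge == "clone_precursor", tumour_of == 1] <- 1
  }
  for (t in seq_len(config$n_tumours)) {
    cf_tum[edge == paste0("trunk_t", t), tumour_of == t] <- 1
  }
  for (s in tumour_ids) cf_tum[edge == paste0("private_", s), s] <- 1

  loh <- config$loh
  in_loh <- chrom == g$loh_region$chrom & pos > g$loh_region$start &
    pos <= g$loh_region$end
  retained <- rep(NA_character_, n_var)
  if (!is.null(loh)) {
    i_snp <- which(in_loh & class_vec == "germline")
    retained[i_snp] <- sample(c("alt", "ref"), length(i_snp), replace = TRUE)
  }
  in_gain <- chrom == g$gain_region$chrom & pos > g$gain_region$start &
    pos <= g$gain_region$end
  multiplicity <- rep(1L, n_var)
  if (!is.null(loh) && loh$mode == "copy_neutral") {
    multiplicity[in_loh & edge == "trunk_t1"] <- 2L
  }

  ## ---- expected VAF and depth scale per sample -----------------------
  vaf_exp <- matrix(0, n_var, length(sample_ids),
                    dimnames = list(NULL, sample_ids))
  dscale <- matrix(1, n_var, length(sample_ids),
                   dimnames = list(NULL, sample_ids))
  is_male_x <- chrom == "chrX" & sex == "M"
  dscale[is_male_x, ] <- 0.5

  normal_loh_vaf <- function(f, mode, ret) {
    # retained-allele orientation: VAF of the *alt* allele at a germline
    # het SNP in a tissue where fraction f of cells underwent LOH
    if (mode == "deletion") {
      ifelse(ret == "alt", 1 / (2 - f), (1 - f) / (2 - f))
    } else {
      ifelse(ret == "alt", (1 + f) / 2, (1 - f) / 2)
    }
  }

  for (s in sample_ids) {
    ti <- samples$tissue[samples$sample_id == s]
    if (ti != "tumour") {
      cf <- if (ti == "blood") cf_blood else cf_kidney
      v <- cf / 2
      v[is_male_x & class_vec == "germline"] <- 1
      affected <- !is.null(loh) && (ti == "kidney" || loh$in_blood)
      if (affected) {
        i <- which(!is.na(retained))
        v[i] <- normal_loh_vaf(loh$f, loh$mode, retained[i])
        if (loh$mode == "deletion") dscale[in_loh, s] <- (2 - loh$f) / 2
      }
      vaf_exp[, s] <- v
    } else {
      p <- config$purity
      t <- samples$tumour[samples$sample_id == s]
      cn_t <- rep(2, n_var)
      cn_t[is_male_x] <- 1
      if (t == 1) {
        cn_t[in_gain] <- 3
        if (!is.null(loh)) cn_t[in_loh] <- if (loh$mode == "deletion") 1 else 2
      }
      contam_copies <- rep(2, n_var)  # normal-cell total copies
      contam_copies[is_male_x] <- 1
      D <- p * cn_t + (1 - p) * contam_copies
      # germline variants
      m_t <- rep(1, n_var)
      if (t == 1 && !is.null(loh)) {
        i <- which(!is.na(retained))
        m_t[i] <- ifelse(retained[i] == "alt",
                         if (loh$mode == "deletion") 1 else 2, 0)
      }
      m_t[is_male_x & class_vec == "germline"] <- 1
      ig <- class_vec == "germline"
      contam_alt <- rep(1, n_var)  # het in contaminating normal cells
      vaf_exp[ig, s] <- (p * m_t[ig] + (1 - p) * contam_alt[ig]) / D[ig]
      # somatic variants
      iso <- class_vec %in% c("embryonic_mosaic", "kidney_clone",
                              "tumour_trunk", "tumour_private")
      m <- as.numeric(multiplicity)
      vaf_exp[iso, s] <- (p * cf_tum[iso, s] * m[iso] +
                            (1 - p) * cf_kidney[iso]) / D[iso]
      dscale[, s] <- D / 2
      dscale[is_male_x, s] <- 0.5
    }
  }
  vaf_exp <- pmin(vaf_exp, 1)

  ## ---- draw counts ---------------------------------------------------
  ns <- length(sample_ids)
  depth <- matrix(stats::rpois(n_var * ns, config$depth_mean * dscale),
                  n_var, ns, dimnames = list(NULL, sample_ids))
  e <- config$seq_error
  veff <- vaf_exp * (1 - e) + (1 - vaf_exp) * e
  alt_m <- matrix(stats::rbinom(n_var * ns, depth, veff), n_var, ns,
                  dimnames = list(NULL, sample_ids))
  if (length(i_art)) {
    for (s in sample_ids) {
      alt_m[i_art, s] <- rbetabinom(length(i_art), depth[i_art, s],
                                    config$artifact_mu, config$artifact_rho)
    }
  }
  reten <- ifelse(class_vec == "artifact", config$artifact_hq_retention,
                  config$hq_retention)
  hq_alt <- matrix(stats::rbinom(n_var * ns, alt_m, reten), n_var, ns,
                   dimnames = list(NULL, sample_ids))
  hq_ref <- matrix(stats::rbinom(n_var * ns, depth - alt_m, 0.97), n_var, ns)
  hq_depth <- hq_alt + hq_ref
  dimnames(hq_depth) <- dimnames(hq_alt)

  variants <- data.frame(
    variant_id = sprintf("%s_v%05d", pid, seq_len(n_var)),
    chrom = chrom, pos = pos, ref = ref, alt = alt, channel = channel,
    near_indel_bp = near_indel, gene = gene, consequence = consequence,
    protein_pos = protein_pos, stringsAsFactors = FALSE)
  rownames(alt_m) <- rownames(depth) <- rownames(hq_alt) <-
    rownames(hq_depth) <- variants$variant_id
  counts <- variant_counts(variants, alt_m, depth, hq_alt, hq_depth)

  ## ---- copy-number segments ------------------------------------------
  seg <- list()
  for (s in sample_ids) {
    ti <- samples$tissue[samples$sample_id == s]
    t <- samples$tumour[samples$sample_id == s]
    pu <- samples$purity[samples$sample_id == s]
    cx <- if (sex == "M") c(1L, 0L) else c(2L, 1L)
    base <- data.frame(
      chrom = c("chr1", "chr11", "chrX"), start = 0L,
      end = as.integer(g$chr_lengths), sample_id = s,
      cn_total = c(2L, 2L, cx[1]), cn_minor = c(1L, 1L, cx[2]),
      purity = pu, stringsAsFactors = FALSE)
    if (ti == "tumour" && t == 1) {
      base <- rbind(base, data.frame(
        chrom = g$gain_region$chrom, start = g$gain_region$start,
        end = g$gain_region$end, sample_id = s, cn_total = 3L, cn_minor = 1L,
        purity = pu, stringsAsFactors = FALSE))
      if (!is.null(loh)) {
        base <- rbind(base, data.frame(
          chrom = g$loh_region$chrom, start = g$loh_region$start,
          end = g$loh_region$end, sample_id = s,
          cn_total = if (loh$mode == "deletion") 1L else 2L, cn_minor = 0L,
          purity = pu, stringsAsFactors = FALSE))
      }
    }
    seg[[s]] <- base
  }
  segments <- do.call(rbind, c(seg, list(make.row.names = FALSE)))

  ## ---- truth ----------------------------------------------------------
  truth_var <- data.frame(
    variant_id = variants$variant_id, class = class_vec, edge = edge,
    cf_blood = cf_blood, cf_kidney = cf_kidney, multiplicity = multiplicity,
    loh_retained = retained, stringsAsFactors = FALSE)
  truth_var <- cbind(truth_var,
                     stats::setNames(as.data.frame(cf_tum),
                                     paste0("cf_", tumour_ids)))
  true_presence <- cbind(
    blood = cf_blood > 0, kidney = cf_kidney > 0, cf_tum > 0)
  colnames(true_presence)[1:2] <- c(paste0(pid, "_blood"), paste0(pid, "_kidney"))
  somatic <- class_vec %in% c("embryonic_mosaic", "kidney_clone",
                              "tumour_trunk", "tumour_private")
  # truth construction never prunes: the true tree is exact by definition
  tree <- build_tree_from_patterns(true_presence[somatic, , drop = FALSE],
                                   min_internal_support = 1)
  truth <- list(
    patient_id = pid, sex = sex, age_months = config$age_months,
    variants = truth_var, tree_newick = tree$newick,
    loh_mode = if (is.null(loh)) NA_character_ else loh$mode,
    loh_f = if (is.null(loh)) NA_real_ else loh$f)

  structure(list(counts = counts, segments = segments, samples = samples,
                 truth = truth),
            class = "sim_patient")
}

#' Simulate a reference panel of normal blood samples
#'
#' Draws panel read counts at the patient's variant sites: sequencing-error
#' binomial noise at ordinary sites and overdispersed beta-binomial noise at
#' the patient's artifact sites (systematic artifacts recur across unrelated
#' individuals, which is what makes a panel of normals informative).
#'
#' @param patient a `sim_patient`
#' @param config the generating [sim_config()]
#' @param n_panel number of panel samples
#' @param seed seed (default derived from the config seed)
#' @return list with `alt` and `depth` matrices (site x panel sample) and
#'   `variant_id`
#' @export
simulate_panel <- function(patient, config, n_panel = config$n_panel,
                           seed = child_seed(config$seed, 999983)) {
  if (n_panel < 2) stopf("a reference panel needs at least 2 samples")
  set.seed(seed)
  v <- patient$counts$variants
  n <- nrow(v)
  art <- patient$truth$variants$class == "artifact"
  ids <- sprintf("panel%03d", seq_len(n_panel))
  depth <- matrix(stats::rpois(n * n_panel, config$depth_mean), n, n_panel,
                  dimnames = list(v$variant_id, ids))
  alt <- matrix(stats::rbinom(n * n_panel, depth, config$seq_error), n, n_panel,
                dimnames = list(v$variant_id, ids))
  if (any(art)) {
    for (j in seq_len(n_panel)) {
      alt[art, j] <- rbetabinom(sum(art), depth[art, j],
                                config$artifact_mu, config$artifact_rho)
    }
  }
  list(variant_id = v$variant_id, alt = alt, depth = depth)
}

#' Simulate null-only sites for error-model calibration
#'
#' Generates sites carrying no true somatic mutation in any sample:
#' ordinary sites draw binomial sequencing error, a subset of artifact
#' sites draws overdispersed beta-binomial noise. The same generative
#' process produces a matched reference panel, so the fitted site error
#' models are correctly specified and downstream false-discovery control
#' can be measured directly.
#'
#' @param n_sites total sites
#' @param n_samples patient samples to emit
#' @param n_panel reference panel samples
#' @param depth_mean per-site Poisson depth mean
#' @param seq_error base error rate of ordinary sites
#' @param artifact_sites number of overdispersed sites
#' @param artifact_mu,artifact_rho artifact noise parameters
#' @param seed integer seed
#' @return list with `counts` (a [variant_counts()]) and `panel`
#' @export
simulate_null_sites <- function(n_sites = 2000, n_samples = 5, n_panel = 50,
                                depth_mean = 80, seq_error = 1e-3,
                                artifact_sites = 200, artifact_mu = 0.03,
                                artifact_rho = 0.25, seed = 1) {
  set.seed(seed)
  ids <- sprintf("null_v%05d", seq_len(n_sites))
  art <- seq_len(n_sites) <= artifact_sites
  draw <- function(ncol, prefix) {
    depth <- matrix(stats::rpois(n_sites * ncol, depth_mean), n_sites, ncol)
    alt <- matrix(stats::rbinom(n_sites * ncol, depth, seq_error),
                  n_sites, ncol)
    for (j in seq_len(ncol)) {
      alt[art, j] <- rbetabinom(sum(art), depth[art, j], artifact_mu,
                                artifact_rho)
    }
    dimnames(alt) <- dimnames(depth) <-
      list(ids, sprintf("%s%03d", prefix, seq_len(ncol)))
    list(alt = alt, depth = depth)
  }
  s <- draw(n_samples, "S")
  p <- draw(n_panel, "panel")
  variants <- data.frame(
    variant_id = ids, chrom = "chr1", pos = seq_len(n_sites) * 100L,
    ref = "C", alt = "T", stringsAsFactors = FALSE)
  list(counts = variant_counts(variants, s$alt, s$depth, s$alt, s$depth),
       panel = list(variant_id = ids, alt = p$alt, depth = p$depth))
}

#' Simulate and write a full cohort to disk
#'
#' Writes, per patient, the count table, segment table, sample metadata,
#' panel counts, truth JSON and truth tree Newick, plus a cohort-level
#' config YAML and a manifest with md5 checksums of every file.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory
#' @param overwrite refuse to write into an existing non-empty directory
#'   unless `TRUE`
#' @return the manifest, invisibly
#' @export
simulate_cohort <- function(config, out_dir, overwrite = FALSE) {
  config <- validate_sim_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stopf("output directory '%s' is non-empty; use overwrite = TRUE", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sim_config(config, file.path(out_dir, "config.yaml"))
  files <- "config.yaml"
  patients <- character(config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pat <- simulate_patient(config, i)
    pid <- pat$truth$patient_id
    patients[i] <- pid
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    write_counts(pat$counts, file.path(pdir, "counts.tsv"))
    write_tsv(pat$segments, file.path(pdir, "segments.tsv"),
              comment = "segment coordinates are 0-based half-open")
    write_tsv(pat$samples, file.path(pdir, "samples.tsv"))
    panel <- simulate_panel(pat, config,
                            seed = child_seed(config$seed, 999983 + i))
    ptab <- data.frame(variant_id = panel$variant_id,
                       stats::setNames(as.data.frame(panel$alt),
                                       paste0(colnames(panel$alt), ".alt")),
                       stats::setNames(as.data.frame(panel$depth),
                                       paste0(colnames(panel$depth), ".depth")),
                       check.names = FALSE)
    write_tsv(ptab, file.path(pdir, "panel.tsv"))
    jsonlite::write_json(pat$truth, file.path(pdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(pat$truth$tree_newick, file.path(pdir, "truth_tree.newick"))
    files <- c(files, file.path(pid, c("counts.tsv", "segments.tsv",
                                       "samples.tsv", "panel.tsv",
                                       "truth.json", "truth_tree.newick")))
  }
  md5 <- as.vector(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(package = "somafoot", seed = config$seed,
                   patients = patients,
                   files = data.frame(path = files, md5 = md5,
                                      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
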