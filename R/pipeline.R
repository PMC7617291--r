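.read_panel_tsv <- function(path) {
  tab <- read_tsv(path)
  ac <- grep("\\.alt$", names(tab), value = TRUE)
  ids <- sub("\\.alt$", "", ac)
  alt <- as.matrix(tab[, paste0(ids, ".alt")])
  depth <- as.matrix(tab[, paste0(ids, ".depth")])
  dimnames(alt) <- dimnames(depth) <- list(tab$variant_id, ids)
  list(variant_id = tab$variant_id, alt = alt, depth = depth)
}

.subset_counts <- function(counts, ids) {
  i <- match(ids, counts$variants$variant_id)
  variant_counts(counts$variants[i, , drop = FALSE],
                 counts$alt[i, , drop = FALSE],
                 counts$depth[i, , drop = FALSE],
                 counts$hq_alt[i, , drop = FALSE],
                 counts$hq_depth[i, , drop = FALSE])
}

#' Analyse one patient in memory
#'
#' Runs the full per-patient stage chain: germline/somatic classification,
#' site filters, panel-of-normals error models and beta-binomial presence
#' calls, developmental timing, clone detection, LOH screen, phylogeny
#' reconstruction, relatedness of multiple tumours, driver annotation with
#' cancer cell fractions, and signature deconvolution of the somatic
#' spectrum.
#'
#' @param counts a [variant_counts()]
#' @param segments segment table
#' @param samples sample metadata
#' @param panel panel counts (list with `variant_id`, `alt`, `depth`)
#' @param alpha germline/somatic rejection threshold
#' @param q_cutoff FDR threshold for presence calls
#' @param min_presence_reads read-evidence threshold used (in addition to
#'   the statistical call) when mapping presence to tissues for timing
#' @param roles,hotspots optional driver role/hotspot tables (defaults:
#'   packaged toy tables)
#' @param references signature reference matrix (default packaged)
#' @param cosine_threshold signature deconvolution acceptance threshold
#' @return list of per-stage results
#' @export
analyse_patient <- function(counts, segments, samples, panel,
                            alpha = 1e-5, q_cutoff = 0.005,
                            min_presence_reads = 2,
                            roles = NULL, hotspots = NULL,
                            references = NULL, cosine_threshold = 0.8) {
  classification <- classify_variants(counts, samples, segments, alpha)
  filters <- apply_site_filters(counts, samples)
  # Artifact-prone sites (indel-adjacent, low-depth, low high-quality
  # fraction) are excluded before presence calling; the blood-read filter
  # belongs to burden counting, not to presence.
  hard_fail <- vapply(strsplit(filters$reasons, ","), function(r)
    any(r %in% c("near_indel", "low_depth", "low_hq_fraction")), logical(1))
  somatic_ids <- classification$variant_id[
    classification$class == "somatic" & !hard_fail]
  som_counts <- .subset_counts(counts, somatic_ids)

  panel_idx <- match(somatic_ids, panel$variant_id)
  models <- fit_error_models(list(variant_id = somatic_ids,
                                  alt = panel$alt[panel_idx, , drop = FALSE],
                                  depth = panel$depth[panel_idx, , drop = FALSE]))
  calls <- call_true_somatic(som_counts, models, q_cutoff)

  # Timing presence is read-sensitive: a statistical call OR at least
  # min_presence_reads supporting reads in the tissue (the same >= 2-read
  # evidence convention used for the blood-absence definition). Mosaic
  # variants near the detection floor must not be mistaken for
  # tumour-only mutations.
  tissues <- samples$tissue[match(colnames(calls$call), samples$sample_id)]
  tissue_present <- function(t) {
    cols <- which(tissues == t)
    if (!length(cols)) return(rep(FALSE, nrow(calls$call)))
    ev <- calls$call[, cols, drop = FALSE] |
      (som_counts$alt[, cols, drop = FALSE] >= min_presence_reads)
    rowSums(ev) > 0
  }
  timing_som <- classify_timing(rep("somatic", length(somatic_ids)),
                                tissue_present("blood"),
                                tissue_present("kidney"),
                                tissue_present("tumour"))
  timing <- stats::setNames(rep(NA_character_, nrow(classification)),
                            classification$variant_id)
  timing[classification$class == "germline"] <- "germline"
  timing[somatic_ids] <- timing_som$timing

  clones <- tryCatch(clone_report(calls, som_counts, samples, segments),
                     error = function(e) NULL)
  # het candidates from blood: unaffected by kidney-confined mosaic LOH
  loh <- tryCatch(
    screen_loh(counts, samples, segments,
               normal_samples = samples$sample_id[samples$tissue == "blood"]),
    error = function(e) NULL)

  pm <- build_presence_matrix(calls, som_counts, samples, segments)
  tree <- reconstruct_phylogeny(pm$presence, timing = timing[somatic_ids],
                                samples = samples)

  tum <- samples[samples$tissue == "tumour", , drop = FALSE]
  related <- NULL
  if (!is.null(tum$tumour) && length(unique(tum$tumour)) >= 2) {
    ts <- sort(unique(tum$tumour))
    related <- lapply(ts[-1], function(t2) {
      r <- relatedness(pm$presence,
                       tum$sample_id[tum$tumour == ts[1]],
                       tum$sample_id[tum$tumour == t2],
                       timing = timing[somatic_ids])
      data.frame(primary = ts[1], secondary = t2, verdict = r$verdict,
                 n_shared_somatic = r$n_shared_somatic)
    })
    related <- do.call(rbind, related)
  }

  refs <- references %||% load_reference_signatures()
  spec_tab <- table(factor(som_counts$variants$channel,
                           levels = rownames(refs)))
  spectrum <- stats::setNames(as.integer(spec_tab), rownames(refs))
  signatures <- if (sum(spectrum) >= 1) {
    fit <- em_deconvolve(spectrum, refs)
    c(accept_deconvolution(fit, spectrum, cosine_threshold),
      list(fit = fit))
  } else NULL

  if (is.null(roles)) {
    roles <- read_tsv(system.file("extdata", "gene_roles.tsv",
                                  package = "somafoot", mustWork = TRUE))
  }
  if (is.null(hotspots)) {
    hotspots <- read_tsv(system.file("extdata", "hotspots.tsv",
                                     package = "somafoot", mustWork = TRUE))
  }
  drivers <- NULL
  v <- som_counts$variants
  if (!is.null(v$gene) && any(!is.na(v$gene))) {
    ev <- v[!is.na(v$gene), , drop = FALSE]
    ann <- annotate_small_variant(ev, roles, hotspots)
    if (nrow(tum)) {
      s1 <- tum$sample_id[1]
      cn <- .cn_lookup(segments, s1, ann$chrom, ann$pos)
      cn[is.na(cn)] <- 2L
      vaf <- vaf_matrix(som_counts)[ann$variant_id, s1]
      ccf <- cancer_cell_fraction(ifelse(is.na(vaf), 0, vaf),
                                  tum$purity[1], pmax(cn, 1))
      ann <- cbind(ann, sample_id = s1, ccf)
    }
    drivers <- ann
  }

  list(classification = cbind(classification,
                              filter_pass = filters$pass,
                              filter_reasons = filters$reasons,
                              timing = timing),
       filters = filters, models = models, calls = calls,
       somatic_ids = somatic_ids, timing = timing, clones = clones,
       loh = loh, presence = pm, tree = tree, relatedness = related,
       signatures = signatures, drivers = drivers, spectrum = spectrum)
}

#' Run the pipeline over a simulated or on-disk cohort
#'
#' Reads a cohort directory written by [simulate_cohort()] (or any
#' directory following its layout), analyses each patient independently,
#' and writes per-patient reports plus a cohort summary. A failing patient
#' is recorded with its reason and does not abort the others. Outputs are
#' byte-deterministic given identical inputs.
#'
#' @param cohort_dir input cohort directory (must contain `manifest.json`)
#' @param out_dir report directory (created; must be empty unless
#'   `overwrite`)
#' @param alpha,q_cutoff stage thresholds (see [analyse_patient()])
#' @param overwrite allow writing into a non-empty directory
#' @return invisibly, the cohort summary data.frame
#' @export
run_pipeline <- function(cohort_dir, out_dir, alpha = 1e-5,
                         q_cutoff = 0.005, overwrite = FALSE) {
  man_path <- file.path(cohort_dir, "manifest.json")
  if (!file.exists(man_path)) stopf("no manifest.json in '%s'", cohort_dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stopf("output directory '%s' is non-empty; use overwrite = TRUE", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_rows <- list()
  for (pid in manifest$patients) {
    pdir <- file.path(cohort_dir, pid)
    odir <- file.path(out_dir, pid)
    dir.create(odir, showWarnings = FALSE)
    res <- tryCatch({
      counts <- read_counts(file.path(pdir, "counts.tsv"))
      segments <- read_tsv(file.path(pdir, "segments.tsv"))
      samples <- read_tsv(file.path(pdir, "samples.tsv"))
      panel <- .read_panel_tsv(file.path(pdir, "panel.tsv"))
      suppressWarnings(
        analyse_patient(counts, segments, samples, panel, alpha, q_cutoff))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      summary_rows[[pid]] <- data.frame(
        patient_id = pid, status = "failed",
        reason = conditionMessage(res), n_somatic = NA_integer_,
        n_precursor = NA_integer_, loh_flagged = NA,
        stringsAsFactors = FALSE)
      next
    }
    write_tsv(res$classification, file.path(odir, "classification.tsv"))
    calls_tab <- data.frame(variant_id = rep(rownames(res$calls$p),
                                             ncol(res$calls$p)),
                            sample_id = rep(colnames(res$calls$p),
                                            each = nrow(res$calls$p)),
                            p = as.vector(res$calls$p),
                            q = as.vector(res$calls$q),
                            call = as.vector(res$calls$call),
                            stringsAsFactors = FALSE)
    write_tsv(calls_tab, file.path(odir, "calls.tsv"))
    if (!is.null(res$clones)) {
      write_tsv(res$clones$summary, file.path(odir, "clones_summary.tsv"))
      if (nrow(res$clones$detail)) {
        write_tsv(res$clones$detail, file.path(odir, "clones_detail.tsv"))
      }
    }
    if (!is.null(res$loh)) write_tsv(res$loh, file.path(odir, "loh.tsv"))
    writeLines(res$tree$newick, file.path(odir, "tree.newick"))
    write_tsv(res$tree$edges, file.path(odir, "tree_edges.tsv"))
    if (!is.null(res$relatedness)) {
      write_tsv(res$relatedness, file.path(odir, "relatedness.tsv"))
    }
    if (!is.null(res$signatures)) {
      w <- res$signatures$fit$weights
      write_tsv(data.frame(signature = names(w), weight = as.numeric(w),
                           status = res$signatures$status,
                           cosine = res$signatures$cosine),
                file.path(odir, "signature_weights.tsv"))
    }
    if (!is.null(res$drivers)) {
      write_tsv(res$drivers, file.path(odir, "drivers.tsv"))
    }
    summary_rows[[pid]] <- data.frame(
      patient_id = pid, status = "ok", reason = "",
      n_somatic = length(res$somatic_ids),
      n_precursor = if (!is.null(res$clones))
        res$clones$summary$n_mutations[res$clones$summary$set == "precursor"]
      else NA_integer_,
      loh_flagged = if (!is.null(res$loh)) any(res$loh$flag) else NA,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  write_tsv(summary, file.path(out_dir, "cohort_summary.tsv"))
  log <- list(package = "somafoot",
              version = as.character(utils::packageVersion("somafoot")),
              seed = manifest$seed,
              config_md5 = as.vector(
                tools::md5sum(file.path(cohort_dir, "config.yaml"))),
              alpha = alpha, q_cutoff = q_cutoff)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
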