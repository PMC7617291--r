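#' Annotate small variants against driver rules
#'
#' Missense mutations and in-frame indels are drivers when they hit a
#' canonical hotspot of an oncogene; truncating mutations are drivers when
#' they disrupt the footprint of a recessive cancer gene. Consequence
#' classes other than `missense`, `inframe`, `truncating` are skipped with
#' a warning. Sites listed in `always_keep` (e.g. promoter hotspots that
#' fail upstream caller filters) are retained as drivers regardless.
#'
#' @param events data.frame with `gene`, `consequence` and, for hotspot
#'   matching, `protein_pos`
#' @param roles data.frame with `gene`, `role`
#'   (`oncogene`/`recessive`/`both`)
#' @param hotspots data.frame with `gene`, `protein_pos`
#' @param always_keep optional vector of `gene:protein_pos` keys always
#'   kept as drivers
#' @return `events` with logical `driver` and character `rule` columns;
#'   row order never affects the result
#' @export
annotate_small_variant <- function(events, roles, hotspots,
                                   always_keep = character(0)) {
  role_of <- function(g) {
    r <- roles$role[match(g, roles$gene)]
    ifelse(is.na(r), "none", r)
  }
  role <- role_of(events$gene)
  onc <- role %in% c("oncogene", "both")
  rec <- role %in% c("recessive", "both")
  hs_key <- paste(hotspots$gene, hotspots$protein_pos, sep = ":")
  ev_key <- paste(events$gene, events$protein_pos, sep = ":")
  known <- events$consequence %in% c("missense", "inframe", "truncating")
  if (any(!known & !is.na(events$consequence))) {
    warnf("skipping %d event(s) with unknown consequence class",
          sum(!known & !is.na(events$consequence)))
  }
  hot <- events$consequence %in% c("missense", "inframe") & onc &
    ev_key %in% hs_key
  trunc <- events$consequence == "truncating" & rec
  kept <- ev_key %in% always_keep
  events$driver <- (known & (hot | trunc)) | kept
  events$rule <- ifelse(kept & !(hot | trunc), "always_keep",
                 ifelse(hot, "hotspot",
                 ifelse(trunc, "truncating", "")))
  events$rule[!events$driver] <- ""
  events
}

#' Annotate copy-number events against driver rules
#'
#' Focal events (shorter than 1 Mb) are drivers when they are homozygous
#' deletions (`cn_total = 0`) over recessive genes, or amplifications
#' strictly above copy number 4 (diploid tumours) / 8 (tetraploid) over
#' oncogenes. Sub-threshold amplifications of oncogenes are rescued when
#' accompanied by significantly elevated expression
#' (`expression_z >= expr_rescue_z`).
#'
#' @param events data.frame with `gene`, `cn_total`, `start`, `end`,
#'   optional `ploidy` (`"diploid"`/`"tetraploid"`) and `expression_z`
#' @param roles role table as in [annotate_small_variant()]
#' @param focal_max maximum focal length in bp (strict <)
#' @param expr_rescue_z expression z-score rescue threshold
#' @return `events` with `driver` and `rule` columns
#' @export
annotate_copy_number <- function(events, roles, focal_max = 1e6,
                                 expr_rescue_z = 3) {
  role <- roles$role[match(events$gene, roles$gene)]
  role[is.na(role)] <- "none"
  onc <- role %in% c("oncogene", "both")
  rec <- role %in% c("recessive", "both")
  ploidy <- events$ploidy %||% rep(NA_character_, nrow(events))
  if (any(is.na(ploidy))) {
    warnf("missing ploidy for %d event(s); assuming diploid", sum(is.na(ploidy)))
    ploidy[is.na(ploidy)] <- "diploid"
  }
  amp_thr <- ifelse(ploidy == "tetraploid", 8, 4)
  len <- events$end - events$start
  focal <- len < focal_max
  z <- events$expression_z %||% rep(NA_real_, nrow(events))
  homdel <- focal & events$cn_total == 0 & rec
  amp <- focal & events$cn_total > amp_thr & onc
  rescue <- focal & onc & events$cn_total > 2 & events$cn_total <= amp_thr &
    !is.na(z) & z >= expr_rescue_z
  events$driver <- homdel | amp | rescue
  events$rule <- ifelse(homdel, "homozygous_deletion",
                 ifelse(amp, "amplification",
                 ifelse(rescue, "amplification_expression_rescue", "")))
  events
}

#' Annotate rearrangements against driver rules
#'
#' A rearrangement is a driver when it generates a whitelisted oncogenic
#' fusion, when a breakpoint disrupts the footprint of a recessive gene,
#' or when it hits a regulatory domain of an oncogene with elevated
#' expression (z-score rescue).
#'
#' @param events data.frame with `gene`, `partner_gene`, `hit`
#'   (`"footprint"`/`"regulatory"`), optional `expression_z`
#' @param roles role table
#' @param fusions data.frame with `gene_a`, `gene_b` whitelisted pairs
#'   (orientation-insensitive)
#' @param expr_rescue_z expression z-score rescue threshold
#' @return `events` with `driver` and `rule` columns
#' @export
annotate_rearrangement <- function(events, roles, fusions,
                                   expr_rescue_z = 3) {
  role <- roles$role[match(events$gene, roles$gene)]
  role[is.na(role)] <- "none"
  onc <- role %in% c("oncogene", "both")
  rec <- role %in% c("recessive", "both")
  fkey <- c(paste(fusions$gene_a, fusions$gene_b, sep = "|"),
            paste(fusions$gene_b, fusions$gene_a, sep = "|"))
  ekey <- paste(events$gene, events$partner_gene, sep = "|")
  ok <- !is.na(events$gene) & (is.na(events$hit) |
                                 events$hit %in% c("footprint", "regulatory"))
  if (any(!ok)) warnf("skipping %d malformed rearrangement(s)", sum(!ok))
  z <- events$expression_z %||% rep(NA_real_, nrow(events))
  fusion <- ekey %in% fkey
  disrupt <- !is.na(events$hit) & events$hit == "footprint" & rec
  reg <- !is.na(events$hit) & events$hit == "regulatory" & onc &
    !is.na(z) & z >= expr_rescue_z
  events$driver <- ok & (fusion | disrupt | reg)
  events$rule <- ifelse(fusion, "fusion",
                 ifelse(disrupt, "footprint_disruption",
                 ifelse(reg, "regulatory_expression_rescue", "")))
  events$rule[!events$driver] <- ""
  events
}

#' Cancer cell fraction from VAF, purity, copy number and multiplicity
#'
#' `ccf = vaf * (purity * cn_total + 2 (1 - purity)) / (purity * m)`.
#' When the multiplicity `m` is missing it is estimated as
#' `round(vaf * (purity * cn_total + 2 (1 - purity)) / purity)` clamped to
#' `[1, cn_total]`. Raw values are capped at 1.25 (larger values indicate
#' an inconsistent copy-number/multiplicity assignment) before clamping
#' the reported fraction to 1. A mutation is clonal when its ccf reaches
#' `clonal_cutoff`.
#'
#' @param vaf variant allele fraction (vectorised)
#' @param purity tumour purity in (0, 1]
#' @param cn_total local total copy number (>= 1)
#' @param multiplicity copies bearing the mutation; `NA` to estimate
#' @param clonal_cutoff clonality threshold on ccf (default 0.8)
#' @return data.frame with `ccf`, `ccf_raw`, `multiplicity`, `clonal`
#' @export
cancer_cell_fraction <- function(vaf, purity, cn_total, multiplicity = NA,
                                 clonal_cutoff = 0.8) {
  if (any(purity <= 0 | purity > 1)) stopf("purity must be in (0, 1]")
  if (any(cn_total < 1)) stopf("cn_total must be >= 1")
  n <- max(length(vaf), length(purity), length(cn_total))
  vaf <- rep_len(vaf, n); purity <- rep_len(purity, n)
  cn_total <- rep_len(cn_total, n)
  multiplicity <- rep_len(multiplicity, n)
  denom_copies <- purity * cn_total + 2 * (1 - purity)
  m_est <- pmin(pmax(round(vaf * denom_copies / purity), 1), cn_total)
  m <- ifelse(is.na(multiplicity), m_est, multiplicity)
  if (any(m < 1 | m > cn_total)) stopf("multiplicity must be in [1, cn_total]")
  raw <- pmin(vaf * denom_copies / (purity * m), 1.25)
  ccf <- pmin(raw, 1)
  data.frame(ccf = ccf, ccf_raw = raw, multiplicity = m,
             clonal = ccf >= clonal_cutoff)
}

#' Call promoter hypermethylation from beta values and expression
#'
#' Z-scores each gene's promoter beta value and expression across the
#' cohort; a sample is called hypermethylated for a gene when the beta
#' z-score is at least `beta_z` and the expression z-score at most
#' `expr_z` (low expression; the threshold is read as -3, a z of +3 being
#' high expression). Genes with zero variance across the cohort yield no
#' call, with a warning.
#'
#' @param beta numeric matrix genes x samples of promoter beta values in
#'   \[0, 1\]
#' @param expr numeric matrix genes x samples of log expression values
#' @param beta_z minimum beta z-score (default 3)
#' @param expr_z maximum expression z-score (default -3)
#' @param min_samples minimum cohort size for z-scoring (default 10)
#' @return logical matrix genes x samples of hypermethylation calls
#' @export
call_promoter_hypermethylation <- function(beta, expr, beta_z = 3,
                                           expr_z = -3, min_samples = 10) {
  if (!identical(dim(beta), dim(expr))) stopf("beta and expr dims differ")
  if (ncol(beta) < min_samples) {
    stopf("need at least %d samples per gene for z-scoring", min_samples)
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stopf("beta values must be in [0,1]")
  zrow <- function(m) {
    mu <- rowMeans(m); sd <- apply(m, 1, stats::sd)
    (m - mu) / sd
  }
  zb <- zrow(beta); ze <- zrow(expr)
  flat <- apply(beta, 1, stats::sd) == 0 | apply(expr, 1, stats::sd) == 0
  if (any(flat)) {
    warnf("zero variance for %d gene(s): no call possible", sum(flat))
    zb[flat, ] <- NA; ze[flat, ] <- NA
  }
  out <- !is.na(zb) & !is.na(ze) & zb >= beta_z & ze <= expr_z
  dimnames(out) <- dimnames(beta)
  out
}

#' Annotate precomputed methylation z-scores against the driver rule
#'
#' Rule-engine entry point for event tables that already carry cohort
#' z-scores (as produced by [call_promoter_hypermethylation()] internals
#' or an external methylation pipeline): hypermethylation requires
#' `beta_z >= 3` and `expression_z <= -3`.
#'
#' @param events data.frame with `beta_z` and `expr_z` columns
#' @param beta_cut,expr_cut thresholds
#' @return `events` with `driver` and `rule` columns
#' @export
annotate_methylation_z <- function(events, beta_cut = 3, expr_cut = -3) {
  events$driver <- !is.na(events$beta_z) & !is.na(events$expr_z) &
    events$beta_z >= beta_cut & events$expr_z <= expr_cut
  events$rule <- ifelse(events$driver, "promoter_hypermethylation", "")
  events
}

#' Second-hit check for recessive predisposition genes
#'
#' A monoallelic germline variant in a recessive gene is biallelic when
#' any somatic event of the qualifying classes (substitution, indel,
#' rearrangement, deletion/LOH, promoter hypermethylation) affects the
#' same gene; otherwise it is monoallelic.
#'
#' @param gene the recessive gene symbol
#' @param somatic_events data.frame with `gene` and `class` columns
#' @return list with `status` (`"biallelic"`/`"monoallelic"`) and
#'   `second_hits` (the qualifying event classes found)
#' @export
second_hit_check <- function(gene, somatic_events) {
  classes <- c("substitution", "indel", "rearrangement", "deletion", "loh",
               "hypermethylation")
  hits <- somatic_events$class[somatic_events$gene == gene &
                                 somatic_events$class %in% classes]
  list(status = if (length(hits)) "biallelic" else "monoallelic",
       second_hits = unique(hits))
}
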