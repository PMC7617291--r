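.rho_grid <- function(lo = 1e-6, hi = 0.89, length.out = 41) {
  exp(seq(log(lo), log(hi), length.out = length.out))
}

#' Fit a per-locus beta-binomial error model from a reference panel
#'
#' The mean error rate is a pseudocount-stabilised pooled estimate,
#' `mu = (sum(alt) + 0.1) / (sum(depth) + 0.2)`; the overdispersion `rho`
#' is estimated on a log-spaced grid over \[1e-6, 0.89\] holding `mu`
#' fixed: the grid maximum-likelihood value, unless the whole profile is
#' effectively flat (no grid value beats the minimal-overdispersion model
#' by at least 0.5 log-likelihood units), in which case the minimal model
#' wins. The flatness guard matters at clean sites: with no or almost no
#' alt reads the profile is nearly flat yet weakly increasing in `rho`,
#' and raw maximisation would report maximal overdispersion for a site
#' that shows none; genuinely overdispersed sites have a sharply peaked
#' profile and take the true maximiser.
#'
#' @param panel_alt,panel_depth integer vectors of per-panel-sample counts
#'   at one site (at least 2 samples)
#' @param rho_grid overdispersion search grid
#' @return object of class `site_error_model`: list with `mu`, `rho`,
#'   `n_panel`, `panel_alt`, `panel_depth`
#' @export
fit_site_error <- function(panel_alt, panel_depth,
                           rho_grid = .rho_grid()) {
  keep <- panel_depth >= 1
  panel_alt <- panel_alt[keep]
  panel_depth <- panel_depth[keep]
  if (length(panel_alt) < 2) stopf("insufficient panel: need >= 2 samples with depth >= 1")
  mu <- (sum(panel_alt) + 0.1) / (sum(panel_depth) + 0.2)
  ll <- vapply(rho_grid, function(r) {
    sum(lbetabinom(panel_alt, panel_depth, mu, r))
  }, numeric(1))
  rho <- if (max(ll) - ll[1] < 0.5) rho_grid[1] else rho_grid[which.max(ll)]
  structure(list(mu = mu, rho = rho,
                 n_panel = length(panel_alt),
                 panel_alt = sum(panel_alt), panel_depth = sum(panel_depth)),
            class = "site_error_model")
}

#' Fit site error models for every site of a panel
#'
#' Vectorised over sites: equivalent to [fit_site_error()] per row of the
#' panel matrices.
#'
#' @param panel list with `variant_id`, `alt` and `depth` matrices
#'   (site x panel sample), as produced by [simulate_panel()] or read from
#'   a panel count TSV
#' @param rho_grid overdispersion search grid
#' @return data.frame with `variant_id`, `mu`, `rho`, `n_panel`
#' @export
fit_error_models <- function(panel, rho_grid = .rho_grid()) {
  alt <- panel$alt
  depth <- panel$depth
  if (ncol(alt) < 2) stopf("insufficient panel: need >= 2 samples")
  use <- depth >= 1
  n_panel <- rowSums(use)
  if (any(n_panel < 2)) stopf("insufficient panel at %d site(s)", sum(n_panel < 2))
  mu <- (rowSums(alt * use) + 0.1) / (rowSums(depth * use) + 0.2)
  ll <- matrix(0, nrow(alt), length(rho_grid))
  for (j in seq_along(rho_grid)) {
    l <- lbetabinom(alt, depth, mu, rho_grid[j])  # mu recycles down columns
    l[!use] <- 0
    ll[, j] <- rowSums(l)
  }
  # flatness guard, then per-site maximum likelihood (see fit_site_error)
  best <- apply(ll, 1, max)
  pick <- max.col(ll, ties.method = "first")
  pick[best - ll[, 1] < 0.5] <- 1L
  data.frame(variant_id = panel$variant_id, mu = mu,
             rho = rho_grid[pick],
             n_panel = n_panel, stringsAsFactors = FALSE)
}

#' Beta-binomial upper-tail p-value
#'
#' `P(X >= alt | depth, mu, rho)` under the site's beta-binomial error
#' null, by direct summation of the probability mass from `alt` to
#' `depth`. `alt = 0` returns exactly 1; as `rho -> 0` the binomial upper
#' tail at rate `mu` is recovered.
#'
#' @param alt,depth observed counts (`depth >= 1`, `alt <= depth`)
#' @param model a `site_error_model`, or `NULL` to use `mu`/`rho` directly
#' @param mu,rho error model parameters when `model` is `NULL`
#' @return upper-tail probability in \[0, 1\]
#' @export
betabinom_pvalue <- function(alt, depth, model = NULL, mu = NULL, rho = NULL) {
  if (!is.null(model)) { mu <- model$mu; rho <- model$rho }
  if (depth < 1) stopf("depth must be >= 1")
  if (alt > depth) stopf("alt exceeds depth")
  if (alt == 0) return(1)
  min(1, sum(exp(lbetabinom(alt:depth, depth, mu, rho))))
}

.betabinom_pvalues <- function(alt, depth, mu, rho) {
  n <- length(alt)
  p <- rep(1, n)
  todo <- which(alt > 0 & depth >= 1)
  for (i in todo) {
    p[i] <- min(1, sum(exp(lbetabinom(alt[i]:depth[i], depth[i],
                                      mu[i], rho[i]))))
  }
  p[depth < 1] <- NA_real_
  p
}

#' Call true somatic mutations per sample under FDR control
#'
#' Tests every variant x sample count against its site's beta-binomial
#' error model, applies Benjamini-Hochberg correction jointly across all
#' variant-sample tests of the patient (one coherent error budget per
#' patient; `family = "sample"` corrects within each sample instead), and
#' calls presence where `q < q_cutoff`.
#'
#' @param counts a [variant_counts()] restricted to the variants to test
#' @param models data.frame from [fit_error_models()] (or rows of
#'   `site_error_model` values) covering the variants; sites without a
#'   model fall back to the configured global model with a warning, or
#'   error when `fallback = NULL`
#' @param q_cutoff FDR threshold (default 0.005)
#' @param family `"patient"` or `"sample"` BH family
#' @param fallback global error model for orphan sites,
#'   `list(mu = 1e-3, rho = 1e-2)` by default
#' @return list with `p`, `q` and logical `call` matrices
#'   (variant x sample)
#' @export
call_true_somatic <- function(counts, models, q_cutoff = 0.005,
                              family = c("patient", "sample"),
                              fallback = list(mu = 1e-3, rho = 1e-2)) {
  family <- match.arg(family)
  v <- counts$variants
  idx <- match(v$variant_id, models$variant_id)
  if (anyNA(idx)) {
    orphans <- v$variant_id[is.na(idx)]
    if (is.null(fallback)) {
      stopf("no error model for site(s): %s", paste(orphans, collapse = ", "))
    }
    warnf("no panel model for %d site(s); using global fallback (mu=%g, rho=%g)",
          length(orphans), fallback$mu, fallback$rho)
  }
  mu <- ifelse(is.na(idx), fallback$mu %||% NA_real_, models$mu[idx])
  rho <- ifelse(is.na(idx), fallback$rho %||% NA_real_, models$rho[idx])
  ns <- length(counts$sample_ids)
  p <- matrix(NA_real_, nrow(v), ns,
              dimnames = list(v$variant_id, counts$sample_ids))
  for (s in counts$sample_ids) {
    p[, s] <- .betabinom_pvalues(counts$alt[, s], counts$depth[, s], mu, rho)
  }
  q <- p
  if (family == "patient") {
    ok <- !is.na(p)
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
  } else {
    for (s in counts$sample_ids) {
      ok <- !is.na(p[, s])
      q[ok, s] <- stats::p.adjust(p[ok, s], method = "BH")
    }
  }
  call <- !is.na(q) & q < q_cutoff
  list(p = p, q = q, call = call)
}
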