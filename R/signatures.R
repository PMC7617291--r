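#' Cosine similarity between two spectra
#'
#' @param a,b numeric vectors of equal length (e.g. 96-channel spectra)
#' @return scalar in \[-1, 1\]; in \[0, 1\] for non-negative inputs
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 1, 0))
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stopf("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Deconvolve a mutation spectrum into reference signatures by EM
#'
#' Fits the multinomial mixture model in which each mutation arises from
#' reference signature j with probability w_j and then falls in channel i
#' with probability S_ij. The E-step computes the responsibility of
#' signature j for channel i as w_j S_ij / sum_l w_l S_il; the M-step sets
#' w_j to the responsibility-weighted fraction of mutations. Weights start
#' uniform. The log-likelihood is non-decreasing across iterations.
#'
#' @param spectrum numeric count vector over channels (total >= 1)
#' @param references matrix of reference signatures (channels x signatures),
#'   each column a probability vector
#' @param tol stop when the log-likelihood improves by less than this
#' @param max_iter iteration cap; `0` returns the uniform initialisation
#'   with a warning
#' @param n_restarts additional random restarts (best log-likelihood kept);
#'   the likelihood is concave in the weights so the default single uniform
#'   start suffices, restarts only guard numerical ties
#' @return list with `weights` (simplex over signatures), `fitted`
#'   (probability vector over channels), `loglik` (trace, one value per
#'   completed iteration) and `n_iter`
#' @export
em_deconvolve <- function(spectrum, references, tol = 1e-8, max_iter = 10000,
                          n_restarts = 0) {
  x <- as.numeric(spectrum)
  S <- as.matrix(references)
  if (length(x) != nrow(S)) stopf("spectrum length does not match reference rows")
  if (any(x < 0)) stopf("spectrum counts must be non-negative")
  if (sum(x) < 1) stopf("spectrum total must be at least 1")
  bad <- abs(colSums(S) - 1) > 1e-6
  if (any(bad)) {
    stopf("reference column(s) not summing to 1: %s",
          paste(colnames(S)[bad] %||% which(bad), collapse = ", "))
  }
  k <- ncol(S)
  run_em <- function(w) {
    trace <- numeric(0)
    ll_old <- -Inf
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      mix <- as.vector(S %*% w)
      mix_safe <- pmax(mix, 1e-300)
      ll <- sum(x * log(mix_safe))
      trace <- c(trace, ll)
      # M-step: w_j <- sum_i x_i w_j S_ij / mix_i / sum(x)
      w_new <- w * as.vector(crossprod(S, x / mix_safe)) / sum(x)
      w_new <- pmax(w_new, 0)
      w_new <- w_new / sum(w_new)
      if (is.finite(ll_old) && ll - ll_old < tol) {
        w <- w_new
        break
      }
      ll_old <- ll
      w <- w_new
    }
    list(weights = w, loglik = trace, n_iter = iter)
  }
  w0 <- rep(1 / k, k)
  if (max_iter == 0) {
    warnf("max_iter = 0: returning uniform weights without EM iterations")
    fitted <- as.vector(S %*% w0)
    return(list(weights = stats::setNames(w0, colnames(S)), fitted = fitted,
                loglik = numeric(0), n_iter = 0L))
  }
  best <- run_em(w0)
  if (n_restarts > 0) {
    for (r in seq_len(n_restarts)) {
      w <- stats::rgamma(k, 1); w <- w / sum(w)
      cand <- run_em(w)
      if (max(cand$loglik) > max(best$loglik)) best <- cand
    }
  }
  w <- stats::setNames(best$weights, colnames(S))
  list(weights = w, fitted = as.vector(S %*% best$weights),
       loglik = best$loglik, n_iter = best$n_iter)
}

#' Accept or reject a signature deconvolution
#'
#' A fitted mixture replaces the input spectrum only when it reproduces it
#' with cosine similarity strictly greater than the threshold; otherwise the
#' spectrum is reported unresolved and kept as is.
#'
#' @param fit result of [em_deconvolve()]
#' @param spectrum the original count spectrum
#' @param threshold cosine similarity acceptance threshold (strict `>`)
#' @return list with `status` (`"deconvolved"` or `"kept_as_is"`), `cosine`,
#'   and `weights` (`NULL` when kept as is)
#' @export
accept_deconvolution <- function(fit, spectrum, threshold = 0.8) {
  cs <- cosine_similarity(fit$fitted, as.numeric(spectrum))
  if (cs > threshold) {
    list(status = "deconvolved", cosine = cs, weights = fit$weights)
  } else {
    list(status = "kept_as_is", cosine = cs, weights = NULL)
  }
}
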