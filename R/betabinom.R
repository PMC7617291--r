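# Beta-binomial parameterised by mean error rate mu and overdispersion rho:
# X | p ~ Binomial(n, p), p ~ Beta(a, b) with
#   a = mu (1 - rho) / rho,  b = (1 - mu) (1 - rho) / rho,
# so E[X/n] = mu and rho -> 0 recovers the plain binomial.

#' Beta-binomial log density
#'
#' @param k number of successes (vectorised)
#' @param n number of trials
#' @param mu mean success probability in (0,1)
#' @param rho overdispersion in (0,1); small values approach the binomial
#' @return log density, same length as `k`
#' @keywords internal
lbetabinom <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Beta-binomial random counts
#' @keywords internal
rbetabinom <- function(m, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  stats::rbinom(m, n, stats::rbeta(m, a, b))
}
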