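test_that("site error fitting handles the zero-count boundary and bad input", {
  # 50 clean panel samples at depth 100: pseudocounts dominate
  m <- fit_site_error(rep(0L, 50), rep(100L, 50))
  expect_equal(m$mu, 0.1 / 5000.2, tolerance = 1e-12)
  expect_equal(m$rho, 1e-6, tolerance = 1e-9)  # grid minimum
  expect_identical(m$n_panel, 50L)

  expect_error(fit_site_error(0L, 100L), "insufficient panel")
  expect_error(fit_site_error(c(0L, 0L), c(0L, 0L)), "insufficient panel")
})

test_that("error model estimation recovers simulated site parameters", {
  set.seed(101)
  mus <- rhos <- numeric(60)
  for (r in 1:60) {
    depth <- rep(100L, 50)
    alt <- somafoot:::rbetabinom(50, depth, 0.005, 0.01)
    m <- fit_site_error(alt, depth)
    mus[r] <- m$mu; rhos[r] <- m$rho
  }
  expect_lt(abs(stats::median(mus) - 0.005) / 0.005, 0.5)
  expect_lt(abs(stats::median(rhos) - 0.01) / 0.01, 0.5)
})

test_that("vectorised panel fitting agrees with the per-site fit", {
  set.seed(5)
  n <- 30
  depth <- matrix(rpois(n * 20, 80), n, 20)
  alt <- matrix(rbinom(n * 20, depth, 0.002), n, 20)
  alt[1:5, ] <- somafoot:::rbetabinom(5 * 20, depth[1:5, ], 0.03, 0.2)
  panel <- list(variant_id = sprintf("s%02d", 1:n), alt = alt, depth = depth)
  models <- fit_error_models(panel)
  for (i in c(1, 3, 17, 30)) {
    m <- fit_site_error(alt[i, ], depth[i, ])
    expect_equal(models$mu[i], m$mu)
    expect_equal(models$rho[i], m$rho)
  }
})

test_that("beta-binomial p-values are exact at the boundaries and match oracles", {
  m <- list(mu = 0.001, rho = 1e-4)
  expect_identical(betabinom_pvalue(0, 100, mu = m$mu, rho = m$rho), 1)
  expect_error(betabinom_pvalue(11, 10, mu = m$mu, rho = m$rho), "exceeds")
  expect_error(betabinom_pvalue(0, 0, mu = m$mu, rho = m$rho), "depth")

  # vanishing overdispersion recovers the binomial upper tail
  set.seed(9)
  for (i in 1:50) {
    d <- sample(10:300, 1); a <- sample(0:min(d, 20), 1)
    mu <- runif(1, 1e-4, 0.1)
    expect_lt(abs(betabinom_pvalue(a, d, mu = mu, rho = 1e-9) -
                    pbinom(a - 1, d, mu, lower.tail = FALSE)), 1e-6)
  }

  # plain-space summation agrees with an independent log-space summation
  p <- betabinom_pvalue(10, 100, mu = 0.001, rho = 1e-4)
  o <- betabinom_upper_oracle(10, 100, 0.001, 1e-4)
  expect_equal(p, o, tolerance = 1e-10)
  for (i in 1:20) {
    d <- sample(20:500, 1); a <- sample(1:10, 1)
    mu <- runif(1, 1e-4, 0.05); rho <- 10^runif(1, -6, -0.5)
    expect_equal(betabinom_pvalue(a, d, mu = mu, rho = rho),
                 betabinom_upper_oracle(a, d, mu, rho),
                 tolerance = 1e-10)
  }
})

test_that("BH correction matches the direct formula and controls calls", {
  counts <- make_counts(rbind(c(6, 0, 0, 0), c(2, 0, 0, 0), c(0, 1, 0, 0)),
                        matrix(80L, 3, 4,
                               dimnames = list(NULL, c("B", "K", "T1", "T2"))))
  models <- data.frame(variant_id = counts$variants$variant_id,
                       mu = 0.001, rho = 1e-6, n_panel = 50)
  res <- call_true_somatic(counts, models)
  # q = min_{j >= i} p_(j) m / j, elementwise q >= p, monotone in p-rank
  pv <- as.vector(res$p); qv <- as.vector(res$q)
  mq <- length(pv)
  o <- order(pv)
  direct <- rev(cummin(rev(pv[o] * mq / seq_len(mq))))
  expect_equal(qv[o], pmin(direct, 1), tolerance = 1e-12)
  expect_true(all(qv >= pv - 1e-15))
  expect_true(all(diff(qv[o]) >= -1e-15))

  # the textbook worked example
  q <- p.adjust(c(0.001, 0.02, 0.9), method = "BH")
  expect_equal(q, c(0.003, 0.03, 0.9), tolerance = 1e-12)

  # all p = 1: no calls
  counts1 <- make_counts(matrix(0L, 2, 4, dimnames = list(NULL, c("B", "K", "T1", "T2"))),
                         matrix(60L, 2, 4))
  res1 <- call_true_somatic(counts1, models[1:2, ])
  expect_true(all(res1$q == 1))
  expect_false(any(res1$call))
})

test_that("orphan sites use the global fallback or fail loudly", {
  counts <- make_counts(rbind(c(6, 0, 0, 0)),
                        matrix(80L, 1, 4,
                               dimnames = list(NULL, c("B", "K", "T1", "T2"))))
  models <- data.frame(variant_id = "other", mu = 0.001, rho = 1e-6)
  expect_warning(res <- call_true_somatic(counts, models), "fallback")
  expect_true(all(is.finite(res$p)))
  expect_error(call_true_somatic(counts, models, fallback = NULL),
               "no error model")
})

test_that("false discovery is controlled on null-only sites", {
  ns <- simulate_null_sites(n_sites = 600, n_samples = 4, n_panel = 40,
                            artifact_sites = 60, seed = 3)
  models <- fit_error_models(ns$panel)
  calls <- call_true_somatic(ns$counts, models)
  n_tests <- length(calls$call)
  bound <- 0.005 + 3 * sqrt(0.005 * 0.995 / n_tests)
  expect_lte(mean(calls$call), bound)
  # p-values under the fitted null are super-uniform
  expect_gte(mean(calls$p > 0.5), 0.5)
})

test_that("clonal trunk mutations are called with near-complete sensitivity", {
  set.seed(77)
  n <- 500
  depth <- matrix(rpois(n, 60), n, 1, dimnames = list(NULL, "T1"))
  alt <- matrix(rbinom(n, depth, 0.2), n, 1, dimnames = list(NULL, "T1"))
  counts <- make_counts(alt, depth)
  models <- data.frame(variant_id = counts$variants$variant_id,
                       mu = 1e-3, rho = 1e-2)
  res <- call_true_somatic(counts, models)
  expect_gte(mean(res$call), 0.99)
})
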