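make_exact_summaries <- function(n = 80, c0 = 2, z = 0.5) {
  N <- 10^seq(3, 6, length.out = n)
  data.frame(sample_id = sprintf("s%d", seq_len(n)), N = N,
             S = c0 * N^z, Nmax = N^0.9,
             evenness = 0.5 * N^-0.1, rarity = 0.2 + 0.1 * log10(N))
}

test_that("noiseless summaries recover the exact line in every bootstrap", {
  s <- make_exact_summaries()
  fit <- suppressMessages(fit_dar(s, "richness", n_boot = 50,
                                  n_per_boot = 60, seed = 1))
  expect_equal(fit$exponent_mean, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept_mean, log10(2), tolerance = 1e-12)
  expect_true(all(abs(fit$boot$slope - 0.5) < 1e-12))
  expect_equal(fit$r2_mean, 1, tolerance = 1e-12)
  expect_true(fit$exponent_ci[1] <= fit$exponent_mean &&
                fit$exponent_mean <= fit$exponent_ci[2])

  # rarity is fit untransformed: slope 0.1 against log10 N
  fr <- suppressMessages(fit_dar(s, "rarity", n_boot = 20, n_per_boot = 60,
                                 seed = 1))
  expect_equal(fr$exponent_mean, 0.1, tolerance = 1e-12)
  expect_false(fr$log_response)
})

test_that("exponents are invariant to rescaling N; intercept shifts", {
  s <- make_exact_summaries()
  s2 <- s; s2$N <- s2$N * 7
  f1 <- suppressMessages(fit_dar(s, "dominance", n_boot = 30,
                                 n_per_boot = 50, seed = 2))
  f2 <- suppressMessages(fit_dar(s2, "dominance", n_boot = 30,
                                 n_per_boot = 50, seed = 2))
  expect_equal(f2$exponent_mean, f1$exponent_mean, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f2$intercept_mean, f1$intercept_mean)))
})

test_that("degenerate and malformed inputs are rejected", {
  s <- make_exact_summaries()
  s$N <- 1000
  expect_error(suppressMessages(fit_dar(s, "richness")), "distinct N")
  expect_error(fit_dar(data.frame(N = 1:5), "richness"), "columns")
})

test_that("stratified and unstratified fits agree on a balanced corpus", {
  corp <- generate_corpus(corpus_spec(n_samples = 400, seed = 17))
  sc <- summarize_corpus(corp$table)
  fs <- fit_dar(sc, "richness", n_boot = 300, n_per_boot = 300, seed = 3)
  fu <- fit_dar(sc, "richness", n_boot = 300, n_per_boot = 300, seed = 3,
                strata_width = NULL)
  expect_true(fu$exponent_mean >= fs$exponent_ci[1] &&
                fu$exponent_mean <= fs$exponent_ci[2])
  expect_equal(fs$strata$n_strata >= 3, TRUE)
  expect_equal(fu$strata$n_strata, 1L)
})

test_that("bootstrap CI covers the generator's exponents", {
  corp <- generate_corpus(corpus_spec(n_samples = 1000, z_richness = 0.5,
                                      sad_sigma = 2, noise_sigma = 0.05,
                                      seed = 23))
  sc <- summarize_corpus(corp$table)
  fit <- fit_dar(sc, "richness", n_boot = 500, n_per_boot = 500, seed = 4)
  expect_true(fit$exponent_ci[1] <= 0.5 && 0.5 <= fit$exponent_ci[2])
  fd <- fit_dar(sc, "dominance", n_boot = 500, n_per_boot = 500, seed = 4)
  expect_true(fd$exponent_ci[1] <= 0.9 && 0.9 <= fd$exponent_ci[2])
  expect_gt(fd$r2_mean, 0.8)
})

test_that("predict_nmax evaluates and clips the dominance power law", {
  s <- make_exact_summaries()
  fit <- suppressMessages(fit_dar(s, "dominance", n_boot = 20,
                                  n_per_boot = 50, seed = 5))
  # construction: Nmax = N^0.9 exactly
  expect_equal(predict_nmax(fit, 1e4), (1e4)^0.9, tolerance = 1e-9)

  fit_iso <- fit
  fit_iso$intercept_mean <- 0; fit_iso$exponent_mean <- 1
  expect_equal(predict_nmax(fit_iso, 12345), 12345)
  fit_half <- fit
  fit_half$intercept_mean <- log10(0.5); fit_half$exponent_mean <- 1
  expect_equal(predict_nmax(fit_half, 100), 50)

  frich <- suppressMessages(fit_dar(s, "richness", n_boot = 10,
                                    n_per_boot = 50, seed = 5))
  expect_error(predict_nmax(frich, 100), "dominance")
  expect_error(predict_nmax(fit, -1), "positive")
})

test_that("prediction intervals: zero width when exact, nested, noise-monotone", {
  s <- make_exact_summaries()
  fit <- suppressMessages(fit_dar(s, "richness", n_boot = 30,
                                  n_per_boot = 50, seed = 6))
  pi0 <- prediction_interval(fit, 1e4)
  expect_equal(pi0$lower, pi0$fit, tolerance = 1e-6)
  expect_equal(pi0$upper, pi0$fit, tolerance = 1e-6)

  # noisy corpus: interval brackets the point, 0.95 contains 0.90
  corp <- generate_corpus(corpus_spec(n_samples = 300, noise_sigma = 0.1,
                                      seed = 31))
  sc <- summarize_corpus(corp$table)
  f <- fit_dar(sc, "richness", n_boot = 200, n_per_boot = 300, seed = 7)
  p95 <- prediction_interval(f, 1e4, 0.95)
  p90 <- prediction_interval(f, 1e4, 0.90)
  expect_lt(p95$lower, p95$fit); expect_gt(p95$upper, p95$fit)
  expect_lt(p95$lower, p90$lower); expect_gt(p95$upper, p90$upper)

  # more noise -> wider interval at fixed N
  corp2 <- generate_corpus(corpus_spec(n_samples = 300, noise_sigma = 0.3,
                                       seed = 31))
  f2 <- fit_dar(summarize_corpus(corp2$table), "richness", n_boot = 200,
                n_per_boot = 300, seed = 7)
  p2 <- prediction_interval(f2, 1e4, 0.95)
  expect_gt(log10(p2$upper / p2$lower), log10(p95$upper / p95$lower))

  expect_error(prediction_interval(f, 1e4, level = 1.2), "level")
  expect_error(prediction_interval(f, -5), "positive")
})
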