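test_that("JZS Bayes factor has the right invariances and null behavior", {
  set.seed(5)
  d <- rnorm(20)
  bf <- jzs_paired_bayes_factor(d)
  # scale invariance of the t statistic
  expect_equal(jzs_paired_bayes_factor(3.7 * d), bf, tolerance = 1e-8)
  # BF10 * BF01 = 1 by construction of the ratio
  bf01 <- 1 / bf
  expect_lt(abs(bf * bf01 - 1), 1e-9)
  # perfectly antisymmetric differences at large n favor the null
  d0 <- rep(c(-1.3, 1.3), 20)
  expect_lt(jzs_paired_bayes_factor(d0), 1)
  # errors
  expect_error(jzs_paired_bayes_factor(rep(2, 10)), "degenerate")
  expect_error(jzs_paired_bayes_factor(1.2), "at least 2")
})

test_that("JZS Bayes factor agrees with the independent g-integral oracle", {
  set.seed(11)
  for (i in 1:8) {
    n <- sample(5:40, 1)
    d <- rnorm(n, mean = runif(1, -1.5, 1.5), sd = runif(1, 0.5, 2))
    bf <- jzs_paired_bayes_factor(d)
    oracle <- jzs_bf_g_oracle(d)
    expect_lt(abs(bf / oracle - 1), 1e-3)
  }
})

test_that("median null Bayes factor favors the null", {
  set.seed(77)
  bfs <- replicate(200, jzs_paired_bayes_factor(rnorm(31)))
  expect_lt(median(bfs), 1)
})

test_that("posterior effect-size samples behave like a posterior", {
  set.seed(9)
  d <- rnorm(25, 0.8, 1)
  s1 <- posterior_effect_samples(d, n_samples = 2e5, seed = 4)
  s2 <- posterior_effect_samples(d, n_samples = 2e5, seed = 4)
  expect_identical(s1, s2)
  h <- hdi(s1)
  expect_lte(h[1], h[2])
  expect_gte(mean(s1 >= h[1] & s1 <= h[2]), 0.95 - 1e-3)
  # approximately symmetric about the median for this near-symmetric posterior
  med <- median(s1)
  expect_lt(abs((h[2] - med) - (med - h[1])), 0.02 * (h[2] - h[1]) + 0.02)
  # shifting the data shifts the posterior in the same direction
  s_shift <- posterior_effect_samples(d + 1, n_samples = 2e5, seed = 4)
  expect_gt(mean(s_shift), mean(s1))
  expect_gt(quantile(s_shift, 0.25), quantile(s1, 0.25))
  # HDI width shrinks with n on fixed-effect data
  set.seed(10)
  dd <- rnorm(400, 0.5, 1)
  h_small <- hdi(posterior_effect_samples(dd[1:20], 1e5, seed = 1))
  h_big <- hdi(posterior_effect_samples(dd, 1e5, seed = 1))
  expect_lt(diff(h_big), diff(h_small))
})

test_that("hdi returns the shortest interval with the requested mass", {
  set.seed(3)
  x <- c(rnorm(8000, 0, 0.3), rnorm(2000, 5, 0.3))
  h <- hdi(x, 0.75)
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.75 - 1e-3)
  expect_lt(h[2], 4)  # the short interval excludes the minor mode
})

test_that("information-criterion differences classify into guideline bands", {
  expect_equal(as.character(classify_delta(0)), "no preference")
  expect_equal(as.character(classify_delta(100)), "very strong for")
  expect_equal(as.character(classify_delta(-100)), "very strong against")
  # band edges are half-open, lower-inclusive
  expect_equal(as.character(classify_delta(c(2, 4, 7, 10) - 1e-9)),
               c("no preference", "weak for", "moderate for", "strong for"))
  expect_equal(as.character(classify_delta(c(2, 4, 7, 10))),
               c("weak for", "moderate for", "strong for", "very strong for"))
  expect_equal(bf_evidence_label(c(2, 5, 20, 50, 200)),
               c("anecdotal", "moderate", "strong", "very strong", "extreme"))
  expect_equal(bf_evidence_label(1 / 40), "very strong against")
})

test_that("cohort-level comparison detects the generative model", {
  design <- fixture_design()
  spec_t <- model_spec("wev")
  st <- fit_settings(n_starts = 1, n_restarts = 1, max_iterations = 400)
  fits_wev <- list()
  fits_sdt <- list()
  for (i in 1:5) {
    par <- sample_parameters(spec_t, seed = 300 + i)
    cnt <- tabulate_trials(simulate_trials(spec_t, par, design), design)
    id <- sprintf("p%02d", i)
    fits_wev[[id]] <- fit_model(spec_t, cnt, st)
    fits_sdt[[id]] <- fit_model(model_spec("sdt"), cnt, st)
  }
  cmp <- compare_models(fits_wev, fits_sdt, "aicc", n_samples = 1e4)
  expect_gt(cmp$mean_delta, 0)          # positive favors the wev model
  expect_equal(cmp$n, 5)
  expect_equal(cmp$mean_delta, mean(cmp$deltas))
  expect_lte(cmp$hdi95[1], cmp$hdi95[2])
  # identical fits give zero-variance differences: degenerate by design
  expect_error(compare_models(fits_wev, fits_wev, "aicc"), "degenerate")
  # criterion switch changes each delta by the exact algebraic difference
  cmp_b <- compare_models(fits_wev, fits_sdt, "bic", n_samples = 1e4)
  k_a <- 16L; k_b <- 14L; n <- 550L
  corr <- function(k) 2 * k + 2 * k * (k + 1) / (n - k - 1)
  shift <- (k_b - k_a) * log(n) - (corr(k_b) - corr(k_a))
  expect_equal(unname(cmp_b$deltas - cmp$deltas), rep(shift, 5), tolerance = 1e-9)
})
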