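test_that("gamma matches exhaustive pair enumeration", {
  expect_equal(goodman_kruskal_gamma(1:3, 1:3), 1)
  expect_equal(goodman_kruskal_gamma(1:3, c(3, 2, 1)), -1)
  expect_equal(goodman_kruskal_gamma(1:3, c(1, 2, 1)), 0)   # C = 1, D = 1
  expect_true(is.nan(goodman_kruskal_gamma(c(1, 1, 1), c(2, 2, 2))))
  set.seed(6)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    got <- goodman_kruskal_gamma(x, y)
    want <- gamma_enumerate(x, y)
    if (is.nan(want)) expect_true(is.nan(got)) else expect_equal(got, want)
  }
})

test_that("gamma is antisymmetric under reversing one order", {
  set.seed(12)
  for (i in 1:20) {
    x <- sample(1:4, 12, replace = TRUE)
    y <- sample(1:4, 12, replace = TRUE)
    g <- goodman_kruskal_gamma(x, y)
    gr <- goodman_kruskal_gamma(x, max(y) + 1 - y)
    if (is.nan(g)) expect_true(is.nan(gr)) else expect_equal(gr, -g)
  }
})

test_that("gamma by accuracy splits and degenerates correctly", {
  tr <- data.frame(soa_ms = c(10, 20, 30), stimulus = c(1, 1, 1),
                   response = c(1, 1, 1), category = 0:2)
  g <- gamma_by_accuracy(tr)
  expect_equal(g$gamma_correct, 1)
  expect_true(is.nan(g$gamma_incorrect))
  # shuffled ratings: near-zero association on average
  set.seed(14)
  gs <- replicate(100, {
    d <- data.frame(soa_ms = rep(c(10, 20, 30, 40, 50), each = 40),
                    stimulus = 1, response = 1,
                    category = sample(rep(0:4, 40)))
    gamma_by_accuracy(d)$gamma_correct
  })
  expect_lt(abs(mean(gs)), 0.05)
})

test_that("model-implied gamma matches simulation and shows the wev signature", {
  design <- fixture_design()
  # strength-independent observer: SOA-exchangeable, gamma exactly 0
  spec <- model_spec("sdt")
  par0 <- fixture_params("sdt")
  par0$S_s <- rep(1.5, 5)
  pg0 <- predicted_gamma(spec, par0, design)
  expect_equal(pg0$gamma_correct, 0, tolerance = 1e-12)
  expect_equal(pg0$gamma_incorrect, 0, tolerance = 1e-12)
  # expected-count gamma converges to simulated-trial gamma
  parw <- fixture_params("wev")
  pgw <- predicted_gamma(model_spec("wev"), parw, design)
  tr <- simulate_trials(model_spec("wev"), parw, design, seed = 44,
                        trials_per_soa = 60000)
  gs <- gamma_by_accuracy(tr)
  expect_lt(abs(pgw$gamma_correct - gs$gamma_correct), 0.01)
  expect_lt(abs(pgw$gamma_incorrect - gs$gamma_incorrect), 0.01)
  # strength evidence keeps rating and SOA associated even on errors:
  # the wev gamma in incorrect trials exceeds sdt's at matched sensitivity
  pars <- fixture_params("sdt")
  pgs <- predicted_gamma(model_spec("sdt"), pars, design)
  expect_gt(pgw$gamma_incorrect, 0)
  expect_gt(pgw$gamma_incorrect, pgs$gamma_incorrect)
})

test_that("dissociation contingencies behave at the 20% threshold", {
  # identical judgments never dissociate
  tr <- data.frame(participant = "a", rating_vis = runif(200),
                   rating_conf = NA)
  tr$rating_conf <- tr$rating_vis
  c0 <- contingency_20(tr)
  expect_equal(c0$p_vis_given_lowconf, 0)
  expect_equal(c0$p_conf_given_lowvis, 0)
  # independent uniform ratings: P(U > 0.2) = 0.8 on both sides
  set.seed(15)
  tri <- data.frame(participant = rep(sprintf("p%d", 1:10), each = 4000),
                    rating_vis = runif(40000), rating_conf = runif(40000))
  ci <- contingency_20(tri)
  expect_equal(ci$p_vis_given_lowconf, 0.8, tolerance = 0.02)
  expect_equal(ci$p_conf_given_lowvis, 0.8, tolerance = 0.02)
  expect_equal(ci$n_excluded_vis, 0)
  # values invariant to monotone relabeling away from the threshold
  mono <- function(x) ifelse(x < 0.2, x * 0.5, 0.2 + (x - 0.2)^0.7 * 0.8)
  trm <- tri
  trm$rating_vis <- mono(trm$rating_vis)
  trm$rating_conf <- mono(trm$rating_conf)
  cm <- contingency_20(trm)
  expect_equal(cm$p_vis_given_lowconf, ci$p_vis_given_lowconf, tolerance = 1e-12)
  # exactly-at-threshold ratings count as "not below"
  tre <- data.frame(participant = "a", rating_vis = c(0.2, 0.1),
                    rating_conf = c(0.1, 0.2))
  ce <- contingency_20(tre)
  # 0.2 conditions the first trial (conf < 0.2) but is not "above" as an
  # event, and does not condition the second (conf = 0.2 is not below)
  expect_equal(ce$p_vis_given_lowconf, 0)
  expect_equal(ce$p_conf_given_lowvis, 0)
})

test_that("joint wev simulation reproduces the dissociation asymmetry", {
  par <- fixture_params("wev")
  tr <- generate_joint(par, w_vis = 0.65, w_conf = 0.35, seed = 50,
                       trials_per_soa = 20000)
  tr$participant <- "sim"
  cc <- contingency_20(tr)
  # with a larger visibility weight, confidence-without-visibility is the
  # more common dissociation
  expect_gt(cc$p_conf_given_lowvis, cc$p_vis_given_lowconf)
})
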