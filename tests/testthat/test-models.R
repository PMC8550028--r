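test_that("bivariate normal CDF matches adaptive integration", {
  oracle <- function(h, k, r) {
    if (abs(r) == 1) {
      if (r == 1) return(stats::pnorm(min(h, k)))
      return(max(0, stats::pnorm(h) - stats::pnorm(-k)))
    }
    s <- sqrt(1 - r^2)
    stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((k - r * x) / s),
                     -Inf, h, rel.tol = 1e-12)$value
  }
  grid <- expand.grid(h = c(-2.5, -0.7, 0, 1.3), k = c(-1.8, 0.2, 2.1),
                      r = c(-1, -0.9999, -0.93, -0.5, 0, 0.6, 0.9, 0.99, 0.99999, 1))
  got <- pbvnorm(grid$h, grid$k, grid$r)
  want <- mapply(oracle, grid$h, grid$k, grid$r)
  expect_lt(max(abs(got - want)), 1e-9)
  expect_equal(pbvnorm(1.2, Inf, 0.5), stats::pnorm(1.2))
  expect_equal(pbvnorm(1.2, -Inf, 0.5), 0)
})

test_that("probability tables normalize for every family and variance mode", {
  design <- fixture_design()
  for (fam in all_families()) {
    modes <- if (fam == "bayes2d") "constant" else
      c("constant", "identity_dependent", "soa_dependent")
    for (mode in modes) {
      spec <- model_spec(fam, mode)
      for (s in 1:5) {
        p <- predict_response_probabilities(
          spec, sample_parameters(spec, seed = s, design = design), design)
        expect_true(all(p >= 0) && all(p <= 1))
        expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)
      }
    }
  }
})

test_that("an unbiased observer with zero sensitivity responds at chance", {
  spec <- model_spec("sdt")
  par <- parameter_set(spec, S_s = rep(0, 5), theta_id = 0,
                       theta_v_plus = c(0.5, 1, 1.5, 2),
                       theta_v_minus = -c(0.5, 1, 1.5, 2))
  p <- predict_response_probabilities(spec, par, fixture_design())
  expect_equal(as.vector(apply(p[, , 2, ], c(1, 2), sum)),
               rep(0.5, 10), tolerance = 1e-12)
})

test_that("model reduction chains hold", {
  design <- fixture_design()
  base <- fixture_params("noisy_sdt")
  # wev with w = 0 is exactly noisy SDT
  wev0 <- parameter_set(model_spec("wev"), S_s = base$S_s, theta_id = base$theta_id,
                        theta_v_plus = base$theta_v_plus,
                        theta_v_minus = base$theta_v_minus,
                        sigma_v = base$sigma_v, w = 0)
  p_wev <- predict_response_probabilities(model_spec("wev"), wev0, design)
  p_noisy <- predict_response_probabilities(model_spec("noisy_sdt"), base, design)
  expect_lt(max(abs(p_wev - p_noisy)), 1e-8)

  sdt_par <- fixture_params("sdt")
  p_sdt <- predict_response_probabilities(model_spec("sdt"), sdt_par, design)
  # noisy SDT with vanishing report noise
  tiny <- parameter_set(model_spec("noisy_sdt"), S_s = sdt_par$S_s,
                        theta_id = sdt_par$theta_id,
                        theta_v_plus = sdt_par$theta_v_plus,
                        theta_v_minus = sdt_par$theta_v_minus, sigma_v = 1e-4)
  expect_lt(max(abs(predict_response_probabilities(model_spec("noisy_sdt"),
                                                   tiny, design) - p_sdt)), 1e-4)
  # postdecisional accumulation with vanishing accumulation
  pd <- parameter_set(model_spec("postdecisional"), S_s = sdt_par$S_s,
                      theta_id = sdt_par$theta_id,
                      theta_v_plus = sdt_par$theta_v_plus,
                      theta_v_minus = sdt_par$theta_v_minus, b = 1e-6)
  expect_lt(max(abs(predict_response_probabilities(model_spec("postdecisional"),
                                                   pd, design) - p_sdt)), 1e-4)
  # constant noise and decay with no decay and vanishing noise
  cnd <- parameter_set(model_spec("cnd"), S_s = sdt_par$S_s,
                       theta_id = sdt_par$theta_id,
                       theta_v_plus = sdt_par$theta_v_plus,
                       theta_v_minus = sdt_par$theta_v_minus,
                       sigma_v = 1e-4, rho = rep(1, 5))
  expect_lt(max(abs(predict_response_probabilities(model_spec("cnd"),
                                                   cnd, design) - p_sdt)), 1e-4)
})

test_that("rce cells match adaptive integration of winner density times loser CDF", {
  design <- fixture_design()
  par <- fixture_params("rce")
  p <- predict_response_probabilities(model_spec("rce"), par, design)
  for (si in 1:2) for (t in c(1, 3, 5)) {
    s <- c(-1, 1)[si]
    S <- par$S_s[t]
    mu_m <- 0.5 * (1 - s) * S - par$theta_id
    mu_p <- 0.5 * (1 + s) * S + par$theta_id
    for (v in 0:4) {
      bnd <- c(-Inf, par$theta_v_plus, Inf)
      want <- stats::integrate(function(x) stats::dnorm(x, mu_p, 1) *
                                 stats::pnorm(x - mu_m),
                               bnd[v + 1], bnd[v + 2], rel.tol = 1e-10)$value
      expect_lt(abs(p[si, t, 2, v + 1] - want), 1e-6)
      bnd_m <- c(-Inf, par$theta_v_minus, Inf)
      want_m <- stats::integrate(function(x) stats::dnorm(x, mu_m, 1) *
                                   stats::pnorm(x - mu_p),
                                 bnd_m[v + 1], bnd_m[v + 2], rel.tol = 1e-10)$value
      expect_lt(abs(p[si, t, 1, v + 1] - want_m), 1e-6)
    }
  }
})

test_that("the 2D Bayesian posterior matches an explicit double sum", {
  # exchangeable channels
  expect_equal(posterior_identity(1.3, 1.3, 2, c(1, 2, 5)), 0.5)
  expect_equal(posterior_identity(-0.4, -0.4, 0.7, c(8.3, 133.3)), 0.5)
  # vanishing-noise limit: clear +1 signal
  expect_gt(posterior_identity(0, 2, 1e-3, c(1, 2)), 1 - 1e-10)
  # hand-computed 2x2 sum for delta- = 1, delta+ = 2, s = 1, SOAs {1, 2}
  num <- stats::dnorm(1, 0, 1) * stats::dnorm(2, 1, 1) +
    stats::dnorm(1, 0, 1) * stats::dnorm(2, 2, 1)
  den <- num + stats::dnorm(1, 1, 1) * stats::dnorm(2, 0, 1) +
    stats::dnorm(1, 2, 1) * stats::dnorm(2, 0, 1)
  expect_equal(posterior_identity(1, 2, 1, c(1, 2)), num / den, tolerance = 1e-12)
})

test_that("2D Bayesian cell probabilities match brute-force grid integration", {
  design <- experiment_design(c(10, 30, 80), trials_per_soa = 10L)
  spec <- model_spec("bayes2d")
  par <- parameter_set(spec, s_noise = 20, lambda = 0.05,
                       theta_post = c(.05, .1, .25, .4, .5, .6, .75, .9, .95))
  p <- predict_response_probabilities(spec, par, design)
  gx <- seq(-6, 6, length.out = 701) * par$s_noise
  wx <- stats::dnorm(gx, 0, par$s_noise) * (gx[2] - gx[1])
  for (si in 1:2) for (t in 1:3) {
    s <- c(-1, 1)[si]
    m_m <- 0.5 * (1 - s) * design$soa_levels_ms[t]
    m_p <- 0.5 * (1 + s) * design$soa_levels_ms[t]
    qg <- posterior_identity(rep(m_m + gx, each = length(gx)),
                             rep(m_p + gx, times = length(gx)),
                             par$s_noise, design$soa_levels_ms)
    wg <- rep(wx, each = length(gx)) * rep(wx, times = length(gx)) /
      ((gx[2] - gx[1])^0 * 1)
    wg <- wg / sum(wg)
    opt <- findInterval(qg, par$theta_post) + 1L
    probs <- vapply(1:10, function(o) sum(wg[opt == o]), numeric(1))
    probs <- (1 - par$lambda) * probs + par$lambda / 10
    want_minus <- rev(probs[1:5])
    want_plus <- probs[6:10]
    expect_equal(unname(p[si, t, 1, ]), want_minus, tolerance = 4e-3)
    expect_equal(unname(p[si, t, 2, ]), want_plus, tolerance = 4e-3)
  }
})

test_that("accuracy is nondecreasing in sensitivity for fixed criteria", {
  design <- fixture_design()
  for (fam in c("sdt", "wev")) {
    prev <- -Inf
    for (S in c(0, 0.5, 1, 2, 4)) {
      par <- fixture_params(fam)
      par$S_s <- rep(S, 5)
      p <- predict_response_probabilities(model_spec(fam), par, design)
      acc <- mean(c(apply(p[1, , 1, , drop = FALSE], 2, sum),
                    apply(p[2, , 2, , drop = FALSE], 2, sum)))
      expect_gte(acc + 1e-12, prev)
      prev <- acc
    }
  }
})

test_that("simulated frequencies agree with predicted probabilities", {
  design <- fixture_design()
  set.seed(2024)
  combos <- c(lapply(all_families(), function(f) c(f, "constant")),
              list(c("wev", "identity_dependent"), c("rce", "soa_dependent")))
  for (cb in combos) {
    spec <- model_spec(cb[1], cb[2])
    par <- fixture_params(cb[1], cb[2])
    p <- predict_response_probabilities(spec, par, design)
    tr <- simulate_trials(spec, par, design, trials_per_soa = 20000)
    cnt <- tabulate_trials(tr, design)
    for (si in 1:2) for (t in 1:5) {
      n <- sum(cnt[si, t, , ])
      se <- sqrt(p[si, t, , ] * (1 - p[si, t, , ]) / n)
      z <- abs(cnt[si, t, , ] / n - p[si, t, , ]) / pmax(se, 1e-12)
      expect_lt(max(z[se > 0]), 4.75)   # ~1100 cells across combos
    }
  }
})

test_that("an empty simulation and a saturating one behave as expected", {
  design <- fixture_design()
  par <- fixture_params("sdt")
  expect_equal(nrow(simulate_trials(model_spec("sdt"), par, design,
                                    trials_per_soa = 0L)), 0L)
  par$S_s <- c(0.1, 0.5, 1, 2, 12)
  tr <- simulate_trials(model_spec("sdt"), par, design, seed = 5)
  longest <- tr[abs(tr$soa_ms - 133.3) < 1e-6, ]
  expect_equal(mean(longest$response == longest$stimulus), 1)
})

test_that("probability tables export to tidy long format", {
  design <- fixture_design()
  p <- predict_response_probabilities(model_spec("wev"), fixture_params("wev"),
                                      design)
  f <- tempfile(fileext = ".csv")
  long <- probs_to_long(p, file = f)
  expect_equal(nrow(long), 2 * 5 * 2 * 5)
  expect_named(long, c("s_id", "soa_ms", "r_id", "category", "p"))
  expect_equal(sum(long$p), 10, tolerance = 1e-9)   # one unit mass per condition
  # every cell lands in the right row
  expect_equal(long$p[long$s_id == 1 & abs(long$soa_ms - 33.3) < 1e-6 &
                        long$r_id == -1 & long$category == 2],
               unname(p[2, 3, 1, 3]))
  back <- read.csv(f)
  expect_equal(back$p, long$p, tolerance = 1e-12)
})
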