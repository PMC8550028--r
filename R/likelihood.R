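# Model likelihoods: exact joint P(R_id, R_v | S_id, S_s) per condition.
#
# Six families (sdt, noisy_sdt, wev, two_channel, postdecisional, cnd) share
# one structure: the report variable delta_v is affine in the identification
# variable delta_id plus independent Gaussian noise, so (delta_id, delta_v) is
# bivariate normal and every (response x category) cell is a rectangle
# probability, computed exactly with pbvnorm(). The rce model needs a smooth
# 1D integral (winning-channel density times losing-channel CDF); the 2D
# Bayesian model is reduced to 1D by inverting the posterior's level sets,
# which are monotone in delta_plus for fixed delta_minus.

# Gauss-Legendre nodes/weights on (0, 1), Golub-Welsch.
gauss_legendre_01 <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    x <- rev(e$values)
    w <- rev(2 * e$vectors[1, ]^2)
    out <- list(x = (x + 1) / 2, w = w / 2)
    cache[[key]] <<- out
    out
  }
})

N_QUAD <- 61L

# increasing criteria on the minus-response report axis
minus_axis_criteria <- function(params) {
  if (params$spec$family == "rce") params$theta_v_minus else -params$theta_v_minus
}

#' Predicted response probabilities for every condition
#'
#' Computes the exact joint probability of each (identification response,
#' rating category) pair for every (stimulus identity, SOA) condition.
#'
#' @param spec a [model_spec()].
#' @param params a matching `wev_params` (see [parameter_set()]).
#' @param design a [experiment_design()].
#' @return a `wev_probs` array with dimensions `(s_id, soa, r_id, category)`;
#'   each condition's `2 x n_categories` block sums to 1.
#' @export
predict_response_probabilities <- function(spec, params, design) {
  stopifnot(inherits(spec, "wev_spec"), inherits(design, "wev_design"))
  validate_params(params)
  ns <- length(design$soa_levels_ms)
  nc <- design$n_categories
  if (spec$family == "bayes2d") {
    if (length(params$theta_post) != 2L * nc - 1L)
      stop("theta_post must have length 2 * n_categories - 1")
    p <- predict_bayes2d(params, design)
  } else {
    if (length(params$S_s) != ns) stop("S_s must have one entry per SOA")
    if (length(params$theta_v_plus) != nc - 1L)
      stop("criteria sets must have length n_categories - 1")
    p <- if (spec$family == "rce") predict_rce(spec, params, design)
         else predict_affine(spec, params, design)
  }
  dimnames(p) <- list(s_id = c("-1", "1"), soa = design$soa_levels_ms,
                      r_id = c("-1", "1"), category = 0:(nc - 1L))
  structure(p, class = c("wev_probs", "array"), design = design)
}

# sdt, noisy_sdt, wev, two_channel, postdecisional, cnd:
# delta_v = alpha * delta_id + beta + s_rep * Z
predict_affine <- function(spec, params, design) {
  ns <- length(design$soa_levels_ms)
  nc <- design$n_categories
  S <- params$S_s
  Sbar <- mean(S)
  s_id <- rep(c(-1, 1), each = ns)          # condition order: s index slow
  S_c <- rep(S, 2)
  ncond <- 2L * ns
  sig_id <- sigma_id_of(spec, params, s_id, S_c)
  mu_id <- 0.5 * s_id * S_c
  p <- array(0, dim = c(2L, ns, 2L, nc))
  cminus <- minus_axis_criteria(params)     # increasing on nu = -delta_v
  for (ri in 1:2) {
    r <- c(-1, 1)[ri]
    ab <- switch(spec$family,
      sdt            = list(a = rep(1, ncond), b = rep(0, ncond), s = 0),
      noisy_sdt      = list(a = rep(1, ncond), b = rep(0, ncond), s = params$sigma_v),
      wev            = list(a = rep(1 - params$w, ncond),
                            b = params$w * r * (S_c - Sbar), s = params$sigma_v),
      two_channel    = list(a = rep(0, ncond), b = 0.5 * s_id * S_c * params$a, s = 1),
      postdecisional = list(a = rep(1, ncond), b = s_id * S_c * params$b,
                            s = sqrt(params$b)),
      cnd            = list(a = rep(params$rho, 2), b = rep(0, ncond), s = params$sigma_v))
    mu_y <- ab$a * mu_id + ab$b
    sd_y <- sqrt(ab$a^2 * sig_id^2 + ab$s^2)
    rho <- ab$a * sig_id / sd_y
    h <- (params$theta_id - mu_id) / sig_id
    # category boundaries on the delta_v axis, low category to high
    bnd <- if (r > 0) c(-Inf, params$theta_v_plus, Inf)
           else c(-Inf, rev(-cminus), Inf)   # delta_v interval, ascending
    K <- (matrix(bnd, ncond, nc + 1, byrow = TRUE) - mu_y) / sd_y
    H <- matrix(h, ncond, nc + 1)
    R <- matrix(rho, ncond, nc + 1)
    cum <- if (r > 0) {
      # P(X > theta, Y <= c) = pnorm(c) - pbvnorm(h, c)
      stats::pnorm(K) - pbvnorm(H, K, R)
    } else {
      pbvnorm(H, K, R)                      # P(X <= theta, Y <= c)
    }
    cum <- matrix(cum, ncond, nc + 1)
    cells <- cum[, -1, drop = FALSE] - cum[, -(nc + 1), drop = FALSE]
    if (r < 0) cells <- cells[, nc:1, drop = FALSE]  # ascending delta_v -> descending category
    cells <- pmin(pmax(cells, 0), 1)
    for (si in 1:2)
      p[si, , ri, ] <- cells[(si - 1L) * ns + seq_len(ns), ]
  }
  p
}

predict_rce <- function(spec, params, design) {
  ns <- length(design$soa_levels_ms)
  nc <- design$n_categories
  gl <- gauss_legendre_01(N_QUAD)
  S <- params$S_s
  p <- array(0, dim = c(2L, ns, 2L, nc))
  for (si in 1:2) {
    s <- c(-1, 1)[si]
    sig <- sigma_id_of(spec, params, rep(s, ns), S)
    mu_m <- 0.5 * (1 - s) * S - params$theta_id
    mu_p <- 0.5 * (1 + s) * S + params$theta_id
    for (ri in 1:2) {
      if (ri == 2L) { mu_w <- mu_p; mu_l <- mu_m; crit <- params$theta_v_plus }
      else          { mu_w <- mu_m; mu_l <- mu_p; crit <- params$theta_v_minus }
      bnd <- c(-Inf, crit, Inf)
      for (t in seq_len(ns)) {
        # exact response probability: winner minus loser is N(mu_w - mu_l,
        # sig * sqrt(2)); the top category absorbs the tiny quadrature
        # residual so each condition normalizes exactly
        p_resp <- stats::pnorm((mu_w[t] - mu_l[t]) / (sig[t] * sqrt(2)))
        u <- stats::pnorm((bnd - mu_w[t]) / sig[t])
        for (v in seq_len(nc - 1L)) {
          du <- u[v + 1] - u[v]
          if (du <= 0) next
          uu <- u[v] + gl$x * du
          x <- mu_w[t] + sig[t] * stats::qnorm(uu)
          p[si, t, ri, v] <- du * sum(gl$w * stats::pnorm((x - mu_l[t]) / sig[t]))
        }
        p[si, t, ri, nc] <- max(p_resp - sum(p[si, t, ri, seq_len(nc - 1L)]), 0)
      }
    }
  }
  p
}

#' Posterior probability of stimulus identity in the 2D Bayesian model
#'
#' Given the two channel samples `delta_minus` and `delta_plus`, the noise SD
#' `s_noise`, and the discrete SOA set (ms), returns
#' `P(S_id = +1 | delta_minus, delta_plus)` under a flat prior over SOAs and
#' identities, summing Gaussian densities over the SOA set (log-sum-exp
#' guarded). Vectorized over the deltas.
#'
#' @param delta_minus,delta_plus channel samples (recycled to common length).
#' @param s_noise positive noise SD.
#' @param soa_set nonempty vector of SOAs (ms).
#' @return probabilities in `[0, 1]`.
#' @export
posterior_identity <- function(delta_minus, delta_plus, s_noise, soa_set) {
  if (s_noise <= 0) stop("s_noise must be positive")
  if (length(soa_set) < 1) stop("soa_set must be nonempty")
  stats::plogis(logit_posterior_identity(delta_minus, delta_plus, s_noise, soa_set))
}

logit_posterior_identity <- function(delta_minus, delta_plus, s_noise, soa_set) {
  n <- max(length(delta_minus), length(delta_plus))
  dm <- rep_len(delta_minus, n)
  dp <- rep_len(delta_plus, n)
  inv2s2 <- 1 / (2 * s_noise^2)
  # log sum_t exp(-((dm - a_t)^2 + (dp - b_t)^2) / (2 s^2)) for identity +1
  # (a = 0, b = t) minus the same for identity -1 (a = t, b = 0)
  la <- -(outer(dm^2, rep(1, length(soa_set))) +
            outer(dp, soa_set, "-")^2) * inv2s2
  lb <- -(outer(dm, soa_set, "-")^2 +
            outer(dp^2, rep(1, length(soa_set)))) * inv2s2
  lse <- function(m) {
    mx <- m[, 1]
    for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
    mx + log(rowSums(exp(m - mx)))
  }
  lse(la) - lse(lb)
}

predict_bayes2d <- function(params, design) {
  ns <- length(design$soa_levels_ms)
  nc <- design$n_categories
  soa <- design$soa_levels_ms
  sn <- params$s_noise
  lth <- stats::qlogis(params$theta_post)
  gl <- gauss_legendre_01(N_QUAD)
  nopt <- 2L * nc
  p <- array(0, dim = c(2L, ns, 2L, nc))
  # delta_minus node sets: mean 0 (identity +1, all SOAs) or soa[t] (identity -1)
  m_m_set <- c(0, soa)
  xs <- as.vector(outer(sn * stats::qnorm(gl$x), m_m_set, "+"))  # N_QUAD x (ns+1)
  # q(x, g) does not depend on the condition, so the criterion level sets
  # g_j(x) are inverted once over the pooled nodes (vectorized bisection;
  # logit q is strictly increasing in g with slope >= min(soa)/sn^2)
  nx <- length(xs)
  X <- matrix(xs, nx, length(lth))
  TH <- matrix(lth, nx, length(lth), byrow = TRUE)
  half <- (max(abs(lth)) + max(soa) * (max(abs(xs)) + max(soa) + 4 * sn) / sn^2) /
    (min(soa) / sn^2) + max(soa) + 4 * sn
  lo <- matrix(-half, nx, length(lth))
  hi <- matrix(half, nx, length(lth))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    f <- logit_posterior_identity(as.vector(X), as.vector(mid), sn, soa) -
      as.vector(TH)
    below <- matrix(f < 0, nx, length(lth))
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  G <- (lo + hi) / 2                                   # nx x 9
  for (si in 1:2) {
    s <- c(-1, 1)[si]
    for (t in seq_len(ns)) {
      m_m <- 0.5 * (1 - s) * soa[t]
      m_p <- 0.5 * (1 + s) * soa[t]
      rows <- (match(m_m, m_m_set) - 1L) * N_QUAD + seq_len(N_QUAD)
      cum <- cbind(0, stats::pnorm((G[rows, , drop = FALSE] - m_p) / sn), 1)
      opt <- as.vector(gl$w %*% (cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]))
      opt <- (1 - params$lambda) * opt + params$lambda / nopt
      # options ordered along increasing posterior:
      # (-1, v = nc-1) ... (-1, 0), (+1, 0) ... (+1, nc-1)
      p[si, t, 1, ] <- rev(opt[seq_len(nc)])
      p[si, t, 2, ] <- opt[nc + seq_len(nc)]
    }
  }
  p
}

#' Convert a probability table to tidy long format
#'
#' One row per (stimulus identity, SOA, response, category) cell, suitable
#' for plotting observed-versus-predicted rating distributions or export.
#'
#' @param p a `wev_probs` array from [predict_response_probabilities()].
#' @param file optional path; when given, the table is also written as CSV.
#' @return data frame with columns `s_id`, `soa_ms`, `r_id`, `category`, `p`.
#' @export
probs_to_long <- function(p, file = NULL) {
  stopifnot(inherits(p, "wev_probs"))
  design <- attr(p, "design")
  d <- dim(p)
  out <- expand.grid(s_id = c(-1L, 1L), soa_ms = design$soa_levels_ms,
                     r_id = c(-1L, 1L), category = 0:(d[4] - 1L),
                     KEEP.OUT.ATTRS = FALSE)
  out$p <- as.vector(p)
  out <- out[order(out$s_id, out$soa_ms, out$r_id, out$category), ]
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  out
}
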