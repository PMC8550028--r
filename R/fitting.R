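# Per-participant maximum-likelihood estimation on the discretized count
# table: coarse grid search over documented ranges seeds Nelder-Mead simplex
# runs, each restarted from its incumbent to escape premature convergence.
# Optimization runs in an unconstrained internal parameterization (log for
# positive parameters, logit for [0,1] parameters, base + log-increments for
# ordered criteria), so the simplex never leaves the valid region.

#' Fitting procedure settings
#'
#' Defaults reproduce the reference procedure shape: a coarse grid search
#' identifies `n_starts = 5` promising starting points, and each simplex run is
#' restarted `n_restarts = 4` times from its incumbent.
#'
#' @param n_starts number of grid points promoted to simplex starts.
#' @param n_restarts restarts of each simplex run from its incumbent.
#' @param ftol relative convergence tolerance of the simplex.
#' @param max_iterations iteration cap per simplex run.
#' @param seed stored for provenance (the fit itself is deterministic).
#' @return a `wev_fit_settings` list.
#' @export
fit_settings <- function(n_starts = 5L, n_restarts = 4L, ftol = 1e-8,
                         max_iterations = 2000L, seed = 1L) {
  stopifnot(n_starts >= 1L, n_restarts >= 0L, ftol > 0, max_iterations >= 1L)
  structure(list(n_starts = as.integer(n_starts),
                 n_restarts = as.integer(n_restarts),
                 ftol = ftol, max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "wev_fit_settings")
}

#' Negative log-likelihood of a count table under a model
#'
#' `-sum(n_cell * log(max(p_cell, 1e-10)))` with cell probabilities from
#' [predict_response_probabilities()]; the floor guards structural zeros
#' meeting stray counts.
#'
#' @param spec a [model_spec()].
#' @param params a matching `wev_params` (validated before any numerics).
#' @param counts a `wev_counts` table from [tabulate_trials()].
#' @param design the design; defaults to the one attached to `counts`.
#' @return nonnegative scalar.
#' @export
negative_log_likelihood <- function(spec, params, counts,
                                    design = attr(counts, "design")) {
  validate_params(params)
  if (is.null(design)) stop("counts carries no design; pass one explicitly")
  if (!all(dim(counts) == c(2L, length(design$soa_levels_ms), 2L, design$n_categories)))
    stop("counts dimensions do not match the design")
  p <- predict_response_probabilities(spec, params, design)
  -sum(counts * log(pmax(p, 1e-10)))
}

#' Small-sample-corrected Akaike and Bayesian information criteria
#'
#' `aicc = 2*negll + 2k + 2k(k+1)/(n-k-1)`; `bic = 2*negll + k*log(n)`,
#' with `n` the participant's trial count.
#'
#' @param negll fitted negative log-likelihood.
#' @param k number of free parameters.
#' @param n number of trials.
#' @return numeric scalar.
#' @export
aicc <- function(negll, k, n) {
  if (n <= k + 1) stop("aicc requires n > k + 1")
  2 * negll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
bic <- function(negll, k, n) 2 * negll + k * log(n)

## ---- internal transform between wev_params and unconstrained vectors ----

.ord_pack <- function(x) c(x[1], log(pmax(diff(x), 1e-8)))
.ord_unpack <- function(z) cumsum(c(z[1], exp(z[-1])))

pack_params <- function(params) {
  spec <- params$spec
  if (spec$family == "bayes2d") {
    th <- c(.ord_pack(stats::qlogis(params$theta_post)),
            log(params$s_noise),
            stats::qlogis(pmin(pmax(params$lambda, 1e-6), 1 - 1e-6)))
  } else {
    nu_minus <- if (spec$family == "rce") params$theta_v_minus else -params$theta_v_minus
    th <- c(log(pmax(params$S_s, 1e-6)), params$theta_id,
            .ord_pack(params$theta_v_plus), .ord_pack(nu_minus))
    th <- c(th, switch(spec$family,
                       sdt = NULL,
                       noisy_sdt = log(params$sigma_v),
                       wev = c(log(params$sigma_v),
                               stats::qlogis(pmin(pmax(params$w, 1e-6), 1 - 1e-6))),
                       two_channel = log(pmax(params$a, 1e-6)),
                       postdecisional = log(params$b),
                       cnd = c(log(params$sigma_v),
                               stats::qlogis(pmin(pmax(params$rho, 1e-6), 1 - 1e-6))),
                       rce = NULL))
  }
  if (spec$variance_mode == "identity_dependent") th <- c(th, log(params$r_id))
  if (spec$variance_mode == "soa_dependent") th <- c(th, log(pmax(params$k, 1e-8)))
  th
}

unpack_params <- function(theta, spec, design) {
  ns <- length(design$soa_levels_ms)
  ncrit <- design$n_categories - 1L
  i <- 0L
  take <- function(m) {
    out <- theta[i + seq_len(m)]
    i <<- i + m
    out
  }
  if (spec$family == "bayes2d") {
    th_post <- stats::plogis(.ord_unpack(take(2L * design$n_categories - 1L)))
    s_noise <- exp(take(1L))
    lambda <- stats::plogis(take(1L))
    args <- list(s_noise = s_noise, lambda = lambda, theta_post = th_post)
  } else {
    S_s <- exp(take(ns))
    theta_id <- take(1L)
    plus <- .ord_unpack(take(ncrit))
    nu_minus <- .ord_unpack(take(ncrit))
    minus <- if (spec$family == "rce") nu_minus else -nu_minus
    args <- list(S_s = S_s, theta_id = theta_id,
                 theta_v_plus = plus, theta_v_minus = minus)
    args <- c(args, switch(spec$family,
      sdt = NULL,
      noisy_sdt = list(sigma_v = exp(take(1L))),
      wev = list(sigma_v = exp(take(1L)), w = stats::plogis(take(1L))),
      two_channel = list(a = exp(take(1L))),
      postdecisional = list(b = exp(take(1L))),
      cnd = list(sigma_v = exp(take(1L)), rho = stats::plogis(take(ns))),
      rce = NULL))
  }
  if (spec$variance_mode == "identity_dependent") args$r_id <- exp(take(1L))
  if (spec$variance_mode == "soa_dependent") args$k <- exp(take(1L))
  if (i != length(theta)) stop("parameter vector length mismatch")
  do.call(parameter_set, c(list(spec = spec), args))
}

## ---- starting values ----

# criteria seeds: probit quantiles of the observed category frequencies for a
# response, mapped onto the report-variable mixture scale (M, SD)
.criteria_seed <- function(freq, M, SD, ncrit) {
  cum <- cumsum(freq + 0.5) / (sum(freq) + 0.5 * length(freq))
  q <- stats::qnorm(cum[seq_len(ncrit)])
  out <- M + SD * q
  # enforce strict spacing
  for (j in seq_along(out)[-1])
    out[j] <- max(out[j], out[j - 1] + 1e-3)
  out
}

# mixture moments of the report variable per response for a structural
# candidate (affine families and rce; selection effects ignored: seeds only)
.report_moments <- function(spec, cand, design, n_cond) {
  ns <- length(design$soa_levels_ms)
  s_id <- rep(c(-1, 1), each = ns)
  S <- rep(cand$S_s, 2)
  sig <- sigma_id_of(spec, cand, s_id, S)
  mu_id <- 0.5 * s_id * S
  out <- list()
  for (ri in 1:2) {
    r <- c(-1, 1)[ri]
    if (spec$family == "rce") {
      mu_y <- 0.5 * (1 + r * s_id) * S + r * cand$theta_id   # selected channel
      sd_y <- sig
      mu_other <- 0.5 * (1 - r * s_id) * S - r * cand$theta_id
      pr <- stats::pnorm((mu_y - mu_other) / (sig * sqrt(2)))
    } else {
      ab <- switch(spec$family,
        sdt            = list(a = 1, b = 0, s = 0),
        noisy_sdt      = list(a = 1, b = 0, s = cand$sigma_v),
        wev            = list(a = 1 - cand$w, b = cand$w * r * (S - mean(cand$S_s)),
                              s = cand$sigma_v),
        two_channel    = list(a = 0, b = 0.5 * s_id * S * cand$a, s = 1),
        postdecisional = list(a = 1, b = s_id * S * cand$b, s = sqrt(cand$b)),
        cnd            = list(a = rep(cand$rho, 2), b = 0, s = cand$sigma_v))
      mu_y <- ab$a * mu_id + ab$b
      sd_y <- sqrt(ab$a^2 * sig^2 + ab$s^2)
      pr <- stats::pnorm(r * (mu_id - cand$theta_id) / sig)
      if (r < 0) { mu_y <- -mu_y }                 # report axis nu = -delta_v
    }
    wgt <- pr * n_cond
    wgt <- wgt / max(sum(wgt), 1e-12)
    M <- sum(wgt * mu_y)
    V <- sum(wgt * (sd_y^2 + mu_y^2)) - M^2
    out[[ri]] <- c(M = M, SD = sqrt(max(V, 1e-6)))
  }
  out
}

# coarse grid of candidate parameter sets over documented ranges
starting_grid <- function(spec, counts, design) {
  ns <- length(design$soa_levels_ms)
  nc <- design$n_categories
  ncrit <- nc - 1L
  n_cond <- as.vector(apply(counts, c(1, 2), sum))      # s slow, like .report_moments
  corr <- sapply(seq_len(ns), function(t) sum(counts[1, t, 1, ]) + sum(counts[2, t, 2, ]))
  tot <- sapply(seq_len(ns), function(t) sum(counts[, t, , ]))
  acc <- ifelse(tot > 0, corr / pmax(tot, 1), 0.75)
  S_acc <- 2 * stats::qnorm(pmin(pmax(acc, 0.51), 0.995))
  S_acc <- pmax(S_acc, 0.05)
  freq_plus <- apply(counts[, , 2, , drop = FALSE], 4, sum)
  freq_minus_nu <- apply(counts[, , 1, , drop = FALSE], 4, sum)
  if (spec$family == "bayes2d") {
    # option frequencies along the posterior ordering
    f <- c(rev(freq_minus_nu), freq_plus)
    cum <- cumsum(f + 0.5) / (sum(f) + 0.5 * length(f))
    th0 <- pmin(pmax(cum[seq_len(2L * nc - 1L)], 1e-3), 1 - 1e-3)
    for (j in seq_along(th0)[-1]) th0[j] <- max(th0[j], th0[j - 1] + 1e-4)
    cands <- list()
    for (sn in c(0.25, 0.5, 1) * mean(design$soa_levels_ms))
      for (lam in c(0.01, 0.05))
        cands[[length(cands) + 1L]] <- parameter_set(
          spec, s_noise = sn, lambda = lam, theta_post = th0)
    return(cands)
  }
  profiles <- list(S_acc, 0.6 * S_acc)
  for (v in c(0.05, 1, 2, 4)) profiles[[length(profiles) + 1L]] <- rep(v, ns)
  extras <- switch(spec$family,
    sdt = list(list()),
    noisy_sdt = lapply(c(0.25, 1, 4), function(s) list(sigma_v = s)),
    wev = unlist(lapply(c(0.25, 1, 4), function(s)
      lapply(c(0.25, 0.5, 0.75), function(w) list(sigma_v = s, w = w))),
      recursive = FALSE),
    two_channel = lapply(c(0.5, 1, 2), function(a) list(a = a)),
    postdecisional = lapply(c(0.5, 1, 2), function(b) list(b = b)),
    cnd = unlist(lapply(c(0.25, 1, 4), function(s)
      lapply(c(0.3, 0.7), function(r) list(sigma_v = s, rho = rep(r, ns)))),
      recursive = FALSE),
    rce = list(list()))
  var_extra <- switch(spec$variance_mode,
    constant = list(list()),
    identity_dependent = lapply(c(0.8, 1, 1.25), function(r) list(r_id = r)),
    soa_dependent = lapply(c(0.01, 0.1, 0.3), function(k) list(k = k)))
  cands <- list()
  for (prof in profiles) for (th_id in c(-0.5, 0, 0.5))
    for (ex in extras) for (vx in var_extra) {
      cand <- c(list(S_s = prof, theta_id = th_id), ex, vx)
      cand_tmp <- cand
      cand_tmp$spec <- spec
      mom <- .report_moments(spec, cand_tmp, design, n_cond)
      plus <- .criteria_seed(freq_plus, mom[[2]]["M"], mom[[2]]["SD"], ncrit)
      nu_minus <- .criteria_seed(freq_minus_nu, mom[[1]]["M"], mom[[1]]["SD"], ncrit)
      minus <- if (spec$family == "rce") nu_minus else -nu_minus
      cands[[length(cands) + 1L]] <- do.call(parameter_set,
        c(list(spec = spec, theta_v_plus = plus, theta_v_minus = minus), cand))
    }
  cands
}

#' Fit a model to a participant's count table by maximum likelihood
#'
#' A coarse grid over documented per-parameter ranges (criteria seeded from
#' probit quantiles of the observed category frequencies) is evaluated; the
#' `n_starts` best grid points seed Nelder-Mead simplex runs in an
#' unconstrained internal parameterization; each run is restarted
#' `n_restarts` times from its incumbent. Deterministic given data and
#' settings; the final negative log-likelihood never exceeds the best grid
#' value.
#'
#' @param spec a [model_spec()].
#' @param counts a `wev_counts` table from [tabulate_trials()].
#' @param settings a [fit_settings()].
#' @param design defaults to the design attached to `counts`.
#' @return a `wev_fit` object: fitted `params`, `negll`, `aicc`, `bic`,
#'   `n_trials`, `k_free`, `converged`, and an `optimizer_trace` of
#'   (start, restart, iterations, negll) rows.
#' @export
fit_model <- function(spec, counts, settings = fit_settings(),
                      design = attr(counts, "design")) {
  stopifnot(inherits(spec, "wev_spec"), inherits(settings, "wev_fit_settings"))
  if (is.null(design)) stop("counts carries no design; pass one explicitly")
  n_trials <- sum(counts)
  if (n_trials == 0L) stop("counts is empty")
  obj <- function(theta) {
    p <- tryCatch(unpack_params(theta, spec, design), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    nll <- negative_log_likelihood(spec, p, counts, design)
    if (!is.finite(nll)) 1e10 else nll
  }
  cands <- starting_grid(spec, counts, design)
  grid_nll <- vapply(cands, function(p) negative_log_likelihood(spec, p, counts, design),
                     numeric(1))
  ord <- order(grid_nll)
  # promote the best grid points, but spread the starts over distinct
  # structural-parameter combinations: the top of the ranking is often many
  # criteria-variants of one basin, and the simplex rarely crosses basins
  key <- vapply(cands, function(p) {
    v <- flatten_params(p)
    keep <- !grepl("^(S_s|theta_v|theta_id|theta_post)", names(v))
    paste(signif(v[keep], 6), collapse = ",")
  }, character(1))
  starts <- integer(0)
  used <- character(0)
  for (j in ord) {
    if (length(starts) >= settings$n_starts) break
    if (key[j] %in% used) next
    starts <- c(starts, j)
    used <- c(used, key[j])
  }
  for (j in ord) {
    if (length(starts) >= min(settings$n_starts, length(cands))) break
    if (!(j %in% starts)) starts <- c(starts, j)
  }
  best <- list(value = min(grid_nll), theta = pack_params(cands[[ord[1]]]), conv = FALSE)
  trace <- NULL
  for (si in seq_along(starts)) {
    theta <- pack_params(cands[[starts[si]]])
    value <- grid_nll[starts[si]]
    conv <- FALSE
    for (run in seq_len(settings$n_restarts + 1L)) {
      opt <- stats::optim(theta, obj, method = "Nelder-Mead",
                          control = list(maxit = settings$max_iterations,
                                         reltol = settings$ftol))
      if (opt$value <= value) {
        theta <- opt$par
        value <- opt$value
      }
      conv <- opt$convergence == 0L
      trace <- rbind(trace, data.frame(start = si, restart = run - 1L,
                                       iterations = opt$counts[1],
                                       negll = opt$value))
    }
    if (value < best$value) best <- list(value = value, theta = theta, conv = conv)
  }
  params <- unpack_params(best$theta, spec, design)
  k <- count_free_parameters(spec, design)
  out <- list(spec = spec, params = params, negll = best$value,
              aicc = aicc(best$value, k, n_trials),
              bic = bic(best$value, k, n_trials),
              n_trials = n_trials, k_free = k,
              converged = best$conv, grid_best_negll = min(grid_nll),
              optimizer_trace = trace, settings = settings)
  class(out) <- "wev_fit"
  out
}

#' @export
print.wev_fit <- function(x, ...) {
  cat(sprintf("Fit: %s (%s)  negLL = %.2f  AICc = %.2f  BIC = %.2f  k = %d  n = %d\n",
              x$spec$family, x$spec$variance_mode, x$negll, x$aicc, x$bic,
              x$k_free, x$n_trials))
  invisible(x)
}
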