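# Trial simulation draws the model's latent variables directly from the
# generative equations (never from the predicted probability table), so the
# simulator and the likelihood are independent implementations that can be
# cross-validated against each other.

#' Simulate trials from a generative model
#'
#' Draws `trials_per_soa` trials at every SOA, identities split as evenly as
#' possible (an odd trial is assigned at random), by sampling each model's
#' latent decision variables.
#'
#' @param spec a [model_spec()].
#' @param params a matching `wev_params`.
#' @param design a [experiment_design()].
#' @param seed optional integer seed (same seed, same output).
#' @param trials_per_soa override of the design's trial count per SOA; 0 gives
#'   an empty table.
#' @return data frame with columns `soa_ms`, `stimulus`, `response`,
#'   `category`.
#' @export
simulate_trials <- function(spec, params, design, seed = NULL,
                            trials_per_soa = design$trials_per_soa) {
  stopifnot(inherits(spec, "wev_spec"), inherits(design, "wev_design"))
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  nper <- as.integer(trials_per_soa)
  if (nper == 0L)
    return(data.frame(soa_ms = numeric(0), stimulus = integer(0),
                      response = integer(0), category = integer(0)))
  ns <- length(design$soa_levels_ms)
  id_per_soa <- function() {
    base <- rep(c(-1L, 1L), floor(nper / 2))
    if (nper %% 2L) base <- c(base, sample(c(-1L, 1L), 1L))
    sample(base)
  }
  soa_idx <- rep(seq_len(ns), each = nper)
  s_id <- as.integer(unlist(lapply(seq_len(ns), function(i) id_per_soa())))
  soa <- design$soa_levels_ms[soa_idx]
  n <- length(s_id)
  nc <- design$n_categories
  if (spec$family == "bayes2d") {
    sn <- params$s_noise
    d_m <- stats::rnorm(n, 0.5 * (1 - s_id) * soa, sn)
    d_p <- stats::rnorm(n, 0.5 * (1 + s_id) * soa, sn)
    q <- posterior_identity(d_m, d_p, sn, design$soa_levels_ms)
    opt <- findInterval(q, params$theta_post) + 1L        # 1..2*nc
    lapse <- stats::runif(n) < params$lambda
    if (any(lapse)) opt[lapse] <- sample.int(2L * nc, sum(lapse), replace = TRUE)
    r_id <- ifelse(opt > nc, 1L, -1L)
    category <- ifelse(opt > nc, opt - nc - 1L, nc - opt)
    return(data.frame(soa_ms = soa, stimulus = s_id, response = r_id,
                      category = as.integer(category)))
  }
  S <- params$S_s[soa_idx]
  sig_id <- sigma_id_of(spec, params, s_id, S)
  if (spec$family == "rce") {
    d_m <- stats::rnorm(n, 0.5 * (1 - s_id) * S - params$theta_id, sig_id)
    d_p <- stats::rnorm(n, 0.5 * (1 + s_id) * S + params$theta_id, sig_id)
    r_id <- ifelse(d_m > d_p, -1L, 1L)
    winner <- ifelse(r_id > 0, d_p, d_m)
    category <- integer(n)
    up <- r_id > 0
    category[up] <- findInterval(winner[up], params$theta_v_plus)
    category[!up] <- findInterval(winner[!up], params$theta_v_minus)
    return(data.frame(soa_ms = soa, stimulus = s_id, response = r_id,
                      category = as.integer(category)))
  }
  d_id <- stats::rnorm(n, 0.5 * s_id * S, sig_id)
  r_id <- ifelse(d_id < params$theta_id, -1L, 1L)
  d_v <- switch(spec$family,
    sdt = d_id,
    noisy_sdt = stats::rnorm(n, d_id, params$sigma_v),
    wev = stats::rnorm(n, (1 - params$w) * d_id +
                         params$w * r_id * (S - mean(params$S_s)), params$sigma_v),
    two_channel = stats::rnorm(n, 0.5 * s_id * S * params$a, 1),
    postdecisional = stats::rnorm(n, d_id + s_id * S * params$b, sqrt(params$b)),
    cnd = stats::rnorm(n, d_id * params$rho[soa_idx], params$sigma_v))
  category <- integer(n)
  up <- r_id > 0
  category[up] <- findInterval(d_v[up], params$theta_v_plus)
  category[!up] <- findInterval(-d_v[!up], -params$theta_v_minus)
  data.frame(soa_ms = soa, stimulus = s_id, response = r_id,
             category = as.integer(category))
}
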