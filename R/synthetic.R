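# Synthetic experiments with the statistical structure the analysis assumes:
# masked-orientation identification with graded visual-analogue ratings.
# Default parameter ranges are chosen once to produce realistic behavior on
# the 5-SOA design -- chance accuracy at 8.3 ms, near-ceiling at 133.3 ms,
# all five rating categories populated -- and stand in for the unavailable
# fitted parameters of real observers.

#' Default parameter ranges for the synthetic sampler
#'
#' Uniform sampling ranges per parameter. Sensitivities follow an increasing
#' profile over SOA from near 0 to about 4 (accuracy from chance to ceiling);
#' report criteria are built from a base and positive steps so that all rating
#' categories are populated.
#'
#' @param spec a [model_spec()].
#' @param design a [experiment_design()].
#' @return named list of `c(lo, hi)` ranges (vectors for per-SOA parameters).
#' @export
default_parameter_ranges <- function(spec, design = design_exp1()) {
  ns <- length(design$soa_levels_ms)
  prof_lo <- c(0.0, 0.3, 1.0, 2.0, 3.2)
  prof_hi <- c(0.4, 1.0, 2.2, 3.4, 4.8)
  if (ns != 5L) {
    # interpolate the increasing profile onto other designs
    at <- seq(0, 1, length.out = ns)
    prof_lo <- stats::approx(seq(0, 1, length.out = 5L), prof_lo, at)$y
    prof_hi <- stats::approx(seq(0, 1, length.out = 5L), prof_hi, at)$y
  }
  r <- list(S_s = cbind(prof_lo, prof_hi),
            theta_id = c(-0.3, 0.3),
            crit_base = c(-0.8, -0.2),
            crit_step = c(0.4, 1.0))
  if (spec$family == "rce") {
    r$crit_base <- c(0.2, 0.8)
    r$crit_step <- c(0.3, 0.8)
  }
  if (spec$family %in% c("noisy_sdt", "wev", "cnd")) r$sigma_v <- c(0.5, 1.5)
  if (spec$family == "wev") r$w <- c(0.2, 0.7)
  if (spec$family == "two_channel") r$a <- c(0.5, 1.5)
  if (spec$family == "postdecisional") r$b <- c(0.3, 1.5)
  if (spec$family == "cnd") r$rho <- c(0.3, 0.9)
  if (spec$family == "bayes2d") {
    r$s_noise <- c(20, 60)
    r$lambda <- c(0.005, 0.05)
    r$theta_post_jitter <- c(0.8, 1.25)   # factor on logit-scale increments
  }
  if (spec$variance_mode == "identity_dependent") r$r_id <- c(0.8, 1.25)
  if (spec$variance_mode == "soa_dependent") r$k <- c(0, 0.2)
  r
}

#' Draw a random parameter set within ranges
#'
#' Parameters are drawn uniformly within their ranges; ordered criteria are
#' generated as base plus positive steps, so every draw satisfies the
#' family's constraints by construction. Deterministic given `seed`.
#'
#' @param spec a [model_spec()].
#' @param ranges as from [default_parameter_ranges()]; point-mass ranges
#'   (`lo == hi`) give exactly that value.
#' @param seed optional integer seed.
#' @param design a [experiment_design()].
#' @return a `wev_params` object.
#' @export
sample_parameters <- function(spec, ranges = default_parameter_ranges(spec, design),
                              seed = NULL, design = design_exp1()) {
  if (!is.null(seed)) set.seed(seed)
  u <- function(r) stats::runif(1, r[1], r[2])
  ns <- length(design$soa_levels_ms)
  ncrit <- design$n_categories - 1L
  if (spec$family == "bayes2d") {
    nopt <- 2L * design$n_categories
    base <- stats::qlogis(seq(0.5 / nopt, 1 - 0.5 / nopt, length.out = nopt - 1L) *
                            0.9 + 0.05)
    steps <- diff(base) * stats::runif(nopt - 2L, ranges$theta_post_jitter[1],
                                       ranges$theta_post_jitter[2])
    th <- stats::plogis(cumsum(c(base[1] * stats::runif(1, 0.8, 1.25), steps)))
    args <- list(s_noise = u(ranges$s_noise), lambda = u(ranges$lambda),
                 theta_post = th)
  } else {
    S_s <- vapply(seq_len(ns), function(i) u(ranges$S_s[i, ]), numeric(1))
    plus <- cumsum(c(u(ranges$crit_base),
                     stats::runif(ncrit - 1L, ranges$crit_step[1], ranges$crit_step[2])))
    nu_minus <- cumsum(c(u(ranges$crit_base),
                         stats::runif(ncrit - 1L, ranges$crit_step[1], ranges$crit_step[2])))
    minus <- if (spec$family == "rce") nu_minus else -nu_minus
    args <- list(S_s = S_s, theta_id = u(ranges$theta_id),
                 theta_v_plus = plus, theta_v_minus = minus)
    if (!is.null(ranges$sigma_v)) args$sigma_v <- u(ranges$sigma_v)
    if (!is.null(ranges$w)) args$w <- u(ranges$w)
    if (!is.null(ranges$a)) args$a <- u(ranges$a)
    if (!is.null(ranges$b)) args$b <- u(ranges$b)
    if (!is.null(ranges$rho))
      args$rho <- stats::runif(ns, ranges$rho[1], ranges$rho[2])
  }
  if (!is.null(ranges$r_id)) args$r_id <- u(ranges$r_id)
  if (!is.null(ranges$k)) args$k <- u(ranges$k)
  do.call(parameter_set, c(list(spec = spec), args))
}

#' Configure a synthetic cohort
#'
#' @param preset `"exp1"` (110 trials/SOA), `"exp2"` (81 trials/SOA), or
#'   `"custom"` with an explicit `design`.
#' @param n_participants cohort size.
#' @param spec generative [model_spec()].
#' @param ranges parameter sampling ranges.
#' @param seed master seed; participant `i` uses `seed + i`.
#' @param design required when `preset = "custom"`.
#' @return a `wev_cohort_config` list.
#' @export
cohort_config <- function(preset = c("exp1", "exp2", "custom"),
                          n_participants = 10L, spec = model_spec("wev"),
                          ranges = NULL, seed = 1L, design = NULL) {
  preset <- match.arg(preset)
  design <- switch(preset, exp1 = design_exp1(), exp2 = design_exp2(),
                   custom = design)
  if (is.null(design)) stop("custom preset needs an explicit design")
  if (is.null(ranges)) ranges <- default_parameter_ranges(spec, design)
  structure(list(preset = preset, n_participants = as.integer(n_participants),
                 spec = spec, ranges = ranges, seed = as.integer(seed),
                 design = design),
            class = "wev_cohort_config")
}

# continuous rating drawn uniformly within the category's partition, so
# discretize_rating() inverts it exactly
.emit_continuous <- function(category, nc) {
  (category + stats::runif(length(category)) * (1 - 1e-12)) / nc
}

#' Generate a synthetic cohort of participants
#'
#' Per participant: draws a parameter set from the ranges, simulates the
#' design's trials via [simulate_trials()], and emits a continuous rating
#' uniformly within the trial's category partition (so discretization
#' round-trips exactly). Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return data frame in canonical trial format (with both `rating` and
#'   `category`), plus a `params` attribute listing each participant's
#'   generating parameters.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "wev_cohort_config"))
  nc <- config$design$n_categories
  out <- vector("list", config$n_participants)
  pars <- vector("list", config$n_participants)
  ids <- sprintf("p%02d", seq_len(config$n_participants))
  for (i in seq_len(config$n_participants)) {
    pars[[i]] <- sample_parameters(config$spec, config$ranges,
                                   seed = config$seed + i, design = config$design)
    tr <- simulate_trials(config$spec, pars[[i]], config$design)
    tr$rating <- .emit_continuous(tr$category, nc)
    tr$participant <- ids[i]
    tr$trial <- seq_len(nrow(tr))
    out[[i]] <- tr
  }
  names(pars) <- ids
  res <- do.call(rbind, out)
  res <- res[, c("participant", "trial", "soa_ms", "stimulus", "response",
                 "category", "rating")]
  attr(res, "params") <- pars
  res
}

#' Generate joint visibility and confidence trials from the WEV model
#'
#' One identification sample per trial; the visibility and confidence report
#' variables are computed with their own weights `w_vis` and `w_conf`. Under
#' `noise_mode = "shared"` the same report-noise disturbance feeds both
#' judgments; under `"independent"` it is redrawn. Both ratings use the same
#' criteria sets, and continuous ratings are emitted uniformly within the
#' category partition.
#'
#' @param params a `wev_params` for the `wev` family (its `w` is ignored).
#' @param w_vis,w_conf weights for the two judgments.
#' @param design a [experiment_design()].
#' @param noise_mode `"shared"` or `"independent"`.
#' @param seed optional integer seed.
#' @param trials_per_soa override of the design trial count.
#' @return data frame with `soa_ms`, `stimulus`, `response`, `category_vis`,
#'   `category_conf`, `rating_vis`, `rating_conf`.
#' @export
generate_joint <- function(params, w_vis, w_conf, design = design_exp1(),
                           noise_mode = c("shared", "independent"),
                           seed = NULL, trials_per_soa = design$trials_per_soa) {
  noise_mode <- match.arg(noise_mode)
  spec <- params$spec
  if (spec$family != "wev") stop("joint generation is defined for the wev family")
  if (!is.null(seed)) set.seed(seed)
  ns <- length(design$soa_levels_ms)
  nper <- as.integer(trials_per_soa)
  nc <- design$n_categories
  soa_idx <- rep(seq_len(ns), each = nper)
  s_id <- as.integer(unlist(lapply(seq_len(ns), function(i) {
    base <- rep(c(-1L, 1L), floor(nper / 2))
    if (nper %% 2L) base <- c(base, sample(c(-1L, 1L), 1L))
    sample(base)
  })))
  n <- length(s_id)
  S <- params$S_s[soa_idx]
  Sbar <- mean(params$S_s)
  sig_id <- sigma_id_of(spec, params, s_id, S)
  d_id <- stats::rnorm(n, 0.5 * s_id * S, sig_id)
  r_id <- ifelse(d_id < params$theta_id, -1L, 1L)
  eps_vis <- stats::rnorm(n, 0, params$sigma_v)
  eps_conf <- if (noise_mode == "shared") eps_vis else stats::rnorm(n, 0, params$sigma_v)
  dv <- function(w, eps) (1 - w) * d_id + w * r_id * (S - Sbar) + eps
  categorize <- function(d_v) {
    category <- integer(n)
    up <- r_id > 0
    category[up] <- findInterval(d_v[up], params$theta_v_plus)
    category[!up] <- findInterval(-d_v[!up], -params$theta_v_minus)
    category
  }
  cat_vis <- categorize(dv(w_vis, eps_vis))
  cat_conf <- categorize(dv(w_conf, eps_conf))
  data.frame(soa_ms = design$soa_levels_ms[soa_idx], stimulus = s_id,
             response = r_id,
             category_vis = cat_vis, category_conf = cat_conf,
             rating_vis = .emit_continuous(cat_vis, nc),
             rating_conf = .emit_continuous(cat_conf, nc))
}
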