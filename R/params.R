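WEV_FAMILIES <- c("sdt", "noisy_sdt", "wev", "two_channel", "postdecisional",
                  "cnd", "rce", "bayes2d")
WEV_VARIANCE_MODES <- c("constant", "identity_dependent", "soa_dependent")

#' Specify a model family and variance mode
#'
#' @param family one of `"sdt"` (SDT rating model), `"noisy_sdt"`, `"wev"`
#'   (weighted evidence and visibility), `"two_channel"`, `"postdecisional"`
#'   (postdecisional accumulation), `"cnd"` (constant noise and decay), `"rce"`
#'   (response-congruent evidence), `"bayes2d"` (2D Bayesian observer with
#'   lapses).
#' @param variance_mode `"constant"` (sigma_id = 1), `"identity_dependent"`
#'   (sigma_id = r_id^s_id), or `"soa_dependent"`
#'   (sigma_id = sqrt(1 + k * S_s^2)). The 2D Bayesian model admits only
#'   `"constant"`: its noise is the free parameter `s_noise`.
#' @return an object of class `wev_spec`.
#' @examples
#' model_spec("wev")
#' @export
model_spec <- function(family = WEV_FAMILIES, variance_mode = WEV_VARIANCE_MODES) {
  family <- match.arg(family)
  variance_mode <- match.arg(variance_mode)
  if (family == "bayes2d" && variance_mode != "constant")
    stop("the 2D Bayesian model admits only variance_mode = 'constant'")
  structure(list(family = family, variance_mode = variance_mode),
            class = "wev_spec")
}

#' @export
print.wev_spec <- function(x, ...) {
  cat("Model:", x$family, "| variance:", x$variance_mode, "\n")
  invisible(x)
}

#' Construct a parameter set for a model family
#'
#' Only the fields relevant to `spec` are stored. Rating criteria come as two
#' sets of four, one per identification response. `theta_v_plus` is strictly
#' increasing on the report-variable axis. For the six SDT-axis families the
#' minus-response mapping is mirrored (more negative report variable means a
#' higher category), so `theta_v_minus` is strictly decreasing; for the RCE
#' model the rating tracks the winning channel's positively oriented evidence
#' and `theta_v_minus` is strictly increasing on that axis.
#'
#' @param spec a [model_spec()].
#' @param S_s nonnegative sensitivity per SOA (one per design SOA); not used by
#'   `bayes2d`.
#' @param theta_id identification criterion (bias, for `rce`).
#' @param theta_v_plus,theta_v_minus rating criteria (length
#'   `n_categories - 1`).
#' @param sigma_v report noise SD (`noisy_sdt`, `wev`, `cnd`).
#' @param w weight on identity-irrelevant strength evidence, in `[0, 1]`
#'   (`wev`).
#' @param a second-channel signal fraction (`two_channel`).
#' @param b postdecisional accumulation amount (`postdecisional`).
#' @param rho per-SOA signal reduction in `(0, 1]` (`cnd`).
#' @param s_noise perceptual noise SD on the SOA (ms) axis (`bayes2d`).
#' @param lambda lapse rate in `[0, 1]` (`bayes2d`).
#' @param theta_post 9 strictly increasing posterior criteria in `(0, 1)`
#'   (`bayes2d`), separating the 10 ordered (response x category) options.
#' @param r_id identity-dependent variance ratio (> 0), used when
#'   `variance_mode = "identity_dependent"`.
#' @param k slope of the variance increase with squared strength (>= 0), used
#'   when `variance_mode = "soa_dependent"`.
#' @return an object of class `wev_params`.
#' @export
parameter_set <- function(spec, S_s = NULL, theta_id = 0,
                          theta_v_plus = NULL, theta_v_minus = NULL,
                          sigma_v = NULL, w = NULL, a = NULL, b = NULL,
                          rho = NULL, s_noise = NULL, lambda = NULL,
                          theta_post = NULL, r_id = NULL, k = NULL) {
  stopifnot(inherits(spec, "wev_spec"))
  p <- list(spec = spec)
  if (spec$family != "bayes2d") {
    p$S_s <- as.numeric(S_s)
    p$theta_id <- as.numeric(theta_id)
    p$theta_v_plus <- as.numeric(theta_v_plus)
    p$theta_v_minus <- as.numeric(theta_v_minus)
  }
  if (spec$family %in% c("noisy_sdt", "wev", "cnd")) p$sigma_v <- as.numeric(sigma_v)
  if (spec$family == "wev") p$w <- as.numeric(w)
  if (spec$family == "two_channel") p$a <- as.numeric(a)
  if (spec$family == "postdecisional") p$b <- as.numeric(b)
  if (spec$family == "cnd") p$rho <- as.numeric(rho)
  if (spec$family == "bayes2d") {
    p$s_noise <- as.numeric(s_noise)
    p$lambda <- as.numeric(lambda)
    p$theta_post <- as.numeric(theta_post)
  }
  if (spec$variance_mode == "identity_dependent") p$r_id <- as.numeric(r_id)
  if (spec$variance_mode == "soa_dependent") p$k <- as.numeric(k)
  class(p) <- "wev_params"
  validate_params(p)
  p
}

#' Validate a parameter set against its family's constraints
#'
#' @param params a `wev_params` object.
#' @return `params`, invisibly; otherwise an error describing the violated
#'   constraint.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "wev_params"))
  spec <- params$spec
  chk <- function(cond, msg) if (!cond) stop("invalid parameters: ", msg, call. = FALSE)
  if (spec$family != "bayes2d") {
    chk(length(params$S_s) >= 1 && all(is.finite(params$S_s)) && all(params$S_s >= 0),
        "S_s must be nonnegative")
    chk(length(params$theta_id) == 1 && is.finite(params$theta_id), "theta_id must be finite")
    chk(all(is.finite(params$theta_v_plus)) && !is.unsorted(params$theta_v_plus, strictly = TRUE),
        "theta_v_plus must be strictly increasing")
    chk(all(is.finite(params$theta_v_minus)), "theta_v_minus must be finite")
    if (spec$family == "rce") {
      chk(!is.unsorted(params$theta_v_minus, strictly = TRUE),
          "theta_v_minus must be strictly increasing (winning-channel axis)")
    } else {
      chk(!is.unsorted(rev(params$theta_v_minus), strictly = TRUE),
          "theta_v_minus must be strictly decreasing (mirror convention)")
    }
    chk(length(params$theta_v_minus) == length(params$theta_v_plus),
        "criteria sets must have equal length")
  }
  if (!is.null(params$sigma_v)) chk(params$sigma_v > 0, "sigma_v must be positive")
  if (!is.null(params$w)) chk(params$w >= 0 && params$w <= 1, "w must lie in [0, 1]")
  if (!is.null(params$a)) chk(params$a >= 0, "a must be nonnegative")
  if (!is.null(params$b)) chk(params$b > 0, "b must be positive")
  if (!is.null(params$rho)) chk(all(params$rho > 0) && all(params$rho <= 1),
                                "rho must lie in (0, 1]")
  if (spec$family == "bayes2d") {
    chk(params$s_noise > 0, "s_noise must be positive")
    chk(params$lambda >= 0 && params$lambda <= 1, "lambda must lie in [0, 1]")
    chk(all(params$theta_post > 0) && all(params$theta_post < 1) &&
          !is.unsorted(params$theta_post, strictly = TRUE),
        "theta_post must be strictly increasing within (0, 1)")
  }
  if (spec$variance_mode == "identity_dependent")
    chk(is.finite(params$r_id) && params$r_id > 0, "r_id must be positive")
  if (spec$variance_mode == "soa_dependent")
    chk(is.finite(params$k) && params$k >= 0, "k must be nonnegative")
  invisible(params)
}

#' @export
print.wev_params <- function(x, ...) {
  cat("Parameters (", x$spec$family, ", ", x$spec$variance_mode, "):\n", sep = "")
  flat <- flatten_params(x)
  print(round(flat, 3))
  invisible(x)
}

#' Flatten a parameter set to a named numeric vector
#'
#' @param params a `wev_params` object.
#' @return named numeric vector of all active parameters.
#' @export
flatten_params <- function(params) {
  p <- unclass(params)
  p$spec <- NULL
  out <- numeric(0)
  for (nm in names(p)) {
    v <- p[[nm]]
    names(v) <- if (length(v) > 1) paste0(nm, seq_along(v)) else nm
    out <- c(out, v)
  }
  out
}

#' Number of free parameters of a model
#'
#' For the 5-SOA, 5-category configuration with constant variance this equals
#' 14 (SDT rating), 15 (noisy SDT), 16 (WEV), 15 (two-channel), 15
#' (postdecisional), 20 (constant noise and decay), 14 (response-congruent
#' evidence), 11 (2D Bayesian). The identity-dependent and SOA-dependent
#' variance modes each add one parameter (r_id or k), except for the 2D
#' Bayesian model.
#'
#' @param spec a [model_spec()].
#' @param design a [experiment_design()] (default: the 5-SOA, 5-category
#'   masked-orientation design).
#' @return integer count of free parameters.
#' @export
count_free_parameters <- function(spec, design = design_exp1()) {
  stopifnot(inherits(spec, "wev_spec"))
  ns <- length(design$soa_levels_ms)
  ncrit <- design$n_categories - 1L
  base <- if (spec$family == "bayes2d") {
    # s_noise + lambda + (2 * n_categories - 1) posterior criteria
    2L + (2L * design$n_categories - 1L)
  } else {
    ns + 1L + 2L * ncrit +
      switch(spec$family,
             sdt = 0L, noisy_sdt = 1L, wev = 2L, two_channel = 1L,
             postdecisional = 1L, cnd = ns + 1L, rce = 0L)
  }
  base + if (spec$variance_mode == "constant") 0L else 1L
}

#' Standard deviation of the identification decision variable
#'
#' Returns sigma_id under the spec's variance mode: 1 for `"constant"`,
#' `r_id^s_id` for `"identity_dependent"`, and `sqrt(1 + k * S_s^2)` for
#' `"soa_dependent"`.
#'
#' @param spec a [model_spec()].
#' @param params a `wev_params` object.
#' @param s_id stimulus identity, -1 or +1 (vectorized).
#' @param S_s stimulus strength (vectorized).
#' @return positive numeric vector.
#' @export
sigma_id_of <- function(spec, params, s_id, S_s) {
  n <- max(length(s_id), length(S_s))
  s_id <- rep_len(s_id, n)
  S_s <- rep_len(S_s, n)
  switch(spec$variance_mode,
         constant = rep(1, n),
         identity_dependent = params$r_id^s_id,
         soa_dependent = sqrt(1 + params$k * S_s^2))
}
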