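# Shared fixtures: one representative parameter set per family on the
# standard 5-SOA design, built in code.

fixture_design <- function() design_exp1()

fixture_params <- function(fam, mode = "constant") {
  spec <- model_spec(fam, mode)
  if (fam == "bayes2d") {
    return(parameter_set(spec, s_noise = 30, lambda = 0.03,
                         theta_post = c(.03, .08, .2, .35, .5, .65, .8, .92, .97)))
  }
  parameter_set(
    spec,
    S_s = c(0.2, 0.6, 1.4, 2.5, 3.8), theta_id = 0.1,
    theta_v_plus = c(-0.5, 0.3, 1.1, 1.9),
    theta_v_minus = if (fam == "rce") c(0.2, 0.8, 1.5, 2.2)
                    else -c(-0.5, 0.3, 1.1, 1.9),
    sigma_v = if (fam %in% c("noisy_sdt", "wev", "cnd")) 1 else NULL,
    w = if (fam == "wev") 0.4 else NULL,
    a = if (fam == "two_channel") 0.8 else NULL,
    b = if (fam == "postdecisional") 0.7 else NULL,
    rho = if (fam == "cnd") c(.9, .8, .7, .6, .5) else NULL,
    r_id = if (mode == "identity_dependent") 1.2 else NULL,
    k = if (mode == "soa_dependent") 0.1 else NULL)
}

all_families <- function() c("sdt", "noisy_sdt", "wev", "two_channel",
                             "postdecisional", "cnd", "rce", "bayes2d")

# independent slow oracle for gamma: explicit enumeration of all pairs
gamma_enumerate <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1
    if (s < 0) D <- D + 1
  }
  if (C + D == 0) return(NaN)
  (C - D) / (C + D)
}

# independent oracle for the JZS Bayes factor: the classic g-integral form
# (normal prior on delta given g, inverse-gamma(1/2, scale^2/2) mixing), on a
# fine log-spaced grid
jzs_bf_g_oracle <- function(diffs, scale = 1, n_nodes = 1e5) {
  n <- length(diffs)
  tt <- mean(diffs) / (stats::sd(diffs) / sqrt(n))
  nu <- n - 1
  lg <- seq(-12, 12, length.out = n_nodes)
  g <- exp(lg)
  dens_g <- (scale^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-scale^2 / (2 * g))
  lik1 <- (1 + n * g)^(-0.5) * (1 + tt^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2)
  num <- sum(lik1 * dens_g * g) * (lg[2] - lg[1])   # d g = g d(log g)
  den <- (1 + tt^2 / nu)^(-(nu + 1) / 2)
  num / den
}
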