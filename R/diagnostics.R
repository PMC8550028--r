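# Observed-vs-predicted descriptive machinery: Goodman-Kruskal gamma between
# stimulus strength and rating split by identification accuracy, and the
# dissociation contingencies between two graded judgments at the 20% scale
# threshold.

# gamma from a (possibly fractional) two-way contingency table: concordant
# minus discordant over their sum, ties excluded.
gamma_from_table <- function(tab) {
  tab <- as.matrix(tab)
  nr <- nrow(tab)
  nc <- ncol(tab)
  if (nr < 1L || nc < 1L || sum(tab) <= 0) return(NaN)
  C <- 0
  D <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    w <- tab[i, j]
    if (w == 0) next
    if (i < nr && j < nc) C <- C + w * sum(tab[(i + 1):nr, (j + 1):nc])
    if (i < nr && j > 1L) D <- D + w * sum(tab[(i + 1):nr, 1:(j - 1)])
  }
  if (C + D == 0) return(NaN)
  (C - D) / (C + D)
}

#' Goodman-Kruskal gamma
#'
#' Ordinal association `(C - D) / (C + D)` over all unordered pairs, `C`
#' concordant and `D` discordant, ties excluded. Returns `NaN` when no
#' untied pair exists.
#'
#' @param x,y ordinal vectors of equal length >= 2.
#' @return scalar in `[-1, 1]`, or `NaN` if undefined.
#' @examples
#' goodman_kruskal_gamma(1:3, c(3, 2, 1))  # -1
#' @export
goodman_kruskal_gamma <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  gamma_from_table(table(x, y))
}

#' Gamma between stimulus strength and rating, split by accuracy
#'
#' Computes the Goodman-Kruskal gamma between SOA rank and rating category
#' separately within correct (`response == stimulus`) and incorrect trials.
#'
#' @param trials data frame with `soa_ms`, `stimulus`, `response`, and
#'   `category` (or `rating`, discretized with `n_categories` bins).
#' @param n_categories bins used if only `rating` is present.
#' @return a `wev_gamma` list: `gamma_correct`, `gamma_incorrect` (either may
#'   be `NaN` when undefined), `n_correct`, `n_incorrect`.
#' @export
gamma_by_accuracy <- function(trials, n_categories = 5L) {
  cat <- if ("category" %in% names(trials)) trials$category
         else discretize_rating(trials$rating, n_categories)
  soa_rank <- match(trials$soa_ms, sort(unique(trials$soa_ms)))
  correct <- trials$response == trials$stimulus
  g <- function(keep) {
    if (sum(keep) < 2L) return(NaN)
    gamma_from_table(table(soa_rank[keep], cat[keep]))
  }
  structure(list(gamma_correct = g(correct), gamma_incorrect = g(!correct),
                 n_correct = sum(correct), n_incorrect = sum(!correct)),
            class = "wev_gamma")
}

#' @export
print.wev_gamma <- function(x, ...) {
  cat(sprintf("Gamma(SOA, rating): correct %.3f (n=%.4g), incorrect %.3f (n=%.4g)\n",
              x$gamma_correct, x$n_correct, x$gamma_incorrect, x$n_incorrect))
  invisible(x)
}

#' Model-implied gamma between stimulus strength and rating
#'
#' Same statistic as [gamma_by_accuracy()] but computed exactly from the
#' model's expected cell frequencies (pair counts weighted by products of
#' expected frequencies; no simulation, no rounding), split by accuracy.
#' Stimulus identities are taken as equiprobable.
#'
#' @param spec a [model_spec()].
#' @param params a matching `wev_params`.
#' @param design a [experiment_design()].
#' @return a `wev_gamma` list (expected trial masses in place of counts).
#' @export
predicted_gamma <- function(spec, params, design) {
  p <- predict_response_probabilities(spec, params, design)
  ns <- length(design$soa_levels_ms)
  nc <- design$n_categories
  corr_tab <- matrix(0, ns, nc)
  inc_tab <- matrix(0, ns, nc)
  for (t in seq_len(ns)) {
    corr_tab[t, ] <- 0.5 * (p[1, t, 1, ] + p[2, t, 2, ])
    inc_tab[t, ] <- 0.5 * (p[1, t, 2, ] + p[2, t, 1, ])
  }
  structure(list(gamma_correct = gamma_from_table(corr_tab),
                 gamma_incorrect = gamma_from_table(inc_tab),
                 n_correct = sum(corr_tab), n_incorrect = sum(inc_tab)),
            class = "wev_gamma")
}

#' Dissociation contingencies between two graded judgments
#'
#' For joint visibility+confidence trials, computes the probability of a
#' rating above 20% of the scale on one judgment conditional on the other
#' judgment being below 20%: `P(vis > 0.2 | conf < 0.2)` and
#' `P(conf > 0.2 | vis < 0.2)`. Ratings exactly at the threshold count as
#' "not below". Computed per participant, then averaged; participants with an
#' empty conditioning set are excluded from that mean (their number is
#' reported).
#'
#' @param trials data frame with columns `participant`, `rating_vis`,
#'   `rating_conf` in `[0, 1]`.
#' @param threshold scale fraction (default 0.2).
#' @return list with `p_vis_given_lowconf`, `p_conf_given_lowvis`,
#'   `n_excluded_vis`, `n_excluded_conf`, and the per-participant values.
#' @export
contingency_20 <- function(trials, threshold = 0.2) {
  need <- c("participant", "rating_vis", "rating_conf")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials is missing columns: ", paste(miss, collapse = ", "))
  per <- lapply(split(trials, trials$participant), function(d) {
    lowconf <- d$rating_conf < threshold
    lowvis <- d$rating_vis < threshold
    c(vis = if (any(lowconf)) mean(d$rating_vis[lowconf] > threshold) else NA_real_,
      conf = if (any(lowvis)) mean(d$rating_conf[lowvis] > threshold) else NA_real_)
  })
  m <- do.call(rbind, per)
  list(p_vis_given_lowconf = mean(m[, "vis"], na.rm = TRUE),
       p_conf_given_lowvis = mean(m[, "conf"], na.rm = TRUE),
       n_excluded_vis = sum(is.na(m[, "vis"])),
       n_excluded_conf = sum(is.na(m[, "conf"])),
       per_participant = m)
}

#' Per-participant diagnostics table
#'
#' Tidy data frame of observed (and, when fits are supplied, model-implied)
#' gamma correlations per participant, ready for export.
#'
#' @param trials canonical trial table with a `participant` column.
#' @param fits optional named list of `wev_fit` objects (names matching
#'   participants).
#' @param design design used for model-implied gammas.
#' @return data frame with one row per participant.
#' @export
diagnostics_table <- function(trials, fits = NULL, design = NULL) {
  out <- lapply(split(trials, trials$participant), function(d) {
    g <- gamma_by_accuracy(d)
    row <- data.frame(participant = d$participant[1],
                      gamma_correct = g$gamma_correct,
                      gamma_incorrect = g$gamma_incorrect)
    pid <- as.character(d$participant[1])
    if (!is.null(fits) && pid %in% names(fits)) {
      pg <- predicted_gamma(fits[[pid]]$spec, fits[[pid]]$params, design)
      row$pred_gamma_correct <- pg$gamma_correct
      row$pred_gamma_incorrect <- pg$gamma_incorrect
    }
    row
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
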