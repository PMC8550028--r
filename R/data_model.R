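#' wevis: generative models of graded visibility and confidence
#'
#' Tools to simulate, fit, and compare static models of graded visibility and
#' confidence judgments in binary identification tasks. The observer sees a
#' stimulus of identity `s_id` (-1 or +1) at one of several strengths
#' (stimulus-onset asynchronies, SOA, in ms), gives a binary identification
#' response `r_id` and a graded rating on a continuous scale, analyzed in
#' ordered categories. Eight model families describe the joint distribution of
#' response and rating; see [model_spec()].
#'
#' @keywords internal
#' @aliases wevis-package
"_PACKAGE"

# Column dictionary for the canonical trial CSV:
#   participant  token identifying the observer
#   soa_ms       stimulus-onset asynchrony in milliseconds (stimulus strength)
#   stimulus     stimulus identity, -1 or +1
#   response     identification response, -1 or +1
#   rating       graded report as a fraction of scale width, in [0, 1]
#   judgment     "visibility" or "confidence"
#   trial        trial index within participant (optional)

#' Define an experiment design
#'
#' The design records the SOA levels (the experimental manipulation of stimulus
#' strength), the number of trials per SOA, and the number of ordered rating
#' categories the continuous scale is discretized into.
#'
#' @param soa_levels_ms strictly increasing vector of positive SOAs in ms.
#' @param trials_per_soa trials presented at each SOA (identities are split as
#'   evenly as possible between -1 and +1 when simulating).
#' @param n_categories number of ordered rating categories (default 5).
#' @return an object of class `wev_design`.
#' @examples
#' design_exp1()
#' @export
experiment_design <- function(soa_levels_ms, trials_per_soa, n_categories = 5L) {
  soa_levels_ms <- as.numeric(soa_levels_ms)
  if (length(soa_levels_ms) < 1L || any(!is.finite(soa_levels_ms)) || any(soa_levels_ms <= 0))
    stop("soa_levels_ms must be positive finite values")
  if (is.unsorted(soa_levels_ms, strictly = TRUE))
    stop("soa_levels_ms must be strictly increasing")
  trials_per_soa <- as.integer(trials_per_soa)
  if (trials_per_soa < 1L) stop("trials_per_soa must be a positive integer")
  n_categories <- as.integer(n_categories)
  if (n_categories < 2L) stop("n_categories must be at least 2")
  structure(
    list(soa_levels_ms = soa_levels_ms,
         trials_per_soa = trials_per_soa,
         n_categories = n_categories),
    class = "wev_design")
}

#' @rdname experiment_design
#' @details `design_exp1()` is the masked-orientation design with SOAs
#'   \{8.3, 16.7, 33.3, 66.7, 133.3\} ms and 11 blocks of 50 trials (10 per SOA
#'   per block, so 110 trials per SOA); `design_exp2()` has 9 blocks of 45
#'   trials (9 per SOA per block, 81 trials per SOA).
#' @export
design_exp1 <- function() {
  experiment_design(c(8.3, 16.7, 33.3, 66.7, 133.3), trials_per_soa = 110L)
}

#' @rdname experiment_design
#' @export
design_exp2 <- function() {
  experiment_design(c(8.3, 16.7, 33.3, 66.7, 133.3), trials_per_soa = 81L)
}

#' @export
print.wev_design <- function(x, ...) {
  cat("Experiment design:", length(x$soa_levels_ms), "SOAs (",
      paste(x$soa_levels_ms, collapse = ", "), "ms ),",
      x$trials_per_soa, "trials/SOA,", x$n_categories, "rating categories\n")
  invisible(x)
}

#' Discretize a continuous rating into ordered categories
#'
#' The continuous scale `[0, 1]` is divided into `n_categories` partitions of
#' equal length; bins are half-open `[l, u)` except the last, which is closed
#' at 1, so the top boundary falls into the last category.
#'
#' @param rating numeric vector in `[0, 1]`.
#' @param n_categories number of partitions (>= 2), default 5.
#' @return integer categories in `0:(n_categories - 1)`.
#' @examples
#' discretize_rating(c(0, 0.5, 1), 5)  # 0 2 4
#' @export
discretize_rating <- function(rating, n_categories = 5L) {
  n_categories <- as.integer(n_categories)
  if (n_categories < 2L) stop("n_categories must be at least 2")
  if (any(!is.finite(rating)) || any(rating < 0) || any(rating > 1))
    stop("rating must lie in [0, 1]")
  pmin(as.integer(floor(rating * n_categories)), n_categories - 1L)
}

match_soa_index <- function(soa_ms, design, tol = 1e-6) {
  idx <- rep(NA_integer_, length(soa_ms))
  for (j in seq_along(design$soa_levels_ms))
    idx[abs(soa_ms - design$soa_levels_ms[j]) <= tol] <- j
  if (anyNA(idx))
    stop("trial SOA not in design: ", paste(unique(soa_ms[is.na(idx)]), collapse = ", "))
  idx
}

#' Tabulate trials into a response-frequency table
#'
#' Counts trials in each (stimulus identity, SOA, identification response,
#' rating category) cell; the frequency table is the sufficient statistic for
#' all model likelihoods.
#'
#' @param trials data frame with columns `soa_ms`, `stimulus`, `response`, and
#'   either `category` or `rating` (the latter is discretized with
#'   [discretize_rating()]).
#' @param design a [experiment_design()].
#' @return a `wev_counts` object: an integer array with dimensions
#'   `(s_id, soa, r_id, category)`; `s_id`/`r_id` indices 1 and 2 correspond to
#'   -1 and +1.
#' @export
tabulate_trials <- function(trials, design) {
  stopifnot(inherits(design, "wev_design"))
  nc <- design$n_categories
  ns <- length(design$soa_levels_ms)
  cnt <- array(0L, dim = c(2L, ns, 2L, nc),
               dimnames = list(s_id = c("-1", "1"), soa = design$soa_levels_ms,
                               r_id = c("-1", "1"), category = 0:(nc - 1L)))
  if (nrow(trials) == 0L)
    return(structure(cnt, class = c("wev_counts", "array"), design = design))
  need <- c("soa_ms", "stimulus", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials is missing columns: ", paste(miss, collapse = ", "))
  if (!any(c("category", "rating") %in% names(trials)))
    stop("trials needs a 'category' or 'rating' column")
  if (!all(trials$stimulus %in% c(-1, 1))) stop("stimulus must be -1 or +1")
  if (!all(trials$response %in% c(-1, 1))) stop("response must be -1 or +1")
  cat <- if ("category" %in% names(trials)) as.integer(trials$category)
         else discretize_rating(trials$rating, nc)
  if (any(cat < 0L) || any(cat >= nc)) stop("category out of range")
  t_idx <- match_soa_index(trials$soa_ms, design)
  i_s <- (trials$stimulus > 0) + 1L
  i_r <- (trials$response > 0) + 1L
  lin <- i_s + 2L * ((t_idx - 1L) + ns * ((i_r - 1L) + 2L * cat))
  cnt[] <- tabulate(lin, nbins = 2L * ns * 2L * nc)
  structure(cnt, class = c("wev_counts", "array"), design = design)
}

#' @export
print.wev_counts <- function(x, ...) {
  cat("Response-frequency table:", sum(x), "trials;",
      dim(x)[2], "SOAs x", dim(x)[4], "categories\n")
  acc <- apply(x, 2, function(m) (m[1, 1, ] %*% rep(1, dim(x)[4]) +
                                  m[2, 2, ] %*% rep(1, dim(x)[4])) / max(sum(m), 1))
  cat("Accuracy by SOA:", paste(sprintf("%.2f", acc), collapse = " "), "\n")
  invisible(x)
}

#' Read and write canonical trial tables
#'
#' The canonical CSV has columns `participant, soa_ms, stimulus, response,
#' rating, judgment` (and optionally `trial`, `category`, `rating_vis`,
#' `rating_conf` for joint visibility+confidence tables).
#'
#' @param path file path.
#' @param trials data frame of trials.
#' @return `read_trials` returns a data frame; `write_trials` returns `path`
#'   invisibly.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "soa_ms", "stimulus", "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  bad <- which(!(df$stimulus %in% c(-1, 1)) | !(df$response %in% c(-1, 1)) |
               !is.finite(df$soa_ms) | df$soa_ms <= 0)
  if ("rating" %in% names(df))
    bad <- union(bad, which(!is.finite(df$rating) | df$rating < 0 | df$rating > 1))
  if (length(bad))
    stop(sprintf("%s: malformed values in data row(s) %s",
                 path, paste(utils::head(sort(bad), 5L), collapse = ", ")))
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
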