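#' Per-patient paired differences of tumor-specific counts
#'
#' The change in the number of tumor-specific variants from primary tumor to
#' relapse, one value per patient; the cohort mean is the single trend
#' parameter tested by [mc_difference_test()].
#'
#' @param counts Per-patient count table with columns \code{patient,
#'   ts_primary, ts_relapse} ([count_table()] output or a published
#'   fixture).
#' @return data.frame \code{patient, p_count, r_count, difference} with the
#'   cohort mean in attribute \code{"mean"}.
#' @export
paired_differences <- function(counts) {
  miss <- setdiff(c("patient", "ts_primary", "ts_relapse"), names(counts))
  if (length(miss))
    stop("counts table missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(patient = counts$patient,
                    p_count = counts$ts_primary,
                    r_count = counts$ts_relapse,
                    difference = counts$ts_relapse - counts$ts_primary)
  attr(out, "mean") <- mean(out$difference)
  out
}

#' Least-squares slope of counts over disease stages
#'
#' Fits, per patient, an ordinary least-squares line through the variant
#' counts at normal tissue, primary tumor and relapse, coded at times
#' 0, 1, 2. For three equally spaced points the slope reduces to
#' \code{(r - n) / 2}; the general covariance formula is used so the
#' implementation does not depend on that reduction.
#'
#' @param n,p,r Numeric vectors (recycled to common length) of counts in
#'   normal, primary and relapse samples.
#' @return Numeric vector of slopes.
#' @export
fit_trend <- function(n, p, r) {
  y <- rbind(n, p, r)
  t <- c(0, 1, 2)
  tc <- t - mean(t)
  as.numeric(colSums(tc * (y - rep(colMeans(y), each = 3L))) / sum(tc^2))
}

mc_p_value <- function(null, observed, sidedness) {
  k <- switch(sidedness,
              two_sided = sum(abs(null) >= abs(observed)),
              greater = sum(null >= observed),
              less = sum(null <= observed))
  (1 + k) / (1 + length(null))
}

new_mc_result <- function(statistic, observed_mean, null, iterations, seed,
                          sidedness, range_mode, ranges) {
  structure(list(statistic = statistic, observed_mean = observed_mean,
                 null_draws = null,
                 p_value = mc_p_value(null, observed_mean, sidedness),
                 iterations = iterations, seed = seed, sidedness = sidedness,
                 range_mode = range_mode, ranges = ranges),
            class = "mc_trend_test")
}

#' @export
print.mc_trend_test <- function(x, ...) {
  cat("Monte Carlo trend test (", x$statistic, ")\n", sep = "")
  cat("  observed mean:", format(x$observed_mean), "\n")
  cat("  p-value:", format(x$p_value), "(", x$sidedness, ",",
      x$iterations, "iterations )\n")
  invisible(x)
}

runif_mat <- function(iterations, n, rng) {
  matrix(stats::runif(iterations * n, rng[1], rng[2]), iterations, n)
}

#' Monte Carlo test for the mean paired difference
#'
#' Tests the null hypothesis that the mean relapse-minus-primary difference
#' of tumor-specific variant counts is 0 when there is no gain or loss of
#' variants between stages. Each iteration draws surrogate per-sample counts
#' as continuous uniform values on the range of the observed counts
#' (pooled over primary and relapse by default), rebuilds each patient's
#' difference and takes the cohort mean. The p-value uses the add-one
#' estimator \code{(1 + k) / (1 + iterations)}, never exactly zero.
#'
#' @param p_counts,r_counts Tumor-specific counts per patient in primary and
#'   relapse.
#' @param iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Optional integer seed (recorded in the result).
#' @param sidedness \code{"two_sided"} (default, on the absolute mean),
#'   \code{"greater"} or \code{"less"}.
#' @param range_mode \code{"pooled"} (one uniform range for all roles,
#'   default) or \code{"per_role"} (each role drawn on its own observed
#'   range).
#' @return \code{mc_trend_test} object: observed mean, null draws, p-value
#'   and the configuration that produced them.
#' @export
mc_difference_test <- function(p_counts, r_counts, iterations = 10000L,
                               seed = NULL,
                               sidedness = c("two_sided", "greater", "less"),
                               range_mode = c("pooled", "per_role")) {
  sidedness <- match.arg(sidedness); range_mode <- match.arg(range_mode)
  if (length(p_counts) != length(r_counts))
    stop("p_counts and r_counts must have the same length")
  n <- length(p_counts)
  if (n < 2L) stop("at least 2 patients required")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rngs <- if (range_mode == "pooled") {
    r <- range(c(p_counts, r_counts)); list(p = r, r = r)
  } else list(p = range(p_counts), r = range(r_counts))
  null <- rowMeans(runif_mat(iterations, n, rngs$r) -
                   runif_mat(iterations, n, rngs$p))
  new_mc_result("difference", mean(r_counts - p_counts), null, iterations,
                seed, sidedness, range_mode, rngs)
}

#' Monte Carlo test for the mean regression slope
#'
#' Tests the null hypothesis that the mean per-patient slope of germline
#' variant counts over the normal, primary, relapse stages is 0 when counts
#' are randomly (uniformly) distributed over the observed range. Surrogate
#' counts for all three stages are drawn per iteration and each patient's
#' slope is refitted with [fit_trend()].
#'
#' When the normal-tissue counts are unavailable but per-patient slopes are
#' (e.g. a published coefficient column), pass them via \code{observed}
#' together with an explicit \code{range} for the surrogate counts.
#'
#' @param n_counts,p_counts,r_counts Germline counts per patient in normal,
#'   primary and relapse samples.
#' @param observed Optional per-patient slopes replacing
#'   \code{fit_trend(n_counts, p_counts, r_counts)}.
#' @param range Length-2 numeric range for surrogate counts; mandatory with
#'   \code{observed}, otherwise defaults to the pooled observed range.
#' @inheritParams mc_difference_test
#' @return \code{mc_trend_test} object.
#' @export
mc_slope_test <- function(n_counts = NULL, p_counts = NULL, r_counts = NULL,
                          observed = NULL, range = NULL,
                          iterations = 10000L, seed = NULL,
                          sidedness = c("two_sided", "greater", "less"),
                          range_mode = c("pooled", "per_role")) {
  sidedness <- match.arg(sidedness); range_mode <- match.arg(range_mode)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (is.null(observed)) {
    if (is.null(n_counts) || is.null(p_counts) || is.null(r_counts))
      stop("supply n_counts, p_counts and r_counts, or 'observed' slopes")
    if (length(unique(c(length(n_counts), length(p_counts),
                        length(r_counts)))) != 1L)
      stop("count vectors must have the same length")
    observed <- fit_trend(n_counts, p_counts, r_counts)
    pooled <- range(c(n_counts, p_counts, r_counts))
  } else {
    if (is.null(range))
      stop("'range' is required when 'observed' slopes are supplied")
    pooled <- NULL
  }
  n <- length(observed)
  if (n < 2L) stop("at least 2 patients required")
  if (!is.null(range)) {
    pooled <- sort(as.numeric(range))
    range_mode <- "pooled"
  }
  if (!is.null(seed)) set.seed(seed)
  rngs <- if (range_mode == "pooled") list(n = pooled, p = pooled, r = pooled)
          else list(n = range(n_counts), p = range(p_counts),
                    r = range(r_counts))
  Nm <- runif_mat(iterations, n, rngs$n)
  Pm <- runif_mat(iterations, n, rngs$p)
  Rm <- runif_mat(iterations, n, rngs$r)
  slopes <- matrix(fit_trend(as.vector(Nm), as.vector(Pm), as.vector(Rm)),
                   iterations, n)
  null <- rowMeans(slopes)
  new_mc_result("slope", mean(observed), null, iterations, seed, sidedness,
                range_mode, rngs)
}
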