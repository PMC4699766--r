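# Descriptive statistics, dose response, tail metrics and the Q-Q
# comparison between observed counts and simulated specific energies.

#' Descriptive statistics of a count (or energy) population
#'
#' Sample statistics with the (n - 1) variance denominator. The mode is the
#' most frequent attained value, ties broken toward the smallest; `sd_rel`
#' is sd / mean, defined as 0 for a constant vector and `NA` when the mean
#' is 0 with nonzero spread.
#'
#' @param x Numeric vector, length >= 2.
#' @return Tibble with one row: `n`, `mean`, `median`, `mode`, `var`, `sd`,
#'   `sd_rel`.
#' @export
#' @examples
#' describe_counts(c(2, 2, 5))
describe_counts <- function(x) {
  if (length(x) < 2L) stop_invalid("need at least 2 values")
  if (anyNA(x)) stop_invalid("missing values not allowed")
  tab <- table(x)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  m <- mean(x)
  v <- stats::var(x)
  s <- sqrt(v)
  sd_rel <- if (s == 0) 0 else if (m == 0) NA_real_ else s / m
  tibble::tibble(n = length(x), mean = m, median = stats::median(x),
                 mode = min(modes), var = v, sd = s, sd_rel = sd_rel)
}

#' Fold changes of spread along a dose-doubling ladder
#'
#' For populations ordered by dose, returns the ratio of `sd_rel` (and of
#' `sd`) at each dose to the value at the preceding dose. Under the
#' energy-spread relation every dose doubling multiplies `sd` by sqrt(2) and
#' `sd_rel` by 1/sqrt(2). A warning is issued (ratios still computed) if the
#' doses do not form a doubling ladder.
#'
#' @param stats Data frame with columns `dose_Gy`, `sd`, `sd_rel`, one row
#'   per dose, any order.
#' @return Tibble with `dose_from`, `dose_to`, `sd_rel_ratio`, `sd_ratio`.
#' @export
fold_change_series <- function(stats) {
  need <- c("dose_Gy", "sd", "sd_rel")
  if (!all(need %in% names(stats))) {
    stop_invalid("stats need columns %s", paste(need, collapse = ", "))
  }
  stats <- stats[order(stats$dose_Gy), , drop = FALSE]
  if (nrow(stats) < 2L) stop_invalid("need at least 2 dose levels")
  d <- stats$dose_Gy
  if (any(abs(d[-1] / d[-length(d)] - 2) > 1e-8)) {
    warning("doses do not form a doubling ladder; fold changes computed anyway",
            call. = FALSE)
  }
  i <- seq_len(nrow(stats) - 1L)
  tibble::tibble(dose_from = d[i], dose_to = d[i + 1L],
                 sd_rel_ratio = stats$sd_rel[i + 1L] / stats$sd_rel[i],
                 sd_ratio = stats$sd[i + 1L] / stats$sd[i])
}

#' Linear dose-response fit on replicate means
#'
#' Ordinary least squares of the mean focus count on dose, fitted on the
#' per-dose means of the replicate means (the between-replicate SDs are
#' reported for error bars but do not weight the fit). The slope estimates
#' the focus yield per gray. A replicate-level fit (all replicate means as
#' points) is reported alongside, since the two can differ slightly.
#'
#' @param replicate_means Data frame with columns `dose_Gy`, `mean_rif`,
#'   one row per replicate (or per dose if already aggregated).
#' @return Object of class `dose_response_fit`: slope (RIF/Gy), intercept
#'   (RIF), r_squared, per-dose table with between-replicate SDs, and the
#'   replicate-level slope.
#' @export
#' @examples
#' fit_dose_response(data.frame(dose_Gy = c(0, 0.5, 1, 2),
#'                              mean_rif = c(0.6, 9.1, 17.6, 30.7)))
fit_dose_response <- function(replicate_means) {
  need <- c("dose_Gy", "mean_rif")
  if (!all(need %in% names(replicate_means))) {
    stop_invalid("replicate_means need columns %s", paste(need, collapse = ", "))
  }
  doses <- sort(unique(replicate_means$dose_Gy))
  if (length(doses) < 3L) stop_invalid("dose-response fit needs at least 3 doses")
  per_dose <- tibble::tibble(
    dose_Gy = doses,
    mean_rif = vapply(doses, function(d) {
      mean(replicate_means$mean_rif[replicate_means$dose_Gy == d])
    }, numeric(1)),
    sd_replicate_means = vapply(doses, function(d) {
      v <- replicate_means$mean_rif[replicate_means$dose_Gy == d]
      if (length(v) > 1L) stats::sd(v) else NA_real_
    }, numeric(1)))
  fit <- stats::lm(mean_rif ~ dose_Gy, data = per_dose)
  fit_rep <- stats::lm(mean_rif ~ dose_Gy, data = replicate_means)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    per_dose = per_dose,
    slope_replicate_level = unname(stats::coef(fit_rep)[2])),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit: slope %.3f RIF/Gy, intercept %.3f RIF, R^2 = %.4f (replicate-level slope %.3f)>\n",
              x$slope, x$intercept, x$r_squared, x$slope_replicate_level))
  invisible(x)
}

#' Quantile-quantile comparison of counts against specific energies
#'
#' Pairs the empirical quantiles of the observed focus counts (y) with those
#' of the simulated specific energies (x). Equal sample sizes are paired as
#' sorted order statistics; otherwise the larger sample is reduced by
#' interpolating its empirical quantiles at probabilities (i - 0.5) / n of
#' the smaller one. An unweighted OLS line is fitted through the pairs; when
#' counts are (approximately) proportional to energy its slope estimates the
#' focus yield per gray. `trim_lower` drops that fraction of the lowest
#' pairs before fitting, to discount the low-count curvature produced by
#' nuclei that have not yet signalled all damage.
#'
#' @param observed Numeric vector of counts.
#' @param energy Numeric vector of specific energies (Gy).
#' @param trim_lower Fraction of lowest-quantile pairs excluded from the
#'   fitted line (default 0).
#' @return Object of class `qq_result`: tibble `pairs` (x, y ascending),
#'   `slope`, `intercept`, `r_squared`, `trim_lower`.
#' @export
qq_compare <- function(observed, energy, trim_lower = 0) {
  if (length(observed) == 0L || length(energy) == 0L) {
    stop_invalid("both samples must be nonempty")
  }
  if (trim_lower < 0 || trim_lower >= 1) stop_invalid("trim_lower must lie in [0, 1)")
  n <- min(length(observed), length(energy))
  if (length(observed) == length(energy)) {
    x <- sort(energy)
    y <- sort(observed)
  } else {
    p <- (seq_len(n) - 0.5) / n
    x <- unname(stats::quantile(energy, p, type = 7))
    y <- unname(stats::quantile(observed, p, type = 7))
  }
  keep <- seq_len(length(x)) > floor(trim_lower * length(x))
  fit <- stats::lm(y[keep] ~ x[keep])
  structure(list(
    pairs = tibble::tibble(x = x, y = y),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    trim_lower = trim_lower),
    class = "qq_result")
}

#' @export
print.qq_result <- function(x, ...) {
  cat(sprintf("<qq_result: %d quantile pairs, slope %.3f, intercept %.3f, R^2 = %.4f>\n",
              nrow(x$pairs), x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Lower-tail metrics of a count population
#'
#' `fraction_below` is the fraction of counts strictly below
#' `reference_mean` (e.g. the fraction of a 2 Gy population below the 1 Gy
#' mean). `percentile_deficit` gives, for each probability in `probs`,
#' `100 * (mean - quantile(p)) / mean`: how far, in percent, the p-th
#' percentile falls short of the population's own mean.
#'
#' @param counts Nonempty numeric vector.
#' @param reference_mean Reference count level.
#' @param probs Percentile probabilities for the deficit (default 0.15).
#' @return List with `fraction_below` and named vector `percentile_deficit`
#'   (percent).
#' @export
#' @examples
#' tail_metrics(rnorm(1e4, 30.6, 5.6), reference_mean = 17.6)
tail_metrics <- function(counts, reference_mean, probs = 0.15) {
  if (length(counts) == 0L) stop_invalid("counts must be nonempty")
  m <- mean(counts)
  q <- stats::quantile(counts, probs, names = FALSE)
  list(fraction_below = mean(counts < reference_mean),
       percentile_deficit = stats::setNames(100 * (m - q) / m,
                                            paste0("p", 100 * probs)))
}
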