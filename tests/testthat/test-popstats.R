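# Descriptive statistics, fold changes, dose response, Q-Q, tail metrics.

test_that("describe_counts matches hand arithmetic", {
  st <- describe_counts(c(2, 2, 5))
  expect_equal(st$mean, 3)
  expect_equal(st$median, 2)
  expect_equal(st$mode, 2)
  expect_equal(st$var, 3)
  expect_equal(st$sd, sqrt(3))
  expect_equal(st$sd_rel, sqrt(3) / 3)
  # constant vector: no spread, sd_rel defined as 0
  cst <- describe_counts(rep(4, 10))
  expect_equal(cst$var, 0)
  expect_equal(cst$sd_rel, 0)
  # zero mean with spread: sd_rel undefined
  expect_true(is.na(describe_counts(c(-1, 1))$sd_rel))
  expect_error(describe_counts(3), "at least 2")
})

test_that("describe_counts agrees with a definitional brute-force computation", {
  set.seed(8)
  for (i in 1:25) {
    x <- sample(0:8, sample(3:40, 1), replace = TRUE)
    st <- describe_counts(x)
    expect_equal(st$mean, sum(x) / length(x))
    expect_equal(st$var, sum((x - mean(x))^2) / (length(x) - 1))
    # brute-force mode with smallest-value tie break
    counts <- vapply(sort(unique(x)), function(v) sum(x == v), integer(1))
    expect_equal(st$mode, sort(unique(x))[which.max(counts)])
  }
})

test_that("fold changes per dose doubling follow the 1/sqrt(2) law", {
  m <- default_model()
  doses <- c(0.5, 1, 2)
  st <- tibble::tibble(dose_Gy = doses,
                       sd_rel = sd_rel(m, 1.6, doses),
                       sd = doses * sd_rel(m, 1.6, doses))
  fc <- fold_change_series(st)
  expect_equal(fc$sd_rel_ratio, rep(1 / sqrt(2), 2))
  expect_equal(fc$sd_ratio, rep(sqrt(2), 2))
  # observed count spreads: 0.363 -> 0.253 gives 0.697
  obs <- rif_reference_counts("Co-60")
  fo <- fold_change_series(obs[, c("dose_Gy", "sd", "sd_rel")])
  expect_equal(round(fo$sd_rel_ratio[1], 3), 0.697)
  expect_warning(
    fold_change_series(tibble::tibble(dose_Gy = c(1, 2.5), sd = c(1, 1),
                                      sd_rel = c(1, 1))),
    "doubling")
})

test_that("dose-response fit recovers slopes from exact and reference data", {
  exact <- data.frame(dose_Gy = c(0, 0.5, 1, 2),
                      mean_rif = 15 * c(0, 0.5, 1, 2) + 0.6)
  f <- fit_dose_response(exact)
  expect_equal(f$slope, 15)
  expect_equal(f$intercept, 0.6)
  expect_equal(f$r_squared, 1)
  # replicate-mean reference values give very nearly 15 RIF per gray
  f2 <- fit_dose_response(co60_replicate_means())
  expect_equal(f2$slope, 14.995, tolerance = 1e-3)
  expect_gt(f2$r_squared, 0.99)
  expect_error(fit_dose_response(data.frame(dose_Gy = c(0, 1),
                                            mean_rif = c(0, 15))),
               "at least 3")
})

test_that("dose-response slope recovers the generator's focus yield", {
  study <- small_study(seed = 2)
  rep_means <- aggregate(rif_count ~ replicate_id + dose_nominal_Gy,
                         data = study, FUN = mean)
  names(rep_means) <- c("replicate_id", "dose_Gy", "mean_rif")
  f <- fit_dose_response(rep_means)
  expect_equal(f$slope, 15.5, tolerance = 0.10)
})

test_that("Q-Q comparison identifies proportionality between counts and energy", {
  z <- sample_specific_energy(energy_spec_for(default_model(), 1.6, 1),
                              6000, seed = 10)
  z <- as.numeric(z)
  # a sample against itself lies on the identity line
  self <- qq_compare(z, z)
  expect_equal(self$slope, 1)
  expect_equal(self$intercept, 0)
  expect_equal(self$r_squared, 1)
  # counts built as round(alpha * z) against the same energies: slope alpha
  alpha <- 15.5
  q <- qq_compare(round(alpha * z), z)
  expect_equal(q$slope, alpha, tolerance = 0.05)
  # unequal sizes pair interpolated quantiles, ascending in both coordinates
  q2 <- qq_compare(round(alpha * z), z[1:3000])
  expect_equal(nrow(q2$pairs), 3000)
  expect_false(is.unsorted(q2$pairs$x))
  expect_false(is.unsorted(q2$pairs$y))
  # trimming drops the lowest quantile pairs from the fitted line
  q3 <- qq_compare(round(alpha * z), z, trim_lower = 0.05)
  expect_equal(q3$slope, alpha, tolerance = 0.05)
  expect_error(qq_compare(numeric(0), z), "nonempty")
})

test_that("tail metrics quantify the low-damage fraction", {
  set.seed(12)
  x <- rnorm(9010, 30.6, 5.6)
  tm <- tail_metrics(x, reference_mean = 17.6, probs = 0.15)
  # Phi((17.6 - 30.6) / 5.6) = Phi(-2.32) ~ 0.010
  expect_equal(tm$fraction_below, 0.010, tolerance = 0.5)
  # 100 * (mean - p15) / mean ~ 1.0364 * 5.6 / 30.6 ~ 19%
  expect_equal(unname(tm$percentile_deficit), 18.97, tolerance = 0.05)
  expect_equal(tail_metrics(c(5, 6, 7), reference_mean = 1)$fraction_below, 0)
})
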