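# Synthetic per-nucleus generator: background, counts, features, study.

test_that("sham background reproduces the overdispersed moments", {
  expect_identical(simulate_background(50, mean = 0), integer(50))
  bg <- simulate_background(25114, mean = 0.6, var = 2.1, seed = 1)
  expect_equal(mean(bg), 0.6, tolerance = 3 * sqrt(2.1 / 25114) / 0.6)
  expect_equal(var(bg), 2.1, tolerance = 0.08)
  # the moment-matched dispersion parameter is mean^2 / (var - mean)
  expect_equal(0.6^2 / (2.1 - 0.6), 0.24)
  # var <= mean falls back to Poisson
  po <- simulate_background(20000, mean = 2, var = 1.5, seed = 2)
  expect_equal(var(po) / mean(po), 1, tolerance = 0.05)
})

test_that("dose zero yields exactly the background population", {
  cfg <- population_config(500, 0)
  expect_identical(simulate_rif_counts(cfg, default_model(), seed = 9),
                   simulate_background(500, 0.6, 2.1, seed = 9))
})

test_that("a vanishing energy spread collapses counts to the deterministic yield", {
  # k1 -> 0 makes sd_z -> 0; with no background every count is round(alpha * D)
  # (alpha chosen off the .5 rounding boundary, where a vanishing jitter
  # around alpha * D would still split between neighbouring integers)
  tiny <- specific_energy_model(1e-12, 0.8)
  cfg <- population_config(200, 1, foci_per_gray = 15, background_mean = 0,
                           rif_mode = "energy_only")
  cnt <- simulate_rif_counts(cfg, tiny, seed = 1)
  expect_true(all(cnt == 15L))
})

test_that("count generation is seeded and mode-sensitive", {
  cfg <- population_config(5000, 1)
  a <- simulate_rif_counts(cfg, default_model(), seed = 4)
  b <- simulate_rif_counts(cfg, default_model(), seed = 4)
  expect_identical(as.integer(a), as.integer(b))
  # the Poisson-given-z mode adds counting noise on top of the energy spread
  cfg_p <- population_config(5000, 1, rif_mode = "poisson_given_z")
  p <- simulate_rif_counts(cfg_p, default_model(), seed = 4)
  expect_equal(mean(p), mean(a), tolerance = 0.05)
  expect_gt(var(p), var(a))
})

test_that("irradiated counts are quasi-Poisson with the energy-driven spread", {
  m <- default_model()
  for (d in c(0.5, 1, 2)) {
    n <- c("0.5" = 8242L, "1" = 8993L, "2" = 9010L)[[as.character(d)]]
    cnt <- simulate_rif_counts(population_config(n, d), m, seed = 1)
    st <- describe_counts(cnt)
    expect_equal(st$mean, 15.5 * d + 0.6, tolerance = 0.03)
    # energy-only hypothesis: count spread tracks the energy spread plus the
    # fixed background variance
    expected_var <- (15.5 * d * sd_rel(m, 1.6, d))^2 + 1 / 12 + 2.1
    expect_equal(st$var, expected_var, tolerance = 0.05)
  }
})

test_that("count spread converges to the energy spread as background vanishes", {
  m <- default_model()
  cfg <- population_config(60000, 1, background_mean = 0)
  cnt <- simulate_rif_counts(cfg, m, seed = 5)
  st <- describe_counts(cnt)
  expect_equal(st$sd_rel, sd_rel(m, 1.6, 1), tolerance = 0.02)
})

test_that("feature generation separates cycling from resting nuclei", {
  set.seed(1)
  ph <- data.frame(phase_true = rep(c("G0G1", "S", "G2M"), c(700, 200, 100)),
                   is_cluster = rep(c(FALSE, TRUE), c(950, 50)),
                   rif_count = rpois(1000, 5))
  rec <- simulate_features(ph, seed = 1)
  cycling <- rec$phase_true != "G0G1"
  expect_gt(mean(rec$a488_int[cycling]), mean(rec$a488_int[!cycling]))
  expect_gt(mean(rec$ki67_int[cycling]), mean(rec$ki67_int[!cycling]))
  expect_gt(median(rec$dapi_int[rec$phase_true == "G2M"]),
            1.8 * median(rec$dapi_int[rec$phase_true == "G0G1"]))
  expect_gt(mean(rec$area_um2[rec$is_cluster]), 2 * mean(rec$area_um2[!rec$is_cluster]))
  expect_true(all(rec$circularity > 0 & rec$circularity <= 1))
})

test_that("KI67 and gamma-H2AX intensities are rank-correlated under defaults", {
  study <- small_study(seed = 3)
  expect_gt(cor(study$ki67_int, study$a488_int, method = "spearman"), 0.5)
})

test_that("a non-cycling population has unimodal DAPI and low gamma-H2AX", {
  study <- simulate_study(default_model(),
                          n_per_dose = c(2000L, 500L, 500L, 500L),
                          config = population_config(1, 0, cycling_fraction = 0),
                          seed = 6)
  # all DNA content at 2N: the spread of log intensity is pure noise
  expect_lt(sd(log(study$dapi_int)), 0.12)
  expect_lt(quantile(study$a488_int, 0.99), 5e5)
})

test_that("the study table has the pooled design and is bit-identical under a fixed seed", {
  s1 <- small_study(seed = 1)
  s2 <- small_study(seed = 1)
  expect_identical(s1, s2)
  expect_equal(as.integer(table(s1$dose_nominal_Gy)[c("0", "0.5", "1", "2")]),
               c(4000L, 2000L, 2000L, 2000L))
  expect_equal(nrow(s1), 10000L)
  expect_named(s1, c("nucleus_id", "replicate_id", "dose_nominal_Gy",
                     "dose_actual_Gy", "phase_true", "is_cluster", "area_um2",
                     "circularity", "dapi_int", "a488_int", "ki67_int",
                     "rif_count"))
})

test_that("replicate dose jitter behaves as a 6 percent relative error", {
  m <- default_model()
  # jitter off: delivered equals nominal
  s0 <- simulate_study(m, n_per_dose = c(300L, 300L, 300L, 300L),
                       config = population_config(1, 0, dose_jitter_rel_sd = 0),
                       seed = 2)
  expect_identical(s0$dose_actual_Gy, s0$dose_nominal_Gy)
  # with many replicates the spread of replicate doses estimates 6%
  s6 <- simulate_study(m, doses = 1, n_per_dose = 8000L, n_replicates = 40L,
                       seed = 2)
  rep_dose <- tapply(s6$dose_actual_Gy, s6$replicate_id, unique)
  expect_equal(sd(rep_dose), 0.06, tolerance = 0.4)
  # and the replicate-mean counts spread on the order of 0.9 RIF at 1 Gy
  rep_mean <- tapply(s6$rif_count, s6$replicate_id, mean)
  expect_gt(sd(rep_mean), 0.4)
  expect_lt(sd(rep_mean), 1.8)
})
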