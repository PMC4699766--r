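# Single-track spectra, convolution engine and compound track model.

test_that("spectrum construction enforces its invariants", {
  expect_error(single_track_spectrum(numeric(0), numeric(0)), "at least one atom")
  expect_error(single_track_spectrum(c(0.3, 0.1), c(0.5, 0.5)), "ascending")
  expect_error(single_track_spectrum(c(-0.1, 0.1), c(0.5, 0.5)), "non-negative")
  expect_error(single_track_spectrum(c(0.1, 0.3), c(0.5, 0.6)), "sum to 1")
  sp <- single_track_spectrum(c(0.1, 0.3), c(1, 1), normalize = TRUE)
  expect_equal(sum(sp$pmf), 1)
})

test_that("single-track moments match hand-computed values", {
  expect_equal(single_track_moments(single_track_spectrum(0.1, 1)),
               c(mean_z1 = 0.1, sd_z1 = 0))
  expect_equal(single_track_moments(two_atom_spectrum()),
               c(mean_z1 = 0.2, sd_z1 = 0.1))
  # mass 0.9 at z = 0, 0.1 at z = 1: mean 0.1, sd sqrt(0.1 * 0.9) = 0.3
  expect_equal(single_track_moments(single_track_spectrum(c(0, 1), c(0.9, 0.1))),
               c(mean_z1 = 0.1, sd_z1 = 0.3))
})

test_that("nu-fold convolution is exact on enumerable cases", {
  sp <- two_atom_spectrum()
  expect_identical(convolve_tracks(sp, 1), sp)
  # zero tracks deposit zero energy
  f0 <- convolve_tracks(sp, 0)
  expect_equal(f0$z, 0)
  expect_equal(f0$pmf, 1)
  # point mass: nu tracks of z1 sum to nu * z1
  pm <- convolve_tracks(single_track_spectrum(0.1, 1), 5)
  expect_equal(pm$z, 0.5)
  expect_equal(pm$pmf, 1)
  # two-track enumeration: {0.2: 1/4, 0.4: 1/2, 0.6: 1/4}
  f2 <- convolve_tracks(sp, 2)
  expect_equal(f2$z, c(0.2, 0.4, 0.6))
  expect_equal(f2$pmf, c(0.25, 0.5, 0.25), tolerance = 1e-12)
})

test_that("convolution matches direct enumeration on random small spectra", {
  set.seed(42)
  for (i in 1:10) {
    sp <- random_spectrum(3)
    for (nu in 2:3) {
      f <- convolve_tracks(sp, nu)
      # enumerate all nu-track sums directly
      sums <- sp$z
      w <- sp$pmf
      for (k in seq_len(nu - 1)) {
        sums <- as.vector(outer(sums, sp$z, "+"))
        w <- as.vector(outer(w, sp$pmf, "*"))
      }
      agg <- tapply(w, round(sums, 9), sum)
      expect_equal(sum(f$z * f$pmf), sum(sums * w), tolerance = 1e-7)
      expect_equal(sum(f$z^2 * f$pmf), sum(sums^2 * w), tolerance = 1e-7)
      expect_equal(length(f$z), length(agg))
    }
  }
})

test_that("convolution refuses to overflow a configured support cap", {
  sp <- two_atom_spectrum()
  expect_error(convolve_tracks(sp, 10, z_max = 2), "exceeds z_max")
  expect_silent(convolve_tracks(sp, 6, z_max = 2))
})

test_that("compound distribution has the compound-Poisson moments", {
  sp <- two_atom_spectrum()
  # no tracks -> all mass at zero
  f0 <- compound_distribution(sp, track_number_model(0))
  expect_equal(f0$z, 0)
  # point-mass single-track spectrum -> scaled Poisson
  z1 <- 0.2
  fp <- compound_distribution(single_track_spectrum(z1, 1),
                              track_number_model(3), 1e-9)
  nu <- round(fp$z / z1)
  expect_equal(fp$z, nu * z1, tolerance = 1e-12)
  expect_equal(fp$pmf, dpois(nu, 3) / sum(dpois(nu, 3)), tolerance = 1e-8)
  # worked example: n = 2 on the two-atom spectrum
  f <- compound_distribution(sp, track_number_model(2), 1e-9)
  m <- single_track_moments(f)
  expect_equal(m[["mean_z1"]], 0.4, tolerance = 1e-7)
  expect_equal(m[["sd_z1"]]^2, 0.10, tolerance = 1e-7)
})

test_that("compound moments agree with the independent oracle and the normal approximation", {
  set.seed(7)
  for (i in 1:8) {
    sp <- random_spectrum()
    n <- runif(1, 0.5, 5)
    f <- compound_distribution(sp, track_number_model(n), 1e-12)
    m <- single_track_moments(f)
    oracle <- oracle_compound_moments(sp, n)
    expect_equal(m[["mean_z1"]], oracle[["mean"]], tolerance = 1e-6)
    expect_equal(m[["sd_z1"]]^2, oracle[["var"]], tolerance = 1e-6)
    # and both equal the closed form n*z1bar, n*(z1bar^2 + sd1^2)
    na <- normal_approximation(sp, track_number_model(n))
    expect_equal(m[["mean_z1"]], na$mean_z, tolerance = 1e-6)
    expect_equal(m[["sd_z1"]], na$sd_z, tolerance = 1e-6)
  }
})

test_that("compound engine directs huge track numbers to the normal approximation", {
  sp <- two_atom_spectrum()
  expect_error(
    compound_distribution(sp, track_number_model(5000), dz = 1e-5,
                          max_grid_points = 1e5),
    "normal_approximation")
})

test_that("normal approximation has the closed-form moments", {
  # pure Poisson fluctuation: point mass z1 = 0.01, n = 100
  na <- normal_approximation(single_track_spectrum(0.01, 1),
                             track_number_model(100))
  expect_equal(na$mean_z, 1.0)
  expect_equal(na$sd_z, 0.1)
  # doubling n scales the sd by sqrt(2)
  sp <- two_atom_spectrum()
  sd1 <- normal_approximation(sp, track_number_model(3))$sd_z
  sd2 <- normal_approximation(sp, track_number_model(6))$sd_z
  expect_equal(sd2 / sd1, sqrt(2))
  # worked example
  na2 <- normal_approximation(sp, track_number_model(2))
  expect_equal(na2$mean_z, 0.4)
  expect_equal(na2$sd_z, sqrt(0.10))
})

test_that("compound distribution converges to the normal law as tracks accumulate", {
  sp <- two_atom_spectrum()
  ks <- vapply(c(5, 20, 50, 100), function(n) {
    f <- compound_distribution(sp, track_number_model(n), 1e-9)
    m <- single_track_moments(f)
    zz <- (f$z - m[["mean_z1"]]) / m[["sd_z1"]]
    # continuity-corrected discrete CDF against the standard normal
    max(abs(cumsum(f$pmf) - f$pmf / 2 - pnorm(zz)))
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_lt(ks[4], 0.01)
})

test_that("spectra round-trip through the TSV format", {
  sp <- two_atom_spectrum()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$z, sp$z)
  expect_equal(back$pmf, sp$pmf, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), bad)
  expect_error(read_spectrum(bad), "z_Gy")
})
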