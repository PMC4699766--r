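# Shared fixtures: all built in code, nothing read from disk.

# Two-atom spectrum used throughout the worked examples.
two_atom_spectrum <- function() {
  single_track_spectrum(c(0.1, 0.3), c(0.5, 0.5))
}

# Random small spectrum (<= 5 atoms) for property loops.
random_spectrum <- function(n_atoms = sample(2:5, 1)) {
  z <- sort(round(runif(n_atoms, 0.05, 1), 3))
  z <- unique(z)
  p <- runif(length(z))
  single_track_spectrum(z, p / sum(p))
}

# The default calibrated model is used by many tests; calibrate once.
default_model <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- co60_default_model()
    cached
  }
})

# Reduced-size study for tests that only need structure, not precision.
small_study <- function(seed = 1, ...) {
  simulate_study(default_model(),
                 n_per_dose = c(4000L, 2000L, 2000L, 2000L),
                 seed = seed, ...)
}

# Independent brute-force moments of the compound track model: Poisson
# mixture over nu of the nu-track sum, using only elementary identities on
# an explicit nu grid (no grids, no convolution engine).
oracle_compound_moments <- function(spectrum, n, nu_max = 200) {
  z <- spectrum$z
  p <- spectrum$pmf
  m1 <- sum(z * p)
  v1 <- sum((z - m1)^2 * p)
  nu <- 0:nu_max
  w <- dpois(nu, n)
  mean_nu <- nu * m1
  var_nu <- nu * v1
  mu <- sum(w * mean_nu)
  second <- sum(w * (var_nu + mean_nu^2))
  c(mean = mu, var = second - mu^2)
}
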