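# Single-track specific-energy spectra and the compound track model.
#
# The specific energy z (Gy) deposited in a micrometre-scale target by photon
# irradiation is the sum of contributions from a Poisson-distributed number of
# particle tracks, each track depositing energy according to the single-track
# frequency distribution f1(z). The compound distribution
#   f(z, D) = sum_nu p(nu) * f_nu(z),   p(nu) = Poisson(n),
# with f_nu the nu-fold self-convolution of f1, converges rapidly to a normal
# law N(n * mean_z1, sqrt(n * (mean_z1^2 + sd_z1^2))) as the mean track number
# n grows. Both routes are implemented: an exact discrete convolution engine
# (the desk-scale oracle) and the closed-form normal approximation.

#' Construct a single-track specific-energy spectrum
#'
#' A discretized probability distribution f1(z) of the specific energy (in Gy)
#' deposited in a target by exactly one particle track.
#'
#' @param z Ascending, non-negative specific-energy grid values (Gy).
#' @param pmf Probability mass at each grid point; must sum to 1 (within 1e-9)
#'   unless `normalize = TRUE`.
#' @param normalize If `TRUE`, rescale `pmf` to sum to 1.
#' @return An object of class `single_track_spectrum` with fields `z` and `pmf`.
#' @export
#' @examples
#' sp <- single_track_spectrum(c(0.1, 0.3), c(0.5, 0.5))
#' single_track_moments(sp)
single_track_spectrum <- function(z, pmf, normalize = FALSE) {
  if (length(z) == 0L) stop_invalid("spectrum must contain at least one atom")
  if (length(z) != length(pmf)) stop_invalid("z and pmf lengths differ")
  if (anyNA(z) || anyNA(pmf)) stop_invalid("spectrum contains missing values")
  if (any(z < 0)) stop_invalid("specific energies must be non-negative")
  if (is.unsorted(z, strictly = TRUE)) stop_invalid("z grid must be strictly ascending")
  if (any(pmf < 0)) stop_invalid("probability masses must be non-negative")
  if (normalize) pmf <- pmf / sum(pmf)
  if (abs(sum(pmf) - 1) > 1e-9) {
    stop_invalid("pmf must sum to 1 within 1e-9 (got %.12f); use normalize = TRUE",
                 sum(pmf))
  }
  structure(list(z = as.numeric(z), pmf = as.numeric(pmf)),
            class = "single_track_spectrum")
}

#' @export
print.single_track_spectrum <- function(x, ...) {
  m <- single_track_moments(x)
  cat(sprintf("<single_track_spectrum: %d atoms, z in [%g, %g] Gy, mean_z1 = %.4g, sd_z1 = %.4g>\n",
              length(x$z), min(x$z), max(x$z), m[["mean_z1"]], m[["sd_z1"]]))
  invisible(x)
}

#' Mean and standard deviation of a single-track spectrum
#'
#' @param spectrum A [single_track_spectrum()].
#' @return Named numeric vector `c(mean_z1, sd_z1)` in Gy.
#' @export
single_track_moments <- function(spectrum) {
  stopifnot(inherits(spectrum, "single_track_spectrum"))
  m <- sum(spectrum$z * spectrum$pmf)
  v <- sum((spectrum$z - m)^2 * spectrum$pmf)
  c(mean_z1 = m, sd_z1 = sqrt(max(v, 0)))
}

# Put a spectrum on a uniform grid starting at 0 with spacing dz, splitting
# each atom's mass between its two bracketing grid points so that the mean is
# preserved exactly. The convolution engine requires a uniform grid.
resample_spectrum <- function(spectrum, dz = NULL) {
  z <- spectrum$z
  p <- spectrum$pmf
  if (is.null(dz)) {
    m <- single_track_moments(spectrum)[["mean_z1"]]
    dz <- if (m > 0) m / 50 else max(z[length(z)], 1) / 50
  }
  if (dz <= 0) stop_invalid("grid spacing must be positive")
  n_bins <- ceiling(max(z) / dz) + 1L
  grid <- seq(0, by = dz, length.out = n_bins + 1L)
  pmf <- numeric(n_bins + 1L)
  idx <- pmin(floor(z / dz), n_bins - 1L)
  frac <- z / dz - idx
  for (i in seq_along(z)) {
    pmf[idx[i] + 1L] <- pmf[idx[i] + 1L] + p[i] * (1 - frac[i])
    pmf[idx[i] + 2L] <- pmf[idx[i] + 2L] + p[i] * frac[i]
  }
  list(dz = dz, pmf = pmf)
}

# Approximate greatest common divisor of positive reals (Euclid with a
# symmetric remainder), used to find the coarsest exact grid for a spectrum.
float_gcd <- function(v, tol) {
  g <- v[1]
  for (b in v[-1]) {
    a <- g
    while (b > tol) {
      r <- abs(a - b * round(a / b))
      a <- b
      b <- r
    }
    g <- a
  }
  g
}

# Exact uniform-grid representation of a spectrum (index i holds mass at
# z = i * dz), when one exists with a tolerable number of points; otherwise
# NULL and the caller resamples.
exact_grid <- function(spectrum, max_points = 65536L) {
  z <- spectrum$z
  pos <- z[z > 0]
  if (length(pos) == 0L) return(list(dz = 1, pmf = 1))
  g <- float_gcd(pos, tol = 1e-9 * max(pos))
  if (g <= 0 || max(z) / g + 1 > max_points) return(NULL)
  pmf <- numeric(round(max(z) / g) + 1L)
  pmf[round(z / g) + 1L] <- spectrum$pmf
  list(dz = g, pmf = pmf)
}

# Grid for the convolution engine: exact when possible, resampled otherwise.
spectrum_grid <- function(spectrum, dz = NULL, max_points = 65536L) {
  if (!is.null(dz)) return(resample_spectrum(spectrum, dz))
  g <- exact_grid(spectrum, max_points)
  if (is.null(g)) g <- resample_spectrum(spectrum)
  g
}

# Trim trailing grid points whose mass is zero (below tol), keeping at least
# one point; renormalization is NOT performed (trimmed mass must be ~0).
trim_pmf <- function(pmf, tol = 0) {
  keep <- max(which(pmf > tol), 1L)
  pmf[seq_len(keep)]
}

#' nu-fold self-convolution of a single-track spectrum
#'
#' Computes f_nu(z), the distribution of the total specific energy deposited
#' by exactly `nu` tracks. `nu = 0` yields a point mass at z = 0. The spectrum
#' is resampled to a uniform grid (default spacing `mean_z1 / 50`) if needed.
#'
#' @param spectrum A [single_track_spectrum()].
#' @param nu Non-negative integer track count.
#' @param dz Uniform grid spacing (Gy); default resamples at `mean_z1 / 50`.
#' @param z_max Optional hard cap on the support (Gy). If the exact support
#'   `nu * max(z)` exceeds it, an error is raised rather than truncating.
#' @return A [single_track_spectrum()] for the nu-track sum.
#' @export
#' @examples
#' sp <- single_track_spectrum(c(0.1, 0.3), c(0.5, 0.5))
#' convolve_tracks(sp, 2)
convolve_tracks <- function(spectrum, nu, dz = NULL, z_max = NULL) {
  stopifnot(inherits(spectrum, "single_track_spectrum"))
  if (length(nu) != 1L || nu < 0 || nu != round(nu)) {
    stop_invalid("nu must be a single non-negative integer")
  }
  nu <- as.integer(nu)
  if (nu == 0L) return(single_track_spectrum(0, 1))
  support_max <- nu * max(spectrum$z)
  if (!is.null(z_max) && support_max > z_max) {
    stop_invalid("support of %d-track convolution (%.4g Gy) exceeds z_max = %.4g Gy",
                 nu, support_max, z_max)
  }
  if (nu == 1L) return(spectrum)
  g <- spectrum_grid(spectrum, dz)
  out <- g$pmf
  for (i in seq_len(nu - 1L)) {
    out <- convolve_pmf(out, g$pmf)
  }
  out <- trim_pmf(out)
  grid <- seq(0, by = g$dz, length.out = length(out))
  keep <- out > 1e-12 * max(out)   # drop FFT ripple far below any real mass
  keep[1] <- keep[1] || !any(keep)
  single_track_spectrum(grid[keep], out[keep] / sum(out[keep]))
}

# Linear convolution of two pmfs on the same uniform grid (index = z / dz).
# stats::convolve uses FFT; clamp the tiny negative ripples it can produce.
convolve_pmf <- function(a, b) {
  out <- stats::convolve(a, rev(b), type = "open")
  out[out < 0] <- 0
  out
}

#' Poisson track-number model
#'
#' The number of tracks nu traversing the target is Poisson with mean `n`.
#' Above `approximation_threshold` the Poisson law is well approximated by
#' N(n, sqrt(n)), which is the regime the closed-form normal approximation
#' of the compound distribution relies on.
#'
#' @param n Mean number of tracks (>= 0).
#' @param approximation_threshold Track count above which the normal
#'   approximation to the Poisson is considered accurate (default 20).
#' @return An object of class `track_number_model`.
#' @export
track_number_model <- function(n, approximation_threshold = 20) {
  if (length(n) != 1L || !is.finite(n) || n < 0) {
    stop_invalid("mean track number n must be a single non-negative number")
  }
  structure(list(n = as.numeric(n),
                 approximation_threshold = approximation_threshold),
            class = "track_number_model")
}

# Truncated Poisson pmf over nu = 0, 1, ..., stopping once cumulative mass
# reaches 1 - mass_tolerance.
track_number_pmf <- function(tracks, mass_tolerance = 1e-9) {
  n <- tracks$n
  nu_max <- max(stats::qpois(1 - mass_tolerance, n), 0L)
  nu <- 0:nu_max
  list(nu = nu, p = stats::dpois(nu, n))
}

#' Compound specific-energy distribution
#'
#' Mixes the nu-fold convolutions of the single-track spectrum over the
#' Poisson track-number law: f(z, D) = sum_nu p(nu) f_nu(z). The nu sum is
#' truncated once the cumulative Poisson mass reaches `1 - mass_tolerance`,
#' and the result is renormalized. Moments satisfy mean = n * mean_z1 and
#' variance = n * (mean_z1^2 + sd_z1^2) up to truncation and grid error.
#'
#' @param spectrum A [single_track_spectrum()].
#' @param tracks A [track_number_model()].
#' @param mass_tolerance Poisson truncation tolerance, in (0, 1e-3].
#' @param dz Uniform grid spacing (see [convolve_tracks()]).
#' @param max_grid_points Guard on grid size; exceeding it raises an error
#'   suggesting [normal_approximation()] for large track numbers.
#' @return A [single_track_spectrum()] holding the compound distribution.
#' @export
#' @examples
#' sp <- single_track_spectrum(c(0.1, 0.3), c(0.5, 0.5))
#' f <- compound_distribution(sp, track_number_model(2))
#' single_track_moments(f)
compound_distribution <- function(spectrum, tracks, mass_tolerance = 1e-9,
                                  dz = NULL, max_grid_points = 2^20) {
  stopifnot(inherits(spectrum, "single_track_spectrum"),
            inherits(tracks, "track_number_model"))
  if (mass_tolerance <= 0 || mass_tolerance > 1e-3) {
    stop_invalid("mass_tolerance must lie in (0, 1e-3]")
  }
  if (tracks$n == 0) return(single_track_spectrum(0, 1))
  if (length(spectrum$z) == 1L && spectrum$z[1] == 0) {
    return(single_track_spectrum(0, 1))
  }
  pn <- track_number_pmf(tracks, mass_tolerance)
  nu_max <- max(pn$nu)
  g <- spectrum_grid(spectrum, dz)
  needed <- nu_max * (length(g$pmf) - 1L) + 1L
  if (needed > max_grid_points) {
    stop_invalid(paste0(
      "compound distribution needs %d grid points (nu up to %d); ",
      "the mean track number is too large for the exact engine - ",
      "use normal_approximation() instead"), needed, nu_max)
  }
  acc <- numeric(needed)
  acc[1] <- pn$p[1]             # nu = 0: point mass at z = 0
  f_nu <- 1                     # delta at index 1
  for (k in seq_len(nu_max)) {
    f_nu <- convolve_pmf(f_nu, g$pmf)
    acc[seq_along(f_nu)] <- acc[seq_along(f_nu)] + pn$p[k + 1L] * f_nu
  }
  acc <- trim_pmf(acc)
  grid <- seq(0, by = g$dz, length.out = length(acc))
  keep <- acc > 1e-15 | seq_along(acc) == 1L
  single_track_spectrum(grid[keep], acc[keep] / sum(acc[keep]))
}

#' Normal approximation to the compound specific-energy distribution
#'
#' Closed-form limit of [compound_distribution()]: for mean track number n,
#' the specific energy is approximately
#' N(n * mean_z1, sqrt(n * (mean_z1^2 + sd_z1^2))).
#'
#' @param spectrum A [single_track_spectrum()].
#' @param tracks A [track_number_model()] with `n > 0`.
#' @return An [energy_distribution_spec()] with `mean_z`, `sd_z`, `sd_rel`.
#' @export
normal_approximation <- function(spectrum, tracks) {
  stopifnot(inherits(spectrum, "single_track_spectrum"),
            inherits(tracks, "track_number_model"))
  if (tracks$n <= 0) stop_invalid("normal approximation requires n > 0")
  m <- single_track_moments(spectrum)
  mean_z <- tracks$n * m[["mean_z1"]]
  sd_z <- sqrt(tracks$n * (m[["mean_z1"]]^2 + m[["sd_z1"]]^2))
  energy_distribution_spec(mean_z = mean_z, sd_z = sd_z, D = mean_z)
}

#' Read / write single-track spectra as two-column TSV
#'
#' The on-disk format is a header line `z_Gy<TAB>probability` followed by one
#' row per grid point.
#'
#' @param path File path.
#' @return [read_spectrum()] returns a [single_track_spectrum()];
#'   [write_spectrum()] returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  tb <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "numeric")
  if (!all(c("z_Gy", "probability") %in% names(tb))) {
    stop_invalid("spectrum file must have columns 'z_Gy' and 'probability'")
  }
  single_track_spectrum(tb$z_Gy, tb$probability, normalize = TRUE)
}

#' @rdname read_spectrum
#' @param spectrum A [single_track_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "single_track_spectrum"))
  utils::write.table(
    data.frame(z_Gy = spectrum$z, probability = spectrum$pmf),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
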