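# Target-volume geometry.
#
# Two idealized targets are compared with the matching volume recovered from
# the count spread: the flattened adherent endothelial nucleus, modelled as an
# elliptic cylinder, and the genomic DNA (6 Gbp, hydration shell included),
# modelled as a long thin cylinder. Axis conventions matter: "major axis" and
# "minor axis" are full axis lengths, not semi-axes.

.length_scales_um <- c(nm = 1e-3, um = 1, mm = 1e3, m = 1e6)

#' Convert a length between unit scales
#'
#' @param x Numeric length(s).
#' @param from,to Unit tags: one of `"nm"`, `"um"`, `"mm"`, `"m"`.
#' @return Length(s) expressed in `to` units.
#' @export
#' @examples
#' convert_length(2.3, "nm", "um")
convert_length <- function(x, from, to) {
  if (!from %in% names(.length_scales_um)) stop_invalid("unknown unit tag '%s'", from)
  if (!to %in% names(.length_scales_um)) stop_invalid("unknown unit tag '%s'", to)
  x * .length_scales_um[[from]] / .length_scales_um[[to]]
}

#' Elliptic-cylinder nucleus geometry
#'
#' @param major_axis Full major axis, um (> 0).
#' @param minor_axis Full minor axis, um (> 0, <= major_axis).
#' @param thickness Cylinder height, um (> 0).
#' @return Object of class `nucleus_geometry`.
#' @export
#' @examples
#' elliptic_cylinder_volume(nucleus_geometry(17, 11, 2))
nucleus_geometry <- function(major_axis, minor_axis, thickness) {
  dims <- c(major_axis, minor_axis, thickness)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop_invalid("all nucleus dimensions must be positive")
  }
  if (minor_axis > major_axis) {
    stop_invalid("minor axis (%g) exceeds major axis (%g)", minor_axis, major_axis)
  }
  structure(list(major_axis = major_axis, minor_axis = minor_axis,
                 thickness = thickness),
            class = "nucleus_geometry")
}

#' @rdname nucleus_geometry
#' @param g A `nucleus_geometry`.
#' @return Volume in um^3.
#' @export
elliptic_cylinder_volume <- function(g) {
  stopifnot(inherits(g, "nucleus_geometry"))
  pi * (g$major_axis / 2) * (g$minor_axis / 2) * g$thickness
}

#' Circular-cylinder geometry with explicit unit tags
#'
#' Used for the DNA-molecule target: e.g. diameter 2.3 nm, length 2.04 m
#' (the stretched contour length of 6 Gbp).
#'
#' @param diameter,length Positive scalars.
#' @param diameter_unit,length_unit Unit tags (`"nm"`, `"um"`, `"mm"`, `"m"`).
#' @return Object of class `cylinder_geometry`.
#' @export
#' @examples
#' cylinder_volume(cylinder_geometry(2.3, 2.04, "nm", "m"))
cylinder_geometry <- function(diameter, length, diameter_unit = "um",
                              length_unit = "um") {
  if (!is.finite(diameter) || diameter <= 0) stop_invalid("diameter must be positive")
  if (!is.finite(length) || length <= 0) stop_invalid("length must be positive")
  # resolve unit tags immediately; arithmetic on mixed units is never done
  structure(list(diameter_um = convert_length(diameter, diameter_unit, "um"),
                 length_um = convert_length(length, length_unit, "um")),
            class = "cylinder_geometry")
}

#' @rdname cylinder_geometry
#' @param g A `cylinder_geometry`.
#' @return Volume in um^3.
#' @export
cylinder_volume <- function(g) {
  stopifnot(inherits(g, "cylinder_geometry"))
  pi * (g$diameter_um / 2)^2 * g$length_um
}

#' Volume fraction of a sub-volume
#'
#' @param v_sub,v_total Positive volumes (same units).
#' @return Dimensionless ratio `v_sub / v_total`.
#' @export
#' @examples
#' volume_fraction(8.5, 293.7)  # DNA occupies < 3% of the nucleus
volume_fraction <- function(v_sub, v_total) {
  if (any(v_sub <= 0) || any(v_total <= 0)) stop_invalid("volumes must be positive")
  v_sub / v_total
}
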