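# Flow-cytometry-like selection of isolated G0/G1 nuclei.
#
# Two scatter-plot regions are intersected, exactly as one would draw them on
# a cytometry workstation: a morphology region on (area, circularity) that
# removes nucleus clusters, and an intensity region on (DAPI, gamma-H2AX
# integrated intensity) that isolates the 2N, low-background subpopulation.
# Holding DNA content constant across the scored nuclei is what makes the
# per-nucleus focus counts comparable, so the gate provenance (all
# thresholds) is kept alongside the result.

#' Rectangular or polygonal gate region on two features
#'
#' @param axis_x,axis_y Feature column names.
#' @param xlim,ylim Numeric `c(min, max)` for a rectangle region.
#' @param vertices Optional two-column matrix of polygon vertices (in the
#'   same axis order); overrides `xlim`/`ylim`.
#' @param log_axes Length-2 logical; apply the region in log10 space on that
#'   axis (limits/vertices are then given in log10 units).
#' @return Object of class `gate_region`.
#' @export
gate_region <- function(axis_x, axis_y, xlim = NULL, ylim = NULL,
                        vertices = NULL, log_axes = c(FALSE, FALSE)) {
  if (is.null(vertices)) {
    if (is.null(xlim) || is.null(ylim)) {
      stop_invalid("a rectangle region needs both xlim and ylim")
    }
    if (xlim[1] >= xlim[2] || ylim[1] >= ylim[2]) {
      stop_invalid("region limits must satisfy min < max on both axes")
    }
  } else {
    vertices <- as.matrix(vertices)
    if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
      stop_invalid("polygon vertices must be an n x 2 matrix with n >= 3")
    }
  }
  structure(list(axis_x = axis_x, axis_y = axis_y, xlim = xlim, ylim = ylim,
                 vertices = vertices, log_axes = log_axes),
            class = "gate_region")
}

# Even-odd ray-casting point-in-polygon test; boundary points count as inside.
point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > y) != (vy[j] > y)
    xint <- vx[i] + (y - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
    flip <- cross & x < xint
    inside <- xor(inside, flip)
    j <- i
  }
  inside
}

#' Test which records fall inside a gate region
#'
#' @param region A [gate_region()].
#' @param records Data frame containing the region's feature columns.
#' @return Logical vector.
#' @export
in_region <- function(region, records) {
  stopifnot(inherits(region, "gate_region"))
  for (ax in c(region$axis_x, region$axis_y)) {
    if (!ax %in% names(records)) {
      stop_invalid("records lack the gated feature column '%s'", ax)
    }
  }
  x <- records[[region$axis_x]]
  y <- records[[region$axis_y]]
  if (region$log_axes[1]) x <- log10(x)
  if (region$log_axes[2]) y <- log10(y)
  if (is.null(region$vertices)) {
    x >= region$xlim[1] & x <= region$xlim[2] &
      y >= region$ylim[1] & y <= region$ylim[2]
  } else {
    point_in_polygon(x, y, region$vertices[, 1], region$vertices[, 2])
  }
}

#' Apply the two-region G0/G1 gate
#'
#' A nucleus is selected iff it lies inside both the morphology region and
#' the intensity region. The result partitions the input exactly into
#' selected records and records rejected by the morphology gate, the
#' intensity gate, or both; focus counts are never altered, only subset.
#'
#' @param records Per-nucleus data frame.
#' @param morpho_gate [gate_region()] on (area_um2, circularity).
#' @param intensity_gate [gate_region()] on (dapi_int, a488_int).
#' @return Object of class `gate_result`: list with `records` (the input
#'   plus logical `selected` and character `rejected_by`), `counts`
#'   (selected / morphology / intensity / both), and the two gates.
#' @export
apply_gate <- function(records, morpho_gate, intensity_gate) {
  in_m <- in_region(morpho_gate, records)
  in_i <- in_region(intensity_gate, records)
  selected <- in_m & in_i
  rejected_by <- rep("none", nrow(records))
  rejected_by[!in_m & in_i] <- "morphology"
  rejected_by[in_m & !in_i] <- "intensity"
  rejected_by[!in_m & !in_i] <- "both"
  records$selected <- selected
  records$rejected_by <- rejected_by
  structure(list(
    records = records,
    counts = c(selected = sum(selected),
               rejected_morphology = sum(!in_m & in_i),
               rejected_intensity = sum(in_m & !in_i),
               rejected_both = sum(!in_m & !in_i)),
    morpho_gate = morpho_gate,
    intensity_gate = intensity_gate),
    class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<gate_result: %d / %d selected (%.1f%%); rejected morphology %d, intensity %d, both %d>\n",
              x$counts[["selected"]], n, 100 * x$counts[["selected"]] / n,
              x$counts[["rejected_morphology"]], x$counts[["rejected_intensity"]],
              x$counts[["rejected_both"]]))
  invisible(x)
}

# Robust fence half-widths: k * MAD of log10 values. Falls back to a plain
# percentile fence when the MAD degenerates (constant feature).
robust_fence <- function(v, k) {
  med <- stats::median(v)
  mad <- stats::mad(v)
  if (mad <= 0) {
    return(stats::quantile(v, c(0.005, 0.995), names = FALSE))
  }
  c(med - k * mad, med + k * mad)
}

#' Derive default gate regions from the data
#'
#' Data-driven stand-in for hand-drawn scatter-plot regions. The DAPI window
#' is centred on the dominant (2N) mode of the log10 intensity density with a
#' configurable half-width; the gamma-H2AX ceiling is a robust upper fence
#' (median + `a488_fence_k` * MAD in log10 space) of the subpopulation inside
#' the DAPI window; the morphology region uses robust fences on log10 area
#' and a lower fence on circularity. All thresholds are returned so gate
#' provenance can be recorded. Deterministic: two identical runs give
#' identical thresholds, and rescaling all DAPI intensities by a constant
#' shifts the window by the same factor.
#'
#' @param records Per-nucleus data frame (>= 200 rows).
#' @param dapi_halfwidth_log10 Half-width of the DAPI window in log10 units
#'   (default 0.12; the 4N peak sits +0.30 above the 2N mode).
#' @param a488_fence_k,area_fence_k,circ_fence_k Robust-fence multipliers.
#' @return List with `morpho_gate`, `intensity_gate` ([gate_region()]s) and
#'   `thresholds` (named numeric vector of every cut applied).
#' @export
auto_gate_thresholds <- function(records,
                                 dapi_halfwidth_log10 = 0.12,
                                 a488_fence_k = 3.5,
                                 area_fence_k = 5,
                                 circ_fence_k = 5) {
  if (nrow(records) < 200L) {
    stop_invalid("auto-gating needs at least 200 records (got %d)", nrow(records))
  }
  for (ax in c("area_um2", "circularity", "dapi_int", "a488_int")) {
    if (!ax %in% names(records)) {
      stop_invalid("records lack the gated feature column '%s'", ax)
    }
  }
  ldapi <- log10(records$dapi_int)
  dens <- stats::density(ldapi, n = 512)
  dapi_mode <- dens$x[which.max(dens$y)]
  dapi_win <- dapi_mode + c(-1, 1) * dapi_halfwidth_log10
  in_win <- ldapi >= dapi_win[1] & ldapi <= dapi_win[2]
  if (!any(in_win)) {
    warning("no records inside the DAPI window; falling back to percentile gates",
            call. = FALSE)
    dapi_win <- stats::quantile(ldapi, c(0.05, 0.6), names = FALSE)
    in_win <- ldapi >= dapi_win[1] & ldapi <= dapi_win[2]
  }
  la488 <- log10(records$a488_int[in_win])
  a488_ceiling <- stats::median(la488) + a488_fence_k * stats::mad(la488)
  larea <- log10(records$area_um2)
  area_win <- robust_fence(larea, area_fence_k)
  circ <- records$circularity
  circ_floor <- stats::median(circ) - circ_fence_k * stats::mad(circ)
  morpho <- gate_region("area_um2", "circularity",
                        xlim = area_win,
                        ylim = c(max(circ_floor, 0), 1),
                        log_axes = c(TRUE, FALSE))
  intensity <- gate_region("dapi_int", "a488_int",
                           xlim = dapi_win,
                           ylim = c(-Inf, a488_ceiling),
                           log_axes = c(TRUE, TRUE))
  list(morpho_gate = morpho, intensity_gate = intensity,
       thresholds = c(dapi_mode_log10 = dapi_mode,
                      dapi_lo_log10 = dapi_win[1], dapi_hi_log10 = dapi_win[2],
                      a488_ceiling_log10 = a488_ceiling,
                      area_lo_log10 = area_win[1], area_hi_log10 = area_win[2],
                      circularity_floor = max(circ_floor, 0)))
}

#' Gate a study table with automatically derived regions
#'
#' Convenience wrapper: derives the default regions with
#' [auto_gate_thresholds()] and applies them with [apply_gate()].
#'
#' @param records Per-nucleus data frame.
#' @param ... Passed to [auto_gate_thresholds()].
#' @return A `gate_result` (with the thresholds attached as attribute
#'   `"thresholds"`).
#' @export
auto_gate <- function(records, ...) {
  g <- auto_gate_thresholds(records, ...)
  res <- apply_gate(records, g$morpho_gate, g$intensity_gate)
  attr(res, "thresholds") <- g$thresholds
  res
}
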