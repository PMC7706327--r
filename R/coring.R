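#' Specification of a virtual soil core
#'
#' A vertical cylindrical core of given diameter (default 44 mm, matching the
#' field corer) centred at `(x, y)` relative to the focal plant, with root
#' length reported in half-open depth bins `[lo, hi)` (default 10 cm
#' increments to 60 cm).
#'
#' @param center Numeric length-2, core centre (x across-row, y in-row), cm.
#' @param diameter Core diameter, cm.
#' @param depth_bins Strictly increasing breakpoints starting at 0, cm.
#' @param location_id Location label (`1`..`6`, or `"random"`).
#' @return An `rc_core_spec`.
#' @export
core_spec <- function(center, diameter = 4.4, depth_bins = seq(0, 60, 10),
                      location_id = NA) {
  stop_if(length(center) != 2 || !is.numeric(center), "center must be (x, y)")
  stop_if(diameter <= 0, "diameter must be > 0")
  stop_if(length(depth_bins) < 2 || depth_bins[1] != 0 ||
            any(diff(depth_bins) <= 0),
          "depth_bins must be strictly increasing and start at 0")
  structure(list(center = as.numeric(center), diameter = diameter,
                 depth_bins = as.numeric(depth_bins),
                 location_id = location_id),
            class = "rc_core_spec")
}

# Vectorised kernel: length of each segment inside the vertical cylinder of
# radius r at the origin, per depth slab.  Segments are given relative to the
# cylinder axis.  Returns [n_segment x n_bin] matrix.  Analytic: the in-cyl
# parameter interval solves a quadratic in t; each bin adds a z-interval.
cyl_bin_lengths <- function(x0, y0, z0, x1, y1, z1, len, r, breaks) {
  nb <- length(breaks) - 1L
  n <- length(len)
  out <- matrix(0, n, nb)
  if (n == 0L) return(out)
  dx <- x1 - x0; dy <- y1 - y0; dz <- z1 - z0
  a <- dx * dx + dy * dy
  b <- 2 * (x0 * dx + y0 * dy)
  c0 <- x0 * x0 + y0 * y0 - r * r
  vert <- a < 1e-18
  t1 <- numeric(n); t2 <- numeric(n)
  # vertical in xy: inside iff radial offset <= r
  t1[vert] <- ifelse(c0[vert] <= 0, 0, 1)
  t2[vert] <- ifelse(c0[vert] <= 0, 1, 0)
  nv <- !vert
  disc <- b[nv]^2 - 4 * a[nv] * c0[nv]
  sq <- sqrt(pmax(disc, 0))
  lo <- (-b[nv] - sq) / (2 * a[nv])
  hi <- (-b[nv] + sq) / (2 * a[nv])
  lo[disc <= 0] <- 1; hi[disc <= 0] <- 0
  t1[nv] <- pmax(0, lo); t2[nv] <- pmin(1, hi)

  flat <- abs(dz) < 1e-12
  for (bin in seq_len(nb)) {
    zl <- breaks[bin]; zh <- breaks[bin + 1L]
    s1 <- (zl - z0) / dz; s2 <- (zh - z0) / dz
    zlo <- pmin(s1, s2); zhi <- pmax(s1, s2)
    zlo[flat] <- ifelse(z0[flat] >= zl & z0[flat] < zh, 0, 1)
    zhi[flat] <- ifelse(z0[flat] >= zl & z0[flat] < zh, 1, 0)
    out[, bin] <- len * pmax(0, pmin(t2, zhi) - pmax(t1, zlo))
  }
  out
}

#' Length of one root segment inside a core's depth bin
#'
#' Analytic intersection of a 3-D segment with the infinite vertical cylinder
#' of the core, clipped to the depth slab `[depth_bins[bin_index],
#' depth_bins[bin_index + 1])`.  The cylinder-wall crossings solve a quadratic
#' in the segment parameter.
#'
#' @param segment A one-row data.frame (or list) with `x0,y0,z0,x1,y1,z1` and
#'   `length_cm` (coordinates in plot frame, cm).
#' @param spec An [core_spec()]; its `center` is taken in the same frame.
#' @param bin_index Depth-bin number (1-based).
#' @return Intersection length, cm (0 for a degenerate zero-length segment).
#' @export
segment_cylinder_length <- function(segment, spec, bin_index) {
  stopifnot(inherits(spec, "rc_core_spec"))
  stop_if(bin_index < 1 || bin_index > length(spec$depth_bins) - 1L,
          "bin_index out of range")
  len <- segment$length_cm %||%
    sqrt((segment$x1 - segment$x0)^2 + (segment$y1 - segment$y0)^2 +
           (segment$z1 - segment$z0)^2)
  if (len <= 0) return(0)
  m <- cyl_bin_lengths(segment$x0 - spec$center[1], segment$y0 - spec$center[2],
                       segment$z0,
                       segment$x1 - spec$center[1], segment$y1 - spec$center[2],
                       segment$z1, len, spec$diameter / 2, spec$depth_bins)
  m[1L, bin_index]
}

#' Extract a virtual soil core from a simulated plot
#'
#' Sums segment-cylinder intersection lengths over all root segments under
#' the periodic (nearest-image) plot boundary: each segment is translated by
#' the whole-cell shift that brings its midpoint closest to the core axis, so
#' cores near the plot edge see the neighbouring plots' roots exactly as a
#' fully bordered field plant would.
#'
#' @param plot An `rc_plot`.
#' @param spec An [core_spec()]; `center` is relative to the focal plant at
#'   the origin.
#' @return An `rc_core` with `root_length_by_bin` (cm) and `rld_by_bin`
#'   (cm cm^-3, length / (pi (d/2)^2 * bin height)).
#' @export
extract_core <- function(plot, spec) {
  stopifnot(inherits(plot, "rc_plot"), inherits(spec, "rc_core_spec"))
  seg <- plot$segments
  breaks <- spec$depth_bins
  nb <- length(breaks) - 1L
  if (nrow(seg) == 0L) {
    rl <- rep(0, nb)
  } else {
    Lx <- plot$domain[1]; Ly <- plot$domain[2]
    mx <- (seg$x0 + seg$x1) / 2 - spec$center[1]
    my <- (seg$y0 + seg$y1) / 2 - spec$center[2]
    sx <- Lx * round(mx / Lx)
    sy <- Ly * round(my / Ly)
    # bounding-box prefilter: a segment can only touch the cylinder if its
    # wrapped midpoint is within radius + half its length on both axes
    r <- spec$diameter / 2
    reach <- r + seg$length_cm / 2 + 1e-9
    keep <- abs(mx - sx) <= reach & abs(my - sy) <= reach
    rl <- colSums(cyl_bin_lengths(
      seg$x0[keep] - spec$center[1] - sx[keep],
      seg$y0[keep] - spec$center[2] - sy[keep], seg$z0[keep],
      seg$x1[keep] - spec$center[1] - sx[keep],
      seg$y1[keep] - spec$center[2] - sy[keep], seg$z1[keep],
      seg$length_cm[keep], r, breaks))
  }
  vol <- pi * (spec$diameter / 2)^2 * diff(breaks)
  structure(list(location_id = spec$location_id,
                 replicate_id = plot$replicate_id,
                 species = plot$species, phenotype = plot$phenotype,
                 depth_bins = breaks,
                 root_length_by_bin = rl, rld_by_bin = rl / vol,
                 spec = spec),
            class = "rc_core")
}

#' @export
print.rc_core <- function(x, ...) {
  cat(sprintf("<rc_core> loc %s (%s/%s): RL by bin [%s] cm\n",
              format(x$location_id), x$species %||% "?", x$phenotype %||% "?",
              paste(sprintf("%.2f", x$root_length_by_bin), collapse = ", ")))
  invisible(x)
}

#' Whole-plot root length density profile (the ground truth)
#'
#' Total segment length per depth bin divided by the layer's soil volume
#' (plot area `n_plants * row_spacing * plant_spacing` times bin height).
#'
#' @param plot An `rc_plot` with positive total root length.
#' @param depth_bins Depth breakpoints, cm.
#' @return An `rc_profile` with `provenance = "whole_plot"`.
#' @export
whole_plot_profile <- function(plot, depth_bins = seq(0, 60, 10)) {
  stopifnot(inherits(plot, "rc_plot"))
  seg <- plot$segments
  stop_if(nrow(seg) == 0L || sum(seg$length_cm) <= 0,
          "degenerate simulation: plot has zero total root length")
  rl <- colSums(slab_lengths(seg$z0, seg$z1, seg$length_cm, depth_bins))
  area <- plot$n_plants * plot$row_spacing * plot$plant_spacing
  rld_profile(rl / (area * diff(depth_bins)), depth_bins,
              provenance = "whole_plot")
}

#' Construct an RLD-by-depth profile
#'
#' @param rld Non-negative RLD per depth bin, cm cm^-3.
#' @param depth_bins Breakpoints, cm (length `length(rld) + 1`).
#' @param provenance One of `whole_plot`, `unadjusted`, `voronoi`, `trench`,
#'   `field`, `core`.
#' @param n_contributing_cores Number of cores the profile aggregates.
#' @return An `rc_profile`.
#' @export
rld_profile <- function(rld, depth_bins = seq(0, 60, 10),
                        provenance = "core", n_contributing_cores = NA_integer_) {
  stop_if(length(rld) != length(depth_bins) - 1L,
          "rld length must match depth bins")
  stop_if(any(rld < 0), "RLD must be non-negative")
  structure(list(rld_by_bin = as.numeric(rld),
                 depth_bins = as.numeric(depth_bins),
                 provenance = provenance,
                 n_contributing_cores = n_contributing_cores),
            class = "rc_profile")
}

#' @export
print.rc_profile <- function(x, ...) {
  cat(sprintf("<rc_profile> %s: [%s] cm cm^-3\n", x$provenance,
              paste(sprintf("%.4f", x$rld_by_bin), collapse = ", ")))
  invisible(x)
}

#' Draw a uniformly random coring location
#'
#' The centre is uniform over one plant's unit cell
#' `[-R/2, R/2] x [-P/2, P/2]` around the focal plant, emulating the study's
#' extra random core per simulated plot.  Uses the current RNG state.
#'
#' @param plot An `rc_plot` (supplies the cell dimensions).
#' @param diameter,depth_bins Passed to [core_spec()].
#' @return An [core_spec()] with `location_id = "random"`.
#' @export
place_random_core <- function(plot, diameter = 4.4, depth_bins = seq(0, 60, 10)) {
  stopifnot(inherits(plot, "rc_plot"))
  R <- plot$row_spacing; P <- plot$plant_spacing
  core_spec(c(runif(1, -R / 2, R / 2), runif(1, -P / 2, P / 2)),
            diameter = diameter, depth_bins = depth_bins,
            location_id = "random")
}

#' Convert a core sample to an RLD profile
#' @param core An `rc_core`.
#' @return An `rc_profile` with provenance `"core"`.
#' @export
core_profile <- function(core) {
  stopifnot(inherits(core, "rc_core"))
  rld_profile(core$rld_by_bin, core$depth_bins, provenance = "core",
              n_contributing_cores = 1L)
}
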