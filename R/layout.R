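#' Standard coring-location layout for a species
#'
#' Coordinates (cm) of the six study coring locations relative to the focal
#' plant at the origin, x across-row and y along-row:
#' 1 between-row next to the plant base, 2 halfway between plants in the row,
#' 3 between-row 5 cm from the plant base, 4 halfway between plants of
#' neighbouring rows, 5 equidistant from four plants in two rows, 6 in-row
#' next to the plant base.  "Next to the plant base" is one core radius
#' (2.2 cm) from the stem axis, the closest a 44 mm core can be centred
#' without containing the stem.  Between-row x-offsets are shared by the two
#' species; in-row y-offsets compress with bean's tighter plant spacing.
#'
#' @param species `"maize"` or `"bean"`.
#' @param field_2016 If `TRUE` and `species == "bean"`, drop location 4 (the
#'   2016 field protocol omitted it: bean's dense in-row spacing makes 4 and 5
#'   nearly coincide).
#' @return An `rc_layout`: `species`, `row_spacing`, `plant_spacing`, and
#'   `locations` (named list of `(x, y)`).
#' @export
default_layout <- function(species = c("maize", "bean"), field_2016 = FALSE) {
  species <- match.arg(species)
  R <- 76
  P <- if (species == "maize") 23 else 10
  loc <- list(`1` = c(2.2, 0), `2` = c(0, P / 2), `3` = c(5, 0),
              `4` = c(R / 2, 0), `5` = c(R / 2, P / 2), `6` = c(0, 2.2))
  if (species == "bean" && field_2016) loc[["4"]] <- NULL
  structure(list(species = species, row_spacing = R, plant_spacing = P,
                 locations = loc),
            class = "rc_layout")
}

#' @export
print.rc_layout <- function(x, ...) {
  cat(sprintf("<rc_layout> %s (R=%g, P=%g)\n", x$species, x$row_spacing,
              x$plant_spacing))
  for (id in names(x$locations))
    cat(sprintf("  loc %s: (%.1f, %.1f)\n", id, x$locations[[id]][1],
                x$locations[[id]][2]))
  invisible(x)
}

#' Expand coring locations by the plot's symmetry group
#'
#' Each location is mapped under \{identity, reflection across the row,
#' 180-degree rotation about the focal plant, both\} — i.e. images
#' `(+-x, +-y)` — then wrapped into the unit cell `[-R/2, R/2) x [-P/2, P/2)`
#' and de-duplicated (within 1e-6 cm), keeping location provenance.
#'
#' @param layout An [default_layout()] object.
#' @param subset Character or integer ids of the locations to expand.
#' @return Data frame with `location_id`, `x`, `y` (one row per distinct
#'   image).
#' @export
expand_by_symmetry <- function(layout, subset = names(layout$locations)) {
  stopifnot(inherits(layout, "rc_layout"))
  subset <- as.character(subset)
  stop_if(length(subset) == 0, "subset must be non-empty")
  missing <- setdiff(subset, names(layout$locations))
  stop_if(length(missing) > 0,
          paste("unknown location(s):", paste(missing, collapse = ", ")))
  R <- layout$row_spacing; P <- layout$plant_spacing
  wrap <- function(v, L) ((v + L / 2) %% L) - L / 2
  out <- do.call(rbind, lapply(subset, function(id) {
    p <- layout$locations[[id]]
    img <- unique(expand.grid(x = c(p[1], -p[1]), y = c(p[2], -p[2])))
    data.frame(location_id = id, x = wrap(img$x, R), y = wrap(img$y, P))
  }))
  # collapse duplicate images of the same location only; coincidence of
  # distinct locations is left for voronoi_weights() to reject
  key <- paste(out$location_id, round(out$x * 1e6), round(out$y * 1e6))
  out[!duplicated(key), , drop = FALSE]
}

# Clip convex polygon (matrix [n x 2]) to half-plane a*x + b*y <= c
# (Sutherland-Hodgman, one edge).
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - c
  inside <- d <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Voronoi-area weights for a subset of coring locations
#'
#' Computes the Voronoi tessellation of the symmetry-expanded coring points
#' over the periodic unit cell (ghost copies of every point in the eight
#' neighbouring cells bound all regions), sums each location's polygon areas
#' within one cell, and normalises to weights `w_i = area_i / sum(areas)` —
#' the `w_i` of the area-weighted whole-plot RLD estimator.  Areas are exact:
#' each region is the cell rectangle clipped by perpendicular-bisector
#' half-planes.
#'
#' @param layout An [default_layout()].
#' @param subset Ids of the locations in use (Voronoi areas are recomputed
#'   for every subset).
#' @return An `rc_weights`: `subset`, `w` (named, sums to 1), `areas` (cm^2).
#' @export
voronoi_weights <- function(layout, subset = names(layout$locations)) {
  stopifnot(inherits(layout, "rc_layout"))
  subset <- as.character(subset)
  pts <- expand_by_symmetry(layout, subset)
  # detect true coincidence of distinct locations
  key <- paste(round(pts$x * 1e6), round(pts$y * 1e6))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    ids <- unique(pts$location_id[dup])
    stop_if(length(ids) > 1,
            paste("coincident coring locations after symmetry expansion:",
                  paste(ids, collapse = " vs ")))
  }
  R <- layout$row_spacing; P <- layout$plant_spacing
  shifts <- expand.grid(sx = c(-R, 0, R), sy = c(-P, 0, P))
  all_pts <- data.frame(
    location_id = rep(pts$location_id, nrow(shifts)),
    x = rep(pts$x, nrow(shifts)) + rep(shifts$sx, each = nrow(pts)),
    y = rep(pts$y, nrow(shifts)) + rep(shifts$sy, each = nrow(pts)))
  cell <- cbind(c(-R / 2, R / 2, R / 2, -R / 2), c(-P / 2, -P / 2, P / 2, P / 2))
  areas <- setNames(numeric(length(subset)), subset)
  for (k in seq_len(nrow(all_pts))) {
    p <- c(all_pts$x[k], all_pts$y[k])
    poly <- cell
    for (j in seq_len(nrow(all_pts))) {
      if (j == k) next
      q <- c(all_pts$x[j], all_pts$y[j])
      if (sum((q - p)^2) < 1e-18) next  # own periodic duplicate
      # keep side of the bisector nearer p: 2(q-p).z <= |q|^2 - |p|^2
      poly <- clip_halfplane(poly, 2 * (q[1] - p[1]), 2 * (q[2] - p[2]),
                             sum(q^2) - sum(p^2))
      if (nrow(poly) < 3L) break
    }
    id <- as.character(all_pts$location_id[k])
    areas[id] <- areas[id] + polygon_area(poly)
  }
  w <- areas / sum(areas)
  structure(list(subset = subset, w = w, areas = areas,
                 cell_area = R * P),
            class = "rc_weights")
}

#' @export
print.rc_weights <- function(x, ...) {
  cat("<rc_weights>\n")
  for (id in x$subset)
    cat(sprintf("  loc %s: w = %.4f (area %.1f cm^2)\n", id, x$w[[id]],
                x$areas[[id]]))
  invisible(x)
}

#' Area-weighted whole-plot RLD estimate from per-location cores
#'
#' The adjusted estimator `RLD_adj = sum_i RLD_i * w_i` over the locations in
#' the weight subset, per depth bin.
#'
#' @param cores Named list (by location id) of `rc_profile` or `rc_core`
#'   objects covering exactly the weight subset, with matching depth bins.
#' @param weights An [voronoi_weights()] result.
#' @return An `rc_estimate` with `profile` (the adjusted profile),
#'   `method = "voronoi"`, `weights`, and `per_location_profiles`.
#' @export
estimate_rld <- function(cores, weights) {
  stopifnot(inherits(weights, "rc_weights"))
  profs <- lapply(cores, as_profile)
  stop_if(!setequal(names(profs), weights$subset),
          "cores must cover exactly the weight subset")
  profs <- profs[weights$subset]
  bins <- profs[[1]]$depth_bins
  for (p in profs)
    stop_if(!isTRUE(all.equal(p$depth_bins, bins)), "depth bin mismatch")
  rld <- Reduce(`+`, Map(function(p, w) p$rld_by_bin * w,
                         profs, weights$w[weights$subset]))
  structure(list(
    profile = rld_profile(rld, bins, provenance = "voronoi",
                          n_contributing_cores = length(profs)),
    method = "voronoi", subset = weights$subset, weights = weights,
    per_location_profiles = profs),
    class = "rc_estimate")
}

#' Unweighted mean of per-location core profiles
#'
#' The conventional estimator: the arithmetic mean of the per-location RLD
#' profiles, per depth bin.
#'
#' @param cores Named list of `rc_profile` / `rc_core` (>= 1), matching bins.
#' @return An `rc_estimate` with `method = "unadjusted"`.
#' @export
unadjusted_mean <- function(cores) {
  stop_if(length(cores) == 0, "need at least one core profile")
  profs <- lapply(cores, as_profile)
  bins <- profs[[1]]$depth_bins
  for (p in profs)
    stop_if(!isTRUE(all.equal(p$depth_bins, bins)), "depth bin mismatch")
  rld <- Reduce(`+`, lapply(profs, `[[`, "rld_by_bin")) / length(profs)
  structure(list(
    profile = rld_profile(rld, bins, provenance = "unadjusted",
                          n_contributing_cores = length(profs)),
    method = "unadjusted", subset = names(profs), weights = NULL,
    per_location_profiles = profs),
    class = "rc_estimate")
}

as_profile <- function(x) {
  if (inherits(x, "rc_profile")) x
  else if (inherits(x, "rc_core")) core_profile(x)
  else if (inherits(x, "rc_estimate")) x$profile
  else stop("expected an rc_profile, rc_core or rc_estimate", call. = FALSE)
}

#' @export
print.rc_estimate <- function(x, ...) {
  cat(sprintf("<rc_estimate> %s over locations {%s}: [%s]\n", x$method,
              paste(x$subset, collapse = ","),
              paste(sprintf("%.4f", x$profile$rld_by_bin), collapse = ", ")))
  invisible(x)
}

#' Serialize a layout and weights to JSON
#' @param layout An `rc_layout`.
#' @param weights Optional `rc_weights`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, weights = NULL, path) {
  obj <- list(species = layout$species, row_spacing = layout$row_spacing,
              plant_spacing = layout$plant_spacing,
              locations = layout$locations)
  if (!is.null(weights))
    obj$weights <- list(subset = weights$subset, w = as.list(weights$w),
                        areas = as.list(weights$areas))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
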