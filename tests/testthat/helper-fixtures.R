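# Shared fixtures: small, fast configurations for unit tests.  The full-size
# calibrated defaults are exercised in test-acceptance.R only.

small_config <- function(species = "maize", phenotype = "intermediate", ...) {
  sim_config(species, phenotype,
             elongation_budget = if (species == "maize") 2000 else 1500, ...)
}

small_plot <- function(seed = 1, species = "maize",
                       phenotype = "intermediate", ...) {
  simulate_plot(small_config(species, phenotype, ...), seed = seed)
}

# Brute-force oracle: segment-in-cylinder length by fine subdivision with a
# midpoint in/out test (n pieces).
subdivision_cyl_length <- function(p0, p1, center, r, zlo, zhi, n = 1e4) {
  t <- (seq_len(n) - 0.5) / n
  mx <- p0[1] + t * (p1[1] - p0[1]) - center[1]
  my <- p0[2] + t * (p1[2] - p0[2]) - center[2]
  mz <- p0[3] + t * (p1[3] - p0[3])
  inside <- (mx^2 + my^2 <= r^2) & (mz >= zlo) & (mz < zhi)
  sqrt(sum((p1 - p0)^2)) * sum(inside) / n
}

# Rasterization oracle for Voronoi weights: 1 mm pixels over one unit cell,
# each assigned to the nearest symmetry-expanded point (ghosts included).
raster_weights <- function(layout, subset = names(layout$locations),
                           pixel = 0.1) {
  pts <- expand_by_symmetry(layout, subset)
  R <- layout$row_spacing; P <- layout$plant_spacing
  shifts <- expand.grid(sx = c(-R, 0, R), sy = c(-P, 0, P))
  px <- rep(pts$x, nrow(shifts)) + rep(shifts$sx, each = nrow(pts))
  py <- rep(pts$y, nrow(shifts)) + rep(shifts$sy, each = nrow(pts))
  pid <- rep(as.character(pts$location_id), nrow(shifts))
  gx <- seq(-R / 2 + pixel / 2, R / 2 - pixel / 2, by = pixel)
  gy <- seq(-P / 2 + pixel / 2, P / 2 - pixel / 2, by = pixel)
  grid <- expand.grid(x = gx, y = gy)
  best <- rep(Inf, nrow(grid)); who <- integer(nrow(grid))
  for (k in seq_along(px)) {
    d2 <- (grid$x - px[k])^2 + (grid$y - py[k])^2
    sel <- d2 < best
    best[sel] <- d2[sel]; who[sel] <- k
  }
  counts <- tapply(rep(1, nrow(grid)), pid[who], sum)
  w <- rep(0, length(subset)); names(w) <- as.character(subset)
  w[names(counts)] <- counts / nrow(grid)
  w
}

# Rasterization oracle for depth quantiles: deposit each bin's mass uniformly
# at `res` resolution and scan the cumulative sum.
raster_depth_quantile <- function(v, p, breaks, res = 0.01) {
  z <- seq(0, max(breaks), by = res)[-1] - res / 2
  dens <- numeric(length(z))
  for (b in seq_along(v)) {
    sel <- z > breaks[b] & z < breaks[b + 1]
    dens[sel] <- v[b] / sum(sel)
  }
  cum <- cumsum(dens) / sum(dens)
  z[which(cum >= p / 100)[1]] + res / 2
}

# Subdivision oracle refined by bisection at inclusion transitions; accuracy
# ~1e-12 of the parameter while staying a pure in/out construction.
refined_cyl_length <- function(p0, p1, center, r, zlo, zhi, n = 1e4) {
  inside <- function(t) {
    x <- p0[1] + t * (p1[1] - p0[1]) - center[1]
    y <- p0[2] + t * (p1[2] - p0[2]) - center[2]
    z <- p0[3] + t * (p1[3] - p0[3])
    (x^2 + y^2 <= r^2) & (z >= zlo) & (z < zhi)
  }
  ts <- seq(0, 1, length.out = n + 1)
  ins <- inside(ts)
  total <- sum(ins[-length(ins)] & ins[-1]) / n
  for (k in which(ins[-length(ins)] != ins[-1])) {
    lo <- ts[k]; hi <- ts[k + 1]; flo <- ins[k]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (inside(mid) == flo) lo <- mid else hi <- mid
    }
    cross <- (lo + hi) / 2
    total <- total + if (flo) cross - ts[k] else ts[k + 1] - cross
  }
  sqrt(sum((p1 - p0)^2)) * total
}
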