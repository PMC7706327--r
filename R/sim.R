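#' Configuration for a stochastic root-architecture plot simulation
#'
#' Builds the parameter set for [simulate_plot()]: a four-plant plot of maize
#' or common bean grown to 40 days, with the three depth phenotypes
#' (shallow / intermediate / deep) differing only in the emergence angle of
#' axial (maize nodal) or basal (bean) roots.  All other parameters — total
#' elongation budget, branching frequency, gravitropism, tip deflection — are
#' identical across phenotypes, so phenotypes contrast in the *placement* of
#' root length, not its amount.
#'
#' The angle offsets follow the study convention: bean 0/+20/+40 and maize
#' -30/0/+30 for shallow/intermediate/deep, with a larger offset meaning a
#' *more vertical* (deeper) axial system; internally the effective emergence
#' angle from vertical is `default_angle - angle_offset`, clamped to
#' \[5, 85\] degrees.
#'
#' @param species `"maize"` or `"bean"`.
#' @param phenotype `"shallow"`, `"intermediate"` or `"deep"`; sets
#'   `angle_offset` unless that is given explicitly.
#' @param angle_offset Degrees added to the species' depth-offset convention;
#'   overrides `phenotype` if supplied.
#' @param row_spacing,plant_spacing Row and in-row plant spacing in cm
#'   (defaults 76, and 23 maize / 10 bean).
#' @param n_plants Number of plants in the plot (2 rows x 2 plants).
#' @param growth_days Nominal growth duration; mapped onto `elongation_budget`.
#' @param elongation_budget Total root length produced per plant (cm),
#'   axial + lateral; default 2500 maize, 1200 bean.  Identical across
#'   phenotypes by construction.
#' @param step_length Growth-step discretisation of axial roots, cm.
#' @param gravitropism_rate Degrees of heading rotation toward vertical per cm
#'   of axial growth.
#' @param branching_frequency First-order laterals per cm of axial root.
#' @param tip_deflection_sd SD (degrees) of the random per-step deflection of
#'   the growing tip, applied on both bending axes.
#' @param stochastic_cv Coefficient of variation of the per-replicate
#'   truncated-Normal(1, cv) multipliers on elongation partitioning,
#'   branching, gravitropism and tip deflection.
#' @param axial_fraction Fraction of the elongation budget allocated to axial
#'   roots at multiplier 1 (default 0.3 maize, 0.06 bean — bean carries most
#'   of its length in laterals); the per-replicate elongation multiplier
#'   scales this split (total length stays fixed).
#' @param max_depth Maximum soil depth tracked, cm (>= 60).
#' @param seed Default seed used by [simulate_plot()] when none is passed.
#' @return An object of class `rc_config` (a list).
#' @examples
#' cfg <- sim_config("maize", "deep")
#' plot <- simulate_plot(cfg, seed = 1)
#' @export
sim_config <- function(species = c("maize", "bean"),
                       phenotype = c("intermediate", "shallow", "deep"),
                       angle_offset = NULL,
                       row_spacing = 76,
                       plant_spacing = NULL,
                       n_plants = 4L,
                       growth_days = 40,
                       elongation_budget = NULL,
                       step_length = 0.5,
                       gravitropism_rate = 0.3,
                       branching_frequency = NULL,
                       tip_deflection_sd = 4,
                       stochastic_cv = 0.15,
                       axial_fraction = NULL,
                       max_depth = 100,
                       seed = NULL) {
  species <- match.arg(species)
  phenotype <- match.arg(phenotype)
  if (is.null(plant_spacing)) plant_spacing <- if (species == "maize") 23 else 10
  if (is.null(elongation_budget))
    elongation_budget <- if (species == "maize") 10000 else 20000
  if (is.null(branching_frequency))
    branching_frequency <- if (species == "maize") 0.6 else 2.0
  if (is.null(axial_fraction))
    axial_fraction <- if (species == "maize") 0.3 else 0.06
  if (is.null(angle_offset)) {
    angle_offset <- switch(species,
      bean  = c(shallow = 0, intermediate = 20, deep = 40)[[phenotype]],
      maize = c(shallow = -30, intermediate = 0, deep = 30)[[phenotype]])
  }
  stop_if(step_length <= 0, "step_length must be > 0")
  stop_if(elongation_budget < 0, "elongation_budget must be >= 0")
  stop_if(gravitropism_rate < 0, "gravitropism_rate must be >= 0")
  stop_if(branching_frequency < 0, "branching_frequency must be >= 0")
  stop_if(tip_deflection_sd < 0, "tip_deflection_sd must be >= 0")
  stop_if(stochastic_cv < 0, "stochastic_cv must be >= 0")
  stop_if(max_depth < 60, "max_depth must be >= 60")
  stop_if(row_spacing <= 0 || plant_spacing <= 0, "spacings must be > 0")
  structure(list(
    species = species, phenotype = phenotype, angle_offset = angle_offset,
    row_spacing = row_spacing, plant_spacing = plant_spacing,
    n_plants = as.integer(n_plants), growth_days = growth_days,
    elongation_budget = elongation_budget, step_length = step_length,
    gravitropism_rate = gravitropism_rate,
    branching_frequency = branching_frequency,
    tip_deflection_sd = tip_deflection_sd, stochastic_cv = stochastic_cv,
    axial_fraction = axial_fraction, max_depth = max_depth, seed = seed),
    class = "rc_config")
}

# Species axial-root templates: per-root default emergence angle from vertical
# (deg), nominal length (cm), and emergence geometry (whorl depth, crown
# radial offset).  Bean: taproot + 3 whorls of 4 basal roots at 30/55/80 deg
# emerging along the hypocotyl; maize: taproot surrogate + 4 nodal whorls of
# 6 roots at 60 deg emerging from a shallow crown.  Defaults are calibration
# choices (the donor root model's parameter files are not reproduced here);
# angles are from vertical, so the phenotype offset is subtracted.
axial_template <- function(species) {
  if (species == "maize") {
    data.frame(
      root_class = c("taproot", rep("axial", 36L)),
      angle0 = c(10, rep(c(35, 55, 65, 75), each = 9L)),
      nominal = c(60, rep(75, 36L)),
      z_emerge = c(0, rep(0.8 * (0:3), each = 9L)),
      r_emerge = c(0, rep(c(0.5, 1, 1.5, 2), each = 9L)),
      stiffness = c(0.3, rep(1, 36L)),
      offsettable = c(FALSE, rep(TRUE, 36L)))
  } else {
    data.frame(
      root_class = c("taproot", rep("axial", 18L)),
      angle0 = c(5, rep(c(45, 65, 85), each = 6L)),
      nominal = c(50, rep(58, 18L)),
      z_emerge = c(0, rep(1 + 1.5 * (0:2), each = 6L)),
      r_emerge = c(0, rep(c(0.8, 1.4, 2), each = 6L)),
      stiffness = c(0.3, rep(1, 18L)),
      offsettable = c(FALSE, rep(TRUE, 18L)))
  }
}

#' Simulate one four-plant plot
#'
#' Grows each plant's axial roots as 3-D polylines (fixed-length steps with
#' Gaussian tip deflection and gravitropic curvature toward vertical), then
#' attaches straight first-order laterals along the axials at the configured
#' branching frequency.  Replicate-to-replicate variation comes from
#' truncated-Normal(1, `stochastic_cv`) multipliers on the axial/lateral
#' partition of the elongation budget, branching frequency, gravitropism and
#' tip deflection; the total root length per plant equals the elongation
#' budget exactly, so phenotypes and replicates are length-matched.
#'
#' Depth `z` is positive downward with the soil surface at 0; headings are
#' clamped to at most 89 degrees from vertical so roots never grow upward.
#' The plot is treated as periodic: plants sit at the centres of four
#' `row_spacing x plant_spacing` cells and coring wraps coordinates by the
#' nearest-image rule.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An `rc_plot` with elements `segments` (data.frame: `plant_id`,
#'   `root_class`, `x0,y0,z0,x1,y1,z1`, `length_cm`), `plant_positions`,
#'   `species`, `phenotype`, spacings, `domain` (periodic extents),
#'   `budget_consumed`, `replicate_id`, `seed`, `config`.
#' @export
simulate_plot <- function(config, seed = NULL) {
  stopifnot(inherits(config, "rc_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    R <- config$row_spacing; P <- config$plant_spacing
    plants <- cbind(x = c(0, 0, R, R), y = c(0, P, 0, P))[seq_len(config$n_plants), , drop = FALSE]

    if (config$elongation_budget == 0) {
      seg <- data.frame(plant_id = integer(), root_class = character(),
                        x0 = numeric(), y0 = numeric(), z0 = numeric(),
                        x1 = numeric(), y1 = numeric(), z1 = numeric(),
                        length_cm = numeric())
      return(new_plot(seg, plants, config, seed, 0))
    }

    m <- rtrunc_mult(4L, config$stochastic_cv)  # elong, branch, grav, deflect
    f_ax <- min(0.95, max(0.05, config$axial_fraction * m[1L]))
    if (config$branching_frequency == 0) f_ax <- 1
    budget <- config$elongation_budget
    ax_total <- f_ax * budget                  # per plant
    g_eff <- config$gravitropism_rate * m[3L]
    sd_eff <- config$tip_deflection_sd * m[4L]
    bf_eff <- config$branching_frequency * m[2L]

    tmpl <- axial_template(config$species)
    tmpl$angle <- ifelse(tmpl$offsettable,
                         pmin(85, pmax(5, tmpl$angle0 - config$angle_offset)),
                         tmpl$angle0)
    tmpl$len <- tmpl$nominal * ax_total / sum(tmpl$nominal)

    seg_list <- vector("list", nrow(plants))
    for (p in seq_len(nrow(plants))) {
      seg_list[[p]] <- grow_plant(tmpl, plants[p, 1L], plants[p, 2L], p,
                                  config$step_length, g_eff, sd_eff, bf_eff,
                                  budget - ax_total)
    }
    seg <- do.call(rbind, seg_list)
    new_plot(seg, plants, config, seed, nrow(plants) * budget)
  })
}

# Grow one plant: vectorised over all axial steps, laterals as straight
# segments placed by arc length along the axials.
grow_plant <- function(tmpl, px, py, plant_id, step, g, sd_defl, bf, lat_total) {
  n_steps <- pmax(1L, ceiling(tmpl$len / step))
  root_id <- rep.int(seq_len(nrow(tmpl)), n_steps)
  steps <- rep.int(step, length(root_id))
  last <- cumsum(n_steps)
  steps[last] <- tmpl$len - (n_steps - 1L) * step
  cumlen <- grouped_cumsum(steps, root_id)

  theta0 <- tmpl$angle[root_id]
  sdv <- sd_defl * tmpl$stiffness[root_id]   # thick roots deflect less
  eps_t <- if (sd_defl > 0) rnorm(length(steps), 0, sdv) else numeric(length(steps))
  theta <- theta0 - g * cumlen + grouped_cumsum(eps_t, root_id)
  theta <- pmin(89, pmax(0, theta))
  phi0 <- runif(nrow(tmpl), 0, 2 * pi)[root_id]
  eps_p <- if (sd_defl > 0) rnorm(length(steps), 0, sdv * pi / 180) else numeric(length(steps))
  phi <- phi0 + grouped_cumsum(eps_p, root_id)

  # emergence points: whorl depth plus a small radial crown offset in the
  # root's initial azimuth direction
  ex <- px + tmpl$r_emerge * cos(phi0[!duplicated(root_id)])
  ey <- py + tmpl$r_emerge * sin(phi0[!duplicated(root_id)])
  ez <- tmpl$z_emerge

  tr <- theta * pi / 180
  dx <- steps * sin(tr) * cos(phi)
  dy <- steps * sin(tr) * sin(phi)
  dz <- steps * cos(tr)
  x1 <- ex[root_id] + grouped_cumsum(dx, root_id)
  y1 <- ey[root_id] + grouped_cumsum(dy, root_id)
  z1 <- ez[root_id] + grouped_cumsum(dz, root_id)
  firsts <- c(1L, head(last, -1L) + 1L)
  x0 <- c(0, head(x1, -1L)); x0[firsts] <- ex
  y0 <- c(0, head(y1, -1L)); y0[firsts] <- ey
  z0 <- c(0, head(z1, -1L)); z0[firsts] <- ez

  ax <- data.frame(plant_id = plant_id,
                   root_class = tmpl$root_class[root_id],
                   x0 = x0, y0 = y0, z0 = z0, x1 = x1, y1 = y1, z1 = z1,
                   length_cm = steps)

  n_lat <- if (bf > 0 && lat_total > 0) max(1L, round(bf * sum(tmpl$len))) else 0L
  if (n_lat == 0L) return(ax)
  l_lat <- lat_total / n_lat
  # uniform positions by arc length along the plant's axial system
  cs <- cumsum(steps)
  u <- runif(n_lat, 0, cs[length(cs)])
  i <- findInterval(u, cs) + 1L
  i[i > length(cs)] <- length(cs)
  frac <- (u - c(0, cs)[i]) / steps[i]
  bx <- x0[i] + frac * (x1[i] - x0[i])
  by <- y0[i] + frac * (y1[i] - y0[i])
  bz <- z0[i] + frac * (z1[i] - z0[i])
  # laterals point broadly along the parent's outward azimuth
  lphi <- phi[i] + rnorm(n_lat, 0, pi / 3)
  lth <- runif(n_lat, 50, 85) * pi / 180
  lat <- data.frame(plant_id = plant_id, root_class = "lateral",
                    x0 = bx, y0 = by, z0 = bz,
                    x1 = bx + l_lat * sin(lth) * cos(lphi),
                    y1 = by + l_lat * sin(lth) * sin(lphi),
                    z1 = bz + l_lat * cos(lth),
                    length_cm = l_lat)
  rbind(ax, lat)
}

new_plot <- function(segments, plants, config, seed, budget_consumed,
                     replicate_id = NA_integer_) {
  structure(list(
    segments = segments, plant_positions = plants,
    species = config$species, phenotype = config$phenotype,
    row_spacing = config$row_spacing, plant_spacing = config$plant_spacing,
    n_plants = nrow(plants),
    domain = c(2 * config$row_spacing, 2 * config$plant_spacing),
    budget_consumed = budget_consumed, replicate_id = replicate_id,
    seed = seed, config = config), class = "rc_plot")
}

#' @export
print.rc_plot <- function(x, ...) {
  cat(sprintf("<rc_plot> %s / %s: %d plants, %d segments, total RL %.1f cm (seed %s)\n",
              x$species, x$phenotype, x$n_plants, nrow(x$segments),
              sum(x$segments$length_cm), format(x$seed)))
  invisible(x)
}

#' Total root length of a simulated plot
#' @param plot An `rc_plot`.
#' @return Total segment length, cm.
#' @export
total_root_length <- function(plot) sum(plot$segments$length_cm)

#' Simulate an ensemble of replicate plots
#'
#' Runs [simulate_plot()] once per seed in `seed_sequence`, producing
#' independent stochastic replicates of the same configuration (the study
#' protocol uses 100 per phenotype; a scaled profile uses 25).
#'
#' @param config_base An [sim_config()].
#' @param n_replicates Number of replicates (>= 2); must match
#'   `length(seed_sequence)` when both are given.
#' @param seed_sequence Integer seeds, one per replicate; duplicates trigger a
#'   warning (replicates would be identical).
#' @return List of `rc_plot` (class `rc_ensemble`), with `replicate_id` set.
#' @export
study_ensemble <- function(config_base, n_replicates = NULL, seed_sequence = NULL) {
  if (is.null(seed_sequence)) {
    stop_if(is.null(n_replicates), "give n_replicates or seed_sequence")
    base <- config_base$seed %||% 1L
    seed_sequence <- base + seq_len(n_replicates) - 1L
  }
  n_replicates <- n_replicates %||% length(seed_sequence)
  stop_if(n_replicates < 2, "n_replicates must be >= 2")
  stop_if(length(seed_sequence) != n_replicates,
          "seed_sequence length must equal n_replicates")
  if (anyDuplicated(seed_sequence))
    warning("duplicate seeds in seed_sequence: replicates will be identical")
  out <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    out[[i]] <- simulate_plot(config_base, seed = seed_sequence[i])
    out[[i]]$replicate_id <- i
  }
  structure(out, class = "rc_ensemble")
}

#' Write a plot's segments to CSV (with a JSON config sidecar)
#'
#' @param plot An `rc_plot`.
#' @param path CSV path; a `<path>.json` sidecar holds the configuration.
#' @return `path`, invisibly.
#' @export
write_segments <- function(plot, path) {
  utils::write.csv(plot$segments[, c("plant_id", "root_class",
                                     "x0", "y0", "z0", "x1", "y1", "z1",
                                     "length_cm")],
                   path, row.names = FALSE)
  cfg <- plot$config
  cfg$seed <- plot$seed
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
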