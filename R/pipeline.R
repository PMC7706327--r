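#' Configuration for a full in-silico coring study
#'
#' @param species Character vector, subset of `c("maize", "bean")`.
#' @param phenotypes Subset of `c("shallow", "intermediate", "deep")`.
#' @param n_replicates Replicate plots per species x phenotype (study: 100;
#'   scaled test profile: 25).
#' @param subset_sizes Coring-location subset sizes to rank (1..5).
#' @param seed Base seed; all arm seeds derive from it.
#' @param tost An [tost_config()].
#' @param qda_training_sizes Training sizes for the QDA sweep; sizes that the
#'   replicate pool cannot support are dropped with a note in the manifest.
#' @param qda_repeats Random training draws per size.
#' @param power_reps Resampling replicates per sample size (study: 2000).
#' @param power_n Sample sizes for the power analysis.
#' @param metric_ps Depth-metric percentiles.
#' @param depth_bins Depth breakpoints, cm.
#' @param outdir Output directory for the CSV/JSON bundle.
#' @return An `rc_study_config`.
#' @export
study_config <- function(species = c("maize", "bean"),
                         phenotypes = c("shallow", "intermediate", "deep"),
                         n_replicates = 25,
                         subset_sizes = 1:5,
                         seed = 1L,
                         tost = tost_config(),
                         qda_training_sizes = c(8, 10, 15, 20, 25, 30, 35, 40, 45, 50),
                         qda_repeats = 20,
                         power_reps = 2000,
                         power_n = 2:20,
                         metric_ps = c(50, 80, 90, 95),
                         depth_bins = seq(0, 60, 10),
                         outdir = NULL) {
  species <- match.arg(species, c("maize", "bean"), several.ok = TRUE)
  phenotypes <- match.arg(phenotypes,
                          c("shallow", "intermediate", "deep"),
                          several.ok = TRUE)
  stop_if(n_replicates < 2, "n_replicates must be >= 2")
  stop_if(!all(subset_sizes %in% 1:6), "subset sizes must be within 1..6")
  structure(list(species = species, phenotypes = phenotypes,
                 n_replicates = as.integer(n_replicates),
                 subset_sizes = as.integer(subset_sizes),
                 seed = as.integer(seed), tost = tost,
                 qda_training_sizes = qda_training_sizes,
                 qda_repeats = qda_repeats, power_reps = power_reps,
                 power_n = power_n, metric_ps = metric_ps,
                 depth_bins = depth_bins, outdir = outdir),
            class = "rc_study_config")
}

# Simulate one species x phenotype arm and extract all cores.
# Returns: whole [reps x bins], rld/rl arrays [reps x bins x locations],
# random-core rld/rl [reps x bins], ensemble seeds.
simulate_arm <- function(species, phenotype, n_reps, seed_base, depth_bins,
                         layout = default_layout(species)) {
  cfg <- sim_config(species, phenotype)
  seeds <- seed_base + seq_len(n_reps) - 1L
  ens <- study_ensemble(cfg, n_reps, seeds)
  locs <- names(layout$locations)
  nb <- length(depth_bins) - 1L
  whole <- matrix(NA_real_, n_reps, nb)
  rld <- array(NA_real_, c(n_reps, nb, length(locs)),
               dimnames = list(NULL, bin_labels(depth_bins), locs))
  rl <- rld
  rnd_rld <- matrix(NA_real_, n_reps, nb)
  rnd_rl <- matrix(NA_real_, n_reps, nb)
  for (i in seq_len(n_reps)) {
    plot <- ens[[i]]
    whole[i, ] <- whole_plot_profile(plot, depth_bins)$rld_by_bin
    for (j in seq_along(locs)) {
      cs <- core_spec(layout$locations[[locs[j]]], depth_bins = depth_bins,
                      location_id = locs[j])
      core <- extract_core(plot, cs)
      rld[i, , j] <- core$rld_by_bin
      rl[i, , j] <- core$root_length_by_bin
    }
    rc <- with_seed(seeds[i] + 500000L,
                    extract_core(plot, place_random_core(plot,
                                                         depth_bins = depth_bins)))
    rnd_rld[i, ] <- rc$rld_by_bin
    rnd_rl[i, ] <- rc$root_length_by_bin
  }
  list(species = species, phenotype = phenotype, seeds = seeds,
       depth_bins = depth_bins, locations = locs, whole = whole,
       rld = rld, rl = rl, random_rld = rnd_rld, random_rl = rnd_rl)
}

#' Rank coring-location subsets by Manhattan distance to a reference
#'
#' For every subset of the requested sizes, forms the per-replicate estimate
#' (Voronoi-weighted or unadjusted) from the per-location core RLD profiles,
#' measures its Manhattan distance to the per-replicate reference profile,
#' and ranks subsets by mean distance (SD across replicates reported).
#'
#' @param core_rld 3-D array `[replicate x depth bin x location]` of core RLD
#'   values (dimnames on the location axis are the location ids).
#' @param reference Matrix `[replicate x depth bin]` of reference profiles
#'   (whole-plot truth or the all-6 Voronoi estimate).
#' @param layout An [default_layout()] (needed for subset Voronoi weights).
#' @param method `"voronoi"` or `"unadjusted"`.
#' @param subset_sizes Sizes to enumerate (all combinations per size).
#' @param weight_cache Optional environment memoising subset weights.
#' @return An `rc_subset_ranking` data.frame: `size`, `subset`, `method`,
#'   `mean_distance`, `sd_distance`, `rank` (within size).
#' @export
evaluate_subsets <- function(core_rld, reference, layout,
                             method = c("voronoi", "unadjusted"),
                             subset_sizes = 1:5, weight_cache = NULL) {
  method <- match.arg(method)
  locs <- dimnames(core_rld)[[3]]
  stop_if(is.null(locs), "core_rld needs location dimnames")
  rows <- list()
  for (k in subset_sizes) {
    combos <- utils::combn(locs, k, simplify = FALSE)
    for (sub in combos) {
      if (method == "voronoi") {
        key <- paste(sub, collapse = "+")
        w <- NULL
        if (!is.null(weight_cache) && !is.null(weight_cache[[key]]))
          w <- weight_cache[[key]]
        if (is.null(w)) {
          w <- voronoi_weights(layout, sub)$w
          if (!is.null(weight_cache)) weight_cache[[key]] <- w
        }
        wv <- as.numeric(w[sub])
      } else {
        wv <- rep(1 / k, k)
      }
      est <- matrix(0, nrow(reference), ncol(reference))
      for (j in seq_along(sub))
        est <- est + core_rld[, , sub[j], drop = TRUE] * wv[j]
      d <- rowSums(abs(est - reference))
      rows[[length(rows) + 1L]] <- data.frame(
        size = k, subset = paste(sub, collapse = "+"), method = method,
        mean_distance = mean(d), sd_distance = stats::sd(d))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$size, out$mean_distance), ]
  out$rank <- stats::ave(out$mean_distance, out$size,
                         FUN = function(v) rank(v, ties.method = "first"))
  rownames(out) <- NULL
  structure(out, class = c("rc_subset_ranking", "data.frame"))
}

#' TOST equivalence matrix: estimators vs whole-plot truth
#'
#' Runs [tost_equivalence()] per species x phenotype x depth cell (the
#' study's 36 cells for two species, three phenotypes, six depths) for both
#' the unadjusted and the Voronoi-adjusted all-location estimator against the
#' per-replicate whole-plot truth, and counts the equivalent cells per
#' estimator.
#'
#' @param estimates Data frame with columns `species`, `phenotype`, `depth`,
#'   `replicate`, `truth`, `unadjusted`, `voronoi` (one row per replicate and
#'   depth bin).
#' @param config An [tost_config()].
#' @return List with `cells` (data.frame: species, phenotype, depth, method,
#'   p_value, equivalent) and `counts` (named: equivalent cells per method,
#'   out of `n_cells`).
#' @export
tost_equivalence_matrix <- function(estimates, config = tost_config()) {
  need <- c("species", "phenotype", "depth", "replicate", "truth",
            "unadjusted", "voronoi")
  stop_if(!all(need %in% names(estimates)), "missing columns in estimates")
  cells <- list()
  for (grp in split(estimates,
                    estimates[c("species", "phenotype", "depth")], drop = TRUE)) {
    for (m in c("unadjusted", "voronoi")) {
      res <- tost_equivalence(grp[[m]], grp$truth, config)
      cells[[length(cells) + 1L]] <- data.frame(
        species = grp$species[1], phenotype = grp$phenotype[1],
        depth = grp$depth[1], method = m,
        p_value = res$p_value, equivalent = res$equivalent)
    }
  }
  cells <- do.call(rbind, cells)
  counts <- tapply(cells$equivalent, cells$method, sum)
  list(cells = cells, counts = counts,
       n_cells = nrow(cells) / 2L)
}

#' Run the full in-silico coring study
#'
#' Simulates replicate plots for every species x phenotype, extracts the six
#' located cores plus one random core per plot, computes whole-plot truth and
#' the unadjusted / Voronoi all-location estimates, then produces the TOST
#' equivalence matrix, per-depth ANOVA + Tukey, depth metrics, subset
#' rankings against both references, resampling power curves, and the QDA
#' training-size tables.  All tables are written as CSV (plus a JSON
#' manifest) when `config$outdir` is set; outputs are byte-reproducible for a
#' fixed config and seed.
#'
#' @param config An [study_config()].
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "rc_study_config"))
  bins <- config$depth_bins
  labs <- bin_labels(bins)
  arms <- list()
  arm_i <- 0L
  for (sp in config$species) for (ph in config$phenotypes) {
    arm_i <- arm_i + 1L
    arms[[paste(sp, ph, sep = ".")]] <-
      simulate_arm(sp, ph, config$n_replicates,
                   config$seed + 100000L * arm_i, bins)
  }
  layouts <- lapply(setNames(nm = config$species), default_layout)
  w_all <- lapply(layouts, voronoi_weights)

  core_tab <- list(); whole_tab <- list(); est_tab <- list()
  dp_tab <- list()
  for (a in arms) {
    lay <- layouts[[a$species]]
    n <- nrow(a$whole)
    for (i in seq_len(n)) {
      for (j in seq_along(a$locations)) {
        core_tab[[length(core_tab) + 1L]] <- data.frame(
          species = a$species, phenotype = a$phenotype, replicate = i,
          location = a$locations[j], depth_top_cm = bins[-length(bins)],
          depth_bottom_cm = bins[-1L], root_length_cm = a$rl[i, , j],
          rld_cm_cm3 = a$rld[i, , j])
      }
      core_tab[[length(core_tab) + 1L]] <- data.frame(
        species = a$species, phenotype = a$phenotype, replicate = i,
        location = "random", depth_top_cm = bins[-length(bins)],
        depth_bottom_cm = bins[-1L], root_length_cm = a$random_rl[i, ],
        rld_cm_cm3 = a$random_rld[i, ])
      whole_tab[[length(whole_tab) + 1L]] <- data.frame(
        species = a$species, phenotype = a$phenotype, replicate = i,
        depth_top_cm = bins[-length(bins)], depth_bottom_cm = bins[-1L],
        rld_cm_cm3 = a$whole[i, ])
    }
    w <- w_all[[a$species]]$w
    vor <- matrix(0, n, length(labs))
    for (j in seq_along(a$locations))
      vor <- vor + a$rld[, , j, drop = TRUE] * w[[a$locations[j]]]
    unadj <- apply(a$rld, c(1, 2), mean)
    for (i in seq_len(n)) {
      est_tab[[length(est_tab) + 1L]] <- data.frame(
        species = a$species, phenotype = a$phenotype, replicate = i,
        depth = labs, truth = a$whole[i, ], unadjusted = unadj[i, ],
        voronoi = vor[i, ])
    }
    # depth metrics per core and for truth
    for (p in config$metric_ps) {
      for (j in seq_along(a$locations)) {
        vals <- apply(a$rl[, , j, drop = TRUE], 1, function(v)
          if (sum(v) > 0) depth_quantile(v, p, bins) else NA_real_)
        dp_tab[[length(dp_tab) + 1L]] <- data.frame(
          species = a$species, phenotype = a$phenotype,
          location = a$locations[j], replicate = seq_len(n), p = p,
          value = vals)
      }
      rnd_vals <- apply(a$random_rl, 1, function(v)
        if (sum(v) > 0) depth_quantile(v, p, bins) else NA_real_)
      dp_tab[[length(dp_tab) + 1L]] <- data.frame(
        species = a$species, phenotype = a$phenotype, location = "random",
        replicate = seq_len(n), p = p, value = rnd_vals)
      dp_tab[[length(dp_tab) + 1L]] <- data.frame(
        species = a$species, phenotype = a$phenotype, location = "whole_plot",
        replicate = seq_len(n), p = p,
        value = apply(a$whole, 1, depth_quantile, p = p, depth_bins = bins))
    }
  }
  core_samples <- do.call(rbind, core_tab)
  whole_profiles <- do.call(rbind, whole_tab)
  estimates <- do.call(rbind, est_tab)
  depth_metrics <- do.call(rbind, dp_tab)

  tost <- tost_equivalence_matrix(estimates, config$tost)

  # per-depth ANOVA + Tukey on whole-plot and Voronoi estimates
  anova_tab <- list()
  for (sp in config$species) {
    for (m in c("truth", "voronoi")) {
      sub <- estimates[estimates$species == sp, ]
      if (length(unique(sub$phenotype)) < 2) next
      res <- anova_tukey_by_depth(data.frame(
        rld = sub[[m]], phenotype = sub$phenotype, depth = sub$depth))
      for (d in names(res$by_depth)) {
        pr <- res$by_depth[[d]]$pairs
        anova_tab[[length(anova_tab) + 1L]] <- data.frame(
          species = sp, method = if (m == "truth") "whole_plot" else m,
          depth = d, pair = pr$pair, diff = pr$diff, p_adj = pr$p_adj,
          significant = pr$significant)
      }
    }
  }
  anova_tukey_tab <- if (length(anova_tab)) do.call(rbind, anova_tab) else NULL

  # subset rankings against both references, both methods
  rank_tab <- list()
  for (sp in config$species) {
    cache <- new.env(parent = emptyenv())
    lay <- layouts[[sp]]
    for (ph in config$phenotypes) {
      a <- arms[[paste(sp, ph, sep = ".")]]
      w <- w_all[[sp]]$w
      vor_ref <- matrix(0, nrow(a$whole), length(labs))
      for (j in seq_along(a$locations))
        vor_ref <- vor_ref + a$rld[, , j, drop = TRUE] * w[[a$locations[j]]]
      for (ref in c("whole_plot", "voronoi_all6")) {
        refm <- if (ref == "whole_plot") a$whole else vor_ref
        for (m in c("unadjusted", "voronoi")) {
          r <- evaluate_subsets(a$rld, refm, lay, m, config$subset_sizes,
                                weight_cache = cache)
          r$species <- sp; r$phenotype <- ph; r$reference <- ref
          rank_tab[[length(rank_tab) + 1L]] <- as.data.frame(r)
        }
      }
    }
  }
  subset_ranking <- do.call(rbind, rank_tab)

  # resampling power curves per location and metric
  power_tab <- list()
  if (length(config$phenotypes) >= 2) {
    pow_i <- 0L
    for (sp in config$species) {
      locs <- c(names(layouts[[sp]]$locations), "random")
      for (loc in locs) for (p in config$metric_ps) {
        pools <- lapply(setNames(nm = config$phenotypes), function(ph) {
          dm <- depth_metrics
          v <- dm$value[dm$species == sp & dm$phenotype == ph &
                          dm$location == loc & dm$p == p]
          v
        })
        if (any(vapply(pools, function(v) sum(!is.na(v)) < 2, TRUE))) next
        pow_i <- pow_i + 1L
        pc <- with_seed(config$seed + 900000L + pow_i,
                        resampling_power(pools, config$power_n,
                                         config$power_reps,
                                         metric_p = p, location_id = loc))
        power_tab[[length(power_tab) + 1L]] <- data.frame(
          species = sp, location = loc, p = p, n = pc$n,
          proportion_significant = pc$proportion_significant)
      }
    }
  }
  power_curves <- if (length(power_tab)) do.call(rbind, power_tab) else NULL

  # QDA training-size sweep per location (mid-row locations typically
  # rank-deficient, mirroring the study's exclusion of 4 and 5)
  qda_tab <- list()
  if (length(config$phenotypes) >= 2) {
    n_test <- min(50L, config$n_replicates %/% 2L)
    pool <- config$n_replicates - n_test
    # training sets must fit the pool and exceed the feature dimension
    sizes <- config$qda_training_sizes[config$qda_training_sizes <= pool &
                                         config$qda_training_sizes > length(labs)]
    class_sets <- list(three = config$phenotypes)
    if (all(c("shallow", "deep") %in% config$phenotypes))
      class_sets$two <- c("shallow", "deep")
    class_sets <- Filter(function(s) length(s) >= 2, class_sets)
    qda_i <- 0L
    for (sp in config$species) {
      for (loc in names(layouts[[sp]]$locations)) {
        feats <- lapply(setNames(nm = config$phenotypes), function(ph)
          arms[[paste(sp, ph, sep = ".")]]$rld[, , loc, drop = TRUE])
        for (cs_name in names(class_sets)) {
          cls <- class_sets[[cs_name]]
          qda_i <- qda_i + 1L
          if (length(sizes) == 0) next
          sw <- qda_experiment(feats[cls], sizes, n_test = n_test,
                               n_repeats = config$qda_repeats,
                               seed = config$seed + 800000L + qda_i,
                               location_id = loc,
                               on_rank_deficiency = "skip")
          if (is.null(sw)) {
            qda_tab[[length(qda_tab) + 1L]] <- data.frame(
              species = sp, classes = length(cls), location = loc,
              training_size = NA_real_, misclassification = NA_real_,
              se = NA_real_, status = "rank_deficient")
          } else {
            qda_tab[[length(qda_tab) + 1L]] <- data.frame(
              species = sp, classes = length(cls), location = loc,
              training_size = sw$training_size,
              misclassification = sw$misclassification, se = sw$se,
              status = "ok")
          }
        }
      }
    }
  }
  qda_table <- if (length(qda_tab)) do.call(rbind, qda_tab) else NULL

  manifest <- list(
    config = list(species = config$species, phenotypes = config$phenotypes,
                  n_replicates = config$n_replicates,
                  subset_sizes = config$subset_sizes, seed = config$seed,
                  tost = unclass(config$tost),
                  qda_training_sizes = config$qda_training_sizes,
                  qda_repeats = config$qda_repeats,
                  power_reps = config$power_reps,
                  power_n = config$power_n, metric_ps = config$metric_ps,
                  depth_bins = config$depth_bins),
    voronoi_weights = lapply(w_all, function(w)
      list(subset = w$subset, w = as.list(w$w), areas = as.list(w$areas))),
    tost_counts = as.list(tost$counts),
    arm_seeds = lapply(arms, `[[`, "seeds"))

  out <- list(core_samples = core_samples, whole_profiles = whole_profiles,
              estimates = estimates, depth_metrics = depth_metrics,
              tost = tost, anova_tukey = anova_tukey_tab,
              subset_ranking = subset_ranking, power_curves = power_curves,
              qda_table = qda_table, weights = w_all, manifest = manifest)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) if (!is.null(df))
      utils::write.csv(df, file.path(config$outdir, name), row.names = FALSE)
    wr(core_samples, "core_samples.csv")
    wr(whole_profiles, "whole_plot_profiles.csv")
    wr(estimates, "rld_estimates.csv")
    wr(tost$cells, "tost_matrix.csv")
    wr(anova_tukey_tab, "anova_tukey.csv")
    wr(depth_metrics, "depth_metrics.csv")
    wr(subset_ranking, "subset_ranking.csv")
    wr(power_curves, "power_curves.csv")
    wr(qda_table, "qda_table.csv")
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Read a core-sample table (simulated or field) from CSV
#'
#' Schema: `species, phenotype, replicate, location, depth_top_cm,
#' depth_bottom_cm, root_length_cm, rld_cm_cm3` — the same schema
#' [write_core_table()] emits and the format field coring data should be
#' shaped into.  Validates column presence, non-negative lengths and
#' contiguous depth bins per core; malformed rows are reported with their
#' line numbers.
#'
#' @param path CSV path.
#' @param diameter Core diameter (cm) used to check RLD consistency; checked
#'   only when consistent within 1% (field tables may use other volumes).
#' @return A data.frame of validated rows (class `rc_core_table`), with one
#'   `rc_core` per species/phenotype/replicate/location retrievable via
#'   [core_table_to_cores()].
#' @export
read_core_table <- function(path, diameter = 4.4) {
  need <- c("species", "phenotype", "replicate", "location", "depth_top_cm",
            "depth_bottom_cm", "root_length_cm", "rld_cm_cm3")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(tab))
  stop_if(length(missing) > 0,
          paste("missing column(s):", paste(missing, collapse = ", ")))
  bad <- which(!is.finite(tab$root_length_cm) | tab$root_length_cm < 0)
  stop_if(length(bad) > 0,
          paste("negative or non-finite root_length_cm at data row(s):",
                paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!is.finite(tab$rld_cm_cm3) | tab$rld_cm_cm3 < 0)
  stop_if(length(bad) > 0,
          paste("negative or non-finite rld_cm_cm3 at data row(s):",
                paste(utils::head(bad, 5), collapse = ", ")))
  key <- interaction(tab$species, tab$phenotype, tab$replicate, tab$location,
                     drop = TRUE)
  for (grp in split(seq_len(nrow(tab)), key)) {
    o <- grp[order(tab$depth_top_cm[grp])]
    tops <- tab$depth_top_cm[o]; bots <- tab$depth_bottom_cm[o]
    ok <- tops[1] == 0 && all(bots > tops) &&
      (length(o) < 2 || all(abs(tops[-1] - bots[-length(bots)]) < 1e-9))
    stop_if(!ok, paste("non-contiguous depth bins in core at data row(s):",
                       paste(grp, collapse = ", ")))
  }
  structure(tab, class = c("rc_core_table", "data.frame"),
            diameter = diameter)
}

#' Convert a validated core table into `rc_core` objects
#' @param tab An [read_core_table()] result.
#' @return Named list of `rc_core` (name `species.phenotype.replicate.location`).
#' @export
core_table_to_cores <- function(tab) {
  stopifnot(inherits(tab, "rc_core_table"))
  key <- interaction(tab$species, tab$phenotype, tab$replicate, tab$location,
                     drop = TRUE, sep = ".")
  lapply(split(as.data.frame(tab), key), function(g) {
    g <- g[order(g$depth_top_cm), ]
    breaks <- c(g$depth_top_cm, g$depth_bottom_cm[nrow(g)])
    structure(list(location_id = g$location[1], replicate_id = g$replicate[1],
                   species = g$species[1], phenotype = g$phenotype[1],
                   depth_bins = breaks,
                   root_length_by_bin = g$root_length_cm,
                   rld_by_bin = g$rld_cm_cm3, spec = NULL),
              class = "rc_core")
  })
}

#' Write core samples in the standard CSV schema
#' @param cores List of `rc_core` objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_core_table <- function(cores, path) {
  rows <- lapply(cores, function(co) {
    bins <- co$depth_bins
    data.frame(species = co$species %||% NA, phenotype = co$phenotype %||% NA,
               replicate = co$replicate_id %||% NA,
               location = as.character(co$location_id),
               depth_top_cm = bins[-length(bins)], depth_bottom_cm = bins[-1L],
               root_length_cm = co$root_length_by_bin,
               rld_cm_cm3 = co$rld_by_bin)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
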