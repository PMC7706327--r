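test_that("simulate_plot is deterministic and conserves the budget", {
  cfg <- small_config()
  a <- simulate_plot(cfg, seed = 11)
  b <- simulate_plot(cfg, seed = 11)
  expect_identical(a$segments, b$segments)
  expect_equal(total_root_length(a), a$budget_consumed, tolerance = 1e-6)
  expect_equal(a$budget_consumed, 4 * cfg$elongation_budget)

  # segment length equals endpoint distance
  s <- a$segments
  d <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2 + (s$z1 - s$z0)^2)
  expect_equal(d, s$length_cm, tolerance = 1e-9)

  # depth bounds: nothing above the surface or below max_depth
  expect_true(all(s$z0 >= 0 & s$z1 >= 0))
  expect_true(all(pmax(s$z0, s$z1) <= cfg$max_depth))
})

test_that("config validation rejects bad parameters", {
  expect_error(sim_config("maize", step_length = 0), "step_length")
  expect_error(sim_config("maize", elongation_budget = -5), "budget")
  expect_error(sim_config("maize", gravitropism_rate = -1))
  expect_error(sim_config("maize", max_depth = 30), "max_depth")
})

test_that("degenerate geometry: no noise, no laterals, infinite gravitropism", {
  cfg <- sim_config("maize", "intermediate", elongation_budget = 1000,
                    branching_frequency = 0, tip_deflection_sd = 0,
                    gravitropism_rate = 1e9, stochastic_cv = 0)
  p <- simulate_plot(cfg, seed = 3)
  s <- p$segments
  # every step vertical: x/y constant along each segment
  expect_equal(s$x0, s$x1, tolerance = 1e-9)
  expect_equal(s$y0, s$y1, tolerance = 1e-9)
  # all mass in the columns under the plants (within the emergence crown)
  px <- p$plant_positions[, 1]; py <- p$plant_positions[, 2]
  dmin <- vapply(seq_len(nrow(s)), function(i)
    min(sqrt((s$x0[i] - px)^2 + (s$y0[i] - py)^2)), numeric(1))
  expect_true(all(dmin <= 3 + 1e-9))  # max crown radius

  # a core centred on a plant sees them; one far away (mid-cell) sees nothing
  on_plant <- extract_core(p, core_spec(c(0, 0), location_id = 1))
  expect_gt(sum(on_plant$root_length_by_bin), 0)
  off <- extract_core(p, core_spec(c(20, 8), location_id = "x"))
  expect_equal(sum(off$root_length_by_bin), 0)
})

test_that("zero elongation budget yields an empty plot handled downstream", {
  p <- simulate_plot(sim_config("bean", elongation_budget = 0), seed = 1)
  expect_equal(nrow(p$segments), 0L)
  expect_error(whole_plot_profile(p), "zero total root length")
})

test_that("study_ensemble reproduces seeds and warns on duplicates", {
  cfg <- small_config("bean", "shallow")
  expect_warning(e1 <- study_ensemble(cfg, 2, c(5, 5)), "duplicate")
  expect_identical(e1[[1]]$segments, e1[[2]]$segments)
  e2 <- study_ensemble(cfg, 3, c(1, 2, 3))
  e3 <- study_ensemble(cfg, 3, c(1, 2, 3))
  for (i in 1:3) expect_identical(e2[[i]]$segments, e3[[i]]$segments)
  expect_error(study_ensemble(cfg, 1, 1), "n_replicates")

  # between-replicate variance of location-wise core RL is positive at the
  # full study density (mid-row cores are empty at toy densities)
  lay <- default_layout("bean")
  e4 <- study_ensemble(sim_config("bean", "shallow"), 3, c(21, 22, 23))
  rl <- sapply(e4, function(p)
    sapply(names(lay$locations), function(id)
      sum(extract_core(p, core_spec(lay$locations[[id]],
                                    location_id = id))$root_length_by_bin)))
  expect_true(all(apply(rl, 1, var) > 0))
})

test_that("phenotype angle offsets shift mass downward (both species)", {
  # increasing emergence angle toward horizontal raises topsoil RLD
  n <- 12
  for (sp in c("maize", "bean")) {
    top <- sapply(c("shallow", "intermediate", "deep"), function(ph) {
      mean(sapply(seq_len(n), function(i)
        whole_plot_profile(simulate_plot(small_config(sp, ph),
                                         seed = 400 + i))$rld_by_bin[1]))
    })
    expect_true(top["shallow"] > top["intermediate"])
    expect_true(top["intermediate"] > top["deep"])
  }
})

test_that("segments CSV round-trips with a config sidecar", {
  p <- small_plot(seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(p, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(p$segments))
  expect_equal(back$length_cm, p$segments$length_cm)
  cfg <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(cfg$species, "maize")
  expect_equal(cfg$seed, 9)
})
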