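test_that("default layouts place the six study locations", {
  m <- default_layout("maize")
  expect_equal(m$locations[["3"]], c(5, 0))        # 5 cm from plant base
  expect_equal(m$locations[["5"]], c(38, 11.5))    # (R/2, P/2)
  expect_equal(m$locations[["4"]], c(38, 0))
  b <- default_layout("bean")
  expect_equal(b$locations[["2"]], c(0, 5))
  expect_equal(b$locations[["1"]], m$locations[["1"]])  # between-row shared
  # bean locations 4 and 5 nearly coincide (5 cm apart)
  expect_equal(sqrt(sum((b$locations[["4"]] - b$locations[["5"]])^2)), 5)
  # 2016 field protocol drops bean location 4
  expect_false("4" %in% names(default_layout("bean", field_2016 = TRUE)$locations))
  expect_error(default_layout("wheat"))
})

test_that("symmetry expansion wraps images into the unit cell", {
  lay <- default_layout("maize")
  # corner location: all four images collapse to one wrapped point
  e5 <- expand_by_symmetry(lay, "5")
  expect_equal(nrow(e5), 1L)
  # on-axis location: two images at +-x
  e3 <- expand_by_symmetry(lay, "3")
  expect_setequal(e3$x, c(5, -5))
  expect_equal(e3$y, c(0, 0))
  # all images of all locations lie inside the cell
  all6 <- expand_by_symmetry(lay)
  expect_true(all(all6$x >= -38 & all6$x < 38))
  expect_true(all(all6$y >= -11.5 & all6$y < 11.5))
  expect_error(expand_by_symmetry(lay, character(0)), "non-empty")
  expect_error(expand_by_symmetry(lay, "9"), "unknown")
})

test_that("voronoi weights: normalisation, area conservation, symmetry", {
  lay <- default_layout("maize")
  w1 <- voronoi_weights(lay, "3")
  expect_equal(unname(w1$w), 1)

  # two locations mirror-symmetric in the cell share the area equally
  w2 <- voronoi_weights(lay, c("2", "3"))
  # (not mirror-symmetric; use explicit symmetric pair instead)
  sym <- default_layout("maize")
  sym$locations <- list(a = c(10, 0), b = c(28, 0))  # images make +-10, +-28
  wsym <- voronoi_weights(sym, c("a", "b"))
  expect_equal(unname(wsym$w), c(0.5, 0.5), tolerance = 1e-9)

  for (w in list(w1, w2, voronoi_weights(lay))) {
    expect_true(all(w$w >= 0))
    expect_equal(sum(w$w), 1, tolerance = 1e-9)
    expect_equal(sum(w$areas), 76 * 23, tolerance = 76 * 23 * 1e-3)
    expect_equal(unname(w$w), unname(w$areas / sum(w$areas)))
  }

  # coincident distinct locations are an error
  bad <- default_layout("maize")
  bad$locations$dup <- bad$locations[["3"]]
  expect_error(voronoi_weights(bad, c("3", "dup")), "coincident")
})

test_that("voronoi weights match the 1 mm rasterization oracle", {
  for (sp in c("maize", "bean")) {
    lay <- default_layout(sp)
    w <- voronoi_weights(lay)
    ref <- raster_weights(lay)
    expect_equal(unname(w$w[names(ref)]), unname(ref), tolerance = 0.005)
    sub <- c("1", "3", "6")
    wsub <- voronoi_weights(lay, sub)
    refsub <- raster_weights(lay, sub)
    expect_equal(unname(wsub$w[names(refsub)]), unname(refsub),
                 tolerance = 0.005)
  }
})

test_that("adding a location never increases another's area", {
  lay <- default_layout("maize")
  a4 <- voronoi_weights(lay, c("2", "3"))$areas
  a5 <- voronoi_weights(lay, c("2", "3", "5"))$areas
  expect_lte(a5[["2"]], a4[["2"]] + 1e-9)
  expect_lte(a5[["3"]], a4[["3"]] + 1e-9)
})

test_that("estimate_rld and unadjusted_mean follow their algebra", {
  lay <- default_layout("maize")
  bins <- seq(0, 60, 10)
  pa <- rld_profile(rep(1, 6), bins)
  pb <- rld_profile(rep(2, 6), bins)
  w <- structure(list(subset = c("a", "b"), w = c(a = 0.25, b = 0.75),
                      areas = c(a = 437, b = 1311), cell_area = 1748),
                 class = "rc_weights")
  est <- estimate_rld(list(a = pa, b = pb), w)
  expect_equal(est$profile$rld_by_bin, rep(1.75, 6))
  expect_equal(est$method, "voronoi")

  # identical profiles: any valid weights return that profile
  est2 <- estimate_rld(list(a = pa, b = pa), w)
  expect_equal(est2$profile$rld_by_bin, pa$rld_by_bin)

  un <- unadjusted_mean(list(a = pa, b = pb))
  expect_equal(un$profile$rld_by_bin, rep(1.5, 6))
  expect_equal(unadjusted_mean(list(a = pa))$profile$rld_by_bin, pa$rld_by_bin)

  # equal weights reproduce the unadjusted mean exactly
  weq <- structure(list(subset = c("a", "b"), w = c(a = 0.5, b = 0.5),
                        areas = c(a = 874, b = 874), cell_area = 1748),
                   class = "rc_weights")
  expect_equal(estimate_rld(list(a = pa, b = pb), weq)$profile$rld_by_bin,
               un$profile$rld_by_bin)

  # estimator linearity per bin
  pc <- rld_profile(c(3, 0, 1, 2, 0.5, 0), bins)
  lin1 <- estimate_rld(list(a = rld_profile(2 * pa$rld_by_bin + 3 * pc$rld_by_bin, bins),
                            b = pb), w)$profile$rld_by_bin
  lin2 <- 2 * estimate_rld(list(a = pa, b = rld_profile(rep(0, 6), bins)), w)$profile$rld_by_bin +
    3 * estimate_rld(list(a = pc, b = rld_profile(rep(0, 6), bins)), w)$profile$rld_by_bin +
    estimate_rld(list(a = rld_profile(rep(0, 6), bins), b = pb), w)$profile$rld_by_bin
  expect_equal(lin1, lin2, tolerance = 1e-12)

  expect_error(estimate_rld(list(a = pa), w), "subset")
  expect_error(unadjusted_mean(list()), "at least one")
})
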