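test_that("antenna positions lie on the ring with even spacing", {
  scn <- scenario(background = glycerine_bg())
  p <- antenna_positions(scn)
  expect_equal(nrow(p), 8)
  expect_equal(sqrt(rowSums(p^2)), rep(0.065, 8), tolerance = 1e-12)
  ang <- atan2(p[, 2], p[, 1])
  gaps <- diff(ang[1:5])
  expect_equal(gaps, rep(pi / 4, 4), tolerance = 1e-12)
  expect_equal(p[1, ], c(x = 0.065, y = 0), tolerance = 1e-12)

  p2 <- antenna_positions(scenario(background = glycerine_bg(), n_antennas = 2))
  expect_equal(p2[1, ] + p2[2, ], c(x = 0, y = 0), tolerance = 1e-12)

  p16 <- antenna_positions(scenario(background = glycerine_bg(),
                                    n_antennas = 16, array_diam = 0.150))
  expect_equal(sqrt(rowSums(p16^2)), rep(0.075, 16), tolerance = 1e-12)
})

test_that("antenna set is invariant under rotation by one slot", {
  scn <- scenario(background = glycerine_bg())
  a <- antenna_positions(scn)
  scn$antenna_start_angle <- 2 * pi / 8
  b <- antenna_positions(scn)
  key <- function(m) sort(paste(round(m[, 1], 10), round(m[, 2], 10)))
  expect_equal(key(a), key(b))
})

test_that("the 2*beta*alpha antenna-count rule is honored", {
  vac <- debye_medium(1, 0, 1e-12, 0)
  expect_equal(suggest_num_antennas(vac, 1e9, 0.05),
               as.integer(ceiling(2 * (2 * pi * 1e9 / 299792458) * 0.05)))
  expect_equal(suggest_num_antennas(vac, 1e9, 0), 1L)
  # monotone in radius
  r <- seq(0.005, 0.1, by = 0.005)
  n <- vapply(r, function(ri) suggest_num_antennas(glycerine_bg(), 1.5e9, ri),
              integer(1))
  expect_true(all(diff(n) >= 0))
  expect_error(suggest_num_antennas(vac, -1, 0.05), class = "mwtomo_error")
})

test_that("scenario invariants are enforced", {
  bg <- glycerine_bg()
  expect_error(scenario(background = bg, array_diam = 0.25),
               class = "mwtomo_error")
  expect_error(scenario(background = bg, recon_ring_diam = 0.14),
               class = "mwtomo_error")
  expect_error(scenario(background = bg, n_antennas = 1),
               class = "mwtomo_error")
  # target crossing the reconstruction ring
  expect_error(scenario(background = bg,
                        targets = list(cylinder_target(c(0.055, 0), 0.016, bg))),
               class = "mwtomo_error")
})

test_that("rasterization covers disks with the right area", {
  bg <- glycerine_bg()
  tgt <- cylinder_target(c(0.015, 0.012), 0.016, get_material("water"))
  scn <- scenario(background = bg, targets = list(tgt))
  # no targets -> uniform background
  g <- scenario_grid(scn, 2e-3)
  pm0 <- rasterize(scenario(background = bg), g)
  expect_true(all(pm0$eps_inf == bg$eps_inf))
  expect_true(all(pm0$delta_eps == bg$delta_eps))
  # 16 mm disk at 2 mm pitch: cell count within +-15% of pi*8^2/2^2
  pm <- rasterize(scn, g)
  n_cells <- sum(pm$eps_inf != bg$eps_inf)
  expect_gt(n_cells, pi * 64 / 4 * 0.85)
  expect_lt(n_cells, pi * 64 / 4 * 1.15)
  # resolution consistency: count * dx^2 -> disk area as dx shrinks
  area <- pi * 0.008^2
  errs <- vapply(c(4e-3, 2e-3, 1e-3), function(dx) {
    gi <- scenario_grid(scn, dx)
    pmi <- rasterize(scn, gi)
    abs(sum(pmi$eps_inf != bg$eps_inf) * dx^2 - area) / area
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_true(errs[3] <= errs[1])
})

test_that("two disjoint targets rasterize locally", {
  bg <- glycerine_bg()
  wat <- get_material("water")
  t1 <- cylinder_target(c(0.02, 0.02), 0.016, wat)
  t2 <- cylinder_target(c(-0.02, -0.02), 0.016, wat)
  g <- scenario_grid(scenario(background = bg), 2e-3)
  p1 <- rasterize(scenario(background = bg, targets = list(t1)), g)
  p12 <- rasterize(scenario(background = bg, targets = list(t1, t2)), g)
  changed <- which(p12$eps_inf != p1$eps_inf, arr.ind = TRUE)
  ax <- grid_axes(g)
  d2 <- sqrt((ax$x[changed[, 1]] + 0.02)^2 + (ax$y[changed[, 2]] + 0.02)^2)
  expect_true(all(d2 <= 0.008 + 1e-12))
  # PEC targets set the mask, not the dielectric rasters
  pp <- rasterize(scenario(background = bg,
                           targets = list(cylinder_target(c(0.02, 0.02), 0.016, "PEC"))), g)
  expect_gt(sum(pp$pec), 0)
  expect_true(all(pp$eps_inf == bg$eps_inf))
})

test_that("scenario JSON round-trips including media and targets", {
  scn <- demo_scenario(two_targets = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(scn, path)
  scn2 <- read_scenario_json(path)
  expect_equal(scn2$array_diam, scn$array_diam)
  expect_equal(scn2$n_antennas, scn$n_antennas)
  expect_equal(length(scn2$targets), 2)
  expect_equal(scn2$targets[[1]]$center, scn$targets[[1]]$center)
  expect_equal(scn2$background$delta_eps, scn$background$delta_eps,
               tolerance = 1e-12)
  expect_equal(eval_debye(scn2$targets[[2]]$medium, 1.2e9),
               eval_debye(scn$targets[[2]]$medium, 1.2e9), tolerance = 1e-12)
})
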