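# forward-solver tests run at the 2 mm inversion resolution to stay fast;
# the fine-grid oracle comparison lives in the acceptance suite

test_that("pulse spectrum keeps the 0.5-3.5 GHz band edges above 10% of peak", {
  p <- pulse_spec()
  expect_gte(pulse_spectrum_ratio(p, 0.5e9), 0.1)
  expect_gte(pulse_spectrum_ratio(p, 3.5e9), 0.1)
  expect_equal(pulse_spectrum_ratio(p, p$center_freq), 1)
})

test_that("zero-amplitude pulse produces identically zero fields", {
  scn <- scenario(background = glycerine_bg(), n_antennas = 4)
  cfg <- sim_config(dx = 2e-3, max_steps = 600)
  props <- rasterize(scn, scenario_grid(scn, cfg$dx, cfg$pml_cells + 4))
  fs <- suppressWarnings(
    run_fdtd(props, scn, 1, pulse_spec(amplitude = 0), 1.5e9, cfg))
  expect_true(all(Mod(fs$probe) == 0))
})

test_that("probe values equal the field raster at the antenna cells", {
  scn <- scenario(background = glycerine_bg(), n_antennas = 4)
  cfg <- sim_config(dx = 2e-3)
  grid <- scenario_grid(scn, cfg$dx, cfg$pml_cells + 4)
  props <- rasterize(scn, grid)
  ant_cells <- mwtomo:::pos_to_cell(grid, antenna_positions(scn))
  fs <- run_fdtd(props, scn, 1, pulse_spec(), 1.5e9, cfg, cells = ant_cells)
  expect_equal(fs$cells[, 1], unname(fs$probe[, 1]), tolerance = 1e-15)
})

test_that("fieldset probe traces export as CSV", {
  scn <- scenario(background = glycerine_bg(), n_antennas = 4)
  cfg <- sim_config(dx = 2e-3)
  props <- rasterize(scn, scenario_grid(scn, cfg$dx, cfg$pml_cells + 4))
  fs <- cached("fs_4ant", run_fdtd(props, scn, 1, pulse_spec(), 1.5e9, cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fieldset_csv(fs, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 4)
  expect_equal(complex(real = df$re, imaginary = df$im),
               unname(fs$probe[, 1]), tolerance = 1e-15)
})

test_that("FDTD line-source field matches the analytic solution in lossy background", {
  # absolute comparison (amplitude and phase) through the exactly known
  # source current spectrum
  bg <- glycerine_bg()
  scn <- scenario(background = bg)
  cfg <- sim_config(dx = 2e-3)
  props <- rasterize(scn, scenario_grid(scn, cfg$dx, cfg$pml_cells + 4))
  freqs <- c(1.0e9, 2.0e9)
  fs <- run_fdtd(props, scn, 1, pulse_spec(), freqs, cfg)
  ant <- antenna_positions(scn)
  for (fi in seq_along(freqs)) {
    ana <- analytic_line_source_field(eval_debye(bg, freqs[fi]), freqs[fi],
                                      ant[1, ], ant[-1, ],
                                      current = fs$src_spectrum[fi])
    num <- fs$probe[-1, fi]
    expect_lt(sqrt(sum(Mod(num - ana)^2) / sum(Mod(ana)^2)), 0.05)
  }
})

test_that("an unstable time step is caught by the divergence guard", {
  # lossless background: heavy immersion-liquid loss would damp the
  # marginally unstable Nyquist mode
  scn <- scenario(background = debye_medium(1, 0, 1e-12, 0), n_antennas = 4)
  cfg <- sim_config(dx = 2e-3)
  cfg$courant <- 1.1  # bypass the constructor check to force instability
  props <- rasterize(scn, scenario_grid(scn, cfg$dx, cfg$pml_cells + 4))
  expect_error(suppressWarnings(run_fdtd(props, scn, 1, pulse_spec(), 1.5e9, cfg)),
               class = "mwtomo_divergence")
})

test_that("received signal strength follows the log law and ring symmetry", {
  ds <- empty_sweep_2mm()
  s <- received_signal_strength(ds, 1, 1.5e9)
  s10 <- received_signal_strength(scale_dataset(ds, 10), 1, 1.5e9)
  expect_equal(s10 - s, rep(20, 7), ignore_attr = TRUE, tolerance = 1e-10)
  # profile symmetric about the receiver opposite the transmitter
  expect_lt(max(abs(s[c("rx2", "rx3", "rx4")] - s[c("rx8", "rx7", "rx6")])), 0.5)
})

test_that("attenuation grows with frequency in 90% glycerine-water", {
  ds <- empty_sweep_2mm()
  s15 <- received_signal_strength(ds, 1, 1.5e9)
  s20 <- received_signal_strength(ds, 1, 2.0e9)
  expect_true(all(s20 < s15))
})

test_that("a PEC target blocks the receivers across from it", {
  bg <- glycerine_bg()
  cfg <- sim_config(dx = 2e-3)
  ds_e <- empty_sweep_2mm()
  scn_p <- scenario(background = bg,
                    targets = list(cylinder_target(c(0.015, 0.015), 0.016, "PEC")))
  ds_p <- cached("ds_pec_2mm", simulate_dataset(scn_p, 1.5e9, cfg))
  s_e <- received_signal_strength(ds_e, 1, 1.5e9)
  s_p <- received_signal_strength(ds_p, 1, 1.5e9)
  # tx1 sits at (65, 0) mm, the scatterer toward antennas 3-5
  expect_true(all((s_e - s_p)[c("rx3", "rx4", "rx5")] > 0.5))
})
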