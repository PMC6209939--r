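test_that("datasets enforce key uniqueness and transmission-only entries", {
  df <- data.frame(freq_hz = 1e9, tx = c(1, 1), rx = c(2, 2), re = 1, im = 0)
  expect_error(multistatic_dataset(df), class = "mwtomo_error")
  df2 <- data.frame(freq_hz = 1e9, tx = 1, rx = 1, re = 1, im = 0)
  expect_error(multistatic_dataset(df2), class = "mwtomo_error")
})

test_that("a zero-contrast target yields the empty-tank dataset", {
  bg <- glycerine_bg()
  cfg <- sim_config(dx = 2e-3)
  scn0 <- scenario(background = bg, n_antennas = 4)
  # "target" made of the background medium itself
  scn_null <- scenario(background = bg, n_antennas = 4,
                       targets = list(cylinder_target(c(0.015, 0.015), 0.016, bg)))
  d0 <- simulate_dataset(scn0, 1.5e9, cfg)
  d1 <- simulate_dataset(scn_null, 1.5e9, cfg)
  expect_equal(d1$entries, d0$entries, tolerance = 1e-14)
})

test_that("with-target changes are largest at receivers across from the target", {
  ds_e <- empty_sweep_2mm()
  scn_w <- scenario(background = glycerine_bg(),
                    targets = list(cylinder_target(c(0.015, 0.015), 0.016,
                                                   get_material("water"))))
  ds_w <- cached("ds_water_2mm", simulate_dataset(scn_w, 1.5e9, sim_config(dx = 2e-3)))
  e <- ds_e$entries[ds_e$entries$freq_hz == 1.5e9 & ds_e$entries$tx == 1, ]
  w <- ds_w$entries[ds_w$entries$tx == 1, ]
  dmag <- Mod(complex(real = w$re - e$re, imaginary = w$im - e$im))
  expect_gt(max(dmag), 0)
  # target toward antennas 3-5 as seen from tx 1
  expect_true(w$rx[which.max(dmag)] %in% 3:5)
})

test_that("receiver noise is calibrated to the dB floor and deterministic", {
  n_ant <- 4
  v <- complex(real = rep(1, n_ant * (n_ant - 1)), imaginary = 0)
  ds <- arith_dataset(v)
  expect_identical(add_noise(ds, -Inf, 1)$entries, ds$entries)
  a <- add_noise(ds, -40, seed = 123)
  b <- add_noise(ds, -40, seed = 123)
  expect_identical(a$entries, b$entries)
  # signal 40 dB above the floor -> ~1% relative RMS perturbation
  set.seed(99)
  draws <- vapply(1:1000, function(k) {
    nz <- add_noise(ds, -40, seed = k)
    mean(Mod(complex(real = nz$entries$re - 1, imaginary = nz$entries$im))^2)
  }, numeric(1))
  expect_equal(sqrt(mean(draws)), 0.01, tolerance = 0.05)
  # ensemble mean converges to the noiseless dataset
  res <- Reduce(`+`, lapply(1:400, function(k) {
    nz <- add_noise(ds, -40, seed = k)
    complex(real = nz$entries$re, imaginary = nz$entries$im)
  })) / 400
  expect_lt(max(Mod(res - v)), 0.01 * 5 / sqrt(400))
})

test_that("empty-tank calibration is exact under self-calibration", {
  set.seed(5)
  n <- 12
  model_e <- arith_dataset(complex(real = rnorm(n), imaginary = rnorm(n)))
  model_t <- arith_dataset(complex(real = rnorm(n), imaginary = rnorm(n)))
  cal <- calibrate(model_t, model_e, model_e)
  expect_equal(cal$entries$total,
               complex(real = model_t$entries$re, imaginary = model_t$entries$im),
               tolerance = 1e-14)
  expect_equal(cal$entries$scattered,
               complex(real = model_t$entries$re - model_e$entries$re,
                       imaginary = model_t$entries$im - model_e$entries$im),
               tolerance = 1e-14)
  expect_false(any(cal$entries$excluded))
})

test_that("calibration cancels a common per-channel port factor", {
  set.seed(6)
  n <- 12
  me <- arith_dataset(complex(real = rnorm(n), imaginary = rnorm(n)))
  mt <- arith_dataset(complex(real = rnorm(n), imaginary = rnorm(n)))
  mo <- arith_dataset(complex(real = rnorm(n), imaginary = rnorm(n)))
  cal0 <- calibrate(mt, me, mo)
  fac <- 3.7 - 2.1i
  cal1 <- calibrate(scale_dataset(mt, fac), scale_dataset(me, fac), mo)
  expect_equal(cal1$entries$total, cal0$entries$total, tolerance = 1e-12)
  expect_equal(cal1$entries$scattered, cal0$entries$scattered, tolerance = 1e-12)
})

test_that("near-zero empty-tank entries are excluded, not divided", {
  set.seed(8)
  n <- 12
  ve <- complex(real = rnorm(n), imaginary = rnorm(n))
  ve[3] <- 0
  me <- arith_dataset(ve)
  mt <- arith_dataset(complex(real = rnorm(n), imaginary = rnorm(n)))
  mo <- arith_dataset(complex(real = rnorm(n), imaginary = rnorm(n)))
  cal <- calibrate(mt, me, mo)
  expect_true(cal$entries$excluded[3])
  expect_identical(sum(cal$entries$excluded), 1L)
  # mismatched keys are an alignment error
  bad <- arith_dataset(ve[1:6], n_ant = 3)
  expect_error(calibrate(mt, bad, mo), class = "mwtomo_alignment_error")
})

test_that("dataset CSV round-trips losslessly with sidecar metadata", {
  set.seed(9)
  v <- complex(real = rnorm(12), imaginary = rnorm(12))
  ds <- add_noise(arith_dataset(v), -80, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  ds2 <- read_dataset_csv(path)
  expect_equal(ds2$entries$re, ds$entries$re, tolerance = 1e-15)
  expect_equal(ds2$entries$im, ds$entries$im, tolerance = 1e-15)
  expect_equal(ds2$metadata$noise_floor_db, -80)
  # tab-delimited variant reads too
  tabpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(ds$entries, tabpath, sep = "\t", row.names = FALSE)
  ds3 <- read_dataset_csv(tabpath)
  # write.table above prints 15 significant digits, hence the tolerance
  expect_equal(ds3$entries$re, ds$entries$re, tolerance = 1e-12)
  # malformed rows are rejected with line numbers
  lines <- readLines(path)
  lines[4] <- "1e9,1,2,notanumber,0"
  writeLines(lines, path)
  expect_error(read_dataset_csv(path), "line")
})
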