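#' Multistatic dataset
#'
#' Complex transmission values indexed by (frequency, transmitter,
#' receiver), the unit of measurement exchange. Monostatic (tx == rx)
#' entries are never stored: reflection data is dominated by antenna
#' internals the 2-D model cannot express.
#'
#' @param entries Data frame with columns `freq_hz`, `tx`, `rx`, `re`, `im`.
#' @param metadata Named list (noise floor, seed, reference amplitudes,
#'   with/without-target flag, provenance).
#' @return An object of class `multistatic_dataset`.
#' @export
multistatic_dataset <- function(entries, metadata = list()) {
  need <- c("freq_hz", "tx", "rx", "re", "im")
  if (!all(need %in% names(entries)))
    mwt_stop(paste("entries must have columns", paste(need, collapse = ",")))
  if (any(entries$tx == entries$rx))
    mwt_stop("monostatic (tx == rx) entries are not allowed")
  key <- paste(entries$freq_hz, entries$tx, entries$rx)
  if (anyDuplicated(key))
    mwt_stop("duplicate (freq, tx, rx) keys")
  structure(list(entries = entries[order(entries$freq_hz, entries$tx, entries$rx), ,
                                   drop = FALSE],
                 metadata = metadata),
            class = "multistatic_dataset")
}

#' @export
print.multistatic_dataset <- function(x, ...) {
  cat(sprintf("<multistatic_dataset> %d entries, %d frequencies, %d antennas%s\n",
              nrow(x$entries), length(unique(x$entries$freq_hz)),
              length(unique(c(x$entries$tx, x$entries$rx))),
              if (isTRUE(x$metadata$with_target)) ", with target" else ""))
  invisible(x)
}

dataset_values <- function(ds) complex(real = ds$entries$re, imaginary = ds$entries$im)

dataset_ref_amp <- function(ds, freq) {
  ref <- ds$metadata$ref
  if (is.null(ref)) return(1)
  i <- which.min(abs(ref$freq_hz - freq))
  if (abs(ref$freq_hz[i] - freq) > 0.5) return(1)
  ref$amp[i]
}

#' Scale every complex value of a dataset by a constant
#'
#' Emulates a common per-channel cable/port factor; used to demonstrate
#' calibration scale invariance.
#' @param ds A [multistatic_dataset()].
#' @param factor Complex scalar.
#' @export
scale_dataset <- function(ds, factor) {
  v <- dataset_values(ds) * factor
  ds$entries$re <- Re(v)
  ds$entries$im <- Im(v)
  ds
}

#' Simulate a full multistatic acquisition sweep
#'
#' Emulates the measurement campaign: every antenna transmits in turn and
#' all other antennas record, at each requested frequency, yielding
#' `n_antennas * (n_antennas - 1)` transmission entries per frequency.
#'
#' @param scn A [scenario()] (with or without targets).
#' @param freqs Frequencies in Hz.
#' @param config A [sim_config()].
#' @param pulse A [pulse_spec()].
#' @return A [multistatic_dataset()] with reference amplitudes (field one
#'   cell from the source, averaged over transmitters) in the metadata.
#' @export
simulate_dataset <- function(scn, freqs, config = sim_config(),
                             pulse = pulse_spec()) {
  grid <- scenario_grid(scn, config$dx, margin_cells = config$pml_cells + 4)
  props <- rasterize(scn, grid)
  n <- scn$n_antennas
  rows <- list()
  refs <- matrix(0, n, length(freqs))
  for (tx in seq_len(n)) {
    fs <- run_fdtd(props, scn, tx, pulse, freqs, config)
    refs[tx, ] <- Mod(fs$ref)
    for (fi in seq_along(freqs)) {
      rx <- setdiff(seq_len(n), tx)
      v <- fs$probe[rx, fi]
      rows[[length(rows) + 1L]] <-
        data.frame(freq_hz = freqs[fi], tx = tx, rx = rx,
                   re = Re(v), im = Im(v))
    }
  }
  entries <- do.call(rbind, rows)
  multistatic_dataset(entries, metadata = list(
    with_target = length(scn$targets) > 0,
    n_antennas = n,
    dx = config$dx,
    ref = data.frame(freq_hz = freqs, amp = colMeans(refs))))
}

#' Add receiver noise at a given noise floor
#'
#' Adds complex circular Gaussian noise whose RMS amplitude corresponds to
#' the dB noise floor on the dataset's own dB scale (referenced to the
#' stored per-frequency reference amplitude). Deterministic under a fixed
#' seed; `-Inf` leaves the dataset unchanged.
#'
#' @param ds A [multistatic_dataset()].
#' @param noise_floor_db Noise floor in dB (e.g. -100).
#' @param seed Integer RNG seed.
#' @return The noisy dataset; metadata records floor and seed.
#' @export
add_noise <- function(ds, noise_floor_db, seed) {
  stopifnot(inherits(ds, "multistatic_dataset"))
  ds$metadata$noise_floor_db <- noise_floor_db
  ds$metadata$noise_seed <- seed
  if (identical(noise_floor_db, -Inf)) return(ds)
  n <- nrow(ds$entries)
  rms <- vapply(ds$entries$freq_hz, function(f)
    dataset_ref_amp(ds, f) * 10^(noise_floor_db / 20), numeric(1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ds$entries$re <- ds$entries$re + stats::rnorm(n, 0, rms / sqrt(2))
  ds$entries$im <- ds$entries$im + stats::rnorm(n, 0, rms / sqrt(2))
  ds
}

#' Empty-tank calibration
#'
#' Maps measured data into the forward model's frame with the standard
#' multiplicative per-channel procedure: for each (freq, tx, rx),
#' calibrated total = (measured_with_target / measured_empty) x
#' model_empty, and calibrated scattered = calibrated total - model_empty.
#' The per-channel port factors the 2-D model cannot express cancel in the
#' ratio, which is what makes the empty-tank reference meaningful.
#' Entries whose empty-tank magnitude falls below the floor threshold are
#' flagged and excluded rather than divided.
#'
#' @param measured_with_target,measured_empty,model_empty
#'   [multistatic_dataset()]s sharing identical (freq, tx, rx) keys.
#' @param empty_floor Magnitude threshold below which an empty-tank entry
#'   is considered unusable; default `1e-10 * max |measured_empty|`.
#' @return An object of class `calibrated_data`: data frame with the key
#'   columns, complex `total` and `scattered`, and logical `excluded`.
#' @export
calibrate <- function(measured_with_target, measured_empty, model_empty,
                      empty_floor = NULL) {
  key <- function(d) paste(d$entries$freq_hz, d$entries$tx, d$entries$rx)
  k1 <- key(measured_with_target); k2 <- key(measured_empty); k3 <- key(model_empty)
  if (!identical(k1, k2) || !identical(k1, k3))
    mwt_stop("the three datasets must share identical (freq, tx, rx) keys",
             class = "mwtomo_alignment_error")
  mt <- dataset_values(measured_with_target)
  me <- dataset_values(measured_empty)
  mo <- dataset_values(model_empty)
  if (is.null(empty_floor)) empty_floor <- 1e-10 * max(Mod(me))
  excluded <- Mod(me) <= empty_floor
  total <- rep(NA_complex_, length(mt))
  total[!excluded] <- mt[!excluded] / me[!excluded] * mo[!excluded]
  scattered <- total - mo
  out <- measured_with_target$entries[, c("freq_hz", "tx", "rx")]
  out$total <- total
  out$scattered <- scattered
  out$excluded <- excluded
  structure(list(entries = out, model_empty = model_empty,
                 metadata = list(
                   empty_floor = empty_floor,
                   noise_floor_db = measured_with_target$metadata$noise_floor_db,
                   ref = model_empty$metadata$ref)),
            class = "calibrated_data")
}

#' Read / write multistatic datasets as CSV
#'
#' CSV columns `freq_hz,tx,rx,re,im` (comma- or tab-delimited on read) with
#' a sidecar JSON metadata file at `<path>.meta.json`. Malformed rows are
#' rejected with line-numbered diagnostics.
#'
#' @param ds A [multistatic_dataset()].
#' @param path CSV file path.
#' @return `read_dataset_csv` returns a [multistatic_dataset()].
#' @export
write_dataset_csv <- function(ds, path) {
  out <- ds$entries
  # full double precision so write -> read is lossless
  out$re <- sprintf("%.17g", out$re)
  out$im <- sprintf("%.17g", out$im)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- ds$metadata
  if (!is.null(meta$ref)) meta$ref <- as.list(meta$ref)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("freq_hz", "tx", "rx", "re", "im")
  if (!all(need %in% names(raw)))
    mwt_stop(paste("dataset CSV must have columns", paste(need, collapse = ",")))
  df <- data.frame(lapply(raw[need], function(col) suppressWarnings(as.numeric(col))))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    mwt_stop(sprintf("malformed dataset rows at line(s): %s",
                     paste(bad + 1L, collapse = ", ")))
  meta_path <- paste0(path, ".meta.json")
  metadata <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  if (!is.null(metadata$ref)) metadata$ref <- as.data.frame(metadata$ref)
  multistatic_dataset(df, metadata = metadata)
}
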