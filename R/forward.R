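#' Excitation pulse specification
#'
#' Gaussian-modulated sine line-current pulse. The default (center 2 GHz,
#' Gaussian width 0.30 ns) keeps the spectral amplitude at the 0.5 and
#' 3.5 GHz band edges above 10% of the peak, covering the full acquisition
#' band.
#'
#' @param center_freq Modulation frequency, Hz.
#' @param width Gaussian 1/e half-width in seconds.
#' @param delay Pulse delay in seconds (default `4 * width`).
#' @param amplitude Peak current in amperes.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(center_freq = 2.0e9, width = 0.30e-9,
                       delay = 4 * width, amplitude = 1) {
  if (center_freq <= 0 || width <= 0) mwt_stop("center_freq and width must be > 0")
  edge <- exp(-(pi * width * 1.5e9)^2)  # band edges sit 1.5 GHz from center
  structure(list(center_freq = center_freq, width = width, delay = delay,
                 amplitude = amplitude, band_edge_ratio = edge),
            class = "pulse_spec")
}

#' Relative spectral amplitude of a pulse
#' @param pulse A [pulse_spec()].
#' @param freq Frequencies in Hz.
#' @return Spectral magnitude relative to the peak (at `center_freq`).
#' @export
pulse_spectrum_ratio <- function(pulse, freq) {
  exp(-(pi * pulse$width * (freq - pulse$center_freq))^2)
}

pulse_waveform <- function(pulse, t) {
  arg <- (t - pulse$delay) / pulse$width
  pulse$amplitude * sin(2 * pi * pulse$center_freq * (t - pulse$delay)) *
    exp(-arg^2)
}

#' Forward-solver configuration
#'
#' @param dx Cell size in meters (default 1 mm for data generation; the
#'   inversion uses 2 mm, avoiding the inverse crime).
#' @param pml_cells CPML thickness in cells.
#' @param courant Fraction of the 2-D stability limit \eqn{dx/(c\sqrt{2})}.
#' @param conv_tol Trailing-field threshold (fraction of the running peak)
#'   below which the run is declared converged.
#' @param max_steps Hard cap on time steps (`NULL`: auto from geometry).
#' @param check_every Steps between convergence checks.
#' @param kappa_max,alpha_max,sigma_factor CPML grading parameters
#'   (polynomial order 3; `sigma_factor` scales the textbook optimum).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dx = 1e-3, pml_cells = 10, courant = 0.9,
                       conv_tol = 1e-5, max_steps = NULL, check_every = 128,
                       kappa_max = 1, alpha_max = 0.15, sigma_factor = 0.8) {
  if (courant <= 0 || courant >= 1) mwt_stop("courant must be in (0, 1)")
  structure(list(dx = dx, pml_cells = pml_cells, courant = courant,
                 conv_tol = conv_tol, max_steps = max_steps,
                 check_every = check_every, kappa_max = kappa_max,
                 alpha_max = alpha_max, sigma_factor = sigma_factor),
            class = "sim_config")
}

#' Map positions to nearest grid nodes
#' @keywords internal
pos_to_cell <- function(grid, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  cbind(i = as.integer(round((pos[, 1] - grid$origin[1]) / grid$dx)) + 1L,
        j = as.integer(round((pos[, 2] - grid$origin[2]) / grid$dx)) + 1L)
}

#' Run the 2-D FDTD forward solver for one source antenna
#'
#' TM-polarized (Ez) FDTD with single-pole Debye dispersion via the
#' auxiliary-differential-equation method, CPML absorbing boundaries, a
#' soft additive line-current source at the transmitting antenna cell, and
#' a running DFT that extracts steady-state phasors at every antenna probe
#' (plus a reference node one cell from the source) and, optionally, at an
#' arbitrary set of cells. The run auto-extends until the trailing field
#' energy falls below `conv_tol` of its peak; a non-converged run carries a
#' warning flag, a diverging one raises an error.
#'
#' @param props A [rasterize()]d `property_map`.
#' @param scn The [scenario()] (for antenna positions).
#' @param source_index Transmitting antenna (1-based).
#' @param pulse A [pulse_spec()].
#' @param freqs DFT frequencies in Hz.
#' @param config A [sim_config()].
#' @param cells Optional integer matrix (i, j) of cells whose DFT fields
#'   are returned (used by the inversion).
#' @return An object of class `dft_fieldset`: `probe` (antennas x freqs
#'   complex), `ref` (complex, per freq, one cell from the source),
#'   `cells`, `src_spectrum`, `converged`, `steps`, plus grid metadata.
#' @export
run_fdtd <- function(props, scn, source_index, pulse, freqs,
                     config = sim_config(), cells = NULL) {
  stopifnot(inherits(props, "property_map"), inherits(scn, "mwt_scenario"),
            inherits(pulse, "pulse_spec"))
  grid <- props$grid
  dx <- grid$dx
  dt <- config$courant * dx / (C0 * sqrt(2))

  # resolution precondition: >= 10 cells per shortest background wavelength
  fmax <- max(freqs)
  eps_bg <- Re(eval_debye(scn$background, fmax))
  lam_min <- C0 / (fmax * sqrt(eps_bg))
  if (lam_min / dx < 10)
    warning(sprintf("grid resolves the background wavelength at %.2f GHz with only %.1f cells",
                    fmax / 1e9, lam_min / dx))

  ant <- pos_to_cell(grid, antenna_positions(scn))
  if (source_index < 1 || source_index > nrow(ant))
    mwt_stop("source_index out of range")
  src <- ant[source_index, ]

  eps_max <- max(props$eps_inf + props$delta_eps)
  travel <- grid$nx * dx * sqrt(eps_max) / C0
  min_steps <- ceiling((pulse$delay + 4 * pulse$width + 2 * travel) / dt)
  max_steps <- config$max_steps %||% min(60000L, 8L * min_steps)

  t_half <- (seq_len(max_steps) - 0.5) * dt
  wave <- pulse_waveform(pulse, t_half)

  probe_ij <- rbind(ant, ref = c(src[1] + 1L, src[2]))
  cell_ij <- if (is.null(cells)) matrix(integer(0), 0, 2) else cells
  storage.mode(cell_ij) <- "integer"

  out <- fdtd_run_cpp(props$eps_inf, props$delta_eps, props$tau,
                      props$sigma_s, props$pec, dx, dt,
                      src[1], src[2], wave, freqs,
                      probe_ij, cell_ij,
                      as.integer(config$pml_cells), config$kappa_max,
                      config$alpha_max, config$sigma_factor,
                      as.integer(min_steps), as.integer(max_steps),
                      as.integer(config$check_every), config$conv_tol)
  if (out$diverged)
    mwt_stop("FDTD run diverged (field blow-up); reduce dt via the courant factor",
             class = "mwtomo_divergence")
  if (!out$converged)
    warning("FDTD run hit the step cap before the trailing field energy converged")

  np <- nrow(ant)
  structure(list(grid = grid, freqs = freqs,
                 probe = out$probe[seq_len(np), , drop = FALSE],
                 ref = out$probe[np + 1L, ],
                 cells = out$cells, cell_idx = cell_ij,
                 src_spectrum = out$src_spectrum,
                 steps = out$steps, converged = out$converged,
                 source_index = source_index, dt = dt),
            class = "dft_fieldset")
}

#' Export a fieldset's probe traces as CSV
#'
#' Writes the per-antenna complex probe phasors of a [run_fdtd()] result
#' as `freq_hz,antenna,re,im` rows.
#'
#' @param fs A `dft_fieldset`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_fieldset_csv <- function(fs, path) {
  stopifnot(inherits(fs, "dft_fieldset"))
  n <- nrow(fs$probe)
  df <- do.call(rbind, lapply(seq_along(fs$freqs), function(fi)
    data.frame(freq_hz = fs$freqs[fi], antenna = seq_len(n),
               re = sprintf("%.17g", Re(fs$probe[, fi])),
               im = sprintf("%.17g", Im(fs$probe[, fi])))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Received signal strength in dB per receiver
#'
#' `20 log10` of the complex transmission magnitude, referenced to the
#' field one cell from the source in the homogeneous background (recorded
#' at simulation time). Absolute port-calibrated S-parameter levels are
#' not reproduced by the 2-D model; only relative comparisons are
#' meaningful.
#'
#' @param x A `dft_fieldset` or a `multistatic_dataset`.
#' @param tx Transmitter index (for datasets).
#' @param freq Frequency in Hz (must be one of the stored frequencies).
#' @return Named numeric vector of dB values, one per receiver (the
#'   transmitter itself is excluded).
#' @export
received_signal_strength <- function(x, tx, freq) {
  UseMethod("received_signal_strength")
}

#' @export
received_signal_strength.dft_fieldset <- function(x, tx = x$source_index, freq) {
  fi <- match(freq, x$freqs)
  if (is.na(fi)) mwt_stop("freq not among the stored DFT frequencies")
  v <- x$probe[, fi]
  ref <- Mod(x$ref[fi])
  rx <- setdiff(seq_along(v), tx)
  out <- 20 * log10(Mod(v[rx]) / ref)
  names(out) <- paste0("rx", rx)
  out
}

#' @export
received_signal_strength.multistatic_dataset <- function(x, tx, freq) {
  df <- x$entries
  sel <- df$tx == tx & abs(df$freq_hz - freq) < 0.5
  if (!any(sel)) mwt_stop("no entries for the requested (tx, freq)")
  df <- df[sel, ]
  df <- df[order(df$rx), ]
  ref <- dataset_ref_amp(x, freq)
  out <- 20 * log10(Mod(complex(real = df$re, imaginary = df$im)) / ref)
  names(out) <- paste0("rx", df$rx)
  out
}
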