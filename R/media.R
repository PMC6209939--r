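#' Single-pole Debye medium
#'
#' Constructs a dispersive lossy material described by the single-pole Debye
#' law
#' \deqn{\epsilon(\omega) = \epsilon_\infty + \frac{\Delta\epsilon}{1 + j\omega\tau}
#'       - j\,\frac{\sigma_s}{\omega \epsilon_0}}
#' with the package-wide convention of \eqn{e^{+j\omega t}} time dependence,
#' so complex permittivity is \eqn{\epsilon' - j\epsilon''} with
#' \eqn{\epsilon'' \ge 0} for passive (lossy) media.
#'
#' @param eps_inf Relative permittivity at infinite frequency (>= 1).
#' @param delta_eps Dispersion strength \eqn{\Delta\epsilon} (>= 0).
#' @param tau Relaxation time in seconds (> 0).
#' @param sigma_s Static conductivity in S/m (>= 0).
#' @param name Optional material name.
#' @return An object of class `debye_medium`.
#' @examples
#' m <- debye_medium(eps_inf = 5, delta_eps = 10, tau = 35e-12, sigma_s = 0.7)
#' eval_debye(m, 1.2e9)
#' @export
debye_medium <- function(eps_inf, delta_eps, tau, sigma_s, name = NULL) {
  if (!is.numeric(eps_inf) || length(eps_inf) != 1 || eps_inf < 1)
    mwt_stop("eps_inf must be a scalar >= 1")
  if (!is.numeric(delta_eps) || length(delta_eps) != 1 || delta_eps < 0)
    mwt_stop("delta_eps must be a scalar >= 0")
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    mwt_stop("tau must be a scalar > 0 (seconds)")
  if (!is.numeric(sigma_s) || length(sigma_s) != 1 || sigma_s < 0)
    mwt_stop("sigma_s must be a scalar >= 0 (S/m)")
  structure(
    list(eps_inf = eps_inf, delta_eps = delta_eps, tau = tau,
         sigma_s = sigma_s, name = name),
    class = "debye_medium")
}

#' @export
print.debye_medium <- function(x, ...) {
  cat(sprintf("<debye_medium%s> eps_inf=%.4g  delta_eps=%.4g  tau=%.4g ps  sigma_s=%.4g S/m\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$eps_inf, x$delta_eps, x$tau * 1e12, x$sigma_s))
  invisible(x)
}

is_pec <- function(medium) is.character(medium) && length(medium) == 1 &&
  toupper(medium) == "PEC"

#' Evaluate a Debye medium at given frequencies
#'
#' @param medium A [debye_medium()].
#' @param freq Frequencies in Hz (> 0), vectorized.
#' @return Complex relative permittivity \eqn{\epsilon' - j\epsilon''}.
#' @export
eval_debye <- function(medium, freq) {
  stopifnot(inherits(medium, "debye_medium"))
  if (any(!is.finite(freq)) || any(freq <= 0))
    mwt_stop("freq must be positive and finite")
  w <- 2 * pi * freq
  medium$eps_inf + medium$delta_eps / (1 + 1i * w * medium$tau) -
    1i * medium$sigma_s / (w * EPS0)
}

#' Convert between the loss factor and conductivity conventions
#'
#' Bridges measured conductivity (S/m) and the imaginary permittivity
#' \eqn{\epsilon''} at a given frequency: \eqn{\sigma = \omega \epsilon_0 \epsilon''}.
#'
#' @param eps2 Imaginary relative permittivity (>= 0).
#' @param sigma Conductivity in S/m (>= 0).
#' @param freq Frequency in Hz (> 0).
#' @return Conductivity in S/m, or \eqn{\epsilon''} for the inverse.
#' @export
sigma_from_eps2 <- function(eps2, freq) {
  if (any(freq <= 0)) mwt_stop("freq must be > 0")
  if (any(eps2 < 0)) mwt_stop("eps2 must be >= 0")
  2 * pi * freq * EPS0 * eps2
}

#' @rdname sigma_from_eps2
#' @export
eps2_from_sigma <- function(sigma, freq) {
  if (any(freq <= 0)) mwt_stop("freq must be > 0")
  if (any(sigma < 0)) mwt_stop("sigma must be >= 0")
  sigma / (2 * pi * freq * EPS0)
}

#' Tabulated dispersion measurements
#'
#' A table of measured complex relative permittivity versus frequency, the
#' exchange format for fitting Debye models to dielectric-probe data.
#'
#' @param freqs Strictly increasing frequencies in Hz.
#' @param eps_complex Complex permittivities \eqn{\epsilon' - j\epsilon''};
#'   requires \eqn{\epsilon' \ge 1} and \eqn{\epsilon'' \ge 0}.
#' @return An object of class `dispersion_table`.
#' @export
dispersion_table <- function(freqs, eps_complex) {
  if (length(freqs) != length(eps_complex))
    mwt_stop("freqs and eps_complex must have the same length")
  if (any(diff(freqs) <= 0)) mwt_stop("freqs must be strictly increasing")
  if (any(freqs <= 0)) mwt_stop("freqs must be positive")
  eps_complex <- as.complex(eps_complex)
  if (any(Re(eps_complex) < 1)) mwt_stop("eps' must be >= 1")
  if (any(-Im(eps_complex) < -1e-12)) mwt_stop("eps'' must be >= 0 (loss convention eps' - j eps'')")
  structure(list(freqs = as.numeric(freqs), eps_complex = eps_complex),
            class = "dispersion_table")
}

#' Read / write dispersion tables as CSV
#'
#' CSV format: header `freq_hz,eps1,eps2` with `eps2 >= 0` the loss factor.
#' @param path File path.
#' @param table A [dispersion_table()].
#' @return `read_dispersion_csv` returns a [dispersion_table()].
#' @export
read_dispersion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("freq_hz", "eps1", "eps2")
  if (!all(need %in% names(df)))
    mwt_stop(paste("dispersion CSV must have columns", paste(need, collapse = ",")))
  dispersion_table(df$freq_hz, complex(real = df$eps1, imaginary = -df$eps2))
}

#' @rdname read_dispersion_csv
#' @export
write_dispersion_csv <- function(table, path) {
  stopifnot(inherits(table, "dispersion_table"))
  utils::write.csv(
    data.frame(freq_hz = table$freqs,
               eps1 = Re(table$eps_complex),
               eps2 = -Im(table$eps_complex)),
    path, row.names = FALSE)
  invisible(path)
}

#' Fit a single-pole Debye model to a dispersion table
#'
#' Bounded Levenberg–Marquardt least squares on the stacked real and
#' imaginary residuals, with a deterministic multi-start over relaxation
#' times (10, 20, 50, 100 ps) to avoid the Debye fit's local minima.
#'
#' @param table A [dispersion_table()] with at least 3 points spanning at
#'   least one octave.
#' @param weights Optional per-point weights (length = number of points).
#' @return A list of class `debye_fit`: `medium` (the fitted
#'   [debye_medium()]), `residuals` (per-point complex residual magnitude),
#'   `rel_residual` (residual norm / data norm), `tau_start` (the winning
#'   start), `converged`.
#' @export
fit_debye <- function(table, weights = NULL) {
  stopifnot(inherits(table, "dispersion_table"))
  n <- length(table$freqs)
  if (n < 3)
    mwt_stop("need at least 3 dispersion points", class = "mwtomo_insufficient_data")
  if (max(table$freqs) / min(table$freqs) < 2)
    mwt_stop("dispersion table must span at least one octave",
             class = "mwtomo_insufficient_data")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    mwt_stop("weights must be positive, one per point")

  w <- 2 * pi * table$freqs
  y <- table$eps_complex
  resid_fn <- function(p) {
    model <- p[1] + p[2] / (1 + 1i * w * p[3]) - 1i * p[4] / (w * EPS0)
    r <- (model - y) * weights
    c(Re(r), Im(r))
  }
  eps1 <- Re(y); eps2 <- -Im(y)
  lower <- c(1, 0, 1e-14, 0)
  upper <- c(100, 200, 1e-9, 50)
  best <- NULL
  for (tau0 in c(10e-12, 20e-12, 50e-12, 100e-12)) {
    p0 <- c(max(1, min(eps1) * 0.8),
            max(eps1) - min(eps1) + 1e-3,
            tau0,
            max(0, sigma_from_eps2(eps2[1], table$freqs[1]) * 0.5))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-15,
                                                              ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn)
      best <- list(fit = fit, rn = rn, tau_start = tau0)
  }
  if (is.null(best))
    mwt_stop("Debye fit failed to converge from all deterministic starts",
             class = "mwtomo_fit_failure")
  p <- best$fit$par
  medium <- debye_medium(p[1], p[2], p[3], p[4])
  model <- eval_debye(medium, table$freqs)
  res <- abs(model - y)
  rel <- sqrt(sum(res^2)) / sqrt(sum(abs(y)^2))
  converged <- best$fit$info %in% 1:4
  if (!converged && rel > 1e-3)
    mwt_stop(sprintf(
      "Debye fit did not converge (nls.lm info=%d, relative residual %.3g)",
      best$fit$info, rel), class = "mwtomo_fit_failure")
  structure(list(medium = medium, residuals = res, rel_residual = rel,
                 tau_start = best$tau_start, converged = converged),
            class = "debye_fit")
}

#' Construct a Debye medium anchored to one measured complex permittivity
#'
#' Given a measured \eqn{(\epsilon', \epsilon'')} at a single frequency and
#' assumed \eqn{\epsilon_\infty} and \eqn{\tau}, solves \eqn{\Delta\epsilon}
#' and \eqn{\sigma_s} so the medium reproduces the anchor exactly. Used for
#' the shipped material library, whose dispersion away from the anchor is a
#' documented modelling assumption rather than a measurement.
#'
#' @param eps1,eps2 Real and (positive) imaginary relative permittivity.
#' @param freq Anchor frequency in Hz.
#' @param eps_inf Assumed infinite-frequency permittivity.
#' @param tau Assumed relaxation time (s).
#' @inheritParams debye_medium
#' @return A [debye_medium()].
#' @export
debye_from_anchor <- function(eps1, eps2, freq, eps_inf, tau, name = NULL) {
  if (eps1 < eps_inf) mwt_stop("anchor eps1 must be >= eps_inf")
  w <- 2 * pi * freq
  D <- 1 + (w * tau)^2
  delta_eps <- (eps1 - eps_inf) * D
  eps2_pole <- delta_eps * w * tau / D
  if (eps2 < eps2_pole)
    mwt_stop("anchor eps2 smaller than the Debye pole's own loss; decrease tau or eps_inf")
  sigma_s <- w * EPS0 * (eps2 - eps2_pole)
  debye_medium(eps_inf, delta_eps, tau, sigma_s, name = name)
}

#' Shipped material library
#'
#' Loads the package's material library (JSON keyed by material name). Each
#' entry anchors to a measured complex permittivity at one frequency
#' (1.2 GHz for the shipped immersion/target liquids) with assumed
#' \eqn{\epsilon_\infty} and \eqn{\tau}; only the anchor values are measured
#' ground truth.
#'
#' @param path Optional path to an alternative library JSON.
#' @return Named list of [debye_medium()] objects.
#' @export
material_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.json", package = "mwtomo")
  lib <- jsonlite::read_json(path)
  out <- lapply(names(lib), function(nm) {
    e <- lib[[nm]]
    debye_from_anchor(e$anchor_eps1, e$anchor_eps2, e$anchor_freq_hz,
                      e$eps_inf, e$tau_ps * 1e-12, name = nm)
  })
  names(out) <- names(lib)
  out
}

#' @rdname material_library
#' @param name Material name, e.g. `"glycerine90"`, `"water"`, `"saltwater10"`.
#' @export
get_material <- function(name, path = NULL) {
  lib <- material_library(path)
  if (!name %in% names(lib))
    mwt_stop(sprintf("unknown material '%s' (have: %s)", name,
                     paste(names(lib), collapse = ", ")))
  lib[[name]]
}
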